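## Deterministic synthetic model fixtures for exercising grading, pairing and
## propagation without external data.

#' Generate a synthetic metabolite/reaction fixture
#'
#' Builds `n_acyl` acyl chain families (each at least one double bond so every
#' annotation grade is realizable), emitting per family a free acid, an
#' acyl-CoA and an acyl-carnitine connected by activation and
#' carnitine-transfer reactions (hub cofactors included), a transport reaction,
#' plus beta-oxidation links between families whose chains differ by two
#' carbons. Annotation completeness is controlled by the fractions:
#' `frac_full` of the species are fully specified (half of those additionally
#' carry an InChIKey xref), `frac_partial` miss only a minor stereo item
#' (carnitine base stereo, or a 3-hydroxy stereo letter), and the rest miss
#' double-bond positions entirely. Deterministic for a fixed seed; the global
#' RNG state is restored on exit.
#'
#' @param seed Integer seed (below 2^31).
#' @param n_acyl Number of chain families (default 20).
#' @param frac_full,frac_partial,frac_none Fractions summing to 1.
#' @return List: `metabolites` (list of [metabolite_record()]), `reactions`
#'   (list of [reaction()]), `species` (named list id -> parsed
#'   [acyl_species()] skeleton), `grades` (named list id ->
#'   [structural_grade()], as computed by [grade_record()]).
#' @export
generate_fixture_model <- function(seed, n_acyl = 20, frac_full = 0.5,
                                   frac_partial = 0.25, frac_none = 0.25) {
  fr <- c(frac_full, frac_partial, frac_none)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  }
  if (n_acyl < 1) stop("n_acyl must be positive", call. = FALSE)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  ## one family per unique (carbons, double-bond count) so generated ids never
  ## collide even when double-bond positions are dropped for the "none" grade
  db_pool <- c(5L, 8L, 9L, 11L, 12L, 15L)
  combos <- expand.grid(carbons = seq(8L, 26L, by = 2L), ndb = 1:3)
  combos <- combos[vapply(seq_len(nrow(combos)), function(i)
    sum(db_pool <= combos$carbons[i] - 2L) >= combos$ndb[i], logical(1)), ]
  if (n_acyl > nrow(combos)) {
    stop("n_acyl too large (at most ", nrow(combos),
         " distinct chain families)", call. = FALSE)
  }
  picks <- combos[sample(nrow(combos), n_acyl), , drop = FALSE]
  families <- lapply(seq_len(n_acyl), function(i) {
    carbons <- picks$carbons[i]
    eligible <- db_pool[db_pool <= carbons - 2L]
    pos <- sort(eligible[sample.int(length(eligible), picks$ndb[i])])
    acyl_species("fa", carbons,
                 double_bonds = lapply(pos, double_bond, geometry = "Z"))
  })

  metabolites <- list()
  species_map <- list()
  reactions <- list()
  n_sp <- 3L * n_acyl
  cuts <- diff(c(0L, round(cumsum(fr) * n_sp)))
  qualities <- sample(rep(c("full", "partial", "none"), times = cuts))

  add_met <- function(sp, quality, compartment) {
    with_key <- runif(1) < 0.5
    if (quality == "none") {
      sp$double_bonds <- list()  # count kept, positions unknown
    } else if (quality == "partial") {
      if (sp$acyl_class == "carn") {
        sp$base_stereo <- NA_character_
      } else {
        sp <- add_group(sp, "OH", 3L)  # 3-hydroxy without a stereo letter
      }
    } else if (sp$acyl_class == "carn") {
      sp$base_stereo <- "L"
    }
    id <- paste0(to_model_id(sp, stereo_style = "suffix"), "_", compartment)
    xrefs <- if (quality == "full" && with_key) {
      list(InChIKey = paste0("FIXTUREKEY", sprintf("%04d", length(metabolites))))
    } else list()
    name <- if (quality == "none") {
      sprintf("%s (%d:%d)", sp$acyl_class, sp$carbons, sp$n_double_bonds)
    } else format_shorthand(sp)
    metabolites[[length(metabolites) + 1L]] <<- metabolite_record(
      id = id, name = name, compartment = compartment, xrefs = xrefs)
    species_map[[id]] <<- sp
    id
  }

  qi <- 0L
  next_quality <- function() { qi <<- qi + 1L; qualities[qi] }

  fa_ids <- coa_ids <- character(n_acyl)
  for (i in seq_len(n_acyl)) {
    base <- families[[i]]
    fa_id <- add_met(base, next_quality(), "c")
    coa_id <- add_met(with_class(base, "coa"), next_quality(), "c")
    carn_id <- add_met(with_class(base, "carn", base_stereo = "L"),
                       next_quality(), "c")
    fa_ids[i] <- fa_id; coa_ids[i] <- coa_id

    reactions[[length(reactions) + 1L]] <- reaction(
      sprintf("FIX_ACT_%d", i),
      stats::setNames(c(-1, -1, -1, 1, 1, 1),
                      c(fa_id, "atp_c", "coa_c", coa_id, "amp_c", "ppi_c")),
      compartment = "c", step = "activate")
    reactions[[length(reactions) + 1L]] <- reaction(
      sprintf("FIX_CAT_%d", i),
      stats::setNames(c(-1, -1, 1, 1),
                      c(coa_id, "crn__L_c", carn_id, "coa_c")),
      compartment = "c", step = "cpt1")
    reactions[[length(reactions) + 1L]] <- reaction(
      sprintf("FIX_T_%d", i),
      stats::setNames(c(-1, 1), c(fa_id, sub("_c$", "_m", fa_id))),
      reversible = TRUE, is_transport = TRUE, compartment = c("c", "m"),
      step = "transport")
  }

  ## beta-oxidation links between families differing by one C2 unit with the
  ## same double-bond count (pair-network edges across chain lengths)
  for (i in seq_len(n_acyl)) {
    for (j in seq_len(n_acyl)) {
      if (i == j) next
      si <- families[[i]]; sj <- families[[j]]
      shifted <- vapply(si$double_bonds, function(d) d$position - 2L,
                        integer(1))
      pj <- vapply(sj$double_bonds, function(d) d$position, integer(1))
      if (sj$carbons == si$carbons - 2L && identical(sort(shifted), sort(pj))) {
        reactions[[length(reactions) + 1L]] <- reaction(
          sprintf("FIX_BOX_%d_%d", i, j),
          stats::setNames(c(-1, -1, 1, 1),
                          c(coa_ids[i], "coa_c", coa_ids[j], "accoa_c")),
          compartment = "c", step = "betaox_lumped")
        break
      }
    }
  }

  grades <- list()
  for (m in metabolites) {
    grades[[m$id]] <- grade_record(m, parsed = species_map[[m$id]])
  }
  list(metabolites = metabolites, reactions = reactions,
       species = species_map, grades = grades)
}
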