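## Template-based generation of fully detailed, mass- and charge-balanced
## fatty-acid reactions: FAS cycles, ER elongation/desaturation, mitochondrial
## and peroxisomal beta-oxidation (incl. unsaturated handling), carnitine
## shuttle, activation and diffusion, plus a lumping operator.

COMPARTMENTS <- c("c", "m", "x", "r")  # cytosol, mitochondrion, peroxisome, ER

## ---- species helpers -------------------------------------------------------

total_carbons <- function(species) {
  species$carbons +
    sum(vapply(species$groups, function(g) g$kind == "Me", logical(1)))
}

is_iso_branched <- function(species) {
  any(vapply(species$groups, function(g)
    g$kind == "Me" && g$position == species$carbons - 1L, logical(1)))
}

## shift every positional descriptor by `by` carbons (chain grows/shrinks at
## the carboxyl end)
shift_positions <- function(species, by) {
  species$double_bonds <- lapply(species$double_bonds, function(d) {
    d$position <- d$position + as.integer(by); d
  })
  species$groups <- lapply(species$groups, function(g) {
    g$position <- g$position + as.integer(by); g
  })
  species
}

with_class <- function(species, cls, base_stereo = NA_character_) {
  species$acyl_class <- cls
  species$base_stereo <- if (cls %in% CLASSES_WITH_BASE_STEREO) base_stereo
                         else NA_character_
  species
}

add_group <- function(species, kind, position, stereo = NA_character_) {
  species$groups <- c(species$groups,
                      list(functional_group(kind, position, stereo)))
  canonical_order(species)
}

drop_group <- function(species, kind, position) {
  keep <- vapply(species$groups, function(g)
    !(g$kind == kind && g$position == position), logical(1))
  species$groups <- species$groups[keep]
  species
}

add_db <- function(species, position, geometry) {
  species$double_bonds <- c(species$double_bonds,
                            list(double_bond(position, geometry)))
  species$n_double_bonds <- species$n_double_bonds + 1L
  canonical_order(species)
}

drop_db <- function(species, position) {
  keep <- vapply(species$double_bonds, function(d)
    d$position != position, logical(1))
  stopifnot(sum(!keep) == 1L)
  species$double_bonds <- species$double_bonds[keep]
  species$n_double_bonds <- species$n_double_bonds - 1L
  species
}

db_at <- function(species, position) {
  for (d in species$double_bonds) {
    if (d$position == position) return(d)
  }
  NULL
}

## grow the chain by two carbons at the carboxyl end
elongate2 <- function(species) {
  species <- shift_positions(species, 2L)
  species$carbons <- species$carbons + 2L
  species
}

## shorten by two carbons (after thiolysis)
shorten2 <- function(species) {
  species$carbons <- species$carbons - 2L
  shift_positions(species, -2L)
}

## Model id of a species within a compartment. Acetyl- and propionyl-CoA get
## their conventional cofactor ids so generated reactions join the rest of a
## model's namespace.
acyl_id <- function(species, compartment, stereo_style = "suffix") {
  core <- if (species$acyl_class == "coa" && length(species$groups) == 0L &&
              species$n_double_bonds == 0L && species$carbons <= 3L) {
    c("accoa", "ppcoa")[species$carbons - 1L]
  } else {
    to_model_id(species, stereo_style = stereo_style)
  }
  paste0(core, "_", compartment)
}

## ---- reaction assembly -----------------------------------------------------

## build a reaction from a draft stoichiometry, proton-balance it in
## `compartment`, and assert full balance
make_balanced <- function(id, stoich, compartment, step,
                          reversible = FALSE, is_transport = FALSE) {
  r <- reaction(id, stoich, reversible = reversible,
                is_transport = is_transport, compartment = compartment,
                step = step)
  r <- proton_balance(r, compartment)
  stopifnot(is_balanced(r))
  r
}

cof <- function(name, compartment) paste0(name, "_", compartment)

## ---- fatty-acid synthesis (ACP-based) --------------------------------------

#' Generate a detailed fatty-acid synthase reaction set
#'
#' Emits the full per-cycle chemistry of FAS on the acyl-carrier protein:
#' malonyl transacylase loading (`load`), ketoacyl synthase condensation
#' (`condense`; the first cycle condenses the acyl-CoA primer directly with
#' malonyl-ACP, as ketoacyl synthase III does for acetyl and branched-chain
#' primers, so no primer transacylase is required), NADPH 3-keto reduction
#' (`reduce1`), 3-hydroxyacyl dehydration to the 2E-enoyl (`dehydrate`) and
#' NADPH enoyl reduction (`reduce2`) -- five reactions per two-carbon cycle --
#' followed, when `release = TRUE`, by a terminal thioesterase (`release`)
#' hydrolysing the product to the free acid. Every reaction is mass- and
#' charge-balanced.
#'
#' @param primer An [acyl_species()] of class `coa` (e.g. acetyl-CoA, or
#'   isovaleryl-CoA for iso-branched products).
#' @param product_length Total carbon count of the product (longest chain plus
#'   methyl branches); must exceed the primer's by a positive even number.
#' @param compartment `"c"` or `"m"`.
#' @param release Emit the terminal thioesterase (default `TRUE`).
#' @param stereo_style Identifier dialect for intermediates (default
#'   `"suffix"`, the dialect used in curated model tables).
#' @param synthesis_3oh_stereo Stereo letter of the 3-hydroxyacyl-ACP
#'   intermediates (default `"R"`, standard FAS stereochemistry); `NA` to omit.
#' @return List of [reaction()]s with step labels.
#' @export
generate_fas <- function(primer, product_length, compartment = "c",
                         release = TRUE, stereo_style = "suffix",
                         synthesis_3oh_stereo = "R") {
  stopifnot(inherits(primer, "acyl_species"))
  if (primer$acyl_class != "coa") {
    stop("FAS primer must be an acyl-CoA species", call. = FALSE)
  }
  if (!compartment %in% COMPARTMENTS) stop("unknown compartment", call. = FALSE)
  ext <- product_length - total_carbons(primer)
  if (ext <= 0) stop("product_length must exceed the primer carbon count",
                     call. = FALSE)
  if (ext %% 2L != 0L) stop("chain extension must be an even number of carbons",
                            call. = FALSE)
  n_cycles <- ext %/% 2L

  k <- compartment
  prefix <- sprintf("FAS_%s_%s", to_model_id(primer_product_tag(
    primer, product_length), stereo_style = stereo_style), k)
  out <- list()
  cur <- primer  # acyl carried as CoA (cycle 1) then ACP

  for (i in seq_len(n_cycles)) {
    idc <- function(step) sprintf("%s_c%d_%s", prefix, i, step)
    ## malonyl transacylase
    out <- c(out, list(make_balanced(idc("load"), c(
      stats::setNames(-1, cof("malcoa", k)), stats::setNames(-1, cof("acp", k)),
      stats::setNames(+1, cof("malacp", k)), stats::setNames(+1, cof("coa", k))
    ), k, "load")))

    ## condensation: +2 carbons, -CO2; releases CoA (cycle 1, from the
    ## primer thioester) or holo-ACP (later cycles)
    keto <- add_group(elongate2(cur), "O", 3L)
    keto_acp <- with_class(keto, "acp")
    donor_id <- if (i == 1L) acyl_id(cur, k, stereo_style)
                else acyl_id(with_class(cur, "acp"), k, stereo_style)
    freed <- if (i == 1L) cof("coa", k) else cof("acp", k)
    out <- c(out, list(make_balanced(idc("condense"), c(
      stats::setNames(-1, donor_id), stats::setNames(-1, cof("malacp", k)),
      stats::setNames(+1, acyl_id(keto_acp, k, stereo_style)),
      stats::setNames(+1, freed), stats::setNames(+1, cof("co2", k))
    ), k, "condense")))

    ## 3-keto reduction (NADPH)
    oh_acp <- add_group(drop_group(keto_acp, "O", 3L), "OH", 3L,
                        synthesis_3oh_stereo)
    out <- c(out, list(make_balanced(idc("reduce1"), c(
      stats::setNames(-1, acyl_id(keto_acp, k, stereo_style)),
      stats::setNames(-1, cof("nadph", k)),
      stats::setNames(+1, acyl_id(oh_acp, k, stereo_style)),
      stats::setNames(+1, cof("nadp", k))
    ), k, "reduce1")))

    ## dehydration to the 2E-enoyl
    enoyl_acp <- add_db(drop_group(oh_acp, "OH", 3L), 2L, "E")
    out <- c(out, list(make_balanced(idc("dehydrate"), c(
      stats::setNames(-1, acyl_id(oh_acp, k, stereo_style)),
      stats::setNames(+1, acyl_id(enoyl_acp, k, stereo_style)),
      stats::setNames(+1, cof("h2o", k))
    ), k, "dehydrate")))

    ## enoyl reduction (NADPH)
    sat_acp <- drop_db(enoyl_acp, 2L)
    out <- c(out, list(make_balanced(idc("reduce2"), c(
      stats::setNames(-1, acyl_id(enoyl_acp, k, stereo_style)),
      stats::setNames(-1, cof("nadph", k)),
      stats::setNames(+1, acyl_id(sat_acp, k, stereo_style)),
      stats::setNames(+1, cof("nadp", k))
    ), k, "reduce2")))

    cur <- with_class(sat_acp, "coa")  # class re-tagged per cycle arithmetic
  }

  if (release) {
    acyl_acp <- with_class(cur, "acp")
    fa <- with_class(cur, "fa")
    out <- c(out, list(make_balanced(sprintf("%s_release", prefix), c(
      stats::setNames(-1, acyl_id(acyl_acp, k, stereo_style)),
      stats::setNames(-1, cof("h2o", k)),
      stats::setNames(+1, acyl_id(fa, k, stereo_style)),
      stats::setNames(+1, cof("acp", k))
    ), k, "release")))
  }
  out
}

## species describing the FAS product, used only for naming the reaction set
primer_product_tag <- function(primer, product_length) {
  s <- primer
  while (total_carbons(s) < product_length) s <- elongate2(s)
  with_class(s, "fa")
}

## ---- ER elongation and desaturation ----------------------------------------

#' Generate ER elongation cycles on an acyl-CoA
#'
#' Each two-carbon cycle: elongase condensation with malonyl-CoA (releasing
#' CoA and CO2), NADPH 3-keto reduction, dehydration to the 2E-enoyl and NADPH
#' enoyl reduction -- four reactions consuming exactly one malonyl-CoA and two
#' NADPH per C2. Existing double-bond positions shift by +2 per cycle
#' (16:1(9Z) elongates to 18:1(11Z), vaccenoyl-CoA). A zero-cycle request
#' returns an empty list.
#'
#' @param start An [acyl_species()] of class `coa`.
#' @param end_length Total carbon count of the product.
#' @param compartment Default `"r"` (endoplasmic reticulum).
#' @inheritParams generate_fas
#' @return List of [reaction()]s.
#' @export
generate_elongation <- function(start, end_length, compartment = "r",
                                stereo_style = "suffix",
                                synthesis_3oh_stereo = "R") {
  stopifnot(inherits(start, "acyl_species"))
  if (start$acyl_class != "coa") {
    stop("elongation operates on acyl-CoA species", call. = FALSE)
  }
  ext <- end_length - total_carbons(start)
  if (ext == 0) return(list())
  if (ext < 0) stop("end_length below the start carbon count", call. = FALSE)
  if (ext %% 2L != 0L) stop("chain extension must be even", call. = FALSE)

  k <- compartment
  out <- list()
  cur <- start
  for (i in seq_len(ext %/% 2L)) {
    idc <- function(step) sprintf("ELO_%s_%s_c%d_%s",
                                  to_model_id(start, stereo_style), k, i, step)
    keto <- add_group(elongate2(cur), "O", 3L)
    out <- c(out, list(make_balanced(idc("condense"), c(
      stats::setNames(-1, acyl_id(cur, k, stereo_style)),
      stats::setNames(-1, cof("malcoa", k)),
      stats::setNames(+1, acyl_id(keto, k, stereo_style)),
      stats::setNames(+1, cof("coa", k)), stats::setNames(+1, cof("co2", k))
    ), k, "condense")))

    oh <- add_group(drop_group(keto, "O", 3L), "OH", 3L, synthesis_3oh_stereo)
    out <- c(out, list(make_balanced(idc("reduce1"), c(
      stats::setNames(-1, acyl_id(keto, k, stereo_style)),
      stats::setNames(-1, cof("nadph", k)),
      stats::setNames(+1, acyl_id(oh, k, stereo_style)),
      stats::setNames(+1, cof("nadp", k))
    ), k, "reduce1")))

    enoyl <- add_db(drop_group(oh, "OH", 3L), 2L, "E")
    out <- c(out, list(make_balanced(idc("dehydrate"), c(
      stats::setNames(-1, acyl_id(oh, k, stereo_style)),
      stats::setNames(+1, acyl_id(enoyl, k, stereo_style)),
      stats::setNames(+1, cof("h2o", k))
    ), k, "dehydrate")))

    cur <- drop_db(enoyl, 2L)
    out <- c(out, list(make_balanced(idc("reduce2"), c(
      stats::setNames(-1, acyl_id(enoyl, k, stereo_style)),
      stats::setNames(-1, cof("nadph", k)),
      stats::setNames(+1, acyl_id(cur, k, stereo_style)),
      stats::setNames(+1, cof("nadp", k))
    ), k, "reduce2")))
  }
  out
}

#' Generate a fatty acyl-CoA desaturation reaction
#'
#' One oxygen-dependent desaturase step introducing a double bond at the given
#' position: acyl-CoA + O2 + NADH + H+ -> acyl-CoA(+DB) + NAD+ + 2 H2O.
#'
#' @param substrate An [acyl_species()] of class `coa` with no double bond at
#'   `position`.
#' @param position,geometry Double bond to introduce.
#' @param compartment Default `"r"`.
#' @inheritParams generate_fas
#' @return A single [reaction()] (in a list of length one).
#' @export
generate_desaturation <- function(substrate, position, geometry = "Z",
                                  compartment = "r", stereo_style = "suffix") {
  stopifnot(inherits(substrate, "acyl_species"))
  if (!is.null(db_at(substrate, position))) {
    stop("double bond already present at position ", position, call. = FALSE)
  }
  k <- compartment
  product <- add_db(substrate, as.integer(position), geometry)
  id <- sprintf("DES_%s_d%d%s_%s", to_model_id(substrate, stereo_style),
                as.integer(position), tolower(geometry), k)
  list(make_balanced(id, c(
    stats::setNames(-1, acyl_id(substrate, k, stereo_style)),
    stats::setNames(-1, cof("o2", k)), stats::setNames(-1, cof("nadh", k)),
    stats::setNames(+1, acyl_id(product, k, stereo_style)),
    stats::setNames(+1, cof("nad", k)), stats::setNames(+2, cof("h2o", k))
  ), k, "desaturate"))
}

## ---- beta-oxidation ---------------------------------------------------------

#' Generate a beta-oxidation reaction sequence
#'
#' Repeats the canonical cycle -- acyl-CoA dehydrogenation to the 2E-enoyl
#' (FAD in mitochondria; O2 to H2O2 in peroxisomes), 2-enoyl hydration to the
#' (S)-3-hydroxy, NAD+ oxidation to the 3-keto, and thiolysis releasing
#' acetyl-CoA and the chain shortened by two carbons with every double-bond
#' position shifted by -2 -- with the auxiliary chemistry for unsaturated
#' chains: a cis double bond reaching position 3 is handled by
#' enoyl-CoA isomerase (Delta3 -> Delta2-trans) instead of dehydrogenation,
#' and a double bond at position 4 coexisting with the 2-trans intermediate
#' triggers 2,4-dienoyl-CoA reductase (NADPH, yielding the 3E-enoyl) followed
#' by the isomerase. Straight even chains terminate at acetyl-CoA, odd chains
#' at propionyl-CoA, and iso-branched chains at isovaleryl-CoA (handed to
#' branched-chain catabolism).
#'
#' The sequence stops as soon as a produced species already occurs in `known`
#' (an id set accumulated over previously generated sequences): this is where
#' an unsaturated pathway merges into the saturated network, e.g. oleoyl-CoA
#' degradation ends at 2E-dodecenoyl-CoA, an intermediate of saturated C12
#' oxidation.
#'
#' @param species An [acyl_species()] of class `coa`, fully specified,
#'   at least 4 carbons.
#' @param compartment `"m"` (mitochondrion) or `"x"` (peroxisome).
#' @param known Character vector of already-present species ids (with
#'   compartment tags); used for merge termination.
#' @inheritParams generate_fas
#' @return List of [reaction()]s; attribute `"species"` lists every acyl
#'   species id visited (for accumulating `known`), attribute `"terminal"`
#'   the id the sequence ended on.
#' @export
generate_beta_oxidation <- function(species, compartment = "m",
                                    known = character(0),
                                    stereo_style = "suffix") {
  stopifnot(inherits(species, "acyl_species"))
  if (species$acyl_class != "coa") {
    stop("beta-oxidation operates on acyl-CoA species", call. = FALSE)
  }
  if (!is_complete(species)) {
    stop("under-specified double bonds: cannot generate chemistry",
         call. = FALSE)
  }
  if (species$carbons < 4L) stop("chain too short (need >= 4 carbons)",
                                 call. = FALSE)
  if (!compartment %in% c("m", "x")) {
    stop("beta-oxidation compartment must be 'm' or 'x'", call. = FALSE)
  }
  k <- compartment
  sid <- function(s) acyl_id(s, k, stereo_style)
  out <- list()
  visited <- character(0)
  cur <- species
  merged <- FALSE
  cyc <- 0L
  base <- sprintf("BOX_%s_%s", to_model_id(species, stereo_style), k)

  ## emit one reaction; returns TRUE when the sequence should stop (product
  ## known from an earlier sequence)
  emit <- function(step, stoich, product_id) {
    id <- sprintf("%s_c%d_%s", base, cyc, step)
    out[[length(out) + 1L]] <<- make_balanced(id, stoich, k, step)
    if (product_id %in% known) return(TRUE)
    known <<- c(known, product_id)
    visited <<- c(visited, product_id)
    FALSE
  }

  can_cycle <- function(s) {
    if (is_iso_branched(s) && total_carbons(s) <= 5L) return(FALSE)
    s$carbons >= 4L && !(total_carbons(s) == 3L)
  }

  known <- c(known, sid(cur))
  visited <- c(visited, sid(cur))

  while (can_cycle(cur) && !merged) {
    cyc <- cyc + 1L
    db2 <- db_at(cur, 2L); db3 <- db_at(cur, 3L)

    if (!is.null(db3)) {
      ## Delta3 -> Delta2-trans isomerase replaces dehydrogenation
      nxt <- add_db(drop_db(cur, 3L), 2L, "E")
      merged <- emit("isomerize", c(
        stats::setNames(-1, sid(cur)), stats::setNames(+1, sid(nxt))
      ), sid(nxt))
      cur <- nxt
      if (merged) break
    } else if (is.null(db2)) {
      ## dehydrogenation to the 2E-enoyl
      nxt <- add_db(cur, 2L, "E")
      stoich <- if (k == "m") c(
        stats::setNames(-1, sid(cur)), stats::setNames(-1, cof("fad", k)),
        stats::setNames(+1, sid(nxt)), stats::setNames(+1, cof("fadh2", k))
      ) else c(
        stats::setNames(-1, sid(cur)), stats::setNames(-1, cof("o2", k)),
        stats::setNames(+1, sid(nxt)), stats::setNames(+1, cof("h2o2", k))
      )
      merged <- emit("dehydrogenate", stoich, sid(nxt))
      cur <- nxt
      if (merged) break

      if (!is.null(db_at(cur, 4L))) {
        ## 2,4-dienoyl: NADPH reductase to the 3E-enoyl, then isomerase
        nxt <- add_db(drop_db(drop_db(cur, 2L), 4L), 3L, "E")
        merged <- emit("dienoyl_reduce", c(
          stats::setNames(-1, sid(cur)), stats::setNames(-1, cof("nadph", k)),
          stats::setNames(+1, sid(nxt)), stats::setNames(+1, cof("nadp", k))
        ), sid(nxt))
        cur <- nxt
        if (merged) break
        nxt <- add_db(drop_db(cur, 3L), 2L, "E")
        merged <- emit("isomerize", c(
          stats::setNames(-1, sid(cur)), stats::setNames(+1, sid(nxt))
        ), sid(nxt))
        cur <- nxt
        if (merged) break
      }
    }
    ## cur now carries the 2E-enoyl

    ## hydration to the (S)-3-hydroxy
    nxt <- add_group(drop_db(cur, 2L), "OH", 3L, "S")
    merged <- emit("hydrate", c(
      stats::setNames(-1, sid(cur)), stats::setNames(-1, cof("h2o", k)),
      stats::setNames(+1, sid(nxt))
    ), sid(nxt))
    cur <- nxt
    if (merged) break

    ## NAD+ oxidation to the 3-keto
    nxt <- add_group(drop_group(cur, "OH", 3L), "O", 3L)
    merged <- emit("oxidize3oh", c(
      stats::setNames(-1, sid(cur)), stats::setNames(-1, cof("nad", k)),
      stats::setNames(+1, sid(nxt)), stats::setNames(+1, cof("nadh", k))
    ), sid(nxt))
    cur <- nxt
    if (merged) break

    ## thiolysis: acetyl-CoA off, chain -2
    nxt <- shorten2(drop_group(cur, "O", 3L))
    merged <- emit("thiolyze", c(
      stats::setNames(-1, sid(cur)), stats::setNames(-1, cof("coa", k)),
      stats::setNames(+1, sid(nxt)), stats::setNames(+1, cof("accoa", k))
    ), sid(nxt))
    cur <- nxt
  }

  structure(out, species = visited, terminal = sid(cur))
}

## ---- carnitine shuttle, activation, diffusion ------------------------------

#' Generate the three carnitine-shuttle reactions for an acyl-CoA
#'
#' Cytosolic acyl transfer to L-carnitine (CPT1), carnitine/acyl-carnitine
#' antiport across the inner mitochondrial membrane (a transport reaction),
#' and mitochondrial re-transfer to CoA (CPT2). All carnitine species carry
#' the `__L` stereo suffix: models use free L-carnitine and the stereocenter
#' is preserved.
#'
#' @param species An [acyl_species()] of class `coa`.
#' @inheritParams generate_fas
#' @return List of exactly three [reaction()]s.
#' @export
generate_carnitine_shuttle <- function(species, stereo_style = "suffix") {
  stopifnot(inherits(species, "acyl_species"))
  if (species$acyl_class != "coa") {
    stop("carnitine shuttle operates on acyl-CoA species", call. = FALSE)
  }
  carn <- with_class(species, "carn", base_stereo = "L")
  core <- to_model_id(species, stereo_style)
  r1 <- make_balanced(sprintf("CSHUT_%s_cpt1", core), c(
    stats::setNames(-1, acyl_id(species, "c", stereo_style)),
    stats::setNames(-1, "crn__L_c"),
    stats::setNames(+1, acyl_id(carn, "c", stereo_style)),
    stats::setNames(+1, "coa_c")
  ), "c", "cpt1")
  r2 <- reaction(sprintf("CSHUT_%s_tl", core), c(
    stats::setNames(-1, acyl_id(carn, "c", stereo_style)),
    stats::setNames(-1, "crn__L_m"),
    stats::setNames(+1, acyl_id(carn, "m", stereo_style)),
    stats::setNames(+1, "crn__L_c")
  ), reversible = TRUE, is_transport = TRUE, compartment = c("c", "m"),
  step = "translocate")
  stopifnot(is_balanced(r2))
  r3 <- make_balanced(sprintf("CSHUT_%s_cpt2", core), c(
    stats::setNames(-1, acyl_id(carn, "m", stereo_style)),
    stats::setNames(-1, "coa_m"),
    stats::setNames(+1, acyl_id(species, "m", stereo_style)),
    stats::setNames(+1, "crn__L_m")
  ), "m", "cpt2")
  list(r1, r2, r3)
}

#' Generate an ATP-dependent fatty-acid activation reaction
#'
#' Acyl-CoA synthetase: FA + ATP + CoA -> acyl-CoA + AMP + PPi.
#'
#' @param species An [acyl_species()] of class `fa`.
#' @param compartment Compartment tag.
#' @inheritParams generate_fas
#' @return A single [reaction()] (in a list of length one).
#' @export
generate_activation <- function(species, compartment = "c",
                                stereo_style = "suffix") {
  stopifnot(inherits(species, "acyl_species"))
  if (species$acyl_class != "fa") {
    stop("activation operates on free fatty acids", call. = FALSE)
  }
  k <- compartment
  coa_sp <- with_class(species, "coa")
  list(make_balanced(
    sprintf("FACOAL_%s_%s", to_model_id(species, stereo_style), k), c(
      stats::setNames(-1, acyl_id(species, k, stereo_style)),
      stats::setNames(-1, cof("atp", k)), stats::setNames(-1, cof("coa", k)),
      stats::setNames(+1, acyl_id(coa_sp, k, stereo_style)),
      stats::setNames(+1, cof("amp", k)), stats::setNames(+1, cof("ppi", k))
    ), k, "activate"))
}

#' Generate a fatty-acid diffusion (transport) reaction
#'
#' One reversible transport reaction FA_c <-> FA_m, flagged `is_transport` so
#' pair extraction skips it.
#'
#' @param species An [acyl_species()] of class `fa`.
#' @inheritParams generate_fas
#' @return A single [reaction()] (in a list of length one).
#' @export
generate_diffusion <- function(species, stereo_style = "suffix") {
  stopifnot(inherits(species, "acyl_species"))
  if (species$acyl_class != "fa") {
    stop("diffusion template is for free fatty acids", call. = FALSE)
  }
  r <- reaction(
    sprintf("FADIFF_%s", to_model_id(species, stereo_style)), c(
      stats::setNames(-1, acyl_id(species, "c", stereo_style)),
      stats::setNames(+1, acyl_id(species, "m", stereo_style))
    ), reversible = TRUE, is_transport = TRUE, compartment = c("c", "m"),
    step = "diffuse")
  list(r)
}

## ---- lumping ----------------------------------------------------------------

#' Lump a detailed reaction set into its net reaction
#'
#' Sums stoichiometries over the set. Species in `keep` stay regardless of
#' their net coefficient; any other species must cancel exactly -- a nonzero
#' net coefficient on a non-kept intermediate means the pathway is incomplete
#' and raises an error naming it. The result is balanced whenever the inputs
#' are.
#'
#' @param reactions List of [reaction()]s.
#' @param keep Character vector of species ids to retain (cofactors,
#'   primer/substrates, products).
#' @param id Identifier for the lumped reaction.
#' @return A single [reaction()].
#' @export
lump <- function(reactions, keep, id = "lumped") {
  stopifnot(length(reactions) >= 1L)
  acc <- numeric(0)
  for (r in reactions) {
    for (sp in names(r$stoichiometry)) {
      acc[sp] <- sum(acc[sp], r$stoichiometry[[sp]], na.rm = TRUE)
    }
  }
  residual <- acc[!(names(acc) %in% keep) & abs(acc) > 1e-9]
  if (length(residual)) {
    stop("non-cancelling intermediate(s): ",
         paste(sprintf("%s (net %g)", names(residual), residual),
               collapse = ", "), call. = FALSE)
  }
  acc <- acc[names(acc) %in% keep & abs(acc) > 1e-9]
  comps <- unique(unlist(lapply(reactions, function(r) r$compartment)))
  reaction(id, acc, reversible = FALSE, compartment = comps,
           step = "lumped")
}
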