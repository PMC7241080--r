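## Curated pathway rosters and the one-call network generator built on them.

read_roster <- function(file) {
  path <- system.file("extdata", file, package = "acylid")
  if (!nzchar(path)) stop("roster file not found: ", file, call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Default fatty-acid pathway configuration
#'
#' The curated rosters driving [generate_pathways()]: FAS targets (palmitate
#' and the C13iso branched acid, each synthesised in cytosol and
#' mitochondrion), 24 ER elongation cycles, 12 desaturations, the
#' beta-oxidation substrates (saturated and iso-branched chains in
#' mitochondrion and peroxisome, plus the unsaturated chains whose degradation
#' merges into the saturated network), 13 carnitine-shuttle substrates and 5
#' short free acids that cross membranes by diffusion. Rosters are plain TSV
#' tables under `inst/extdata/` and can be swapped for another organism's.
#'
#' @return Named list of data.frames: `fas`, `elongation`, `desaturation`,
#'   `betaox`, `shuttle`, `diffusion`.
#' @export
default_pathway_config <- function() {
  list(
    fas = read_roster("fas_roster.tsv"),
    elongation = read_roster("elongation_roster.tsv"),
    desaturation = read_roster("desaturation_roster.tsv"),
    betaox = read_roster("betaox_roster.tsv"),
    shuttle = read_roster("shuttle_roster.tsv"),
    diffusion = read_roster("diffusion_roster.tsv")
  )
}

#' Generate the full fatty-acid reaction network from a configuration
#'
#' Expands every roster entry through the corresponding template generator.
#' Unsaturated beta-oxidation sequences are generated after the saturated ones
#' and share their species pool per compartment, so each unsaturated pathway
#' stops at the first intermediate already present in the saturated network
#' (see [generate_beta_oxidation()]); within the unsaturated roster the pool
#' also accumulates in roster order.
#'
#' @param config As returned by [default_pathway_config()].
#' @param stereo_style Identifier dialect for intermediates.
#' @return Named list of reaction lists: `fas`, `elongation_desaturation`,
#'   `betaox_saturated`, `betaox_unsaturated`, `shuttle`, `diffusion`.
#' @export
generate_pathways <- function(config = default_pathway_config(),
                              stereo_style = "suffix") {
  sp <- function(id) parse_model_id(id)

  fas <- list()
  for (i in seq_len(nrow(config$fas))) {
    row <- config$fas[i, ]
    fas <- c(fas, generate_fas(sp(row$primer_id), row$product_length,
                               compartment = row$compartment,
                               stereo_style = stereo_style))
  }

  elo_des <- list()
  for (i in seq_len(nrow(config$elongation))) {
    row <- config$elongation[i, ]
    elo_des <- c(elo_des, generate_elongation(sp(row$start_id), row$end_length,
                                              stereo_style = stereo_style))
  }
  for (i in seq_len(nrow(config$desaturation))) {
    row <- config$desaturation[i, ]
    elo_des <- c(elo_des, generate_desaturation(sp(row$substrate_id),
                                                row$position, row$geometry,
                                                stereo_style = stereo_style))
  }

  sat <- config$betaox[config$betaox$category == "saturated", , drop = FALSE]
  unsat <- config$betaox[config$betaox$category == "unsaturated", , drop = FALSE]
  box_sat <- list()
  pool <- list()  # compartment -> species ids seen so far
  for (i in seq_len(nrow(sat))) {
    row <- sat[i, ]
    seqn <- generate_beta_oxidation(sp(row$substrate_id),
                                    compartment = row$compartment,
                                    known = pool[[row$compartment]] %||% character(0),
                                    stereo_style = stereo_style)
    pool[[row$compartment]] <- c(pool[[row$compartment]],
                                 attr(seqn, "species"))
    box_sat <- c(box_sat, seqn)
  }
  box_unsat <- list()
  for (i in seq_len(nrow(unsat))) {
    row <- unsat[i, ]
    seqn <- generate_beta_oxidation(sp(row$substrate_id),
                                    compartment = row$compartment,
                                    known = pool[[row$compartment]] %||% character(0),
                                    stereo_style = stereo_style)
    pool[[row$compartment]] <- c(pool[[row$compartment]],
                                 attr(seqn, "species"))
    box_unsat <- c(box_unsat, seqn)
  }

  shuttle <- list()
  for (id in config$shuttle$substrate_id) {
    shuttle <- c(shuttle, generate_carnitine_shuttle(sp(id),
                                                     stereo_style = stereo_style))
  }

  diffusion <- list()
  for (id in config$diffusion$fa_id) {
    diffusion <- c(diffusion, generate_diffusion(sp(id),
                                                 stereo_style = stereo_style))
  }

  list(fas = fas, elongation_desaturation = elo_des,
       betaox_saturated = box_sat, betaox_unsaturated = box_unsat,
       shuttle = shuttle, diffusion = diffusion)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reaction counts of a generated network
#'
#' One row per category. FAS cycle reactions (steps `load`, `condense`,
#' `reduce1`, `dehydrate`, `reduce2`) and the terminal thioesterases (step
#' `release`) are reported separately.
#'
#' @param pathways As returned by [generate_pathways()].
#' @return data.frame with columns `category` and `count`.
#' @export
pathway_counts <- function(pathways) {
  steps <- function(rxns) vapply(rxns, function(r) r$step, character(1))
  fas_steps <- steps(pathways$fas)
  data.frame(
    category = c("fas_cycle", "fas_release", "elongation_desaturation",
                 "betaox_saturated", "betaox_unsaturated", "shuttle",
                 "diffusion"),
    count = c(sum(fas_steps != "release"), sum(fas_steps == "release"),
              length(pathways$elongation_desaturation),
              length(pathways$betaox_saturated),
              length(pathways$betaox_unsaturated),
              length(pathways$shuttle), length(pathways$diffusion)),
    stringsAsFactors = FALSE
  )
}
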