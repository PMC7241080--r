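## Reactions and mass/charge balance checking.

#' Construct a reaction
#'
#' @param id Reaction identifier.
#' @param stoichiometry Named numeric vector, species id -> signed coefficient
#'   (negative = substrate, positive = product). Species ids carry their
#'   compartment as a trailing `_c`/`_m`/`_x`/`_r` tag.
#' @param reversible Logical.
#' @param is_transport Logical; transport reactions move a species between
#'   compartments and are skipped by [extract_pairs()].
#' @param compartment Compartment tag(s) the reaction spans.
#' @param step Optional step label for generated pathway reactions (e.g.
#'   `"condense"`, `"thiolyze"`).
#' @return An `acyl_reaction` object.
#' @export
reaction <- function(id, stoichiometry, reversible = FALSE,
                     is_transport = FALSE, compartment = character(0),
                     step = NA_character_) {
  stopifnot(is.numeric(stoichiometry), !is.null(names(stoichiometry)))
  if (anyDuplicated(names(stoichiometry))) {
    ## the same species may be contributed twice (e.g. thiolysis of a C4 chain
    ## releases acetyl-CoA and leaves an acetyl-CoA chain): sum coefficients,
    ## preserving first-occurrence order
    un <- unique(names(stoichiometry))
    stoichiometry <- stats::setNames(vapply(un, function(s)
      sum(stoichiometry[names(stoichiometry) == s]), numeric(1)), un)
  }
  stoichiometry <- stoichiometry[stoichiometry != 0]
  if (!any(stoichiometry < 0) || !any(stoichiometry > 0)) {
    stop("reaction needs at least one substrate and one product", call. = FALSE)
  }
  structure(
    list(id = id, stoichiometry = stoichiometry, reversible = reversible,
         is_transport = is_transport, compartment = compartment, step = step),
    class = "acyl_reaction"
  )
}

#' @export
print.acyl_reaction <- function(x, ...) {
  cat("<reaction> ", x$id, ": ", write_reaction_formula(x), "\n", sep = "")
  invisible(x)
}

## strip a trailing single-letter compartment tag
strip_compartment <- function(id) sub("_([a-z])$", "", id)

compartment_of <- function(id) {
  m <- regmatches(id, regexpr("_([a-z])$", id))
  if (length(m)) substring(m, 2L) else NA_character_
}

## Fixed cofactor formulas (BiGG protonation states). Keys are
## compartment-free species ids.
COFACTOR_FORMULAS <- c(
  h      = "H+1",
  h2o    = "H2O",
  co2    = "CO2",
  o2     = "O2",
  h2o2   = "H2O2",
  coa    = "C21H32N7O16P3S-4",
  accoa  = "C23H34N7O17P3S-4",
  malcoa = "C24H33N7O19P3S-5",
  ppcoa  = "C24H36N7O17P3S-4",
  acp    = "C11H21N2O7PRS-1",
  malacp = "C14H22N2O10PRS-2",
  nadph  = "C21H26N7O17P3-4",
  nadp   = "C21H25N7O17P3-3",
  nadh   = "C21H27N7O14P2-2",
  nad    = "C21H26N7O14P2-1",
  fad    = "C27H31N9O15P2-2",
  fadh2  = "C27H33N9O15P2-2",
  atp    = "C10H12N5O13P3-4",
  amp    = "C10H12N5O7P-2",
  ppi    = "HO7P2-3",
  crn__L = "C7H15NO3"
)

#' Formulas for the species of a reaction set
#'
#' Builds a species id -> [elemental_formula()] map: compartment tags are
#' stripped, cofactors are looked up in the built-in table, and every other id
#' is decoded with [parse_model_id()] and sent through [conjugate_formula()].
#'
#' @param ids Character vector of species ids (with or without compartment
#'   tags), or a list of reactions whose species are collected.
#' @param convention A [protonation_convention()].
#' @param extra Named list of [elemental_formula()] overrides/additions
#'   (keyed compartment-free).
#' @return Named list of [elemental_formula()], keyed by the input ids.
#' @export
species_formulas <- function(ids, convention = protonation_convention(),
                             extra = list()) {
  if (is.list(ids)) {
    ids <- unique(unlist(lapply(ids, function(r) names(r$stoichiometry))))
  }
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    key <- strip_compartment(id)
    out[[id]] <- if (key %in% names(extra)) {
      extra[[key]]
    } else if (key %in% names(COFACTOR_FORMULAS)) {
      parse_formula(COFACTOR_FORMULAS[[key]])
    } else {
      conjugate_formula(parse_model_id(key, dialect = "legacy_tolerant"),
                        convention = convention)
    }
  }
  out
}

#' Mass and charge imbalance of a reaction
#'
#' Element-wise difference products minus substrates, weighted by
#' stoichiometry, plus the charge difference. A reaction is balanced iff the
#' result is an all-zero map with zero charge. The ACP pseudo-element `R` is
#' balanced like any other element.
#'
#' @param rxn An [reaction()].
#' @param formulas Named list species id -> [elemental_formula()]; defaults to
#'   [species_formulas()] over the reaction's species.
#' @return Named numeric of nonzero element deltas with a `"charge"` entry
#'   (empty apart from `charge = 0` when balanced).
#' @export
balance_delta <- function(rxn, formulas = species_formulas(list(rxn))) {
  missing <- setdiff(names(rxn$stoichiometry), names(formulas))
  if (length(missing)) {
    stop("no formula for species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  acc <- c(charge = 0)
  for (sp in names(rxn$stoichiometry)) {
    contrib <- formula_times(formulas[[sp]], rxn$stoichiometry[[sp]])
    for (el in names(contrib)) {
      acc[el] <- sum(acc[el], contrib[[el]], na.rm = TRUE)
    }
  }
  keep <- acc != 0 | names(acc) == "charge"
  acc[keep]
}

#' Is a reaction balanced?
#'
#' @inheritParams balance_delta
#' @return Logical scalar.
#' @export
is_balanced <- function(rxn, formulas = species_formulas(list(rxn))) {
  d <- balance_delta(rxn, formulas)
  all(abs(d) < 1e-9)
}

## Add protons (species "h_<comp>") to a draft reaction so hydrogen and charge
## balance; valid only when the H imbalance equals the charge imbalance and
## everything else already balances. Used by the pathway generators, whose
## templates fix all non-proton stoichiometry.
proton_balance <- function(rxn, compartment,
                           formulas = species_formulas(list(rxn))) {
  d <- balance_delta(rxn, formulas)
  dH <- if ("H" %in% names(d)) d[["H"]] else 0
  dq <- d[["charge"]]
  others <- setdiff(names(d), c("H", "charge"))
  if (length(others) && any(abs(d[others]) > 1e-9)) {
    stop("reaction '", rxn$id, "' has non-proton imbalance: ",
         paste(sprintf("%s=%g", others, d[others]), collapse = ", "),
         call. = FALSE)
  }
  if (abs(dH - dq) > 1e-9) {
    stop("reaction '", rxn$id, "' cannot be proton-balanced (H delta ", dH,
         ", charge delta ", dq, ")", call. = FALSE)
  }
  if (abs(dH) > 1e-9) {
    hsp <- paste0("h_", compartment)
    rxn$stoichiometry[hsp] <- sum(rxn$stoichiometry[hsp], -dH, na.rm = TRUE)
    rxn$stoichiometry <- rxn$stoichiometry[rxn$stoichiometry != 0]
  }
  rxn
}
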