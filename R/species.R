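#' @keywords internal
"_PACKAGE"

## Closed vocabularies -------------------------------------------------------

ACYL_CLASSES <- c("fa", "acp", "coa", "carn", "nae")

## Conjugate base moiety of each class (free acid has none).
CLASS_BASE <- c(
  fa   = "free acid",
  acp  = "acyl-carrier protein",
  coa  = "coenzyme A",
  carn = "carnitine",
  nae  = "ethanolamine"
)

## Classes whose base molecule carries its own stereocenter.
CLASSES_WITH_BASE_STEREO <- "carn"

## Functional-group vocabulary in canonical reporting order (after double
## bonds): hydroxy > peroxy > keto > amino > methyl.
GROUP_KINDS <- c("OH", "OOH", "O", "NH2", "Me")

## Kinds that can carry a stereocenter.
STEREO_KINDS <- c("OH", "NH2")

STEREO_LETTERS <- c("R", "S", "D", "L")

#' Describe a carbon-carbon double bond
#'
#' Positions use delta-numbering: the carboxyl (or thioester/amide carbonyl)
#' carbon is C1.
#'
#' @param position Integer carbon index of the first carbon of the bond.
#' @param geometry `"Z"`, `"E"` or `NA` (unspecified).
#' @return A `double_bond` object (a two-field list).
#' @export
double_bond <- function(position, geometry = NA_character_) {
  stopifnot(length(position) == 1L, length(geometry) == 1L)
  structure(
    list(position = as.integer(position), geometry = as.character(geometry)),
    class = "double_bond"
  )
}

#' Describe a functional group on the acyl chain
#'
#' @param kind One of `"OH"`, `"OOH"`, `"O"` (keto), `"NH2"`, `"Me"`.
#' @param position Integer carbon index (delta-numbering).
#' @param stereo `"R"`, `"S"`, `"D"`, `"L"` or `NA`. Only hydroxy and amino
#'   groups can carry a stereo descriptor.
#' @return A `functional_group` object.
#' @export
functional_group <- function(kind, position, stereo = NA_character_) {
  stopifnot(length(kind) == 1L, length(position) == 1L)
  structure(
    list(kind = as.character(kind), position = as.integer(position),
         stereo = as.character(stereo)),
    class = "functional_group"
  )
}

#' Construct an acyl species
#'
#' The canonical in-memory representation of a fatty acyl structure: class tag
#' (free acid, ACP, CoA, carnitine or N-acylethanolamide conjugate), chain
#' length, declared double-bond count, positional double-bond and
#' functional-group descriptors, and the stereocenter of the base molecule
#' (carnitine). The declared double-bond count may exceed the number of
#' positional descriptors; such species are structurally incomplete (the
#' positions are unknown) and [is_complete()] reports `FALSE` for them.
#'
#' @param acyl_class One of `"fa"`, `"acp"`, `"coa"`, `"carn"`, `"nae"`.
#' @param carbons Number of carbons of the longest chain (C1 = carbonyl).
#' @param n_double_bonds Declared number of double bonds; defaults to the
#'   number of positional descriptors supplied.
#' @param double_bonds List of [double_bond()] descriptors (possibly fewer
#'   than `n_double_bonds` when positions are unknown).
#' @param groups List of [functional_group()] descriptors.
#' @param base_stereo Stereo descriptor of the base molecule (`"L"` for
#'   L-carnitine), or `NA`.
#' @param validate Check invariants and stop on violation (default `TRUE`).
#' @return An `acyl_species` object.
#' @seealso [validate_species()], [canonical_order()]
#' @examples
#' oleoyl_coa <- acyl_species("coa", 18, 1, list(double_bond(9, "Z")))
#' to_model_id(oleoyl_coa)
#' @export
acyl_species <- function(acyl_class, carbons, n_double_bonds = length(double_bonds),
                         double_bonds = list(), groups = list(),
                         base_stereo = NA_character_, validate = TRUE) {
  s <- structure(
    list(
      acyl_class = as.character(acyl_class),
      carbons = as.integer(carbons),
      n_double_bonds = as.integer(n_double_bonds),
      double_bonds = double_bonds,
      groups = groups,
      base_stereo = as.character(base_stereo)
    ),
    class = "acyl_species"
  )
  if (validate) {
    v <- validate_species(s)
    if (length(v)) {
      stop("invalid acyl species: ", paste(v, collapse = "; "), call. = FALSE)
    }
  }
  s
}

#' Validate an acyl species
#'
#' Checks every structural invariant and returns a character vector of
#' violation messages (empty when the species is valid). Validation never
#' mutates and never throws; it is the machine-readable counterpart of the
#' constructor's checks.
#'
#' Chain stereocenters must use a single nomenclature family (all R/S or all
#' D/L). The base-molecule stereocenter (L-carnitine) is exempt from that rule
#' and may coexist with chain R/S descriptors, as it labels a different
#' molecule.
#'
#' @param species An [acyl_species()].
#' @return Character vector of violation descriptors; `character(0)` if valid.
#' @export
validate_species <- function(species) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)

  if (!species$acyl_class %in% ACYL_CLASSES) {
    add(sprintf("acyl_class: unknown class '%s'", species$acyl_class))
  }
  if (is.na(species$carbons) || species$carbons < 2L) {
    add("carbons: chain must have at least 2 carbons")
  }
  if (is.na(species$n_double_bonds) || species$n_double_bonds < 0L) {
    add("n_double_bonds: declared count must be non-negative")
  }
  if (length(species$double_bonds) > species$n_double_bonds) {
    add("double_bonds: more positional descriptors than declared double bonds")
  }

  for (db in species$double_bonds) {
    if (!inherits(db, "double_bond")) {
      add("double_bonds: entries must be double_bond objects")
      next
    }
    if (is.na(db$position) || db$position < 2L) {
      add(sprintf("double_bonds: position %s below 2", db$position))
    } else if (!is.na(species$carbons) && db$position > species$carbons - 1L) {
      add(sprintf("double_bonds: position %d exceeds chain of %d carbons",
                  db$position, species$carbons))
    }
    if (!is.na(db$geometry) && !db$geometry %in% c("Z", "E")) {
      add(sprintf("double_bonds: geometry '%s' not Z/E", db$geometry))
    }
  }
  pos <- vapply(species$double_bonds, function(d) d$position, integer(1))
  if (anyDuplicated(pos)) add("double_bonds: duplicated positions")

  for (g in species$groups) {
    if (!inherits(g, "functional_group")) {
      add("groups: entries must be functional_group objects")
      next
    }
    if (!g$kind %in% GROUP_KINDS) {
      add(sprintf("groups: unknown kind '%s'", g$kind))
    }
    if (is.na(g$position) || g$position < 1L ||
        (!is.na(species$carbons) && g$position > species$carbons)) {
      add(sprintf("groups: position %s outside chain", g$position))
    }
    if (!is.na(g$stereo)) {
      if (!g$stereo %in% STEREO_LETTERS) {
        add(sprintf("groups: stereo '%s' not one of R/S/D/L", g$stereo))
      }
      if (!g$kind %in% STEREO_KINDS) {
        add(sprintf("groups: kind '%s' cannot carry a stereocenter", g$kind))
      }
    }
  }

  ## One nomenclature family for chain stereocenters.
  chain_stereo <- vapply(species$groups, function(g) g$stereo, character(1))
  chain_stereo <- chain_stereo[!is.na(chain_stereo)]
  if (any(chain_stereo %in% c("R", "S")) && any(chain_stereo %in% c("D", "L"))) {
    add("groups: mixed R/S and D/L stereo nomenclature within one chain")
  }

  if (!is.na(species$base_stereo)) {
    if (!species$base_stereo %in% STEREO_LETTERS) {
      add(sprintf("base_stereo: '%s' not one of R/S/D/L", species$base_stereo))
    }
    if (!species$acyl_class %in% CLASSES_WITH_BASE_STEREO) {
      add(sprintf("base_stereo: class '%s' has no base stereocenter",
                  species$acyl_class))
    }
  }

  v
}

#' Put a species' descriptors in canonical order
#'
#' Double bonds are sorted by ascending position; functional groups first by
#' kind in the order hydroxy, peroxy, keto, amino, methyl, then by ascending
#' position. All other fields are untouched. Idempotent.
#'
#' @param species An [acyl_species()].
#' @return The species with sorted descriptor lists.
#' @export
canonical_order <- function(species) {
  if (length(species$double_bonds)) {
    pos <- vapply(species$double_bonds, function(d) d$position, integer(1))
    species$double_bonds <- species$double_bonds[order(pos)]
  }
  if (length(species$groups)) {
    kind <- match(vapply(species$groups, function(g) g$kind, character(1)),
                  GROUP_KINDS)
    pos <- vapply(species$groups, function(g) g$position, integer(1))
    species$groups <- species$groups[order(kind, pos)]
  }
  species
}

#' Is the species structurally complete?
#'
#' A species is complete when every declared double bond has a position and a
#' geometry, and every functional group has a position. Completeness is what
#' separates a "full structural information" annotation from a weaker one and
#' gates chemistry generation ([free_acid_formula()], [to_smiles()]).
#'
#' @param species An [acyl_species()].
#' @param require_stereo Also require a stereo letter on every stereo-capable
#'   group, and the base stereo for classes that have one (default `FALSE`).
#' @return Logical.
#' @export
is_complete <- function(species, require_stereo = FALSE) {
  if (length(species$double_bonds) < species$n_double_bonds) return(FALSE)
  geom <- vapply(species$double_bonds, function(d) d$geometry, character(1))
  if (anyNA(geom)) return(FALSE)
  if (require_stereo) {
    for (g in species$groups) {
      if (g$kind %in% STEREO_KINDS && is.na(g$stereo)) return(FALSE)
    }
    if (species$acyl_class %in% CLASSES_WITH_BASE_STEREO &&
        is.na(species$base_stereo)) {
      return(FALSE)
    }
  }
  TRUE
}

#' @export
print.acyl_species <- function(x, ...) {
  cat("<acyl_species> ", format_shorthand(x, strict = FALSE), "\n", sep = "")
  invisible(x)
}

#' Structural equality of two species
#'
#' Compares all fields after canonical ordering.
#'
#' @param a,b [acyl_species()] objects.
#' @return Logical.
#' @export
species_equal <- function(a, b) {
  identical(unclass_recursive(canonical_order(a)),
            unclass_recursive(canonical_order(b)))
}

unclass_recursive <- function(x) {
  x <- unclass(x)
  if (is.list(x)) x <- lapply(x, unclass_recursive)
  x
}
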