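## Annotation-completeness grading, substrate-product pair extraction with hub
## and transport removal, pairing tabulation, and propagation of structural
## detail across the pair network.

GRADE_LEVELS <- c("none", "partial", "full")  # total order none < partial < full

#' Construct a structural grade
#'
#' @param level `"full"`, `"partial"` or `"none"`.
#' @param rationale Free-text naming the missing items (or the evidence).
#' @return A `structural_grade`.
#' @export
structural_grade <- function(level, rationale = "") {
  level <- match.arg(level, GRADE_LEVELS)
  structure(list(level = level, rationale = rationale),
            class = "structural_grade")
}

#' @export
print.structural_grade <- function(x, ...) {
  cat("<grade> ", x$level, if (nzchar(x$rationale)) paste0(" (", x$rationale, ")"),
      "\n", sep = "")
  invisible(x)
}

## databases whose single accession (or any InChIKey) is taken as a link to a
## unique defined structure
STRUCTURE_DBS <- c("inchikey", "chebi", "lipidmaps", "lipid maps")

#' Grade the structural annotation of a metabolite
#'
#' Three levels: `"full"` when an xref resolves to a unique defined structure
#' (an InChIKey, or a single ChEBI/LipidMaps accession) or the parsed species
#' is completely specified (all double-bond positions and geometries, all
#' group positions, stereo wherever a stereocenter exists); `"partial"` when
#' only a minor item is missing -- the base-molecule stereocenter (e.g. the
#' carnitine of an acyl-carnitine) or a chain stereo letter; `"none"` when
#' major information is missing -- the position or geometry of a double bond
#' or the position of a functional group -- or nothing could be parsed at all.
#' The rationale names the missing items.
#'
#' @param record A [metabolite_record()].
#' @param parsed The codec's best-effort parse of the record's id/name (an
#'   [acyl_species()]), or `NULL` when none is available.
#' @return A [structural_grade()].
#' @export
grade_record <- function(record, parsed = NULL) {
  ## unique-structure cross-references
  for (db in names(record$xrefs)) {
    acc <- record$xrefs[[db]]
    dbl <- tolower(db)
    if (dbl == "inchikey" && length(acc) >= 1L) {
      return(structural_grade("full", sprintf("InChIKey %s", acc[1])))
    }
    if (dbl %in% STRUCTURE_DBS && length(acc) == 1L) {
      return(structural_grade("full", sprintf("unique %s accession %s", db, acc)))
    }
  }
  if (is.null(parsed)) {
    return(structural_grade("none", "no structure derivable from id or name"))
  }

  major <- character(0)
  n_missing_db <- parsed$n_double_bonds - length(parsed$double_bonds)
  if (n_missing_db > 0L) {
    major <- c(major, sprintf("position of %d double bond(s)", n_missing_db))
  }
  for (d in parsed$double_bonds) {
    if (is.na(d$geometry)) {
      major <- c(major, sprintf("geometry of the double bond at %d", d$position))
    }
  }
  if (length(major)) {
    return(structural_grade("none", paste(major, collapse = "; ")))
  }

  minor <- character(0)
  for (g in parsed$groups) {
    if (g$kind %in% STEREO_KINDS && is.na(g$stereo)) {
      minor <- c(minor, sprintf("stereochemistry of the %d%s group",
                                g$position, g$kind))
    }
  }
  if (parsed$acyl_class %in% CLASSES_WITH_BASE_STEREO &&
      is.na(parsed$base_stereo)) {
    minor <- c(minor, "stereochemistry of the carnitine")
  }
  if (length(minor)) {
    return(structural_grade("partial", paste(minor, collapse = "; ")))
  }
  structural_grade("full", "fully specified structure")
}

## default hub metabolites (compartment-free ids): coenzyme A, acetyl-CoA,
## carnitine, acyl-carrier protein
default_hubs <- function() c("coa", "accoa", "crn", "crn__L", "carn", "acp")

## a reaction is transport when flagged, or when the compartment-stripped
## substrate and product species sets coincide
is_transport_reaction <- function(rxn) {
  if (isTRUE(rxn$is_transport)) return(TRUE)
  subs <- strip_compartment(names(rxn$stoichiometry)[rxn$stoichiometry < 0])
  prods <- strip_compartment(names(rxn$stoichiometry)[rxn$stoichiometry > 0])
  setequal(subs, prods) && length(subs) > 0L
}

default_is_acyl <- function(id) {
  key <- strip_compartment(id)
  ok <- tryCatch({
    parse_model_id(key, dialect = "legacy_tolerant"); TRUE
  }, error = function(e) FALSE)
  ok
}

#' Extract substrate-product pairs of acyl metabolites
#'
#' For every non-transport reaction, forms the cross product of acyl-based
#' substrates and products, drops any pair touching a hub metabolite
#' (coenzyme A, acetyl-CoA, carnitine, ACP by default, matched in every
#' compartment), and deduplicates on the unordered id pair. Pairs are the
#' edges of the annotation-propagation network.
#'
#' @param reactions List of [reaction()]s.
#' @param hubs Compartment-free hub ids (default [default_hubs()] extended
#'   with nothing).
#' @param is_acyl Predicate `function(id) -> logical` deciding acyl
#'   membership; the default accepts ids that decode with the tolerant codec
#'   dialect. Supply your own to add name-pattern or whitelist logic.
#' @return data.frame with columns `a`, `b`, `via_reaction`.
#' @export
extract_pairs <- function(reactions, hubs = default_hubs(),
                          is_acyl = default_is_acyl) {
  rows <- list()
  for (r in reactions) {
    if (is_transport_reaction(r)) next
    sp <- names(r$stoichiometry)
    subs <- sp[r$stoichiometry < 0]
    prods <- sp[r$stoichiometry > 0]
    keep <- function(v) {
      v <- v[!(strip_compartment(v) %in% hubs)]
      v[vapply(v, is_acyl, logical(1))]
    }
    subs <- keep(subs); prods <- keep(prods)
    for (s in subs) for (p in prods) {
      if (s == p) next
      pair <- sort(c(s, p))
      rows[[length(rows) + 1L]] <- data.frame(
        a = pair[1], b = pair[2], via_reaction = r$id,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(a = character(0), b = character(0),
                      via_reaction = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[!duplicated(paste(out$a, out$b, sep = "\r")), , drop = FALSE]
}

grade_level_of <- function(g) {
  if (inherits(g, "structural_grade")) g$level else as.character(g)
}

#' Tabulate pairings by grade combination
#'
#' Counts the six unordered combinations of annotation grades across the pair
#' list; the counts sum to the number of pairs.
#'
#' @param pairs data.frame from [extract_pairs()].
#' @param grades Named list/vector, species id -> [structural_grade()] or
#'   level string.
#' @return data.frame with columns `pairing` and `count`, one row per
#'   unordered grade combination.
#' @export
count_pairings <- function(pairs, grades) {
  combos <- c("none<->none", "partial<->none", "partial<->partial",
              "full<->none", "full<->partial", "full<->full")
  counts <- stats::setNames(integer(length(combos)), combos)
  for (i in seq_len(nrow(pairs))) {
    ga <- grades[[pairs$a[i]]]
    gb <- grades[[pairs$b[i]]]
    if (is.null(ga)) stop("no grade for id '", pairs$a[i], "'", call. = FALSE)
    if (is.null(gb)) stop("no grade for id '", pairs$b[i], "'", call. = FALSE)
    lv <- c(grade_level_of(ga), grade_level_of(gb))
    lv <- lv[order(match(lv, GRADE_LEVELS), decreasing = TRUE)]
    key <- paste(lv, collapse = "<->")
    counts[key] <- counts[key] + 1L
  }
  data.frame(pairing = combos, count = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

## transform the source species along one network hop onto the target
## skeleton; NULL when no admissible relation (class transfer at equal chain,
## or a +-2-carbon elongation/beta-oxidation step) applies
hop_species <- function(src, skel) {
  if (is.null(skel)) return(NULL)
  dc <- total_carbons(skel) - total_carbons(src)
  cand <- if (dc == 0L) {
    src
  } else if (dc == 2L) {
    elongate2(src)
  } else if (dc == -2L) {
    shorten2(src)
  } else {
    return(NULL)
  }
  if (dc == 0L && skel$acyl_class == src$acyl_class) return(NULL)  # no-op hop
  if (skel$n_double_bonds != cand$n_double_bonds) return(NULL)
  cand <- with_class(cand, skel$acyl_class,
                     base_stereo = if (skel$acyl_class == "carn") "L"
                                   else NA_character_)
  if (length(validate_species(cand))) return(NULL)
  cand
}

#' Propagate structural annotation across the pair network
#'
#' Breadth-first traversal from every fully annotated node with a parsed
#' structure. A suggestion is emitted for each reachable `none`/`partial`
#' node when every hop on the connecting path is either a class transfer
#' (same acyl chain carried by a different class, e.g. FA <-> CoA <-> Carn)
#' or a two-carbon elongation/beta-oxidation step (chain +-2, double-bond
#' positions shifted accordingly). Suggestions propose the transformed
#' species; existing full grades are never altered. Output is sorted by path
#' length ascending, ties broken by source id.
#'
#' @param pairs data.frame from [extract_pairs()].
#' @param grades Named map id -> grade (as in [count_pairings()]).
#' @param species_map Named list id -> [acyl_species()] (complete for full
#'   nodes, best-effort skeleton -- class, carbons, double-bond count -- for
#'   the others; `NULL` entries are not traversable).
#' @return data.frame with columns `target`, `source`, `path_length`, `path`,
#'   `proposed_shorthand`, `proposed_id`.
#' @export
propagate_grades <- function(pairs, grades, species_map) {
  adj <- list()
  link <- function(a, b) adj[[a]] <<- unique(c(adj[[a]], b))
  for (i in seq_len(nrow(pairs))) {
    link(pairs$a[i], pairs$b[i]); link(pairs$b[i], pairs$a[i])
  }
  lv <- function(id) {
    g <- grades[[id]]
    if (is.null(g)) "none" else grade_level_of(g)
  }
  sources <- names(species_map)[vapply(names(species_map), function(id) {
    lv(id) == "full" && !is.null(species_map[[id]]) &&
      is_complete(species_map[[id]])
  }, logical(1))]
  sources <- intersect(sources, unique(c(pairs$a, pairs$b)))

  rows <- list()
  for (src_id in sort(sources)) {
    ## BFS with the proposed species carried along the path
    frontier <- list(list(id = src_id, species = species_map[[src_id]],
                          path = src_id))
    seen <- src_id
    depth <- 0L
    while (length(frontier)) {
      depth <- depth + 1L
      nxt <- list()
      for (node in frontier) {
        for (nb in adj[[node$id]]) {
          if (nb %in% seen) next
          prop <- hop_species(node$species, species_map[[nb]])
          if (is.null(prop)) next
          seen <- c(seen, nb)
          path <- c(node$path, nb)
          if (lv(nb) != "full") {
            rows[[length(rows) + 1L]] <- data.frame(
              target = nb, source = src_id, path_length = depth,
              path = paste(path, collapse = " -> "),
              proposed_shorthand = format_shorthand(prop),
              proposed_id = to_model_id(prop, stereo_style = "suffix"),
              stringsAsFactors = FALSE)
          }
          nxt[[length(nxt) + 1L]] <- list(id = nb, species = prop, path = path)
        }
      }
      frontier <- nxt
    }
  }
  if (!length(rows)) {
    return(data.frame(target = character(0), source = character(0),
                      path_length = integer(0), path = character(0),
                      proposed_shorthand = character(0),
                      proposed_id = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$path_length, out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}
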