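## Bidirectional codec: Liebisch-style shorthand <-> systematic model IDs.

SHORTHAND_CLASS <- c(fa = "FA", acp = "ACP", coa = "CoA", carn = "Carn",
                     nae = "NAE")

## Descriptor tokens of the model-ID grammar, longest first for maximal munch.
ID_TOKENS <- c("ooh", "nh2", "oh", "me", "o", "z", "e")
ID_TOKEN_KIND <- c(ooh = "OOH", nh2 = "NH2", oh = "OH", me = "Me", o = "O")

codec_error <- function(fmt, ..., offset = NULL) {
  msg <- sprintf(fmt, ...)
  if (!is.null(offset)) msg <- sprintf("%s (at offset %d)", msg, offset)
  stop(msg, call. = FALSE)
}

#' Format a species as lipid shorthand
#'
#' Produces the compact shorthand used in lipidomics, e.g. `CoA(18:1(9Z))` or
#' `CoA(18:1(9Z,3OH[S]))`: class token, carbons:double-bonds, and a
#' parenthesised descriptor block with double bonds first, then functional
#' groups in canonical order. Double bonds with unknown positions are carried
#' in the count only (`FA(14:1)`).
#'
#' @param species An [acyl_species()].
#' @param strict Validate first and error on an invalid species (default).
#' @return A shorthand string; [parse_shorthand()] is its inverse on
#'   canonical species.
#' @export
format_shorthand <- function(species, strict = TRUE) {
  if (strict) {
    v <- validate_species(species)
    if (length(v)) codec_error("cannot format invalid species: %s",
                               paste(v, collapse = "; "))
  }
  species <- canonical_order(species)
  desc <- character(0)
  for (db in species$double_bonds) {
    if (!is.na(db$position)) {
      desc <- c(desc, paste0(db$position,
                             if (is.na(db$geometry)) "" else db$geometry))
    }
  }
  for (g in species$groups) {
    desc <- c(desc, paste0(g$position, g$kind,
                           if (is.na(g$stereo)) "" else sprintf("[%s]", g$stereo)))
  }
  body <- sprintf("%d:%d", species$carbons, species$n_double_bonds)
  if (length(desc)) body <- sprintf("%s(%s)", body, paste(desc, collapse = ","))
  sprintf("%s(%s)", SHORTHAND_CLASS[[species$acyl_class]], body)
}

#' Parse lipid shorthand into a species
#'
#' Accepts the grammar `CLASS(C:D(desc,...))` with class tokens FA, ACP, CoA,
#' Carn, NAE (case-insensitive), double-bond descriptors like `9Z`, and
#' functional-group descriptors like `3OH[S]`. The result is in canonical
#' descriptor order. Carnitine species receive `base_stereo_default` because
#' the shorthand does not encode the carnitine stereocenter (models use free
#' L-carnitine).
#'
#' @param text Shorthand string.
#' @param base_stereo_default Stereo letter assumed for the carnitine base
#'   (default `"L"`); `NA` to leave it unset.
#' @return An [acyl_species()].
#' @export
parse_shorthand <- function(text, base_stereo_default = "L") {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  m <- regexec("^([A-Za-z]+)\\((\\d+):(\\d+)(\\((.*)\\))?\\)$", text)
  parts <- regmatches(text, m)[[1]]
  if (!length(parts)) {
    ## locate the first offending position for a useful message
    pre <- regexpr("^[A-Za-z]+\\(\\d+:\\d*", text)
    off <- if (pre > 0) attr(pre, "match.length") else 0L
    codec_error("malformed shorthand '%s'", text, offset = off)
  }
  cls_tok <- parts[2]
  cls <- names(SHORTHAND_CLASS)[match(tolower(cls_tok), tolower(SHORTHAND_CLASS))]
  if (is.na(cls)) codec_error("unknown class token '%s'", cls_tok)
  carbons <- as.integer(parts[3])
  n_db <- as.integer(parts[4])

  dbs <- list(); grps <- list()
  if (nzchar(parts[6])) {
    for (d in strsplit(parts[6], ",", fixed = TRUE)[[1]]) {
      dm <- regexec("^(\\d+)(Z|E|OOH|OH|O|NH2|Me)(\\[([RSDL])\\])?$", d)
      dp <- regmatches(d, dm)[[1]]
      if (!length(dp)) codec_error("malformed descriptor '%s' in '%s'", d, text)
      pos <- as.integer(dp[2])
      tok <- dp[3]
      stereo <- if (nzchar(dp[5])) dp[5] else NA_character_
      if (tok %in% c("Z", "E")) {
        if (!is.na(stereo)) codec_error("double bond '%s' cannot carry [%s]", d, stereo)
        dbs <- c(dbs, list(double_bond(pos, tok)))
      } else {
        grps <- c(grps, list(functional_group(tok, pos, stereo)))
      }
    }
  }
  if (length(dbs) > n_db) {
    codec_error("%d positional double bonds exceed declared count %d",
                length(dbs), n_db)
  }
  base <- if (cls %in% CLASSES_WITH_BASE_STEREO) base_stereo_default
          else NA_character_
  canonical_order(acyl_species(cls, carbons, n_db, dbs, grps, base))
}

#' Convert a species to a systematic model identifier
#'
#' Builds the BiGG-compatible identifier: lower-case class prefix, carbons and
#' double-bond count separated by `_`, then one underscore and the descriptor
#' string (position + lower-case token, no separator), e.g. `fa18_2_9z12z`.
#' Chain stereocenters are written either inline as a capital letter
#' (`coa18_0_3ohS`, the canonical style) or collected into `__`-separated
#' suffixes (`coa18_1_9z3oh__S`). The base-molecule stereocenter is always a
#' `__` suffix at the very end (`carn18_1_9z__L`).
#'
#' @param species An [acyl_species()]; validated and canonically ordered first.
#' @param stereo_style `"inline"` (default) or `"suffix"` for chain
#'   stereocenters.
#' @return The identifier string; passes [is_valid_model_id()].
#' @export
to_model_id <- function(species, stereo_style = c("inline", "suffix")) {
  stereo_style <- match.arg(stereo_style)
  v <- validate_species(species)
  if (length(v)) codec_error("cannot encode invalid species: %s",
                             paste(v, collapse = "; "))
  species <- canonical_order(species)

  desc <- character(0)
  suffixes <- character(0)
  for (db in species$double_bonds) {
    desc <- c(desc, paste0(db$position,
                           if (is.na(db$geometry)) "" else tolower(db$geometry)))
  }
  for (g in species$groups) {
    piece <- paste0(g$position, tolower(g$kind))
    if (!is.na(g$stereo)) {
      if (stereo_style == "inline") piece <- paste0(piece, g$stereo)
      else suffixes <- c(suffixes, g$stereo)
    }
    desc <- c(desc, piece)
  }

  id <- sprintf("%s%d_%d", species$acyl_class, species$carbons,
                species$n_double_bonds)
  if (length(desc)) id <- paste0(id, "_", paste(desc, collapse = ""))
  if (length(suffixes)) id <- paste0(id, paste0("__", suffixes, collapse = ""))
  if (!is.na(species$base_stereo)) id <- paste0(id, "__", species$base_stereo)
  id
}

#' Parse a systematic model identifier
#'
#' Inverse of [to_model_id()] for both stereo styles. The descriptor string is
#' tokenised by maximal munch over `z`, `e`, `oh`, `ooh`, `o`, `nh2`, `me`
#' after each position integer, so `9z12z`, `3ohS` and `11me` split
#' deterministically. For classes with a base stereocenter (carnitine) the
#' final trailing `__X` suffix is the base descriptor (model ids always carry
#' the carnitine's `__L`); any remaining suffixes are assigned, in order, to
#' stereo-capable groups lacking an inline letter.
#'
#' The `legacy_tolerant` dialect additionally accepts an underscore between
#' class prefix and carbon count (`nae_18_1_9z`) and the `crn` alias for
#' `carn`.
#'
#' @param id Identifier string.
#' @param dialect `"canonical"` (default) or `"legacy_tolerant"`.
#' @return An [acyl_species()].
#' @export
parse_model_id <- function(id, dialect = c("canonical", "legacy_tolerant")) {
  dialect <- match.arg(dialect)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  rest <- id

  ## trailing stereo suffix letters
  suffixes <- character(0)
  while (grepl("__[RSDL]$", rest)) {
    suffixes <- c(substring(rest, nchar(rest), nchar(rest)), suffixes)
    rest <- substring(rest, 1L, nchar(rest) - 3L)
  }

  prefixes <- ACYL_CLASSES
  if (dialect == "legacy_tolerant") prefixes <- c(prefixes, "crn")
  ## longest prefix first so "carn" beats "ca..." style overlaps
  prefixes <- prefixes[order(nchar(prefixes), decreasing = TRUE)]
  cls <- NULL
  for (p in prefixes) {
    pat <- if (dialect == "legacy_tolerant") sprintf("^%s_?(?=\\d)", p)
           else sprintf("^%s(?=\\d)", p)
    m <- regexpr(pat, rest, perl = TRUE)
    if (m == 1L) {
      cls <- if (p == "crn") "carn" else p
      rest <- substring(rest, attr(m, "match.length") + 1L)
      break
    }
  }
  if (is.null(cls)) codec_error("no acyl class prefix in '%s'", id, offset = 0L)

  m <- regexec("^(\\d+)_(\\d+)(_([0-9a-zRSDL]+))?$", rest)
  parts <- regmatches(rest, m)[[1]]
  if (!length(parts)) {
    codec_error("malformed identifier body in '%s'", id,
                offset = nchar(id) - nchar(rest))
  }
  carbons <- as.integer(parts[2])
  n_db <- as.integer(parts[3])
  desc <- parts[5]

  dbs <- list(); grps <- list()
  if (nzchar(desc)) {
    i <- 1L; n <- nchar(desc)
    base_off <- nchar(id) - nchar(rest) + nchar(parts[2]) + nchar(parts[3]) + 2L
    while (i <= n) {
      pm <- regexpr("^\\d+", substring(desc, i))
      if (pm != 1L) {
        codec_error("expected position integer in '%s'", id,
                    offset = base_off + i - 1L)
      }
      pos <- as.integer(substring(desc, i, i + attr(pm, "match.length") - 1L))
      i <- i + attr(pm, "match.length")
      tok <- NULL
      for (t in ID_TOKENS) {  # longest first: maximal munch
        if (substring(desc, i, i + nchar(t) - 1L) == t) { tok <- t; break }
      }
      if (is.null(tok)) {
        codec_error("unknown descriptor token '%s' in '%s'",
                    substring(desc, i, i), id, offset = base_off + i - 1L)
      }
      i <- i + nchar(tok)
      stereo <- NA_character_
      ch <- substring(desc, i, i)
      if (ch %in% STEREO_LETTERS) { stereo <- ch; i <- i + 1L }
      if (tok %in% c("z", "e")) {
        if (!is.na(stereo)) {
          codec_error("stereo letter after double bond in '%s'", id,
                      offset = base_off + i - 2L)
        }
        dbs <- c(dbs, list(double_bond(pos, toupper(tok))))
      } else {
        grps <- c(grps, list(functional_group(ID_TOKEN_KIND[[tok]], pos, stereo)))
      }
    }
  }

  ## distribute suffix stereo letters: for classes with a base stereocenter
  ## the final suffix is, by convention, the base (model ids always carry the
  ## carnitine's __L); the rest go to stereo-less groups in canonical order
  base_stereo <- NA_character_
  if (length(suffixes) && cls %in% CLASSES_WITH_BASE_STEREO) {
    base_stereo <- suffixes[length(suffixes)]
    suffixes <- suffixes[-length(suffixes)]
  }
  if (length(suffixes)) {
    open <- which(vapply(grps, function(g)
      g$kind %in% STEREO_KINDS && is.na(g$stereo), logical(1)))
    k <- min(length(open), length(suffixes))
    if (k > 0) {
      for (j in seq_len(k)) grps[[open[j]]]$stereo <- suffixes[j]
    }
    leftover <- suffixes[seq_len(length(suffixes)) > k]
    if (length(leftover)) {
      codec_error("unassignable stereo suffix '__%s' in '%s'",
                  paste(leftover, collapse = "__"), id)
    }
  }

  s <- acyl_species(cls, carbons, n_db, dbs, grps, base_stereo,
                    validate = FALSE)
  v <- validate_species(s)
  if (length(v)) codec_error("'%s' decodes to an invalid species: %s",
                             id, paste(v, collapse = "; "))
  canonical_order(s)
}

#' Is a string a valid systematic model identifier?
#'
#' Checks the BiGG-compatibility surface rules only: character set
#' `[a-z0-9_]` with capital letters allowed solely as stereo descriptors
#' (inline after a group token, or in `__X` suffixes), first character
#' alphabetic, and no `__` runs other than stereo suffixes. It does not check
#' that the identifier decodes to a chemically valid species; use
#' [parse_model_id()] for that.
#'
#' @param text Character vector of candidate identifiers.
#' @return Logical vector.
#' @export
is_valid_model_id <- function(text) {
  vapply(text, function(x) {
    if (!is.character(x) || is.na(x) || !nzchar(x)) return(FALSE)
    while (grepl("__[RSDL]$", x)) x <- substring(x, 1L, nchar(x) - 3L)
    if (grepl("__", x, fixed = TRUE)) return(FALSE)
    grepl("^[a-z][a-z0-9]*(_[0-9a-z]+([RSDL][0-9a-z]*)*)*$", x)
  }, logical(1), USE.NAMES = FALSE)
}
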