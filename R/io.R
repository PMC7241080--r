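## Readers/writers: reaction-formula strings, metabolite tables (SBtab and
## BiGG-dump dialects), SBtab reaction tables, legacy-ID alias migration.

#' Parse a reaction-formula string
#'
#' Dialect as printed in model dumps: `"c1 id1 + c2 id2 <=> c3 id3 + ..."`,
#' with optional `M_` prefixes on species ids, omitted coefficients meaning 1,
#' `<=>` for reversible and `->`/`-->` for irreversible reactions.
#'
#' @param text Formula string.
#' @param id Reaction id to attach (default `"r1"`).
#' @return A [reaction()]; the `m_prefix` attribute records whether species
#'   carried `M_` prefixes so [write_reaction_formula()] can round-trip.
#' @export
parse_reaction_formula <- function(text, id = "r1") {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  text <- gsub("→", "->", trimws(text))
  rev <- grepl("<=>", text, fixed = TRUE)
  sides <- if (rev) strsplit(text, "<=>", fixed = TRUE)[[1]]
           else strsplit(text, "-+>")[[1]]
  if (length(sides) != 2L) {
    stop("no reaction arrow in '", text, "'", call. = FALSE)
  }
  m_prefix <- FALSE
  parse_side <- function(side, sign) {
    terms <- strsplit(side, "+", fixed = TRUE)[[1]]
    st <- numeric(0)
    for (term in terms) {
      term <- trimws(term)
      if (!nzchar(term)) {
        stop("empty term in '", text, "'", call. = FALSE)
      }
      toks <- strsplit(term, "\\s+")[[1]]
      if (length(toks) == 1L) {
        coef <- 1; sp <- toks[1]
      } else if (length(toks) == 2L) {
        coef <- suppressWarnings(as.numeric(toks[1])); sp <- toks[2]
      } else {
        stop("malformed term '", term, "'", call. = FALSE)
      }
      if (is.na(coef) || coef <= 0) {
        stop("malformed coefficient in term '", term, "'", call. = FALSE)
      }
      if (grepl("^[0-9.]+$", sp)) {
        stop("dangling coefficient '", sp, "' without species", call. = FALSE)
      }
      if (startsWith(sp, "M_")) { m_prefix <<- TRUE; sp <- substring(sp, 3L) }
      st[sp] <- sum(st[sp], sign * coef, na.rm = TRUE)
    }
    st
  }
  st <- c(parse_side(sides[1], -1), parse_side(sides[2], +1))
  comps <- unique(stats::na.omit(vapply(names(st), compartment_of,
                                        character(1))))
  r <- reaction(id, st, reversible = rev, compartment = comps)
  attr(r, "m_prefix") <- m_prefix
  r
}

#' Write a reaction as a formula string
#'
#' Inverse of [parse_reaction_formula()]: coefficient 1 is omitted, other
#' coefficients are written with one decimal when integral (`"11.0"`, as
#' printed in model dumps) and full precision otherwise; `M_` prefixes are
#' restored when the reaction was parsed with them or `m_prefix = TRUE`.
#'
#' @param rxn A [reaction()].
#' @param m_prefix Prefix species ids with `M_` (default: the reaction's
#'   `m_prefix` attribute, else `FALSE`).
#' @return A formula string.
#' @export
write_reaction_formula <- function(rxn, m_prefix = NULL) {
  if (is.null(m_prefix)) m_prefix <- isTRUE(attr(rxn, "m_prefix"))
  if (!length(rxn$stoichiometry)) stop("empty reaction", call. = FALSE)
  fmt_coef <- function(x) {
    if (x == 1) "" else if (x == round(x)) sprintf("%.1f ", x)
    else paste0(format(x, scientific = FALSE), " ")
  }
  fmt_side <- function(st) {
    sp <- names(st)
    if (m_prefix) sp <- paste0("M_", sp)
    paste(paste0(vapply(unname(st), fmt_coef, character(1)), sp),
          collapse = " + ")
  }
  lhs <- -rxn$stoichiometry[rxn$stoichiometry < 0]
  rhs <- rxn$stoichiometry[rxn$stoichiometry > 0]
  arrow <- if (rxn$reversible) "<=>" else "->"
  paste(fmt_side(lhs), arrow, fmt_side(rhs))
}

#' Construct a metabolite record
#'
#' @param id Species identifier (unique within a table).
#' @param name Human-readable name.
#' @param formula Formula string or `NA`.
#' @param charge Integer charge or `NA`.
#' @param compartment Compartment tag or `NA`.
#' @param xrefs Named list, database -> character vector of accessions
#'   (ChEBI, KEGG, HMDB, LipidMaps, InChIKey, ...).
#' @return A `metabolite_record`.
#' @export
metabolite_record <- function(id, name = NA_character_,
                              formula = NA_character_, charge = NA_integer_,
                              compartment = NA_character_, xrefs = list()) {
  stopifnot(nzchar(id))
  structure(list(id = id, name = name, formula = formula,
                 charge = charge, compartment = compartment, xrefs = xrefs),
            class = "metabolite_record")
}

split_xref_cell <- function(cell) {
  if (is.na(cell) || !nzchar(cell)) return(character(0))
  trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
}

#' Read a metabolite table
#'
#' Two dialects: `"sbtab"` (tab-separated, `!`-prefixed headers, optional
#' leading `!!SBtab` declaration line, xrefs in `!Identifiers:<db>` columns)
#' and `"bigg_dump"` (the public tab-separated metabolite listing with a
#' `database_links` column of `DB: url` entries). Multi-valued xref cells are
#' split on `;` with whitespace stripped; missing cells become absent xrefs,
#' not empty strings. Extra columns are tolerated.
#'
#' @param path File path.
#' @param dialect `"sbtab"` or `"bigg_dump"`.
#' @return List of [metabolite_record()]s.
#' @export
read_metabolite_table <- function(path, dialect = c("sbtab", "bigg_dump")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty metabolite table: ", path, call. = FALSE)
  if (dialect == "sbtab" && startsWith(lines[1], "!!SBtab")) {
    lines <- lines[-1]
  }
  if (!length(lines)) stop("no header row in ", path, call. = FALSE)
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          check.names = FALSE, colClasses = "character",
                          na.strings = c("NA", ""))
  if (dialect == "sbtab") {
    if (!"!ID" %in% names(df)) {
      stop("SBtab table lacks mandatory !ID column", call. = FALSE)
    }
    xref_cols <- grep("^!Identifiers:", names(df), value = TRUE)
    lapply(seq_len(nrow(df)), function(i) {
      xr <- list()
      for (col in xref_cols) {
        vals <- split_xref_cell(df[[col]][i])
        if (length(vals)) xr[[sub("^!Identifiers:", "", col)]] <- vals
      }
      getcol <- function(col) if (col %in% names(df)) df[[col]][i] else NA
      metabolite_record(
        id = df[["!ID"]][i],
        name = as.character(getcol("!Name")),
        formula = as.character(getcol("!Formula")),
        charge = suppressWarnings(as.integer(getcol("!Charge"))),
        compartment = as.character(getcol("!Compartment")),
        xrefs = xr
      )
    })
  } else {
    need <- c("bigg_id", "name")
    if (!all(need %in% names(df))) {
      stop("BiGG dump lacks mandatory column(s): ",
           paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
    }
    lapply(seq_len(nrow(df)), function(i) {
      xr <- list()
      if ("database_links" %in% names(df)) {
        for (entry in split_xref_cell(df[["database_links"]][i])) {
          kv <- regmatches(entry, regexec("^([^:]+):\\s*(.*)$", entry))[[1]]
          if (length(kv) == 3L) {
            db <- trimws(kv[2])
            acc <- basename(trimws(kv[3]))
            xr[[db]] <- c(xr[[db]], acc)
          }
        }
      }
      metabolite_record(id = df[["bigg_id"]][i], name = df[["name"]][i],
                        xrefs = xr)
    })
  }
}

#' Write a metabolite table
#'
#' Inverse of [read_metabolite_table()] for both dialects; read-write identity
#' holds on canonical files (modulo line endings).
#'
#' @param records List of [metabolite_record()]s.
#' @param path Output path.
#' @param dialect `"sbtab"` or `"bigg_dump"`.
#' @return `path`, invisibly.
#' @export
write_metabolite_table <- function(records, path,
                                   dialect = c("sbtab", "bigg_dump")) {
  dialect <- match.arg(dialect)
  if (dialect == "sbtab") {
    dbs <- unique(unlist(lapply(records, function(r) names(r$xrefs))))
    header <- c("!ID", "!Name", "!Formula", "!Charge", "!Compartment",
                if (length(dbs)) paste0("!Identifiers:", dbs))
    rows <- vapply(records, function(r) {
      xcells <- vapply(dbs, function(db)
        paste(r$xrefs[[db]], collapse = ";"), character(1))
      paste(c(r$id, blank_na(r$name), blank_na(r$formula),
              blank_na(r$charge), blank_na(r$compartment), xcells),
            collapse = "\t")
    }, character(1))
    writeLines(c(paste(header, collapse = "\t"), rows), path)
  } else {
    rows <- vapply(records, function(r) {
      links <- unlist(lapply(names(r$xrefs), function(db)
        paste0(db, ": ", r$xrefs[[db]])))
      paste(c(r$id, blank_na(r$name), paste(links, collapse = "; ")),
            collapse = "\t")
    }, character(1))
    writeLines(c("bigg_id\tname\tdatabase_links", rows), path)
  }
  invisible(path)
}

blank_na <- function(x) if (is.na(x)) "" else as.character(x)

#' Build a legacy-ID alias table
#'
#' @param legacy Character vector of legacy identifiers.
#' @param source Source namespace of each (`"iCEL1273"`, `"ElegCyc"`,
#'   `"WormJam"`, `"BiGG"`, ...).
#' @param systematic Target systematic identifier; must pass
#'   [is_valid_model_id()].
#' @return A data.frame of class `alias_table`.
#' @export
alias_table <- function(legacy, source, systematic) {
  stopifnot(length(legacy) == length(source),
            length(legacy) == length(systematic))
  bad <- systematic[!is_valid_model_id(systematic)]
  if (length(bad)) {
    stop("invalid systematic id(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(source, legacy, sep = "\r")
  dup <- key[duplicated(key)]
  conflicting <- vapply(unique(dup), function(k) {
    length(unique(systematic[key == k])) > 1L
  }, logical(1))
  if (any(conflicting)) {
    stop("legacy id mapped to several systematic ids within one source",
         call. = FALSE)
  }
  structure(data.frame(legacy = legacy, source = source,
                       systematic = systematic, stringsAsFactors = FALSE),
            class = c("alias_table", "data.frame"))
}

#' Migrate legacy metabolite ids to systematic ids
#'
#' Every record whose id matches an alias-table row is renamed. When two
#' legacy ids collapse onto one systematic id the records are merged (first
#' record wins, xrefs unioned) and flagged in the report: such collisions are
#' how duplicated reactions hidden behind divergent naming are detected.
#' Unmatched ids pass through unchanged and are listed in the report.
#'
#' @param records List of [metabolite_record()]s.
#' @param alias An [alias_table()].
#' @return List with elements `records` (migrated), `report` (data.frame of
#'   old id, new id, status `migrated`/`unmatched`) and `collisions`
#'   (character vector of systematic ids that absorbed several legacy ids).
#' @export
migrate_ids <- function(records, alias) {
  map <- stats::setNames(alias$systematic, alias$legacy)
  old <- vapply(records, function(r) r$id, character(1))
  new <- ifelse(old %in% names(map), unname(map[old]), old)
  status <- ifelse(old %in% names(map), "migrated", "unmatched")
  report <- data.frame(old = old, new = new, status = status,
                       stringsAsFactors = FALSE)

  out <- list(); seen <- character(0); collisions <- character(0)
  for (i in seq_along(records)) {
    r <- records[[i]]
    r$id <- new[i]
    if (r$id %in% seen) {
      collisions <- c(collisions, r$id)
      j <- which(vapply(out, function(x) x$id == r$id, logical(1)))[1]
      for (db in names(r$xrefs)) {
        out[[j]]$xrefs[[db]] <- unique(c(out[[j]]$xrefs[[db]], r$xrefs[[db]]))
      }
    } else {
      out <- c(out, list(r))
      seen <- c(seen, r$id)
    }
  }
  list(records = out, report = report, collisions = unique(collisions))
}

#' Write generated reactions as an SBtab-style table
#'
#' Columns: `!ID`, `!ReactionFormula` (coefficient dialect of
#' [write_reaction_formula()]), `!IsReversible`, `!Compartment`, `!Step`.
#'
#' @param reactions List of [reaction()]s.
#' @param path Output path, or `NULL` to return the lines.
#' @return The lines, invisibly when written to a file.
#' @export
write_reaction_table <- function(reactions, path = NULL) {
  header <- paste(c("!ID", "!ReactionFormula", "!IsReversible",
                    "!Compartment", "!Step"), collapse = "\t")
  rows <- vapply(reactions, function(r) {
    paste(c(r$id, write_reaction_formula(r),
            if (r$reversible) "TRUE" else "FALSE",
            paste(r$compartment, collapse = ","),
            blank_na(r$step)), collapse = "\t")
  }, character(1))
  lines <- c(header, rows)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
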