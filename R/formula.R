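## Elemental formulas with charge, plus the pseudo-element "R" standing for
## the acyl-carrier-protein residue so symbolic balance works without protein
## atomistics.

#' Construct an elemental formula
#'
#' @param counts Named integer vector, element symbol -> count. Zero counts
#'   are dropped; negative counts are an error.
#' @param charge Integer formal charge.
#' @return An `elemental_formula` object.
#' @export
elemental_formula <- function(counts = integer(0), charge = 0L) {
  counts <- counts[counts != 0]
  if (any(counts < 0)) stop("negative element counts", call. = FALSE)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, charge = as.integer(charge)),
            class = "elemental_formula")
}

#' Parse a Hill-order formula string
#'
#' @param text e.g. `"C14H28O2"`; an optional trailing integer charge such as
#'   `"C21H32N7O16P3S-4"` is honoured.
#' @return An [elemental_formula()].
#' @export
parse_formula <- function(text) {
  stopifnot(length(text) == 1L, nzchar(text))
  charge <- 0L
  cm <- regexpr("[+-]\\d*$", text)
  if (cm > 0) {
    tok <- substring(text, cm)
    charge <- if (tok %in% c("+", "-")) as.integer(paste0(tok, "1"))
              else as.integer(tok)
    text <- substring(text, 1L, cm - 1L)
  }
  m <- gregexpr("([A-Z][a-z]?)(\\d*)", text)[[1]]
  if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(text)) {
    stop("cannot parse formula '", text, "'", call. = FALSE)
  }
  pieces <- regmatches(text, gregexpr("[A-Z][a-z]?\\d*", text))[[1]]
  counts <- integer(0)
  for (p in pieces) {
    el <- gsub("\\d", "", p)
    n <- gsub("\\D", "", p)
    counts[el] <- sum(counts[el], if (nzchar(n)) as.integer(n) else 1L,
                      na.rm = TRUE)
  }
  elemental_formula(counts, charge)
}

#' Format a formula in Hill order
#'
#' Carbon first, hydrogen second, remaining elements (including the ACP
#' pseudo-element `R`) alphabetically; nonzero charge appended as a signed
#' integer.
#'
#' @param formula An [elemental_formula()].
#' @param show_charge Append the charge when nonzero (default `TRUE`).
#' @return A string.
#' @export
format_formula <- function(formula, show_charge = TRUE) {
  cnt <- formula$counts
  els <- names(cnt)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  out <- paste0(vapply(ord, function(e)
    paste0(e, if (cnt[[e]] == 1L) "" else cnt[[e]]), character(1)),
    collapse = "")
  if (show_charge && formula$charge != 0L) {
    out <- paste0(out, sprintf("%+d", formula$charge))
  }
  out
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Element-wise formula arithmetic
#'
#' Addition and subtraction are element-wise on counts and additive on charge;
#' subtraction producing a negative count is an error.
#'
#' @param e1,e2 [elemental_formula()] objects.
#' @return An [elemental_formula()].
#' @export
Ops.elemental_formula <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "==")) {
    stop("operation '", .Generic, "' not defined for formulas", call. = FALSE)
  }
  if (.Generic == "==") {
    return(isTRUE(all.equal(sort_counts(e1$counts), sort_counts(e2$counts))) &&
             e1$charge == e2$charge)
  }
  els <- union(names(e1$counts), names(e2$counts))
  a <- ifelse(els %in% names(e1$counts), e1$counts[els], 0L)
  b <- ifelse(els %in% names(e2$counts), e2$counts[els], 0L)
  n <- if (.Generic == "+") a + b else a - b
  names(n) <- els
  ch <- if (.Generic == "+") e1$charge + e2$charge else e1$charge - e2$charge
  elemental_formula(n[n != 0], ch)
}

sort_counts <- function(x) x[order(names(x))]

## scalar multiple, used when weighting by stoichiometric coefficients;
## returns a plain named numeric (may be negative) for delta arithmetic
formula_times <- function(formula, k) {
  c(formula$counts * k, charge = formula$charge * k)
}

## IUPAC 2021 monoisotopic masses; "R" is the symbolic ACP residue.
MONOISOTOPIC_MASS <- c(
  H = 1.00782503207, C = 12.0, N = 14.0030740048, O = 15.9949146196,
  P = 30.97376163, S = 31.97207100, R = 0.0
)

#' Monoisotopic mass of a formula
#'
#' Sum of per-element monoisotopic masses times counts, deterministic to
#' 1e-6 Da. The ACP pseudo-element `R` contributes zero mass; when present the
#' result carries attribute `symbolic = TRUE` to flag that the number is the
#' mass of the non-protein part only.
#'
#' @param formula An [elemental_formula()].
#' @return Mass in Da (numeric scalar).
#' @export
monoisotopic_mass <- function(formula) {
  els <- names(formula$counts)
  unknown <- setdiff(els, names(MONOISOTOPIC_MASS))
  if (length(unknown)) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  m <- sum(MONOISOTOPIC_MASS[els] * formula$counts)
  if ("R" %in% els) attr(m, "symbolic") <- TRUE
  m
}

## Neutral base moieties added on conjugation (ester/thioester/amide bond
## formation loses one H2O). The ACP macro-formula follows the
## phosphopantetheine-arm convention with pseudo-element R for the apo-protein
## and carries the deprotonated phosphate, hence the class charge of -1 with
## no further proton removed.
BASE_MOIETY <- list(
  coa  = "C21H36N7O16P3S",
  carn = "C7H15NO3",
  nae  = "C2H7NO",
  acp  = "C11H21N2O7PRS"
)

#' Protonation conventions for modelling pH
#'
#' The per-class charge state at modelling pH: how many protons are removed
#' from the neutral conjugate and the resulting formal charge. `"bigg"`
#' (default) follows common practice in curated genome-scale models: free
#' fatty acids as carboxylates (-1), CoA thioesters -4, carnitine esters
#' zwitterionic (0), ACP species -1 via the macro-formula's phosphate,
#' N-acylethanolamides neutral. `"neutral"` keeps every class fully protonated
#' and uncharged, which is the scale on which the conservation identity
#' conjugate = free acid + base - H2O holds exactly.
#'
#' @param name `"bigg"` or `"neutral"`.
#' @return Named list class -> `c(delta_H, charge)`.
#' @export
protonation_convention <- function(name = c("bigg", "neutral")) {
  name <- match.arg(name)
  if (name == "neutral") {
    conv <- list(fa = c(0L, 0L), acp = c(0L, 0L), coa = c(0L, 0L),
                 carn = c(0L, 0L), nae = c(0L, 0L))
  } else {
    conv <- list(fa = c(-1L, -1L), acp = c(0L, -1L), coa = c(-4L, -4L),
                 carn = c(0L, 0L), nae = c(0L, 0L))
  }
  structure(conv, class = "protonation_convention")
}

#' Elemental formula of the free fatty acid chain
#'
#' Base chain CnH(2n-2d)O2 for n carbons and d declared double bonds, then per
#' functional group: hydroxy +O, peroxy +O2, keto +O-H2, amino +N+H,
#' methyl +C+H2. The class tag is ignored (chain chemistry only); the result
#' is the neutral acid.
#'
#' @param species An [acyl_species()].
#' @param force Compute even for structurally incomplete species (the formula
#'   depends only on counts, not positions), default `FALSE`.
#' @return An [elemental_formula()] with charge 0.
#' @export
free_acid_formula <- function(species, force = FALSE) {
  if (!force && !is_complete(species)) {
    stop("structurally incomplete species (unspecified double-bond positions/",
         "geometry); use force = TRUE to compute from counts alone",
         call. = FALSE)
  }
  n <- species$carbons
  d <- species$n_double_bonds
  counts <- c(C = n, H = 2L * n - 2L * d, O = 2L)
  for (g in species$groups) {
    delta <- switch(g$kind,
      OH  = c(O = 1L),
      OOH = c(O = 2L),
      O   = c(O = 1L, H = -2L),
      NH2 = c(N = 1L, H = 1L),
      Me  = c(C = 1L, H = 2L))
    for (el in names(delta)) {
      counts[el] <- sum(counts[el], delta[[el]], na.rm = TRUE)
    }
  }
  if (any(counts < 0)) stop("inconsistent chain chemistry", call. = FALSE)
  elemental_formula(counts[counts != 0], 0L)
}

#' Formula of the conjugated (class-specific) species
#'
#' Ester, thioester or amide formation: free acid + base moiety - H2O, where
#' the base moieties are coenzyme A (C21H36N7O16P3S), carnitine (C7H15NO3),
#' ethanolamine (C2H7NO) and the ACP macro-residue (default C11H21N2O7PRS,
#' containing pseudo-element R). The protonation convention then removes
#' protons and sets the formal charge per class. Free fatty acids (`fa`) have
#' no base moiety.
#'
#' @param species An [acyl_species()].
#' @param convention A [protonation_convention()] (default `"bigg"`).
#' @param acp_macro Override for the ACP macro-formula string.
#' @param force Passed to [free_acid_formula()].
#' @return An [elemental_formula()].
#' @export
conjugate_formula <- function(species, convention = protonation_convention(),
                              acp_macro = NULL, force = FALSE) {
  cls <- species$acyl_class
  if (!cls %in% ACYL_CLASSES) stop("unknown class '", cls, "'", call. = FALSE)
  acid <- free_acid_formula(species, force = force)
  f <- if (cls == "fa") {
    acid
  } else {
    base_str <- if (cls == "acp" && !is.null(acp_macro)) acp_macro
                else BASE_MOIETY[[cls]]
    acid + parse_formula(base_str) - parse_formula("H2O")
  }
  adj <- convention[[cls]]
  if (adj[1] > 0L) f <- f + elemental_formula(c(H = adj[1]))
  if (adj[1] < 0L) f <- f - elemental_formula(c(H = -adj[1]))
  f$charge <- adj[2]
  f
}
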