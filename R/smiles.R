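## SMILES generation for fully specified acyl species. Output is the neutral
## (fully protonated / zwitterionic) structure, so oracle element counts match
## conjugate_formula() under protonation_convention("neutral").

## neutral coenzyme A attached via its thiol sulfur (C21H36N7O16P3S as free
## thiol; the leading S forms the thioester)
COA_TAIL <- paste0(
  "SCCNC(=O)CCNC(=O)C(O)C(C)(C)COP(=O)(O)OP(=O)(O)OCC1OC",
  "(n2cnc3c(N)ncnc32)C(O)C1OP(=O)(O)O")

## carnitine zwitterion esterified at its 3-hydroxyl (net charge 0)
CARN_TAIL <- "OC(CC(=O)[O-])C[N+](C)(C)C"

## ethanolamine attached via the amide nitrogen
NAE_TAIL <- "NCCO"

#' SMILES of an acyl species
#'
#' Assembles the chain C1 (carbonyl) to Cn with `/C=C\` (Z) and `/C=C/` (E)
#' double-bond encodings and tetrahedral marks on stereo-bearing hydroxy/amino
#' carbons, attached to the class head group: free acid (`fa`), coenzyme A
#' thioester (`coa`), carnitine ester (`carn`, zwitterionic) or
#' N-acylethanolamide (`nae`). The structure is neutral overall, matching
#' [conjugate_formula()] under [protonation_convention()]`("neutral")`.
#' Canonicalization is left to the consuming cheminformatics toolkit.
#'
#' @param species A fully specified [acyl_species()]; class must not be `acp`
#'   (the ACP residue has no full atomistic structure).
#' @return A SMILES string.
#' @export
to_smiles <- function(species) {
  stopifnot(inherits(species, "acyl_species"))
  if (species$acyl_class == "acp") {
    stop("unsupported structure: ACP species are macro-species without a ",
         "full atomistic structure", call. = FALSE)
  }
  if (!is_complete(species)) {
    stop("structurally incomplete species: all double-bond positions and ",
         "geometries must be specified", call. = FALSE)
  }
  n <- species$carbons

  ## bond j joins carbon j and j+1; "=" for a double bond, "/" or "\\" for
  ## the cis/trans marker single bonds flanking it
  bonds <- rep("", n - 1L)
  for (db in species$double_bonds) {
    p <- db$position
    bonds[p] <- "="
    if (p - 1L >= 1L && bonds[p - 1L] == "") bonds[p - 1L] <- "/"
    if (p + 1L <= n - 1L && bonds[p + 1L] == "") {
      bonds[p + 1L] <- if (db$geometry == "Z") "\\" else "/"
    }
  }

  branch <- function(g) switch(g$kind,
    OH = "(O)", OOH = "(OO)", O = "(=O)", NH2 = "(N)", Me = "(C)")

  atoms <- character(n)
  for (i in 2:n) {
    tok <- "C"
    br <- ""
    for (g in species$groups) {
      if (g$position == i) {
        br <- paste0(br, branch(g))
        if (g$kind %in% STEREO_KINDS && !is.na(g$stereo) &&
            g$stereo %in% c("R", "S")) {
          tok <- if (g$stereo == "R") "[C@@H]" else "[C@H]"
        }
      }
    }
    atoms[i] <- paste0(tok, br)
  }

  head <- switch(species$acyl_class,
    fa   = "O=C(O)",
    coa  = paste0("O=C(", COA_TAIL, ")"),
    carn = paste0("O=C(", CARN_TAIL, ")"),
    nae  = paste0("O=C(", NAE_TAIL, ")"))

  body <- ""
  for (i in 2:n) {
    body <- paste0(body, bonds[i - 1L], atoms[i])
  }
  paste0(head, body)
}
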