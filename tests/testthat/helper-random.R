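## Deterministic random-species generator for property tests.
##
## Generated species are always valid: double-bond positions are distinct and
## within 2..carbons-1, one stereo nomenclature family per chain, carnitines
## carry base stereo L (the shorthand does not encode it, so round-trips
## through shorthand stay faithful).
random_species <- function(n, seed = 42, stereo_family = c("RS", "DL")) {
  set.seed(seed)
  stereo_family <- match.arg(stereo_family)
  letters_pool <- if (stereo_family == "RS") c("R", "S") else c("D", "L")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- sample(c("fa", "acp", "coa", "carn", "nae"), 1)
    carbons <- sample(4:26, 1)
    max_db <- min(3L, carbons - 2L)
    ndb <- sample(0:max_db, 1)
    dbpos <- if (ndb > 0) sort(sample(2:(carbons - 1L), ndb)) else integer(0)
    dbs <- lapply(dbpos, function(p)
      double_bond(p, sample(c("Z", "E"), 1)))
    ngr <- sample(0:2, 1)
    grps <- list()
    if (ngr > 0) {
      kinds <- sample(c("OH", "OOH", "O", "NH2", "Me"), ngr, replace = TRUE)
      for (k in kinds) {
        pos <- sample(2:carbons, 1)
        stereo <- if (k %in% c("OH", "NH2") && runif(1) < 0.5)
          sample(letters_pool, 1) else NA_character_
        grps <- c(grps, list(functional_group(k, pos, stereo)))
      }
    }
    base <- if (cls == "carn") "L" else NA_character_
    out[[i]] <- acyl_species(cls, carbons, ndb, dbs, grps, base)
  }
  out
}

## Random balanced reaction roster spanning every generator, for the balance
## property suite.
random_reaction_roster <- function(seed = 7, min_reactions = 500) {
  set.seed(seed)
  rxns <- list()
  while (length(rxns) < min_reactions) {
    carbons <- sample(seq(6L, 24L, 2L), 1)
    ndb <- sample(0:2, 1)
    dbpos <- if (ndb > 0) sort(sample(seq(5L, carbons - 2L), ndb)) else integer(0)
    sp <- acyl_species("coa", carbons, ndb,
                       lapply(dbpos, double_bond, geometry = "Z"))
    kind <- sample(c("betaox", "elong", "desat", "shuttle", "act"), 1)
    new <- switch(kind,
      betaox = generate_beta_oxidation(sp, sample(c("m", "x"), 1)),
      elong = generate_elongation(sp, carbons + sample(c(2L, 4L), 1)),
      desat = {
        free <- setdiff(seq(4L, carbons - 2L), c(dbpos, dbpos + 1L, dbpos - 1L))
        if (length(free)) generate_desaturation(sp, free[1],
                                                sample(c("Z", "E"), 1))
        else list()
      },
      shuttle = generate_carnitine_shuttle(sp),
      act = generate_activation(with_class_fa(sp), sample(c("c", "m"), 1)))
    rxns <- c(rxns, new)
  }
  rxns
}

with_class_fa <- function(sp) {
  sp$acyl_class <- "fa"
  sp$base_stereo <- NA_character_
  sp
}
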