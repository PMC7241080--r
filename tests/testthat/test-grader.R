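test_that("grade_record implements the three-level scheme", {
  ## unique-structure xref: full regardless of parse
  r <- metabolite_record("x_c", xrefs = list(InChIKey = "TUNFSRHWOTWDNC-UHFFFAOYSA-N"))
  expect_equal(grade_record(r)$level, "full")
  r2 <- metabolite_record("x_c", xrefs = list(ChEBI = "CHEBI:28875"))
  expect_equal(grade_record(r2)$level, "full")
  ## two accessions are not a unique structure
  r3 <- metabolite_record("x_c", xrefs = list(ChEBI = c("CHEBI:1", "CHEBI:2")))
  expect_equal(grade_record(r3)$level, "none")

  ## complete structure: full
  oleoyl <- parse_model_id("coa18_1_9z")
  expect_equal(grade_record(metabolite_record("coa18_1_9z_c"), oleoyl)$level,
               "full")

  ## missing double-bond position or geometry: none, named in the rationale
  nopos <- parse_shorthand("CoA(18:1)")
  g <- grade_record(metabolite_record("coa18_1_c"), nopos)
  expect_equal(g$level, "none")
  expect_match(g$rationale, "position")
  nogeom <- acyl_species("coa", 18, 1, list(double_bond(9)))
  g2 <- grade_record(metabolite_record("x_c"), nogeom)
  expect_equal(g2$level, "none")
  expect_match(g2$rationale, "geometry")

  ## only a minor stereo item missing: partial
  carn <- parse_shorthand("Carn(18:1(9Z))", base_stereo_default = NA)
  g3 <- grade_record(metabolite_record("carn18_1_9z_c"), carn)
  expect_equal(g3$level, "partial")
  expect_match(g3$rationale, "carnitine")
  ohnos <- parse_model_id("coa18_1_9z3oh")
  g4 <- grade_record(metabolite_record("x_c"), ohnos)
  expect_equal(g4$level, "partial")

  ## nothing derivable: none
  expect_equal(grade_record(metabolite_record("mysterious_c"))$level, "none")
})

test_that("extract_pairs removes hubs, transport reactions and duplicates", {
  rxns <- list(
    reaction("act", c(fa16_0_c = -1, atp_c = -1, coa_c = -1,
                      coa16_0_c = 1, amp_c = 1, ppi_c = 1)),
    reaction("cpt1", c(coa16_0_c = -1, crn__L_c = -1,
                       carn16_0__L_c = 1, coa_c = 1)),
    ## transport: skipped even without the flag
    reaction("tx", c(fa16_0_c = -1, fa16_0_m = 1)),
    ## duplicate of act under another id: deduplicated
    reaction("act2", c(fa16_0_c = -1, atp_c = -1, coa_c = -1,
                       coa16_0_c = 1, amp_c = 1, ppi_c = 1)),
    ## hub-only reaction contributes nothing
    reaction("hub", c(accoa_c = -1, coa_c = 1, h2o_c = -1))
  )
  pairs <- extract_pairs(rxns)
  expect_equal(nrow(pairs), 2)
  expect_setequal(paste(pairs$a, pairs$b),
                  c("coa16_0_c fa16_0_c", "carn16_0__L_c coa16_0_c"))
})

test_that("count_pairings equals a brute-force tally on a 12-pair fixture", {
  set.seed(99)
  ids <- sprintf("coa%d_0_c", seq(4, 30, 2))
  grades <- stats::setNames(
    as.list(sample(c("full", "partial", "none"), length(ids), replace = TRUE)),
    ids)
  pairs <- data.frame(a = ids[1:12], b = ids[c(3:14)],
                      via_reaction = sprintf("r%d", 1:12),
                      stringsAsFactors = FALSE)
  tab <- count_pairings(pairs, grades)
  expect_equal(sum(tab$count), 12)
  ## brute force
  brute <- integer(6)
  names(brute) <- tab$pairing
  lv <- c(none = 1, partial = 2, full = 3)
  for (i in 1:12) {
    g <- sort(lv[c(grades[[pairs$a[i]]], grades[[pairs$b[i]]])],
              decreasing = TRUE)
    key <- paste(names(lv)[g], collapse = "<->")
    brute[key] <- brute[key] + 1L
  }
  expect_equal(stats::setNames(tab$count, tab$pairing), brute)
  expect_error(count_pairings(pairs, grades[-1]), "no grade")
})

test_that("propagation suggests structures via class transfer and +-2 hops", {
  ## the arachidonoyl example: full FA(20:4) next to an unannotated acyl-CoA,
  ## which is next to an unannotated acyl-carnitine
  fa <- parse_model_id("fa20_4_5z8z11z14z")
  coa_skel <- parse_shorthand("CoA(20:4)")         # skeleton: counts only
  carn_skel <- parse_shorthand("Carn(20:4)", base_stereo_default = NA)
  elong_skel <- parse_shorthand("CoA(22:4)")
  pairs <- data.frame(
    a = c("arachd_c", "arachdcoa_c", "arachdcoa_c"),
    b = c("arachdcoa_c", "arachdcrn_c", "elong22_c"),
    via_reaction = c("r1", "r2", "r3"), stringsAsFactors = FALSE)
  grades <- list(arachd_c = "full", arachdcoa_c = "none", arachdcrn_c = "none",
                 elong22_c = "none")
  species_map <- list(arachd_c = fa, arachdcoa_c = coa_skel,
                      arachdcrn_c = carn_skel, elong22_c = elong_skel)
  sug <- propagate_grades(pairs, grades, species_map)
  expect_equal(nrow(sug), 3)
  expect_equal(sug$path_length, c(1, 2, 2))
  coa_row <- sug[sug$target == "arachdcoa_c", ]
  expect_equal(coa_row$proposed_shorthand, "CoA(20:4(5Z,8Z,11Z,14Z))")
  expect_equal(coa_row$proposed_id, "coa20_4_5z8z11z14z")
  carn_row <- sug[sug$target == "arachdcrn_c", ]
  expect_equal(carn_row$proposed_id, "carn20_4_5z8z11z14z__L")
  expect_match(carn_row$path, "arachd_c -> arachdcoa_c -> arachdcrn_c")
  ## the +2 elongation hop shifts every double bond by +2
  elong_row <- sug[sug$target == "elong22_c", ]
  expect_equal(elong_row$proposed_id, "coa22_4_7z10z13z16z")

  ## no full sources -> no suggestions
  grades2 <- grades; grades2$arachd_c <- "partial"
  expect_equal(nrow(propagate_grades(pairs, grades2, species_map)), 0)

  ## incompatible skeleton (different double-bond count) is not traversed
  species_map2 <- species_map
  species_map2$arachdcoa_c <- parse_shorthand("CoA(20:3)")
  expect_equal(nrow(propagate_grades(pairs, grades, species_map2)), 0)
})

test_that("fixture grades agree with a recount and fractions are honoured", {
  fx <- generate_fixture_model(5, n_acyl = 12, frac_full = 1,
                               frac_partial = 0, frac_none = 0)
  lv <- vapply(fx$grades, function(g) g$level, character(1))
  expect_true(all(lv == "full"))
  fx2 <- generate_fixture_model(5, n_acyl = 12, frac_full = 0,
                                frac_partial = 0, frac_none = 1)
  lv2 <- vapply(fx2$grades, function(g) g$level, character(1))
  expect_true(all(lv2 == "none"))
  expect_equal(nrow(propagate_grades(extract_pairs(fx2$reactions), fx2$grades,
                                     fx2$species)), 0)
  expect_error(generate_fixture_model(1, frac_full = 0.5, frac_partial = 0.1,
                                      frac_none = 0.1), "sum to 1")
})
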