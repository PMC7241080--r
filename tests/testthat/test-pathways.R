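test_that("every generated pathway reaction is mass- and charge-balanced", {
  pw <- generate_pathways()
  rxns <- unlist(pw, recursive = FALSE)
  expect_gt(length(rxns), 400)
  for (r in rxns) expect_true(is_balanced(r), info = r$id)
})

test_that("FAS emits five reactions per cycle plus a terminal release", {
  rxns <- generate_fas(parse_model_id("coa2_0"), 8, compartment = "c")
  expect_length(rxns, 3 * 5 + 1)
  steps <- vapply(rxns, function(r) r$step, character(1))
  expect_equal(steps[1:5], c("load", "condense", "reduce1", "dehydrate",
                             "reduce2"))
  expect_equal(steps[16], "release")
  ## the first condensation consumes the CoA primer directly
  expect_lt(rxns[[2]]$stoichiometry[["accoa_c"]], 0)
  ## later condensations consume the acyl-ACP
  expect_lt(rxns[[7]]$stoichiometry[["acp4_0_c"]], 0)
  ## release hydrolyses to the free acid
  expect_gt(rxns[[16]]$stoichiometry[["fa8_0_c"]], 0)

  expect_error(generate_fas(parse_model_id("coa4_0"), 4), "must exceed")
  expect_error(generate_fas(parse_model_id("coa4_0"), 7), "even number")
  expect_error(generate_fas(parse_shorthand("FA(4:0)"), 8), "acyl-CoA")
})

test_that("FAS from isovaleryl-CoA lumps to the branched-chain net reaction", {
  rxns <- generate_fas(parse_model_id("coa4_0_3me"), 13, compartment = "c")
  keep <- c("coa4_0_3me_c", "malcoa_c", "nadph_c", "nadp_c", "co2_c", "coa_c",
            "h2o_c", "h_c", "fa12_0_11me_c")
  net <- lump(rxns, keep, id = "net")
  expect_true(is_balanced(net))
  expect_equal(net$stoichiometry[["nadph_c"]], -8)
  expect_equal(net$stoichiometry[["malcoa_c"]], -4)
  expect_equal(net$stoichiometry[["h_c"]], -11)
  expect_equal(net$stoichiometry[["co2_c"]], 4)
  expect_equal(net$stoichiometry[["coa_c"]], 5)
  expect_equal(net$stoichiometry[["h2o_c"]], 3)
  expect_equal(net$stoichiometry[["fa12_0_11me_c"]], 1)
})

test_that("elongation shifts double bonds by +2 and costs 2 NADPH per cycle", {
  rxns <- generate_elongation(parse_model_id("coa16_1_9z"), 18)
  expect_length(rxns, 4)
  ## product is vaccenoyl-CoA: the 9Z bond moves to 11Z
  prods <- unlist(lapply(rxns, function(r)
    names(r$stoichiometry)[r$stoichiometry > 0]))
  expect_true("coa18_1_11z_r" %in% prods)
  net <- lump(rxns, c("coa16_1_9z_r", "coa18_1_11z_r", "malcoa_r", "coa_r",
                      "co2_r", "nadph_r", "nadp_r", "h2o_r", "h_r"))
  expect_equal(net$stoichiometry[["nadph_r"]], -2)
  expect_length(generate_elongation(parse_model_id("coa16_0"), 16), 0)
  expect_error(generate_elongation(parse_model_id("coa16_0"), 14), "below")
})

test_that("desaturation consumes O2 and NADH and refuses duplicate bonds", {
  r <- generate_desaturation(parse_model_id("coa18_0"), 9, "Z")[[1]]
  expect_true(is_balanced(r))
  expect_equal(r$stoichiometry[["o2_r"]], -1)
  expect_equal(r$stoichiometry[["nadh_r"]], -1)
  expect_equal(r$stoichiometry[["h2o_r"]], 2)
  expect_equal(r$stoichiometry[["coa18_1_9z_r"]], 1)
  expect_error(generate_desaturation(parse_model_id("coa18_1_9z"), 9),
               "already present")
})

test_that("beta-oxidation of oleoyl-CoA walks the published intermediates", {
  seqn <- generate_beta_oxidation(parse_model_id("coa18_1_9z"), "m")
  expect_equal(head(attr(seqn, "species"), 5),
               c("coa18_1_9z_m", "coa18_2_2e9z_m", "coa18_1_9z3oh__S_m",
                 "coa18_1_9z3o_m", "coa16_1_7z_m"))
  steps <- vapply(seqn, function(r) r$step, character(1))
  expect_equal(steps[1:4], c("dehydrogenate", "hydrate", "oxidize3oh",
                             "thiolyze"))
  ## the 9Z bond reaches position 3 after three cycles: isomerase takes over
  expect_true("isomerize" %in% steps)
  expect_equal(attr(seqn, "terminal"), "accoa_m")
})

test_that("full mitochondrial C16 beta-oxidation lumps to the closed form", {
  seqn <- generate_beta_oxidation(parse_model_id("coa16_0"), "m")
  expect_length(seqn, 7 * 4)
  net <- lump(seqn, c("coa16_0_m", "fad_m", "fadh2_m", "nad_m", "nadh_m",
                      "h2o_m", "coa_m", "accoa_m", "h_m"))
  expect_equal(net$stoichiometry[["fad_m"]], -7)
  expect_equal(net$stoichiometry[["nad_m"]], -7)
  expect_equal(net$stoichiometry[["h2o_m"]], -7)
  expect_equal(net$stoichiometry[["coa_m"]], -7)
  expect_equal(net$stoichiometry[["accoa_m"]], 8)
  expect_equal(net$stoichiometry[["fadh2_m"]], 7)
  expect_equal(net$stoichiometry[["nadh_m"]], 7)
})

test_that("beta-oxidation terminations: odd, iso-branched, peroxisomal", {
  odd <- generate_beta_oxidation(parse_model_id("coa15_0"), "m")
  expect_equal(attr(odd, "terminal"), "ppcoa_m")
  iso <- generate_beta_oxidation(parse_model_id("coa16_0_15me"), "m")
  expect_equal(attr(iso, "terminal"), "coa4_0_3me_m")
  expect_length(iso, 6 * 4)
  perox <- generate_beta_oxidation(parse_model_id("coa16_0"), "x")
  expect_true(all(vapply(perox, is_balanced, logical(1))))
  ## peroxisomal dehydrogenation uses O2 -> H2O2, not FAD
  expect_equal(perox[[1]]$stoichiometry[["o2_x"]], -1)
  expect_equal(perox[[1]]$stoichiometry[["h2o2_x"]], 1)
  expect_error(generate_beta_oxidation(parse_shorthand("CoA(18:1)"), "m"),
               "under-specified")
  expect_error(generate_beta_oxidation(parse_model_id("coa16_0"), "c"), "'m' or 'x'")
})

test_that("sequences merge into a known network and stop", {
  sat <- generate_beta_oxidation(parse_model_id("coa16_0"), "m")
  known <- attr(sat, "species")
  unsat <- generate_beta_oxidation(parse_model_id("coa16_1_9z"), "m",
                                   known = known)
  expect_length(unsat, 13)
  expect_equal(attr(unsat, "terminal"), "coa10_1_2e_m")
  ## linoleoyl-CoA needs the 2,4-dienoyl reductase detour
  unsat2 <- generate_beta_oxidation(parse_model_id("coa18_2_9z12z"), "m",
                                    known = c(known, attr(unsat, "species")))
  steps <- vapply(unsat2, function(r) r$step, character(1))
  expect_true("dienoyl_reduce" %in% steps)
  expect_true(any(steps == "isomerize"))
})

test_that("carnitine shuttle, activation and diffusion templates", {
  sh <- generate_carnitine_shuttle(parse_model_id("coa18_1_9z"))
  expect_length(sh, 3)
  expect_true(all(vapply(sh, is_balanced, logical(1))))
  expect_true(sh[[2]]$is_transport)
  expect_true(sh[[2]]$reversible)
  ## acyl-carnitines keep the carnitine stereocenter
  expect_true("carn18_1_9z__L_m" %in% names(sh[[3]]$stoichiometry))

  act <- generate_activation(parse_shorthand("FA(16:0)"), "c")[[1]]
  expect_true(is_balanced(act))
  expect_equal(act$stoichiometry[["atp_c"]], -1)
  expect_equal(act$stoichiometry[["ppi_c"]], 1)

  diff <- generate_diffusion(parse_shorthand("FA(4:0)"))[[1]]
  expect_true(diff$is_transport)
  expect_true(diff$reversible)
})

test_that("lump cancels intermediates exactly or reports the leak", {
  rxns <- generate_fas(parse_model_id("coa2_0"), 6, compartment = "c")
  keep <- c("accoa_c", "malcoa_c", "nadph_c", "nadp_c", "co2_c", "coa_c",
            "h2o_c", "h_c", "fa6_0_c")
  expect_true(is_balanced(lump(rxns, keep)))
  ## dropping the release step leaves the acyl-ACP uncancelled
  expect_error(lump(rxns[-length(rxns)], keep), "non-cancelling")
})

test_that("pathway counts are stable and categorised", {
  counts <- pathway_counts(generate_pathways())
  expect_equal(counts$category,
               c("fas_cycle", "fas_release", "elongation_desaturation",
                 "betaox_saturated", "betaox_unsaturated", "shuttle",
                 "diffusion"))
  expect_true(all(counts$count > 0))
  expect_equal(sum(counts$count), length(unlist(generate_pathways(),
                                                recursive = FALSE)))
})
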