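test_that("shorthand parses into canonical species", {
  s <- parse_shorthand("CoA(18:1(9Z))")
  expect_equal(s$acyl_class, "coa")
  expect_equal(s$carbons, 18L)
  expect_equal(s$n_double_bonds, 1L)
  expect_equal(s$double_bonds[[1]]$position, 9L)
  expect_equal(s$double_bonds[[1]]$geometry, "Z")

  s2 <- parse_shorthand("FA(18:2(9Z,12Z))")
  expect_equal(vapply(s2$double_bonds, function(d) d$position, integer(1)),
               c(9L, 12L))

  ## count-only shorthand: positions unknown, species incomplete
  s3 <- parse_shorthand("FA(14:1)")
  expect_equal(s3$n_double_bonds, 1L)
  expect_length(s3$double_bonds, 0)
  expect_false(is_complete(s3))

  ## group with stereo
  s4 <- parse_shorthand("CoA(18:1(9Z,3OH[S]))")
  expect_equal(s4$groups[[1]]$stereo, "S")

  ## carnitine base stereo defaulted
  expect_equal(parse_shorthand("Carn(18:1(9Z))")$base_stereo, "L")
  expect_true(is.na(parse_shorthand("Carn(18:1(9Z))",
                                    base_stereo_default = NA)$base_stereo))
})

test_that("malformed shorthand errors carry an offset", {
  expect_error(parse_shorthand("CoA(18:1(9Q))"), "malformed descriptor")
  expect_error(parse_shorthand("CoA(18:1"), "offset")
  expect_error(parse_shorthand("Xyz(18:1(9Z))"), "unknown class")
  expect_error(parse_shorthand("CoA(18:0(9Z))"), "exceed declared count")
  expect_error(parse_shorthand("CoA(18:1(9Z[S]))"), "cannot carry")
})

test_that("model ids encode in both stereo styles", {
  s <- acyl_species("coa", 18, 0, groups = list(functional_group("OH", 3, "S")))
  expect_equal(to_model_id(s), "coa18_0_3ohS")
  expect_equal(to_model_id(s, stereo_style = "suffix"), "coa18_0_3oh__S")
  carn <- parse_shorthand("Carn(18:1(9Z))")
  expect_equal(to_model_id(carn), "carn18_1_9z__L")
  iso <- parse_shorthand("FA(12:0(11Me))")
  expect_equal(to_model_id(iso), "fa12_0_11me")
})

test_that("model id parsing is maximal-munch and dialect-aware", {
  s <- parse_model_id("fa18_2_9z12z")
  expect_equal(vapply(s$double_bonds, function(d) d$position, integer(1)),
               c(9L, 12L))
  expect_equal(parse_model_id("coa18_0_3ohS")$groups[[1]]$stereo, "S")
  expect_equal(parse_model_id("coa18_1_9z3oh__S")$groups[[1]]$stereo, "S")
  ## "5ooh" must munch as one peroxy group, not keto + trailing letters
  s5 <- parse_model_id("fa18_0_5ooh")
  expect_equal(s5$groups[[1]]$kind, "OOH")

  expect_error(parse_model_id("crn18_1_9z__L"), "no acyl class prefix")
  leg <- parse_model_id("crn18_1_9z__L", dialect = "legacy_tolerant")
  expect_equal(leg$acyl_class, "carn")
  expect_equal(leg$base_stereo, "L")
  leg2 <- parse_model_id("nae_18_1_9z", dialect = "legacy_tolerant")
  expect_equal(leg2$acyl_class, "nae")

  expect_error(parse_model_id("fa18_0_3q"), "unknown descriptor token")
  expect_error(parse_model_id("fa18_1_9z__S"), "unassignable stereo suffix")
})

test_that("is_valid_model_id enforces the surface grammar", {
  expect_true(all(is_valid_model_id(c(
    "fa18_2_9z12z", "coa18_0_3ohS", "coa18_1_9z3oh__S", "carn18_1_9z__L",
    "coa4_0_3me", "accoa"))))
  expect_false(any(is_valid_model_id(c(
    "18fa_0", "fa18__2", "Fa18_0", "fa18_0_3OH", "", "fa18_0__Q"))))
})

test_that("codec round-trips over randomized species (inline style)", {
  for (s in random_species(300, seed = 11)) {
    id <- to_model_id(s)
    expect_true(is_valid_model_id(id))
    back <- parse_model_id(id)
    ## carnitine base stereo is not encoded unless set; generator sets L
    expect_true(species_equal(s, back), info = id)
    sh <- format_shorthand(s)
    expect_true(species_equal(s, parse_shorthand(sh)), info = sh)
  }
})

test_that("suffix style round-trips when stereo assignment is unambiguous", {
  ## the suffix dialect assigns __X letters to stereo-less groups in order
  ## (leftover letter -> base stereocenter), so it is only unambiguous when no
  ## stereo-capable chain group is left unlabelled while another stereo letter
  ## (on a group or the base) is present
  sps <- Filter(function(s) {
    open <- vapply(s$groups, function(g)
      g$kind %in% c("OH", "NH2") && is.na(g$stereo), logical(1))
    labelled <- vapply(s$groups, function(g)
      g$kind %in% c("OH", "NH2") && !is.na(g$stereo), logical(1))
    !(any(open) && (any(labelled) || !is.na(s$base_stereo)))
  }, random_species(300, seed = 12))
  expect_gt(length(sps), 50)
  for (s in sps) {
    id <- to_model_id(s, stereo_style = "suffix")
    expect_true(species_equal(s, parse_model_id(id)), info = id)
  }
})
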