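test_that("formula construction, parsing and Hill-order formatting", {
  f <- parse_formula("C14H28O2")
  expect_equal(unclass(f$counts), c(C = 14L, H = 28L, O = 2L))
  expect_equal(f$charge, 0L)
  expect_equal(format_formula(f), "C14H28O2")

  ## trailing charge
  coa <- parse_formula("C21H32N7O16P3S-4")
  expect_equal(coa$charge, -4L)
  expect_equal(format_formula(coa), "C21H32N7O16P3S-4")

  ## Hill order: C, H, then alphabetical including pseudo-element R
  acp <- parse_formula("C11H21N2O7PRS")
  expect_equal(format_formula(acp), "C11H21N2O7PRS")

  expect_error(elemental_formula(c(C = -1L)), "negative")
  expect_error(parse_formula("C14H28O2junk"), "cannot parse")
})

test_that("formula arithmetic is element-wise and never goes negative", {
  a <- parse_formula("C14H28O2")
  b <- parse_formula("H2O")
  expect_equal(format_formula(a + b), "C14H30O3")
  expect_equal(format_formula(a - b), "C14H26O")
  expect_true(a == parse_formula("C14H28O2"))
  expect_error(b - a, "negative")
})

test_that("free acid formulas follow CnH(2n-2d)O2 plus group deltas", {
  expect_equal(format_formula(free_acid_formula(parse_shorthand("FA(14:0)"))),
               "C14H28O2")
  expect_equal(format_formula(free_acid_formula(parse_shorthand("FA(2:0)"))),
               "C2H4O2")
  expect_equal(format_formula(free_acid_formula(parse_shorthand("FA(18:1(9Z))"))),
               "C18H34O2")
  ## group deltas: OH +O, OOH +O2, keto +O-H2, NH2 +N+H, Me +C+H2
  expect_equal(format_formula(free_acid_formula(
    parse_shorthand("FA(18:0(3OH))"))), "C18H36O3")
  expect_equal(format_formula(free_acid_formula(
    parse_shorthand("FA(18:0(9OOH))"))), "C18H36O4")
  expect_equal(format_formula(free_acid_formula(
    parse_shorthand("FA(18:0(3O))"))), "C18H34O3")
  expect_equal(format_formula(free_acid_formula(
    parse_shorthand("FA(18:0(9NH2))"))), "C18H37NO2")
  expect_equal(format_formula(free_acid_formula(
    parse_shorthand("FA(12:0(11Me))"))), "C13H26O2")

  incomplete <- parse_shorthand("FA(14:1)")
  expect_error(free_acid_formula(incomplete), "incomplete")
  expect_equal(format_formula(free_acid_formula(incomplete, force = TRUE)),
               "C14H26O2")
})

test_that("conjugate formulas are acid + base - H2O plus convention", {
  neutral <- protonation_convention("neutral")
  ## CoA(14:0) neutral = C14H28O2 + C21H36N7O16P3S - H2O
  expect_true(conjugate_formula(parse_shorthand("CoA(14:0)"), neutral) ==
              (parse_formula("C14H28O2") + parse_formula("C21H36N7O16P3S") -
               parse_formula("H2O")))
  ## Carn(18:1(9Z)) = C18H34O2 + C7H15NO3 - H2O
  expect_true(conjugate_formula(parse_shorthand("Carn(18:1(9Z))"), neutral) ==
              (parse_formula("C18H34O2") + parse_formula("C7H15NO3") -
               parse_formula("H2O")))
  ## ACP species contain exactly one pseudo-element R
  facp <- conjugate_formula(parse_shorthand("ACP(14:0)"), neutral)
  expect_equal(facp$counts[["R"]], 1L)

  ## default convention: carboxylate -1, thioester -4
  bigg <- protonation_convention("bigg")
  expect_equal(conjugate_formula(parse_shorthand("FA(14:0)"), bigg)$charge, -1L)
  coa14 <- conjugate_formula(parse_shorthand("CoA(14:0)"), bigg)
  expect_equal(coa14$charge, -4L)
  expect_equal(format_formula(coa14), "C35H58N7O17P3S-4")
})

test_that("conservation identity holds over randomized species", {
  h2o <- parse_formula("H2O")
  bases <- list(coa = "C21H36N7O16P3S", carn = "C7H15NO3",
                nae = "C2H7NO", acp = "C11H21N2O7PRS")
  neutral <- protonation_convention("neutral")
  for (s in random_species(200, seed = 21)) {
    acid <- free_acid_formula(s, force = TRUE)
    conj <- conjugate_formula(s, neutral, force = TRUE)
    lhs <- if (s$acyl_class == "fa") conj
           else conj - parse_formula(bases[[s$acyl_class]]) + h2o
    expect_true(lhs == acid, info = format_shorthand(s, strict = FALSE))
    ## mass conservation to 1e-6 Da (free acids have no base and lose no water)
    expected_mass <- if (s$acyl_class == "fa") {
      as.numeric(monoisotopic_mass(acid))
    } else {
      as.numeric(monoisotopic_mass(acid)) +
        as.numeric(monoisotopic_mass(parse_formula(bases[[s$acyl_class]]))) -
        monoisotopic_mass(h2o)
    }
    expect_equal(as.numeric(monoisotopic_mass(conj)), expected_mass,
                 tolerance = 1e-6)
  }
})

test_that("monoisotopic masses match an independent table", {
  expect_equal(as.numeric(monoisotopic_mass(parse_formula("H2O"))),
               18.010565, tolerance = 1e-6)
  expect_equal(as.numeric(monoisotopic_mass(parse_formula("C14H28O2"))),
               228.208930, tolerance = 1e-6)
  expect_equal(as.numeric(monoisotopic_mass(elemental_formula())), 0)
  ## pseudo-element R: zero mass, flagged symbolic
  m <- monoisotopic_mass(parse_formula("C11H21N2O7PRS"))
  expect_true(attr(m, "symbolic"))
  expect_error(monoisotopic_mass(elemental_formula(c(Xx = 1L))),
               "unknown element")
})
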