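# Exact-mass bookkeeping: compositions, adducts, heavy oxygen, ppm errors.

test_that("monoisotopic masses match hand-computed sums", {
  expect_equal(monoisotopic_mass("H2O"), 18.01056, tolerance = 1e-4)
  expect_equal(monoisotopic_mass(comp()), 0)
  # PC 34:2 neutral
  expect_equal(monoisotopic_mass("C42H80NO8P"), 757.56219, tolerance = 1e-4)
  # internal standard PC15:0/18:1-d7
  expect_equal(
    monoisotopic_mass("C41H73[2H]7NO8P"), 752.6061,
    tolerance = 1e-4
  )
})

test_that("unknown element symbols are rejected by name", {
  expect_error(monoisotopic_mass(c(C = 1, Xx = 2)), "Xx")
  expect_error(parse_formula("C5Qq2"), "parse|unknown")
})

test_that("composition arithmetic is element-wise and never negative", {
  a <- parse_formula("C16H32O2")
  b <- comp(O = 1)
  expect_equal(comp_add(a, b), parse_formula("C16H32O3"))
  expect_equal(comp_subtract(comp_add(a, b), b), a)
  expect_error(comp_subtract(b, a), "negative.*C")
})

test_that("mass is additive over random compositions", {
  set.seed(11)
  for (i in 1:25) {
    a <- comp(
      C = sample(0:50, 1), H = sample(0:100, 1), N = sample(0:3, 1),
      O = sample(0:20, 1), P = sample(0:2, 1)
    )
    b <- comp(
      C = sample(0:50, 1), H = sample(0:100, 1), O = sample(0:20, 1),
      D = sample(0:5, 1), O18 = sample(0:3, 1)
    )
    expect_equal(
      monoisotopic_mass(comp_add(a, b)),
      monoisotopic_mass(a) + monoisotopic_mass(b),
      tolerance = 1e-9
    )
  }
})

test_that("adduct m/z reproduces printed precursor values within 5 ppm", {
  m_pc342_o2 <- monoisotopic_mass("C42H80NO10P")
  expect_lt(abs(ppm_error(adduct_mz(m_pc342_o2, "[M+HCOO]-"), 834.5496)), 5)
  expect_lt(abs(ppm_error(adduct_mz(m_pc342_o2, "[M+H]+"), 790.5598)), 5)
  m_81o <- monoisotopic_mass("C32H62NO9P") # PC16:0_8:1;O
  expect_lt(abs(ppm_error(adduct_mz(m_81o, "[M+HCOO]-"), 680.4138)), 5)
  m_cooh <- monoisotopic_mass("C33H64NO10P") # PC16:0_9:0;COOH
  expect_lt(abs(ppm_error(adduct_mz(m_cooh, "[M-H]-"), 664.4190)), 5)
})

test_that("adduct m/z round-trips to the neutral mass exactly", {
  for (ad in c("[M+HCOO]-", "[M-H]-", "[M+H]+")) {
    m <- 789.55202
    expect_equal(neutral_from_mz(adduct_mz(m, ad), ad), m, tolerance = 1e-12)
  }
  expect_error(adduct_mz(700, "[M+2H]2+"), "unknown adduct")
})

test_that("heavy-oxygen substitution shifts mass by n x 2.00425", {
  cmp <- parse_formula("C42H80NO10P")
  for (n in 0:2) {
    lab <- apply_heavy_oxygen(cmp, n, exchangeable = 2)
    expect_equal(
      monoisotopic_mass(lab) - monoisotopic_mass(cmp),
      n * 2.00425,
      tolerance = 1e-5
    )
  }
  expect_identical(apply_heavy_oxygen(cmp, 0, exchangeable = 2), cmp)
  expect_error(apply_heavy_oxygen(cmp, 3, exchangeable = 2), "exceeds")
  # labeled protonated precursors printed for the imaging work
  lab2 <- apply_heavy_oxygen(cmp, 2, exchangeable = 2)
  expect_lt(
    abs(ppm_error(adduct_mz(monoisotopic_mass(lab2), "[M+H]+"), 794.5682)), 5
  )
  lab386 <- apply_heavy_oxygen(parse_formula("C46H80NO10P"), 2,
    exchangeable = 2
  )
  expect_lt(
    abs(ppm_error(adduct_mz(monoisotopic_mass(lab386), "[M+H]+"), 842.5682)),
    5
  )
})

test_that("ppm error is the signed relative deviation", {
  expect_equal(ppm_error(834.5496, 834.5496), 0)
  expect_equal(ppm_error(834.5538, 834.5496), 5.03, tolerance = 0.01)
  expect_equal(ppm_error(790.5598, 790.55926), 0.68, tolerance = 0.01)
  expect_error(
    ppm_error(700, 700, observed_polarity = "pos", theoretical_polarity = "neg"),
    "polarity"
  )
})

test_that("formula strings round-trip through parse and format", {
  for (f in c("C42H80NO8P", "C41H73[2H]7NO8P", "C42H80NO8[18O]2P", "H2O")) {
    expect_identical(format_formula(parse_formula(f)), f)
  }
})

test_that("display rounding follows the two printed conventions", {
  expect_equal(mz_hrms(790.55926), 790.5593)
  expect_equal(mz_nominal(794.5678), 794.5) # truncation, not rounding
  expect_equal(mz_nominal(772.5487), 772.5)
})
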