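# Catalogue expansion, fragment rules, element bounds, library I/O.

test_that("the default catalogue has 155 valid, unique entries", {
  cat155 <- default_catalogue()
  expect_equal(nrow(cat155), 155)
  expect_silent(validate_catalogue(cat155))
  # taxonomy anchors: full-length classes exist for every PUFA
  for (p in c("18:2", "20:4", "22:6")) {
    for (s in c("O-H2", "O", "OOH", "O2", "O2-H2", "O3", "oxo")) {
      expect_true(paste0(p, ";", s) %in% cat155$name_suffix, info = s)
    }
  }
})

test_that("expansion follows the product rule with unique names", {
  lib <- test_library()
  expect_equal(nrow(lib), 465) # 155 x {16:0, 18:0, 18:1}
  expect_equal(anyDuplicated(lib$name), 0L)

  small <- default_catalogue()[c(1, 40), ]
  four <- expand_catalogue(small, c("16:0", "18:0"))
  expect_equal(nrow(four), 4)
  expect_equal(length(unique(four$name)), 4)
  one <- expand_catalogue(small[1, ], "16:0")
  expect_equal(nrow(one), 1)

  expect_error(expand_catalogue(small, c("16:0", "16:0")), "duplicate")
  dup_cat <- dplyr::bind_rows(small, small[1, ])
  expect_error(expand_catalogue(dup_cat, "16:0"), "duplicate")
  expect_error(expand_catalogue(small[0, ], "16:0"), "empty")
})

test_that("carboxyl species route to the deprotonated adduct", {
  lib <- test_library()
  cooh <- lib[lib$sn2_class == "CARBOXYL_TERMINAL", ]
  expect_true(all(cooh$primary_neg_adduct == "[M-H]-"))
  other <- lib[lib$sn2_class != "CARBOXYL_TERMINAL", ]
  expect_true(all(other$primary_neg_adduct == "[M+HCOO]-"))
})

test_that("fragment rules reproduce the printed diagnostic ions", {
  frag_81o <- predict_fragments(library_entry("PC16:0_8:1;O"), "neg")
  near <- function(frags, printed) {
    any(abs(ppm_error(frags$mz, printed)) <= 5)
  }
  expect_true(near(frag_81o, 255.2324)) # [16:0]-
  expect_true(near(frag_81o, 157.0864)) # [C8H13O3]-
  expect_true(near(frag_81o, 620.3927)) # [M-CH3]-

  lib <- test_library()
  frag_ooh_pos <- predict_fragments("PC16:0_18:2;OOH", "pos", library = lib)
  expect_identical(frag_ooh_pos$rule, "R8")
  expect_true(near(frag_ooh_pos, 756.5544))

  frag_cooh <- predict_fragments("PC16:0_9:0;COOH", "neg", library = lib)
  expect_true(near(frag_cooh, 605.3455)) # trimethylamine loss
  expect_true(near(frag_cooh, 201.1126)) # [C9H15O4 + CH2]-

  frag_o2 <- predict_fragments("PC16:0_18:2;O2", "neg", library = lib)
  expect_true(near(frag_o2, 311.2222)) # [18:2;O2]-
  expect_true(near(frag_o2, 293.2117)) # [18:2;O2 - H2O]-

  # classes without applicable positive rules return the empty subset
  expect_equal(
    nrow(predict_fragments("PC16:0_9:0;COOH", "pos", library = lib)), 0
  )
})

test_that("fragment neutral losses conserve the documented masses", {
  lib <- test_library()
  set.seed(4)
  for (i in sample(nrow(lib), 30)) {
    e <- lib[i, ]
    neg <- predict_fragments(e, "neg")
    if ("R4" %in% neg$rule) {
      expect_equal(e$mz_formate - neg$mz[neg$rule == "R4"], 60.0211,
        tolerance = 1e-4
      )
    }
    if ("R5" %in% neg$rule) {
      expect_equal(e$mz_mh_neg - neg$mz[neg$rule == "R5"], 59.0735,
        tolerance = 1e-4
      )
    }
    pos <- predict_fragments(e, "pos")
    if ("R7" %in% pos$rule) {
      expect_equal(e$mz_mh_pos - pos$mz[pos$rule == "R7"], 18.0106,
        tolerance = 1e-4
      )
    }
    if ("R8" %in% pos$rule) {
      expect_equal(e$mz_mh_pos - pos$mz[pos$rule == "R8"], 34.0055,
        tolerance = 1e-4
      )
    }
    # acyl bookkeeping: sn-1 acid + oxidized acid + backbone - 2 H2O = neutral
    sn1_acid <- monoisotopic_mass(acyl_composition(acyl_from_row(e, "sn1")))
    oxfa_acid <- monoisotopic_mass(acyl_composition(acyl_from_row(e, "sn2")))
    backbone <- monoisotopic_mass("C8H20NO6P")
    expect_equal(
      sn1_acid + oxfa_acid + backbone - 2 * monoisotopic_mass("H2O"),
      e$neutral_mass,
      tolerance = 1e-6
    )
  }
})

test_that("element-count bounds are inclusive and element-wise", {
  expect_true(within_element_bounds("C42H80NO10P"))
  expect_false(within_element_bounds("C20H40NO6P")) # C below 26
  expect_true(within_element_bounds("C26H48NO6P")) # boundary
  expect_true(within_element_bounds("C60H130NO30P")) # boundary
  expect_false(within_element_bounds("C61H130NO30P"))
  # heavy isotopes count toward their element
  expect_true(within_element_bounds("C41H73[2H]7NO8P"))
})

test_that("catalogue and library files round-trip exactly", {
  cat155 <- default_catalogue()
  f <- withr::local_tempfile(fileext = ".csv")
  write_catalogue(cat155, f)
  expect_equal(as.data.frame(load_catalogue(f)), as.data.frame(cat155))

  lib <- expand_catalogue(cat155[1:10, ], "16:0")
  fcsv <- withr::local_tempfile(fileext = ".csv")
  export_library(lib, fcsv, "csv")
  back <- read_library(fcsv, "csv")
  expect_equal(as.data.frame(back), as.data.frame(lib), tolerance = 1e-12)

  fjson <- withr::local_tempfile(fileext = ".json")
  export_library(lib, fjson, "json")
  backj <- read_library(fjson, "json")
  expect_equal(as.data.frame(backj), as.data.frame(lib), tolerance = 1e-12)

  fmgf <- withr::local_tempfile(fileext = ".mgf")
  export_library(lib, fmgf, "mgf")
  spectra <- read_mgf(fmgf)
  expect_equal(length(unique(spectra$title)), 10)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), empty)
  expect_error(load_catalogue(empty))
  expect_error(load_catalogue("no/such/file.csv"), "not found")
})
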