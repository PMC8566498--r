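# Precursor matching, MS/MS annotation, functional-isomer discrimination.

test_that("precursor matching finds isobaric candidates within tolerance", {
  lib <- test_library()
  hits <- match_precursor(834.5496, lib)
  expect_true(all(c("PC16:0_18:2;O2", "PC16:0_18:2;OOH") %in% hits$name))
  expect_true(all(abs(hits$ppm_error) <= 5))

  expect_equal(nrow(match_precursor(834.60, lib)), 0)

  cooh <- match_precursor(664.4190, lib)
  expect_true("PC16:0_9:0;COOH" %in% cooh$name)
  expect_equal(
    cooh$adduct[cooh$name == "PC16:0_9:0;COOH"], "[M-H]-"
  )
})

test_that("annotation requires sn-1 evidence plus a second diagnostic", {
  lib <- test_library()
  e81 <- library_entry("PC16:0_8:1;O")
  sp <- tibble::tibble(
    mz = c(255.2330, 157.0870, 620.3928),
    intensity = c(1e5, 8e4, 2e4), polarity = "neg"
  )
  cand <- dplyr::mutate(e81, ppm_error = 0.5)
  ann <- annotate_msms(sp, cand, library = e81)
  expect_true(ann$accepted)
  expect_equal(ann$score, 3L)
  expect_true(ann$sn1_ion && ann$oxacyl_ion && ann$headgroup_ion)

  noise <- tibble::tibble(
    mz = c(150.01, 300.02, 450.5), intensity = rep(1e4, 3), polarity = "neg"
  )
  un <- annotate_msms(noise, cand, library = e81)
  expect_false(un$accepted)
  expect_equal(un$score, 0L)
  expect_equal(un$functional_class, "UNRESOLVED")

  spc <- tibble::tibble(
    mz = c(255.2330, 605.3459, 201.1132),
    intensity = c(1e5, 5e4, 4e4), polarity = "neg"
  )
  candc <- match_precursor(664.4190, lib)
  annc <- annotate_msms(spc, candc, lib)
  expect_true(annc$accepted)
  expect_equal(annc$name, "PC16:0_9:0;COOH")
  expect_equal(annc$functional_class, "CARBOXYL")
  expect_true(annc$trimethylamine_loss && annc$methylated_oxfa)
})

test_that("a spectrum of predicted fragments annotates back to its entry", {
  lib <- test_library()
  set.seed(5)
  idx <- sample(nrow(lib), 40)
  ok <- vapply(idx, function(i) {
    e <- lib[i, ]
    sp <- simulate_msms(e, "neg", n_decoys = 0, seed = i)
    cand <- match_precursor(sp$precursor_mz[1], lib)
    call <- if (e$sn2_class %in% c("HYDROPEROXIDE", "EPOXIDE_OR_HYDROXIDE")) {
      e$sn2_class
    } else {
      NULL
    }
    ann <- annotate_msms(sp, cand, lib, functional_class_call = call)
    # dehydro/keto twins share every measurable channel; either name is the
    # same annotation for species the spectra cannot separate
    twin_ok <- !is.na(ann$name) &&
      lib$formula[lib$name == ann$name] == e$formula &&
      lib$primary_neg_adduct[lib$name == ann$name] == e$primary_neg_adduct
    identical(ann$name, e$name) || twin_ok
  }, logical(1))
  expect_equal(mean(ok), 1)
})

test_that("annotation stays accurate with 100 random decoy peaks", {
  lib <- test_library()
  set.seed(6)
  idx <- sample(nrow(lib), 40)
  ok <- vapply(idx, function(i) {
    e <- lib[i, ]
    sp <- simulate_msms(e, "neg", n_decoys = 100, seed = 1000 + i)
    cand <- match_precursor(sp$precursor_mz[1], lib)
    call <- if (e$sn2_class %in% c("HYDROPEROXIDE", "EPOXIDE_OR_HYDROXIDE")) {
      e$sn2_class
    } else {
      NULL
    }
    ann <- annotate_msms(sp, cand, lib, functional_class_call = call)
    twin_ok <- !is.na(ann$name) &&
      lib$formula[lib$name == ann$name] == e$formula &&
      lib$primary_neg_adduct[lib$name == ann$name] == e$primary_neg_adduct
    identical(ann$name, e$name) || twin_ok
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("H2O2 loss calls hydroperoxide with precedence over H2O loss", {
  prec <- 790.5598
  hp <- tibble::tibble(mz = 756.5544, intensity = 1e5, polarity = "pos")
  expect_equal(discriminate_functional_isomer(hp, prec), "HYDROPEROXIDE")

  ep <- tibble::tibble(mz = 772.5493, intensity = 1e5, polarity = "pos")
  expect_equal(
    discriminate_functional_isomer(ep, prec), "EPOXIDE_OR_HYDROXIDE"
  )

  empty <- tibble::tibble(
    mz = numeric(0), intensity = numeric(0), polarity = character(0)
  )
  expect_equal(discriminate_functional_isomer(empty, prec), "UNRESOLVED")

  both <- tibble::tibble(
    mz = c(772.5493, 756.5544), intensity = c(1e6, 1e3),
    polarity = "pos"
  )
  expect_equal(discriminate_functional_isomer(both, prec), "HYDROPEROXIDE")
  expect_equal(
    discriminate_functional_isomer(both[2:1, ], prec), "HYDROPEROXIDE"
  )

  negsp <- tibble::tibble(mz = 756.5544, intensity = 1e5, polarity = "neg")
  expect_error(discriminate_functional_isomer(negsp, prec), "positive")
})
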