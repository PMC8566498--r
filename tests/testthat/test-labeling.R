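# 18O transitions, labeling-efficiency estimation, ion images, artifacts.

test_that("labeled transitions reproduce the printed MALDI pairs", {
  lib <- test_library()
  t342 <- labeled_transition("PC16:0_18:2;O2", 2, library = lib)
  expect_equal(c(t342$precursor, t342$product), c(794.5, 774.5))
  t364 <- labeled_transition("PC16:0_20:4;O2", 2, library = lib)
  expect_equal(c(t364$precursor, t364$product), c(818.5, 798.5))
  t386 <- labeled_transition("PC16:0_22:6;O2", 2, library = lib)
  expect_equal(c(t386$precursor, t386$product), c(842.5, 822.5))
  expect_equal(t342$loss, "H2[18O]")
  expect_equal(t342$isolation_width, 1.0)

  # unlabeled water-loss transition of the same species
  t0 <- labeled_transition("PC16:0_18:2;O2", 0, library = lib)
  expect_equal(c(t0$precursor, t0$product), c(790.5, 772.5))
  expect_equal(t0$loss, "H2O")
  expect_equal(t0$precursor_exact, 790.5593, tolerance = 1e-4)
  expect_equal(t0$product_exact, 772.5487, tolerance = 1e-4)

  expect_error(
    labeled_transition("PC16:0_18:2;O2", 3, library = lib), "exceeds"
  )
})

test_that("transition mass deltas match the labeled/unlabeled losses", {
  lib <- test_library()
  tl <- transition_list(
    c("PC16:0_18:2;O2", "PC18:0_20:4;OOH", "PC18:1_22:6;O3"),
    n_labels = 2, library = lib
  )
  expect_true(all(tl$product < tl$precursor))
  expect_true(all(abs(
    (tl$precursor_exact - tl$product_exact) - 20.0148
  ) < 1e-3))
  expect_true(all(abs((tl$precursor - tl$product) - 20.0148) <= 0.05))
  t0 <- labeled_transition("PC16:0_18:2;O2", 0, library = lib)
  expect_true(abs((t0$precursor - t0$product) - 18.0106) <= 0.05)
})

test_that("the envelope estimator is the weighted labeled-atom fraction", {
  expect_equal(estimate_labeling_efficiency(c(0, 0, 1))$p_hat, 1.0)
  expect_equal(estimate_labeling_efficiency(c(0, 1, 1))$p_hat, 0.75)
  expect_error(estimate_labeling_efficiency(c(0, 0, 0)), "all-zero")
  expect_error(estimate_labeling_efficiency(c(-1, 1, 1)), "negative")

  fit <- estimate_labeling_efficiency(c(10, 40, 50))
  expect_equal(fit$p_hat, (40 + 100) / 200)
  td <- generics::tidy(fit)
  expect_equal(td$estimate, fit$p_hat)
  gl <- generics::glance(fit)
  expect_equal(gl$n_exchangeable, 2)
})

test_that("the estimator recovers the binomial labeling probability", {
  env <- simulate_envelope(0.722, n_labels = 2, n_ions = 10000, seed = 7)
  expect_equal(estimate_labeling_efficiency(env)$p_hat, 0.722,
    tolerance = 0.02 / 0.722
  )
  # scale invariance
  expect_equal(
    estimate_labeling_efficiency(env * 1e3)$p_hat,
    estimate_labeling_efficiency(env)$p_hat
  )
  # near-unbiased at large ion counts
  big <- simulate_envelope(0.722, n_labels = 2, n_ions = 1e5, seed = 17)
  expect_lt(abs(estimate_labeling_efficiency(big)$p_hat - 0.722), 0.005)
})

test_that("ion images rescale to 0-100, preserving order and zeros", {
  g <- matrix(c(0, 1e4, 2.5e4, 5e4), 2, 2)
  img <- render_ion_image(g)
  expect_equal(max(img), 100)
  expect_equal(img[1, 1], 0)
  expect_identical(order(as.vector(img)), order(as.vector(g)))
  expect_identical(render_ion_image(g * 2), img)

  zero <- matrix(0, 3, 3)
  expect_identical(render_ion_image(zero), zero)

  neg <- g
  neg[1, 1] <- -5
  expect_error(render_ion_image(neg), "negative")
})

test_that("the artifact screen flags light-channel control signal", {
  scr <- artificial_oxidation_screen(
    labeled = c(1e5, 1e5, 0),
    unlabeled_control = c(0, 5e4, 0)
  )
  expect_equal(scr$flag, c("clean", "ARTIFACT_PRONE", "clean"))
})

test_that("MSI grids round-trip through CSV", {
  sim <- simulate_msi("pericentral", nrow = 20, ncol = 25, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_msi_grid(sim$grid, f)
  back <- read_msi_grid(f)
  expect_equal(dim(back), dim(sim$grid))
  expect_equal(back, sim$grid, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("plot helpers return ggplot objects", {
  lib <- test_library()
  sp <- simulate_msms("PC16:0_18:2;O2", "neg", seed = 2, library = lib)
  expect_s3_class(plot_spectrum(sp), "ggplot")
  eic <- extract_eic(gaussian_run(), 700, 5)
  expect_s3_class(plot_eic(eic), "ggplot")
  sim <- simulate_msi("uniform", nrow = 10, ncol = 10, seed = 4)
  expect_s3_class(plot_ion_image(sim$grid), "ggplot")
  fit <- estimate_labeling_efficiency(c(1, 2, 3))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
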