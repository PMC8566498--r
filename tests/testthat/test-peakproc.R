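# Feature detection, alignment, adduct grouping, background subtraction, EICs.

test_that("a clean Gaussian trace with isotope partner yields one feature", {
  run <- gaussian_run(apex = 5e5, n_scans = 8)
  f <- detect_features(run)
  expect_equal(nrow(f), 1)
  expect_equal(f$mz, 700, tolerance = 1e-3)
  expect_true(f$has_isotopologue)
  expect_gt(f$area, 0)
})

test_that("detection thresholds drop weak, short or partnerless traces", {
  expect_equal(nrow(detect_features(gaussian_run(apex = 5e3))), 0)
  expect_equal(nrow(detect_features(gaussian_run(n_scans = 2))), 0)
  expect_equal(
    nrow(detect_features(gaussian_run(with_partner = FALSE))), 0
  )
  # ... unless the isotope requirement is lifted
  f <- detect_features(
    gaussian_run(with_partner = FALSE),
    detection_params(min_isotopes = 0)
  )
  expect_equal(nrow(f), 1)
  expect_false(f$has_isotopologue)
})

test_that("mixed-polarity runs are rejected", {
  run <- gaussian_run()
  run$polarity[1] <- "pos"
  expect_error(detect_features(run), "polarit")
})

test_that("detection is monotone in the intensity and S/N thresholds", {
  set.seed(21)
  for (rep in 1:5) {
    traces <- lapply(1:6, function(i) {
      gaussian_run(
        mz = 500 + i * 17.3,
        apex = 10^stats::runif(1, 3.5, 6),
        n_scans = sample(2:10, 1),
        rt0 = stats::runif(1, 4, 10)
      )
    })
    run <- dplyr::bind_rows(traces)
    counts_int <- vapply(c(1e3, 1e4, 1e5, 1e6), function(thr) {
      nrow(detect_features(run, detection_params(min_intensity = thr)))
    }, numeric(1))
    expect_true(all(diff(counts_int) <= 0))
    counts_sn <- vapply(c(1, 3, 10, 100, 1e4), function(sn) {
      nrow(detect_features(run, detection_params(sn = sn)))
    }, numeric(1))
    expect_true(all(diff(counts_sn) <= 0))
  }
})

make_features <- function(mz, rt, area, sample) {
  tibble::tibble(
    sample = sample, mz = mz, rt = rt, area = area,
    apex_intensity = area, n_scans = 8L, has_isotopologue = TRUE
  )
}

test_that("runs shifted within the window pair one-to-one", {
  a <- make_features(c(700, 750, 800), c(5, 6, 7), c(1e5, 2e5, 3e5), "a")
  b <- make_features(c(700, 750, 800), c(5, 6, 7) + 0.05, c(1e5, 2e5, 3e5), "b")
  g <- align_runs(list(a, b))
  expect_equal(nrow(g), 3)
  expect_true(all(g$area_a > 0 & g$area_b > 0))
})

test_that("a shift beyond the window with no correction gives no pairs", {
  a <- make_features(c(700, 750, 800), c(5, 6, 7), c(1e5, 2e5, 3e5), "a")
  b <- make_features(c(700, 750, 800), c(5, 6, 7) + 0.2, c(1e5, 2e5, 3e5), "b")
  g <- align_runs(list(a, b), estimate_shift = FALSE)
  expect_equal(nrow(g), 6) # every feature alone in its group
  expect_true(all((g$area_a == 0) != (g$area_b == 0)))
})

test_that("median-shift correction from anchors restores the pairing", {
  a <- make_features(c(700, 750, 800), c(5, 6, 7), c(1e5, 2e5, 3e5), "a")
  b <- make_features(c(700, 750, 800), c(5, 6, 7) + 0.2, c(1e5, 2e5, 3e5), "b")
  g <- align_runs(list(a, b), estimate_shift = TRUE)
  expect_equal(nrow(g), 3)
  expect_true(all(g$area_a > 0 & g$area_b > 0))
})

test_that("alignment group memberships are order-independent", {
  set.seed(9)
  a <- make_features(
    500 + (1:10) * 13, stats::runif(10, 4, 9), stats::runif(10, 1e4, 1e6), "a"
  )
  b <- a
  b$sample <- "b"
  b$rt <- b$rt + stats::rnorm(10, 0, 0.02)
  g1 <- align_runs(list(a, b))
  g2 <- align_runs(list(b, a))
  key <- function(g) {
    g <- g[order(g$mz), ]
    paste(round(g$mz, 3), g$area_a > 0, g$area_b > 0)
  }
  expect_identical(key(g1), key(g2))
})

test_that("formate/deprotonated adduct pairs merge on co-elution", {
  feats <- tibble::tibble(
    mz = c(664.4190, 664.4190 + 46.00548),
    rt = c(3.00, 3.02),
    area = c(1e5, 3e5)
  )
  g <- group_adducts(feats)
  expect_equal(nrow(g), 1)
  expect_equal(g$mz, feats$mz[2]) # the larger-area peak represents
  expect_equal(g$area, 4e5)
  expect_equal(g$n_adducts, 2)

  apart <- feats
  apart$rt <- c(3.0, 3.3)
  expect_equal(nrow(group_adducts(apart)), 2)

  single <- feats[1, ]
  gs <- group_adducts(single)
  expect_equal(nrow(gs), 1)
  expect_equal(gs$area, 1e5)
})

test_that("background subtraction keeps strict ratio > 2 and blank-absent", {
  ox <- tibble::tibble(
    compound_id = c("a", "b", "c"),
    area = c(2.5e6, 2.0e6, 1.0e5)
  )
  bg <- tibble::tibble(
    compound_id = c("a", "b", "c"),
    area = c(1.0e6, 1.0e6, 0)
  )
  kept <- background_subtract(ox, bg)
  expect_setequal(kept$compound_id, c("a", "c"))
  expect_equal(kept$ratio[kept$compound_id == "a"], 2.5)
  expect_true(is.infinite(kept$ratio[kept$compound_id == "c"]))
  bg$area[1] <- -1
  expect_error(background_subtract(ox, bg), "negative")
})

test_that("EICs have one point per MS1 scan and localize spikes", {
  run <- gaussian_run(n_scans = 20)
  none <- extract_eic(run, 900, 5)
  expect_equal(nrow(none), 20)
  expect_true(all(none$intensity == 0))

  spike <- run
  spike$intensity <- 0
  spike$intensity[spike$scan == 10 & spike$mz == 700] <- 1234
  e <- extract_eic(spike, 700, 5)
  expect_equal(which(e$intensity > 0), 10)

  exact <- extract_eic(run, 700, 0)
  expect_equal(sum(exact$intensity > 0), 20)
  expect_true(all(extract_eic(run, 700.0001, 0)$intensity == 0))
})

test_that("EIC area agrees with the detected feature area within 1%", {
  run <- gaussian_run(apex = 5e5, n_scans = 30)
  f <- detect_features(run)
  e <- extract_eic(run[run$mz == 700, ], 700, 5)
  eic_area <- sum(diff(e$rt) * (head(e$intensity, -1) + tail(e$intensity, -1)) / 2)
  expect_equal(f$area, eic_area, tolerance = 0.01)
})
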