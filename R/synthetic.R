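# Synthetic-data generators: paired oxidized/nonoxidized LC-MS runs with
# known ground truth, DDA-style MS/MS spectra, binomial isotopologue
# envelopes, and liver-section-like MSI grids.
#
# Chromatographic peaks are Gaussian (sd 0.05 min) sampled on a 0.012-min
# scan grid (~10 points across the FWHM); every compound carries a +1.00336
# Da isotopologue partner at 30% relative intensity; abundances get
# multiplicative log-normal noise (sd 10%). All generators are deterministic
# under the mandatory seed (R's default Mersenne-Twister stream) and restore
# the caller's RNG state.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification for a simulated oxidized/nonoxidized pair
#'
#' The defaults emulate the in-vitro peroxidation experiments the package
#' models: a shared matrix of nonoxidized PCs at equal abundance in both
#' runs, plus oxPC species spiked into the oxidized run only, with an
#' inducer-dependent class profile.
#'
#' @param seed Mandatory integer seed.
#' @param library Library the spikes are drawn from (default
#'   [build_library()]).
#' @param n_spikes Number of spiked oxPC species (default 10).
#' @param preset Inducer profile weighting the oxidation classes:
#'   `"radical"` (hydroperoxide-dominated, as under peroxyl-radical or
#'   autoxidation stress), `"metal"` (mono-/di-oxygenated and truncated
#'   secondary products dominate) or `"uniform"`.
#' @param spike_abundance Mean apex intensity of spiked species.
#' @param matrix_abundance Mean apex intensity of the nonoxidized matrix
#'   PCs.
#' @param n_noise Random single-scan noise centroids per run.
#' @param noise_intensity Mean intensity of noise centroids.
#' @param abundance_cv Multiplicative log-normal noise (sd on the log scale)
#'   applied to every abundance.
#' @param n_decoys Decoy peaks added to each attached MS/MS spectrum.
#' @param identifiable_only Drop library entries that are analytically
#'   indistinguishable in the simulated channels (identical composition,
#'   same precursor adduct, identical fragment set and no positive-mode
#'   discrimination) from the spike pool, keeping the first of each twin
#'   pair (default `TRUE`; see the methods vignette).
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(seed, library = build_library(), n_spikes = 10,
                            preset = c("radical", "metal", "uniform"),
                            spike_abundance = 5e5, matrix_abundance = 2e6,
                            n_noise = 50, noise_intensity = 3e3,
                            abundance_cv = 0.1, n_decoys = 20,
                            identifiable_only = TRUE) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  preset <- match.arg(preset)
  stopifnot(
    n_spikes > 0, spike_abundance > 0, matrix_abundance > 0,
    n_noise >= 0, abundance_cv >= 0
  )
  structure(
    list(
      seed = as.integer(seed), library = library, n_spikes = n_spikes,
      preset = preset, spike_abundance = spike_abundance,
      matrix_abundance = matrix_abundance, n_noise = n_noise,
      noise_intensity = noise_intensity, abundance_cv = abundance_cv,
      n_decoys = n_decoys, identifiable_only = identifiable_only
    ),
    class = "simulation_spec"
  )
}

# class weights per inducer preset
preset_weights <- function(preset, class, truncated) {
  w <- switch(preset,
    radical = ifelse(class == "HYDROPEROXIDE", 20,
      ifelse(truncated, 1, 2)
    ),
    metal = ifelse(class == "HYDROPEROXIDE", 1,
      ifelse(truncated, 2, 6)
    ),
    uniform = rep(1, length(class))
  )
  as.numeric(w)
}

# entries indistinguishable from an earlier one in the simulated channels:
# same composition, same primary negative adduct, and no positive-mode rule
# that separates them (the dehydro/keto twins)
drop_unidentifiable <- function(library) {
  pos_split <- library$sn2_class %in%
    c("HYDROPEROXIDE", "EPOXIDE_OR_HYDROXIDE")
  key <- paste(library$formula, library$primary_neg_adduct,
    library$sn1_carbons, library$sn1_double_bonds,
    ifelse(pos_split, library$sn2_class, "nosplit"),
    sep = "|"
  )
  library[!duplicated(key), ]
}

# midpoint of an "a-b min" retention class, with a default window
rt_class_mean <- function(rt_class) {
  vapply(rt_class, function(s) {
    m <- regmatches(s, regexec("([0-9.]+)-([0-9.]+)", s))[[1]]
    if (length(m) == 3) (as.numeric(m[2]) + as.numeric(m[3])) / 2 else 13.5
  }, numeric(1), USE.NAMES = FALSE)
}

.scan_step <- 0.012 # minutes; ~10 points across a 0.118-min FWHM peak
.peak_sd <- 0.05 # minutes

# centroid rows for one Gaussian trace (+ isotopologue partner)
gaussian_trace <- function(scan_grid, mz, rt, apex, sample) {
  sel <- which(abs(scan_grid$rt - rt) <= 4 * .peak_sd)
  if (length(sel) == 0) {
    return(NULL)
  }
  inten <- apex * exp(-((scan_grid$rt[sel] - rt)^2) / (2 * .peak_sd^2))
  keep <- inten >= 1
  sel <- sel[keep]
  inten <- inten[keep]
  dplyr::bind_rows(
    tibble::tibble(
      sample = sample, scan = scan_grid$scan[sel], rt = scan_grid$rt[sel],
      ms_level = 1L, polarity = "neg", precursor_mz = NA_real_,
      mz = mz, intensity = inten
    ),
    tibble::tibble(
      sample = sample, scan = scan_grid$scan[sel], rt = scan_grid$rt[sel],
      ms_level = 1L, polarity = "neg", precursor_mz = NA_real_,
      mz = mz + mass_delta("c13_shift"), intensity = 0.3 * inten
    )
  )
}

# the shared nonoxidized PC matrix
matrix_species <- function() {
  c(
    "PC16:0_18:2", "PC16:0_20:4", "PC16:0_22:6",
    "PC18:0_18:2", "PC18:0_20:4", "PC18:0_22:6",
    "PC18:1_18:2", "PC18:1_20:4"
  )
}

#' Simulate a paired oxidized/nonoxidized LC-MS experiment
#'
#' Both runs share the nonoxidized PC matrix at equal mean abundance (times
#' multiplicative log-normal noise); the spiked oxPC species appear only in
#' the oxidized run. DDA-style negative-mode MS/MS spectra (and positive-
#' mode spectra for species the water/peroxide losses can classify) are
#' attached for each spike.
#'
#' @param spec A [simulation_spec()].
#' @return List with elements `oxidized` and `nonoxidized` (run tibbles),
#'   `ms2_neg`, `ms2_pos` (MS/MS tibbles keyed by `precursor_mz` and
#'   `name`), and `truth` (spiked species: `name`, `class`, `adduct`, `mz`,
#'   `rt`, `abundance`).
#' @export
#' @examples
#' sim <- simulate_pair(simulation_spec(seed = 1, n_spikes = 3))
#' sim$truth
simulate_pair <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  lib <- spec$library
  if (spec$identifiable_only) lib <- drop_unidentifiable(lib)
  if (any(!is.finite(lib$mz_formate))) {
    stop("library entry without a precursor m/z", call. = FALSE)
  }
  with_seed(spec$seed, {
    w <- preset_weights(spec$preset, lib$sn2_class, lib$sn2_truncated)
    # spikes must be mutually resolvable at the precursor level (> 20 ppm)
    order_pool <- sample(seq_len(nrow(lib)), nrow(lib), prob = w)
    spike_idx <- integer(0)
    spike_mz <- numeric(0)
    for (i in order_pool) {
      mzi <- if (lib$primary_neg_adduct[i] == "[M-H]-") {
        lib$mz_mh_neg[i]
      } else {
        lib$mz_formate[i]
      }
      if (all(abs(spike_mz - mzi) > 20e-6 * mzi)) {
        spike_idx <- c(spike_idx, i)
        spike_mz <- c(spike_mz, mzi)
      }
      if (length(spike_idx) >= spec$n_spikes) break
    }
    if (length(spike_idx) < spec$n_spikes) {
      stop("library too small for the requested number of spikes",
        call. = FALSE
      )
    }
    spikes <- lib[spike_idx, ]
    spikes$precursor <- spike_mz
    spikes$rt <- stats::rnorm(
      nrow(spikes), rt_class_mean(spikes$rt_class), 0.1
    )
    spikes$abundance <- spec$spike_abundance *
      stats::rlnorm(nrow(spikes), 0, spec$abundance_cv)

    mat <- dplyr::bind_rows(lapply(matrix_species(), library_entry))
    mat$precursor <- mat$mz_formate
    mat$rt <- stats::runif(nrow(mat), 12.5, 14.5)
    mat$abundance <- spec$matrix_abundance *
      stats::rlnorm(nrow(mat), 0, spec$abundance_cv)

    scan_grid <- tibble::tibble(
      rt = seq(2, 15, by = .scan_step)
    )
    scan_grid$scan <- seq_len(nrow(scan_grid))

    make_run <- function(sample, compounds) {
      traces <- lapply(seq_len(nrow(compounds)), function(i) {
        apex <- compounds$abundance[i] *
          stats::rlnorm(1, 0, spec$abundance_cv)
        gaussian_trace(
          scan_grid, compounds$precursor[i], compounds$rt[i], apex, sample
        )
      })
      noise <- if (spec$n_noise > 0) {
        tibble::tibble(
          sample = sample,
          scan = sample(scan_grid$scan, spec$n_noise, replace = TRUE),
          ms_level = 1L, polarity = "neg", precursor_mz = NA_real_,
          mz = stats::runif(spec$n_noise, 400, 950),
          intensity = spec$noise_intensity *
            stats::rlnorm(spec$n_noise, 0, 0.5)
        ) |>
          dplyr::left_join(scan_grid, by = "scan") |>
          dplyr::select(
            "sample", "scan", "rt", "ms_level", "polarity",
            "precursor_mz", "mz", "intensity"
          )
      } else {
        NULL
      }
      dplyr::bind_rows(c(traces, list(noise))) |>
        dplyr::arrange(.data$scan, .data$mz)
    }

    oxidized <- make_run("oxidized", dplyr::bind_rows(
      spikes[, c("precursor", "rt", "abundance")],
      mat[, c("precursor", "rt", "abundance")]
    ))
    nonoxidized <- make_run("nonoxidized", mat[, c(
      "precursor", "rt", "abundance"
    )])

    ms2_neg <- dplyr::bind_rows(lapply(seq_len(nrow(spikes)), function(i) {
      sp <- simulate_msms(spikes[i, ], "neg",
        n_decoys = spec$n_decoys,
        seed = spec$seed + i
      )
      sp$name <- spikes$name[i]
      sp
    }))
    pos_idx <- which(spikes$sn2_class %in%
      c("HYDROPEROXIDE", "EPOXIDE_OR_HYDROXIDE"))
    ms2_pos <- if (length(pos_idx) > 0) {
      dplyr::bind_rows(lapply(pos_idx, function(i) {
        sp <- simulate_msms(spikes[i, ], "pos",
          n_decoys = spec$n_decoys,
          seed = spec$seed + 10000L + i
        )
        sp$name <- spikes$name[i]
        sp
      }))
    } else {
      NULL
    }

    list(
      oxidized = oxidized,
      nonoxidized = nonoxidized,
      ms2_neg = ms2_neg,
      ms2_pos = ms2_pos,
      truth = tibble::tibble(
        name = spikes$name,
        class = spikes$sn2_class,
        adduct = spikes$primary_neg_adduct,
        mz = spikes$precursor,
        rt = spikes$rt,
        abundance = spikes$abundance
      )
    )
  })
}

#' Simulate a DDA-style MS/MS spectrum for a library entry
#'
#' Contains every rule-predicted fragment at a random intensity plus
#' `n_decoys` uniform-random peaks that avoid +-20 ppm of any true fragment.
#'
#' @param entry Library row or shorthand name (with `library`).
#' @param polarity `"neg"` or `"pos"`.
#' @param n_decoys Number of decoy peaks.
#' @param seed Integer seed.
#' @param library Library tibble when `entry` is a name.
#' @return Spectrum tibble: `scan`, `rt`, `ms_level`, `polarity`,
#'   `precursor_mz`, `mz`, `intensity`.
#' @export
simulate_msms <- function(entry, polarity = c("neg", "pos"), n_decoys = 0,
                          seed = 1, library = NULL) {
  polarity <- match.arg(polarity)
  entry <- resolve_entry(entry, library)
  frags <- predict_fragments(entry, polarity)
  precursor <- if (polarity == "pos") {
    entry$mz_mh_pos
  } else if (entry$primary_neg_adduct == "[M-H]-") {
    entry$mz_mh_neg
  } else {
    entry$mz_formate
  }
  with_seed(seed, {
    mzs <- frags$mz
    ints <- stats::runif(length(mzs), 1e3, 1e5)
    if (n_decoys > 0) {
      decoys <- numeric(0)
      while (length(decoys) < n_decoys) {
        cand <- stats::runif(n_decoys, 100, precursor)
        ok <- vapply(cand, function(m) {
          all(abs(ppm_error(m, mzs)) > 20)
        }, logical(1))
        decoys <- c(decoys, cand[ok])
      }
      decoys <- decoys[seq_len(n_decoys)]
      mzs <- c(mzs, decoys)
      ints <- c(ints, stats::runif(n_decoys, 1e2, 1e4))
    }
    o <- order(mzs)
    tibble::tibble(
      scan = 1L, rt = NA_real_, ms_level = 2L, polarity = polarity,
      precursor_mz = precursor, mz = mzs[o], intensity = ints[o]
    )
  })
}

#' Simulate a binomial isotopologue envelope
#'
#' Draws `n_ions` molecules each carrying `n_labels` exchangeable oxygens,
#' every oxygen independently heavy with probability `p`, and returns the
#' intensity envelope I0..In.
#'
#' @param p Per-atom labeling probability.
#' @param n_labels Exchangeable oxygens per molecule (default 2).
#' @param n_ions Number of molecules (default 10,000).
#' @param seed Integer seed.
#' @return Numeric vector of length `n_labels + 1`.
#' @export
#' @examples
#' simulate_envelope(0.722, seed = 7)
simulate_envelope <- function(p, n_labels = 2, n_ions = 10000, seed) {
  stopifnot(p >= 0, p <= 1, n_labels >= 1, n_ions > 0)
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  with_seed(seed, {
    k <- stats::rbinom(n_ions, n_labels, p)
    as.numeric(tabulate(k + 1L, nbins = n_labels + 1L))
  })
}

#' Simulate a liver-section-like MSI grid
#'
#' `"pericentral"` places disks of elevated intensity (zonated signal around
#' central-vein-like centers) on a low background; `"uniform"` is flat
#' signal with multiplicative noise. The returned mask marks truth pixels.
#'
#' @param pattern `"pericentral"` or `"uniform"`.
#' @param nrow,ncol Grid size in pixels.
#' @param n_centers Number of zonation centers.
#' @param radius Disk radius in pixels.
#' @param background Background intensity (0 gives an all-zero grid).
#' @param contrast Disk / background intensity ratio.
#' @param cv Multiplicative log-normal noise (sd on the log scale).
#' @param pitch_um Pixel pitch recorded on the grid.
#' @param seed Integer seed.
#' @return List `grid` (matrix with `pitch_um` attribute) and `mask`
#'   (logical matrix).
#' @export
simulate_msi <- function(pattern = c("pericentral", "uniform"),
                         nrow = 60, ncol = 60, n_centers = 6, radius = 5,
                         background = 100, contrast = 8, cv = 0.1,
                         pitch_um = 60, seed) {
  pattern <- match.arg(pattern)
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(nrow > 0, ncol > 0, background >= 0, contrast > 1)
  with_seed(seed, {
    base <- matrix(background, nrow, ncol)
    mask <- matrix(FALSE, nrow, ncol)
    if (pattern == "pericentral" && background > 0) {
      cx <- stats::runif(n_centers, radius + 1, ncol - radius)
      cy <- stats::runif(n_centers, radius + 1, nrow - radius)
      for (k in seq_len(n_centers)) {
        for (i in seq_len(nrow)) {
          for (j in seq_len(ncol)) {
            if ((i - cy[k])^2 + (j - cx[k])^2 <= radius^2) {
              base[i, j] <- background * contrast
              mask[i, j] <- TRUE
            }
          }
        }
      }
    }
    noise <- matrix(stats::rlnorm(nrow * ncol, 0, cv), nrow, ncol)
    grid <- base * noise
    attr(grid, "pitch_um") <- pitch_um
    list(grid = grid, mask = mask)
  })
}

#' Run the full differential workflow on a simulated pair
#'
#' Convenience wrapper chaining [detect_features()], [align_runs()],
#' [background_subtract()], [match_precursor()] and [annotate_msms()] on the
#' output of [simulate_pair()], using the attached MS/MS spectra; isobaric
#' hydroperoxide / epoxy-hydroxide precursors are split with the
#' positive-mode spectra via [discriminate_functional_isomer()], mirroring
#' the two-step annotation procedure.
#'
#' @param sim Output of [simulate_pair()].
#' @param library Library to annotate against.
#' @param params [detection_params()].
#' @param tol_ppm Precursor tolerance.
#' @param frag_tol_ppm Fragment tolerance.
#' @param ratio_threshold Background-subtraction ratio.
#' @return Tibble of retained, annotated compounds (one row per compound).
#' @export
run_pipeline <- function(sim, library = build_library(),
                         params = detection_params(), tol_ppm = 5,
                         frag_tol_ppm = 10, ratio_threshold = 2.0) {
  f_ox <- detect_features(sim$oxidized, params)
  f_bg <- detect_features(sim$nonoxidized, params)
  aligned <- align_runs(list(f_ox, f_bg), max_shift = params$max_rt_shift,
    ppm = params$ppm
  )
  ox_tab <- tibble::tibble(
    compound_id = aligned$compound_id, mz = aligned$mz, rt = aligned$rt,
    area = aligned$area_oxidized
  )
  bg_tab <- tibble::tibble(
    compound_id = aligned$compound_id, area = aligned$area_nonoxidized
  )
  retained <- background_subtract(ox_tab, bg_tab,
    ratio_threshold = ratio_threshold
  )
  if (nrow(retained) == 0) {
    return(tibble::tibble())
  }
  rows <- lapply(seq_len(nrow(retained)), function(i) {
    cand <- match_precursor(retained[i, ], library, tol_ppm = tol_ppm)
    if (nrow(cand) == 0) {
      return(NULL)
    }
    ms2 <- sim$ms2_neg[
      abs(ppm_error(sim$ms2_neg$precursor_mz, retained$mz[i])) <= tol_ppm,
    ]
    class_call <- NULL
    if (!is.null(sim$ms2_pos) && nrow(sim$ms2_pos) > 0) {
      # positive-mode DDA spectrum of the corresponding [M+H]+ precursor
      neutral <- neutral_from_mz(retained$mz[i], "[M+HCOO]-")
      pos_prec <- adduct_mz(max(neutral, 1e-6), "[M+H]+")
      pos <- sim$ms2_pos[
        abs(ppm_error(sim$ms2_pos$precursor_mz, pos_prec)) <= tol_ppm,
      ]
      if (nrow(pos) > 0) {
        class_call <- discriminate_functional_isomer(
          pos, pos$precursor_mz[1],
          tol_ppm = frag_tol_ppm
        )
      }
    }
    ann <- annotate_msms(ms2, cand, library,
      frag_tol_ppm = frag_tol_ppm,
      polarity = "neg", functional_class_call = class_call
    )
    dplyr::bind_cols(
      retained[i, c("compound_id", "mz", "rt", "area", "ratio")],
      ann
    )
  })
  dplyr::bind_rows(rows)
}
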