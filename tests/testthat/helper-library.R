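# the 465-entry default library is used across test files; build it once
.test_env <- new.env(parent = emptyenv())

test_library <- function() {
  if (is.null(.test_env$lib)) {
    .test_env$lib <- build_library()
  }
  .test_env$lib
}

# a single Gaussian MS1 trace with its +1 isotopologue partner, as a run
gaussian_run <- function(mz = 700, apex = 5e5, n_scans = 8, rt0 = 5,
                         with_partner = TRUE, sample = "run") {
  step <- 0.012
  rts <- rt0 + (seq_len(n_scans) - (n_scans + 1) / 2) * step
  inten <- apex * exp(-((rts - rt0)^2) / (2 * 0.05^2))
  main <- tibble::tibble(
    sample = sample, scan = seq_len(n_scans), rt = rts, ms_level = 1L,
    polarity = "neg", precursor_mz = NA_real_, mz = mz, intensity = inten
  )
  if (!with_partner) {
    return(main)
  }
  partner <- dplyr::mutate(main,
    mz = mz + 1.0033548,
    intensity = intensity * 0.3
  )
  dplyr::bind_rows(main, partner)
}
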