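# Spectrum I/O: native MGF reader/writer and an mzML reader via mzR.

#' Write spectra to a Mascot generic format (MGF) file
#'
#' One `BEGIN IONS` block per spectrum. MS2 spectra carry `PEPMASS` and
#' `CHARGE` (`1-` or `1+`); retention time is written in seconds.
#'
#' @param spectra Tibble of centroids with columns `scan`, `rt`, `ms_level`,
#'   `polarity`, `precursor_mz`, `mz`, `intensity` (MS2 rows only are
#'   written; MGF has no MS1 concept).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  ms2 <- spectra[spectra$ms_level == 2, ]
  if (nrow(ms2) == 0) {
    stop("no MS2 spectra to write", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (sc in unique(ms2$scan)) {
    s <- ms2[ms2$scan == sc, ]
    s <- s[order(s$mz), ]
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=scan_", sc),
      paste0("PEPMASS=", format(round(s$precursor_mz[1], 5), nsmall = 5)),
      paste0("CHARGE=1", if (s$polarity[1] == "neg") "-" else "+"),
      paste0("RTINSECONDS=", format(round(s$rt[1] * 60, 3), nsmall = 3)),
      paste(
        format(round(s$mz, 5), nsmall = 5),
        format(s$intensity, scientific = FALSE, trim = TRUE)
      ),
      "END IONS", ""
    ), con)
  }
  invisible(path)
}

#' Read an MGF file into the tidy spectrum format
#'
#' @param path MGF file.
#' @return Tibble with columns `scan`, `rt` (minutes; `NA` if absent),
#'   `ms_level` (2), `polarity`, `precursor_mz`, `mz`, `intensity`, `title`.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  out <- list()
  i <- 1L
  scan <- 0L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      scan <- scan + 1L
      title <- NA_character_
      pepmass <- NA_real_
      rt <- NA_real_
      polarity <- "pos"
      mzs <- numeric(0)
      ints <- numeric(0)
      i <- i + 1L
      while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (grepl("^TITLE=", ln)) {
          title <- sub("^TITLE=", "", ln)
        } else if (grepl("^PEPMASS=", ln)) {
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), " ")[[1]][1])
        } else if (grepl("^RTINSECONDS=", ln)) {
          rt <- as.numeric(sub("^RTINSECONDS=", "", ln)) / 60
        } else if (grepl("^CHARGE=", ln)) {
          polarity <- if (grepl("-", ln, fixed = TRUE)) "neg" else "pos"
        } else if (grepl("^[0-9]", ln)) {
          xy <- strsplit(ln, "[ \t]+")[[1]]
          mzs <- c(mzs, as.numeric(xy[1]))
          ints <- c(ints, if (length(xy) > 1) as.numeric(xy[2]) else 0)
        }
        i <- i + 1L
      }
      if (length(mzs) > 0) {
        out[[length(out) + 1L]] <- tibble::tibble(
          scan = scan, rt = rt, ms_level = 2L, polarity = polarity,
          precursor_mz = pepmass, mz = mzs, intensity = ints, title = title
        )
      }
    }
    i <- i + 1L
  }
  if (length(out) == 0) {
    stop("no spectra found in ", path, call. = FALSE)
  }
  dplyr::bind_rows(out)
}

#' Read a centroided mzML file into the tidy run format
#'
#' Thin wrapper around the Bioconductor `mzR` parser (required only for this
#' function). Multiply charged precursors are rejected: the toolkit works
#' with singly charged PC ions throughout.
#'
#' @param path mzML file.
#' @return Run tibble (`scan`, `rt`, `ms_level`, `polarity`, `precursor_mz`,
#'   `mz`, `intensity`).
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("read_mzml() needs the mzR package", call. = FALSE)
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  charges <- hdr$precursorCharge
  if (any(!is.na(charges) & charges > 1)) {
    stop("multiply charged precursors are not supported", call. = FALSE)
  }
  out <- lapply(seq_len(nrow(hdr)), function(i) {
    m <- pk[[i]]
    if (nrow(m) == 0) {
      return(NULL)
    }
    tibble::tibble(
      scan = hdr$acquisitionNum[i],
      rt = hdr$retentionTime[i] / 60,
      ms_level = hdr$msLevel[i],
      polarity = if (!is.null(hdr$polarity) && hdr$polarity[i] >= 0 &&
        hdr$polarity[i] == 1) {
        "pos"
      } else {
        "neg"
      },
      precursor_mz = if (hdr$msLevel[i] > 1) hdr$precursorMZ[i] else NA_real_,
      mz = m[, 1], intensity = m[, 2]
    )
  })
  dplyr::bind_rows(out)
}
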