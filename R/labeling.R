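# Heavy-oxygen (18O) labeling support: MALDI-MS/MS transition design,
# labeling-efficiency estimation, artifact screening, and ion-image
# rendering.
#
# In-vivo 18O2 exposure makes oxidation-added oxygens heavy (+2.00425 Da
# each), which separates genuine in-vivo oxidation from sample-workup or
# laser-induced artifacts: the artifactual channel stays at the light mass.

#' Design a MALDI-MS/MS transition for a (labeled) library entry
#'
#' The precursor is the protonated ion with `n_labels` oxidation-added
#' oxygens replaced by 18O; the product is the water neutral loss, which
#' departs as H2-18O (20.0148 Da) when the labeled hydroxide leaves and as
#' ordinary H2O (18.0106 Da) when unlabeled. Nominal ion-trap m/z values are
#' truncated to 1 decimal (the convention behind printed pairs such as
#' 794.5 -> 774.5).
#'
#' @param entry One library row or a shorthand name (with `library`).
#' @param n_labels Number of heavy oxygens (<= the entry's added-oxygen
#'   count).
#' @param library Library tibble when `entry` is a name.
#' @param isolation_width Precursor isolation width in m/z units.
#' @return One-row tibble: `name`, `n_labels`, `precursor`, `product`
#'   (nominal, 1 decimal), `loss`, `isolation_width`, `precursor_exact`,
#'   `product_exact`.
#' @export
#' @examples
#' lib <- build_library()
#' labeled_transition("PC16:0_18:2;O2", 2, library = lib) # 794.5 -> 774.5
labeled_transition <- function(entry, n_labels, library = NULL,
                               isolation_width = 1.0) {
  stopifnot(isolation_width > 0)
  entry <- resolve_entry(entry, library)
  labeled <- apply_heavy_oxygen(
    parse_formula(entry$formula), n_labels,
    exchangeable = entry$sn2_added_o
  )
  prec <- adduct_mz(monoisotopic_mass(labeled), "[M+H]+")
  loss <- if (n_labels > 0) mass_delta("h2o18") else mass_delta("h2o")
  prod <- prec - loss
  tibble::tibble(
    name = entry$name,
    n_labels = as.integer(n_labels),
    precursor = mz_nominal(prec),
    product = mz_nominal(prod),
    loss = if (n_labels > 0) "H2[18O]" else "H2O",
    isolation_width = isolation_width,
    precursor_exact = prec,
    product_exact = prod
  )
}

#' @rdname labeled_transition
#' @param names Character vector of entry names.
#' @return For `transition_list()`, one row per name.
#' @export
transition_list <- function(names, n_labels, library,
                            isolation_width = 1.0) {
  dplyr::bind_rows(lapply(names, labeled_transition,
    n_labels = n_labels,
    library = library, isolation_width = isolation_width
  ))
}

#' Estimate the 18O labeling efficiency from an isotopologue envelope
#'
#' Given intensities I0..In of a species carrying 0..n heavy labels, the
#' per-atom labeling probability is estimated as the intensity-weighted
#' labeled-atom fraction `sum(k * Ik) / (n * sum(Ik))` — the maximum-
#' likelihood estimate under a binomial single-probability model in which
#' both added oxygens come from the same O2 pool. The estimator is
#' scale-invariant in the envelope.
#'
#' @param envelope Numeric vector `c(I0, ..., In)` of non-negative
#'   intensities, not all zero.
#' @return An object of class `oxpc_labeling_fit` with elements `p_hat`,
#'   `n_labels`, `envelope`; supports [generics::tidy()],
#'   [generics::glance()] and `autoplot()`.
#' @export
#' @examples
#' estimate_labeling_efficiency(c(0, 1, 1))$p_hat # 0.75
estimate_labeling_efficiency <- function(envelope) {
  stopifnot(is.numeric(envelope), length(envelope) >= 2)
  if (any(envelope < 0)) {
    stop("envelope intensities must be non-negative", call. = FALSE)
  }
  if (sum(envelope) == 0) {
    stop("all-zero isotopologue envelope", call. = FALSE)
  }
  n <- length(envelope) - 1L
  k <- seq_along(envelope) - 1L
  p_hat <- sum(k * envelope) / (n * sum(envelope))
  structure(
    list(p_hat = p_hat, n_labels = n, envelope = envelope),
    class = "oxpc_labeling_fit"
  )
}

#' @export
print.oxpc_labeling_fit <- function(x, ...) {
  cat(
    "18O labeling efficiency: ", sprintf("%.1f%%", 100 * x$p_hat),
    " (", x$n_labels, " exchangeable oxygens)\n",
    sep = ""
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.oxpc_labeling_fit <- function(x, ...) {
  tibble::tibble(term = "labeling_efficiency", estimate = x$p_hat)
}

#' @export
glance.oxpc_labeling_fit <- function(x, ...) {
  tibble::tibble(
    p_hat = x$p_hat,
    n_exchangeable = x$n_labels,
    total_intensity = sum(x$envelope)
  )
}

#' Rescale an ion image to the 0-100 pseudocolor convention
#'
#' Linear rescale so the maximum pixel maps to 100 and zero stays 0; an
#' all-zero grid is returned unchanged (no division by the maximum). Pixel
#' order is preserved.
#'
#' @param grid Non-negative numeric matrix of transition intensities.
#' @return Matrix of the same shape with values in \[0, 100\].
#' @export
render_ion_image <- function(grid) {
  stopifnot(is.matrix(grid), is.numeric(grid))
  if (any(grid < 0)) {
    stop("negative intensities in the image grid", call. = FALSE)
  }
  mx <- max(grid)
  if (mx == 0) {
    return(grid)
  }
  grid / mx * 100
}

#' Flag compounds prone to artifactual (ex-vivo) oxidation
#'
#' A compound whose unlabeled (16O) transition carries signal in a
#' no-stimulation control above `fraction` of its labeled (18O) channel is
#' flagged `ARTIFACT_PRONE` — the light-mass signal cannot come from
#' labeling-period oxidation. Informational only.
#'
#' @param labeled Numeric vector (or tibble column) of 18O-channel signal.
#' @param unlabeled_control Matched 16O-channel signal in the unstimulated
#'   control.
#' @param fraction Flagging threshold as a fraction of the labeled channel
#'   (default 0.05).
#' @param compound Optional compound labels.
#' @return Tibble `compound`, `labeled`, `unlabeled_control`, `flag`
#'   (`"ARTIFACT_PRONE"` or `"clean"`).
#' @export
artificial_oxidation_screen <- function(labeled, unlabeled_control,
                                        fraction = 0.05, compound = NULL) {
  stopifnot(length(labeled) == length(unlabeled_control), fraction > 0)
  if (is.null(compound)) {
    compound <- paste0("compound_", seq_along(labeled))
  }
  flagged <- unlabeled_control > 0 &
    unlabeled_control > fraction * labeled
  tibble::tibble(
    compound = compound,
    labeled = labeled,
    unlabeled_control = unlabeled_control,
    flag = ifelse(flagged, "ARTIFACT_PRONE", "clean")
  )
}

#' Read / write an MSI intensity grid as CSV
#'
#' The native grid format is a plain CSV matrix (rows x columns of
#' intensities); the pixel pitch travels alongside as an attribute.
#'
#' @param path CSV file.
#' @param pitch_um Pixel pitch in micrometres (default 60, the raster step of
#'   the imaging runs this package models).
#' @return `read_msi_grid()` returns a numeric matrix with attribute
#'   `pitch_um`.
#' @export
read_msi_grid <- function(path, pitch_um = 60) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  attr(m, "pitch_um") <- pitch_um
  m
}

#' @rdname read_msi_grid
#' @param grid Numeric matrix.
#' @export
write_msi_grid <- function(grid, path) {
  utils::write.table(grid, path,
    sep = ",", row.names = FALSE,
    col.names = FALSE
  )
  invisible(path)
}
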