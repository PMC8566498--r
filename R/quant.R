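# Semiquantification against the deuterated internal standard and the
# heat-map normalization (log10 + row autoscaling).

#' Shorthand name and ion masses of the internal standard
#'
#' The deuterated internal standard is PC15:0/18:1-d7 (composition
#' C41H73\[2H\]7NO8P, neutral 752.6061 Da, \[M+H\]+ 753.6134). Spiked before
#' extraction; every semiquantitative value is an area ratio against it.
#'
#' @return One-row tibble: `name`, `formula`, `neutral_mass`, `mz_mh_pos`,
#'   `mz_formate`.
#' @export
internal_standard <- function() {
  cmp <- parse_formula("C41H73[2H]7NO8P")
  mass <- monoisotopic_mass(cmp)
  tibble::tibble(
    name = "PC15:0/18:1-d7",
    formula = format_formula(cmp),
    neutral_mass = mass,
    mz_mh_pos = adduct_mz(mass, "[M+H]+"),
    mz_formate = adduct_mz(mass, "[M+HCOO]-")
  )
}

#' Semiquantify peak areas against the internal standard
#'
#' Divides each compound's area by the internal-standard area of the same
#' sample. Ratios are dimensionless and invariant under per-sample
#' instrument-response rescaling.
#'
#' @param areas Long tibble with columns `compound`, `sample`, `area`. Rows
#'   whose `compound` equals `is_compound` provide the internal-standard
#'   areas when `is_areas` is not given.
#' @param is_areas Optional tibble `sample`, `area` (or named numeric vector
#'   by sample) of internal-standard areas.
#' @param is_compound Internal-standard compound label in `areas`.
#' @param tissue_weight Optional tibble `sample`, `weight` (e.g. liver wet
#'   weight in mg); ratios are additionally divided by it.
#' @return Tibble `compound`, `sample`, `ratio` (internal-standard rows
#'   removed).
#' @export
semiquantify <- function(areas, is_areas = NULL,
                         is_compound = internal_standard()$name,
                         tissue_weight = NULL) {
  stopifnot(all(c("compound", "sample", "area") %in% names(areas)))
  if (is.null(is_areas)) {
    is_areas <- areas[areas$compound == is_compound, c("sample", "area")]
    areas <- areas[areas$compound != is_compound, ]
  } else if (is.numeric(is_areas)) {
    is_areas <- tibble::tibble(
      sample = names(is_areas),
      area = unname(is_areas)
    )
  }
  missing <- setdiff(unique(areas$sample), is_areas$sample)
  bad <- unique(c(missing, is_areas$sample[!(is_areas$area > 0)]))
  if (length(bad) > 0) {
    stop("internal standard missing or nonpositive in sample(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  names(is_areas)[names(is_areas) == "area"] <- "is_area"
  out <- dplyr::left_join(areas, is_areas, by = "sample")
  out$ratio <- out$area / out$is_area
  if (!is.null(tissue_weight)) {
    out <- dplyr::left_join(out, tissue_weight, by = "sample")
    out$ratio <- out$ratio / out$weight
    out$weight <- NULL
  }
  dplyr::select(out, "compound", "sample", "ratio")
}

#' Percentage of oxidized PCs in the total PC pool
#'
#' Per sample, `100 * sum(oxPC ratios) / (sum(oxPC ratios) + sum(PC
#' ratios))`. The compound sets must be disjoint.
#'
#' @param oxpc_ratios,pc_ratios Tibbles `compound`, `sample`, `ratio` (see
#'   [semiquantify()]).
#' @return Tibble `sample`, `oxpc_percent` (always in \[0, 100\]).
#' @export
oxpc_fraction <- function(oxpc_ratios, pc_ratios) {
  overlap <- intersect(oxpc_ratios$compound, pc_ratios$compound)
  if (length(overlap) > 0) {
    stop("oxPC and PC compound sets overlap: ",
      paste(utils::head(overlap, 3), collapse = ", "),
      call. = FALSE
    )
  }
  ox <- oxpc_ratios |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(ox = sum(.data$ratio), .groups = "drop")
  pc <- pc_ratios |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(pc = sum(.data$ratio), .groups = "drop")
  out <- dplyr::full_join(ox, pc, by = "sample")
  out$ox[is.na(out$ox)] <- 0
  out$pc[is.na(out$pc)] <- 0
  if (any(out$ox + out$pc == 0)) {
    bad <- out$sample[out$ox + out$pc == 0]
    stop("no signal at all in sample(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(
    sample = out$sample,
    oxpc_percent = 100 * out$ox / (out$ox + out$pc)
  )
}

#' Log10 + autoscale normalization of a quant matrix
#'
#' Per compound (row): `x -> (log10(x) - mean) / sd` with the population
#' standard deviation (heat-map convention). Every output row has mean 0 and
#' standard deviation 1.
#'
#' @param table Tibble whose first column identifies the compound and whose
#'   remaining columns are strictly positive sample values, or a numeric
#'   matrix with rownames.
#' @param lod_floor Optional detection floor: values below it become `NA`
#'   before the log transform (they are reported missing, not zero, to keep
#'   the log defined); rows keep mean/sd over their observed cells.
#' @return Same shape as the input with normalized values.
#' @export
#' @examples
#' normalize_matrix(tibble::tibble(
#'   compound = "x", s1 = 10, s2 = 100, s3 = 1000
#' ))
normalize_matrix <- function(table, lod_floor = NULL) {
  as_matrix <- is.matrix(table)
  if (as_matrix) {
    m <- table
    ids <- rownames(m)
  } else {
    ids <- table[[1]]
    m <- as.matrix(table[, -1, drop = FALSE])
  }
  if (!is.null(lod_floor)) {
    m[m < lod_floor] <- NA_real_
  }
  bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(
      "nonpositive value at compound \"",
      if (is.null(ids)) bad[1, 1] else ids[bad[1, 1]],
      "\", sample column ", colnames(m)[bad[1, 2]],
      call. = FALSE
    )
  }
  lg <- log10(m)
  mu <- rowMeans(lg, na.rm = TRUE)
  n_obs <- rowSums(!is.na(lg))
  sdp <- sqrt(rowSums((lg - mu)^2, na.rm = TRUE) / n_obs)
  if (any(sdp == 0 | !is.finite(sdp))) {
    i <- which(sdp == 0 | !is.finite(sdp))[1]
    stop("constant (or all-missing) row: ",
      if (is.null(ids)) i else ids[i],
      call. = FALSE
    )
  }
  z <- (lg - mu) / sdp
  if (as_matrix) {
    return(z)
  }
  out <- tibble::as_tibble(z)
  dplyr::bind_cols(table[, 1, drop = FALSE], out)
}
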