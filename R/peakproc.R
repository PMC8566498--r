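# Simplified nontargeted feature workflow: centroid chaining, RT alignment,
# adduct grouping, extracted ion chromatograms, and the oxidized-vs-
# nonoxidized background-subtraction screen.
#
# A "run" is a tidy tibble of centroids: one row per (scan, m/z) with columns
# scan, rt (minutes), ms_level (1|2), polarity ("neg"|"pos"), precursor_mz
# (NA for MS1), mz, intensity.

#' Detection parameters for the nontargeted workflow
#'
#' Defaults follow the optimized filtering criteria of the workflow this
#' package reimplements: 5 ppm mass tolerance, signal-to-noise threshold 3,
#' minimum apex intensity 10,000, minimum 3 scans per peak, at least one
#' co-eluting +1 isotopologue, maximum retention-time shift 0.1 min.
#'
#' @param ppm Mass tolerance in parts-per-million.
#' @param sn Signal-to-noise threshold.
#' @param min_intensity Minimum apex intensity.
#' @param min_scans Minimum scans per peak.
#' @param min_isotopes Minimum isotopologues (0 disables the +1 partner
#'   requirement; 1 requires a co-eluting +1.00336 Da partner).
#' @param max_rt_shift Maximum retention-time shift in minutes.
#' @return A list of validated parameters.
#' @export
detection_params <- function(ppm = 5, sn = 3, min_intensity = 1e4,
                             min_scans = 3, min_isotopes = 1,
                             max_rt_shift = 0.1) {
  stopifnot(
    ppm > 0, sn > 0, min_intensity > 0, min_scans > 0,
    min_isotopes >= 0, max_rt_shift > 0
  )
  list(
    ppm = ppm, sn = sn, min_intensity = min_intensity,
    min_scans = min_scans, min_isotopes = min_isotopes,
    max_rt_shift = max_rt_shift
  )
}

# split sorted m/z values into clusters: a new cluster starts where the gap
# to the previous centroid exceeds the ppm tolerance
mz_cluster_ids <- function(mz, ppm) {
  if (length(mz) == 0) {
    return(integer(0))
  }
  o <- order(mz)
  gaps <- diff(mz[o]) > mz[o][-length(mz)] * ppm * 1e-6
  cl_sorted <- cumsum(c(TRUE, gaps))
  out <- integer(length(mz))
  out[o] <- cl_sorted
  out
}

#' Detect chromatographic features in a centroided run
#'
#' Chains centroids across consecutive scans within the ppm tolerance, then
#' keeps a chain as a feature iff it spans at least `min_scans` scans, its
#' apex intensity reaches `min_intensity`, apex / local noise reaches the
#' signal-to-noise threshold, and (when `min_isotopes >= 1`) a +1.00336 Da
#' isotopologue partner co-elutes within tolerance. Local noise is the median
#' intensity of same-m/z-window centroids outside the chain (floor 1).
#' The feature area is the trapezoidal integral of intensity over time;
#' chains recognized as the +1 isotopologue of a stronger co-eluting chain
#' are folded into their parent and not reported.
#'
#' @param run Run tibble (see module description); single polarity.
#' @param params See [detection_params()].
#' @param sample Sample label stored on the output (defaults to a `sample`
#'   column of `run` when present).
#' @return Tibble of features: `sample`, `mz`, `rt`, `area`,
#'   `apex_intensity`, `n_scans`, `has_isotopologue`.
#' @export
detect_features <- function(run, params = detection_params(), sample = NULL) {
  stopifnot(is.data.frame(run), nrow(run) > 0)
  if (length(unique(run$polarity)) > 1) {
    stop("run mixes polarities; detect each polarity separately",
      call. = FALSE
    )
  }
  if (is.null(sample)) {
    sample <- if ("sample" %in% names(run)) run$sample[1] else "run"
  }
  ms1 <- run[run$ms_level == 1, ]
  if (nrow(ms1) == 0) {
    stop("run contains no MS1 centroids", call. = FALSE)
  }

  ms1$cluster <- mz_cluster_ids(ms1$mz, params$ppm)
  scan_index <- sort(unique(ms1$scan))

  # chain = maximal stretch of (near-)consecutive scans within one m/z cluster
  chains <- ms1 |>
    dplyr::group_by(.data$cluster) |>
    dplyr::arrange(.data$scan, .by_group = TRUE) |>
    dplyr::mutate(
      chain = cumsum(c(
        TRUE,
        diff(match(.data$scan, scan_index)) > 2L
      ))
    ) |>
    dplyr::ungroup()

  stats_tbl <- chains |>
    dplyr::group_by(.data$cluster, .data$chain) |>
    dplyr::summarise(
      # area first: summarise evaluates sequentially and rt is redefined below
      area = if (dplyr::n() > 1) {
        sum(diff(.data$rt) * (utils::head(.data$intensity, -1) +
          utils::tail(.data$intensity, -1)) / 2)
      } else {
        0
      },
      mz = stats::weighted.mean(.data$mz, .data$intensity),
      rt = .data$rt[which.max(.data$intensity)],
      apex_intensity = max(.data$intensity),
      n_scans = dplyr::n(),
      first_scan = min(.data$scan),
      last_scan = max(.data$scan),
      .groups = "drop"
    )

  # local noise: same-m/z-cluster centroids outside the chain
  noise <- vapply(seq_len(nrow(stats_tbl)), function(i) {
    cl <- stats_tbl$cluster[i]
    ch <- stats_tbl$chain[i]
    other <- chains$intensity[chains$cluster == cl & chains$chain != ch]
    if (length(other) == 0) 1 else max(1, stats::median(other))
  }, numeric(1))
  stats_tbl$sn <- stats_tbl$apex_intensity / noise

  # isotopologue partners: chain at +1.00336 Da overlapping in scan range
  shift <- mass_delta("c13_shift")
  has_partner <- logical(nrow(stats_tbl))
  is_partner <- logical(nrow(stats_tbl))
  for (i in seq_len(nrow(stats_tbl))) {
    tol <- stats_tbl$mz[i] * params$ppm * 1e-6
    up <- which(
      abs(stats_tbl$mz - (stats_tbl$mz[i] + shift)) <= tol &
        stats_tbl$first_scan <= stats_tbl$last_scan[i] &
        stats_tbl$last_scan >= stats_tbl$first_scan[i]
    )
    if (length(up) > 0) has_partner[i] <- TRUE
    down <- which(
      abs(stats_tbl$mz - (stats_tbl$mz[i] - shift)) <= tol &
        stats_tbl$first_scan <= stats_tbl$last_scan[i] &
        stats_tbl$last_scan >= stats_tbl$first_scan[i] &
        stats_tbl$apex_intensity > stats_tbl$apex_intensity[i]
    )
    if (length(down) > 0) is_partner[i] <- TRUE
  }

  keep <- stats_tbl$n_scans >= params$min_scans &
    stats_tbl$apex_intensity >= params$min_intensity &
    stats_tbl$sn >= params$sn &
    (params$min_isotopes < 1 | has_partner) &
    !is_partner

  out <- stats_tbl[keep, c(
    "mz", "rt", "area", "apex_intensity", "n_scans"
  )]
  out$has_isotopologue <- has_partner[keep]
  tibble::tibble(sample = sample, out)
}

#' Align feature sets across runs
#'
#' Estimates a per-run retention-time shift relative to the first run as the
#' median RT difference of mutual best m/z matches (within `ppm` and
#' `anchor_window`), subtracts it, then groups features greedily (largest
#' area first) within `ppm` and `max_shift`. Each group takes at most one
#' feature per sample and carries per-sample areas, 0 when absent.
#'
#' @param feature_sets A list of feature tibbles ([detect_features()]) or a
#'   single tibble with a `sample` column; at least 2 samples.
#' @param max_shift Maximum residual RT difference within a group (minutes).
#' @param ppm Mass tolerance.
#' @param estimate_shift Estimate and subtract per-run median shifts before
#'   grouping (set `FALSE` to gate on raw retention times).
#' @param anchor_window RT window (minutes) within which mutual best matches
#'   are accepted as shift-estimation anchors.
#' @return Tibble with one row per aligned group: `compound_id`, `mz`,
#'   `rt`, and one `area_<sample>` column per sample.
#' @export
align_runs <- function(feature_sets, max_shift = 0.1, ppm = 5,
                       estimate_shift = TRUE, anchor_window = 1.0) {
  if (is.data.frame(feature_sets)) {
    feature_sets <- split(feature_sets, feature_sets$sample)
  }
  if (length(feature_sets) < 2) {
    stop("alignment needs at least two feature sets", call. = FALSE)
  }
  samples <- vapply(feature_sets, function(x) x$sample[1], "")
  names(feature_sets) <- samples

  ref <- feature_sets[[1]]
  corrected <- feature_sets
  if (estimate_shift) {
    for (k in seq_along(feature_sets)[-1]) {
      run <- feature_sets[[k]]
      delta <- mutual_best_rt_deltas(ref, run, ppm, anchor_window)
      if (length(delta) > 0) {
        corrected[[k]]$rt <- run$rt - stats::median(delta)
      }
    }
  }

  pool <- dplyr::bind_rows(corrected)
  pool <- pool[order(-pool$area), ]
  pool$group <- NA_integer_
  next_id <- 0L
  for (i in seq_len(nrow(pool))) {
    if (!is.na(pool$group[i])) next
    next_id <- next_id + 1L
    pool$group[i] <- next_id
    tol <- pool$mz[i] * ppm * 1e-6
    cand <- which(
      is.na(pool$group) &
        abs(pool$mz - pool$mz[i]) <= tol &
        abs(pool$rt - pool$rt[i]) <= max_shift &
        pool$sample != pool$sample[i]
    )
    # best (largest-area) candidate per sample joins the group
    for (s in unique(pool$sample[cand])) {
      j <- cand[pool$sample[cand] == s][1]
      pool$group[j] <- next_id
    }
  }

  grouped <- pool |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      mz = stats::weighted.mean(.data$mz, .data$area + 1),
      rt = stats::weighted.mean(.data$rt, .data$area + 1),
      .groups = "drop"
    )
  areas <- pool |>
    dplyr::select("group", "sample", "area") |>
    tidyr::pivot_wider(
      names_from = "sample", values_from = "area",
      names_prefix = "area_", values_fill = 0
    )
  out <- dplyr::left_join(grouped, areas, by = "group")
  for (s in samples) {
    col <- paste0("area_", s)
    if (!col %in% names(out)) out[[col]] <- 0
  }
  out <- out[order(out$mz, out$rt), ]
  out$compound_id <- sprintf("cmp_%04d", seq_len(nrow(out)))
  dplyr::select(
    out, "compound_id", "mz", "rt",
    dplyr::all_of(paste0("area_", samples))
  )
}

# RT differences (b - a) of mutual best m/z matches between two feature sets
mutual_best_rt_deltas <- function(a, b, ppm, window) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(numeric(0))
  }
  best_ab <- vapply(seq_len(nrow(a)), function(i) {
    tol <- a$mz[i] * ppm * 1e-6
    cand <- which(abs(b$mz - a$mz[i]) <= tol &
      abs(b$rt - a$rt[i]) <= window)
    if (length(cand) == 0) {
      return(NA_integer_)
    }
    cand[which.min(abs(b$rt[cand] - a$rt[i]))]
  }, integer(1))
  deltas <- numeric(0)
  for (i in seq_len(nrow(a))) {
    j <- best_ab[i]
    if (is.na(j)) next
    tol <- b$mz[j] * ppm * 1e-6
    back <- which(abs(a$mz - b$mz[j]) <= tol &
      abs(a$rt - b$rt[j]) <= window)
    if (length(back) > 0 &&
      back[which.min(abs(a$rt[back] - b$rt[j]))] == i) {
      deltas <- c(deltas, b$rt[j] - a$rt[i])
    }
  }
  deltas
}

#' Merge adduct pairs into compounds
#'
#' Negative-mode features whose m/z values differ by the formic-acid mass
#' (46.00548 Da, the `[M-H]-` vs `[M+HCOO]-` spacing) within `ppm` and co-elute
#' within `rt_tol` minutes are merged; the most abundant peak represents the
#' compound and the areas are combined.
#'
#' @param features Feature tibble with `mz`, `rt`, `area`.
#' @param ppm Mass tolerance.
#' @param rt_tol Co-elution window (minutes).
#' @return Tibble of compounds: representative `mz`, `rt`, summed `area`,
#'   `n_adducts`, `member_mz` (semicolon-joined).
#' @export
group_adducts <- function(features, ppm = 5, rt_tol = 0.1) {
  stopifnot(is.data.frame(features))
  delta <- mass_delta("hcooh")
  n <- nrow(features)
  parent <- seq_len(n)
  for (i in seq_len(n)) {
    tol <- features$mz[i] * ppm * 1e-6
    mate <- which(
      abs(features$mz - (features$mz[i] + delta)) <= tol &
        abs(features$rt - features$rt[i]) <= rt_tol
    )
    for (j in mate) {
      root_i <- find_root(parent, i)
      root_j <- find_root(parent, j)
      if (root_i != root_j) parent[max(root_i, root_j)] <- min(root_i, root_j)
    }
  }
  roots <- vapply(seq_len(n), function(i) find_root(parent, i), integer(1))
  features$group <- roots
  features |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      mz = .data$mz[which.max(.data$area)],
      rt = .data$rt[which.max(.data$area)],
      area = sum(.data$area),
      n_adducts = dplyr::n(),
      member_mz = paste(round(.data$mz, 4), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::select(!"group")
}

find_root <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Oxidized-vs-nonoxidized background subtraction
#'
#' Retains a compound iff its oxidized area divided by its nonoxidized
#' (background) area strictly exceeds `ratio_threshold`. A compound absent
#' from the background (area 0) but present in the oxidized sample is
#' retained: the screen is a presence filter and must not drop genuine
#' oxidation products on division by zero.
#'
#' @param oxidized,nonoxidized Compound tables sharing a key column and an
#'   `area` column (e.g. per-sample slices of [align_runs()] output).
#' @param ratio_threshold Strict ratio cut-off (default 2.0).
#' @param by Shared key column name.
#' @return The retained oxidized rows with `nonoxidized_area` and `ratio`
#'   columns appended (`Inf` when the background area is 0).
#' @export
background_subtract <- function(oxidized, nonoxidized, ratio_threshold = 2.0,
                                by = "compound_id") {
  stopifnot(by %in% names(oxidized), by %in% names(nonoxidized))
  if (any(oxidized$area < 0) || any(nonoxidized$area < 0)) {
    stop("negative peak areas are invalid", call. = FALSE)
  }
  bg <- nonoxidized[, c(by, "area")]
  names(bg)[2] <- "nonoxidized_area"
  joined <- dplyr::left_join(oxidized, bg, by = by)
  joined$nonoxidized_area[is.na(joined$nonoxidized_area)] <- 0
  joined$ratio <- ifelse(
    joined$nonoxidized_area == 0,
    ifelse(joined$area > 0, Inf, 0),
    joined$area / joined$nonoxidized_area
  )
  joined[joined$ratio > ratio_threshold, ]
}

#' Extracted ion chromatogram
#'
#' Per MS1 scan, the summed intensity of centroids within `tol_ppm` of the
#' target m/z. The trace has one point per MS1 scan, zero where nothing
#' matches; `tol_ppm = 0` keeps exact matches only.
#'
#' @param run Run tibble.
#' @param target_mz Target m/z.
#' @param tol_ppm Tolerance in ppm.
#' @return Tibble `scan`, `rt`, `intensity`.
#' @export
extract_eic <- function(run, target_mz, tol_ppm = 5) {
  stopifnot(is.data.frame(run), nrow(run) > 0, target_mz > 0, tol_ppm >= 0)
  ms1 <- run[run$ms_level == 1, ]
  scans <- ms1 |>
    dplyr::distinct(.data$scan, .data$rt) |>
    dplyr::arrange(.data$scan)
  tol <- target_mz * tol_ppm * 1e-6
  hits <- ms1[abs(ms1$mz - target_mz) <= tol, ] |>
    dplyr::group_by(.data$scan) |>
    dplyr::summarise(intensity = sum(.data$intensity), .groups = "drop")
  out <- dplyr::left_join(scans, hits, by = "scan")
  out$intensity[is.na(out$intensity)] <- 0
  out
}
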