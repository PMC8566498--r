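# Library matching and rule-based MS/MS annotation.
#
# The annotation follows the three-case manual procedure for oxPCs:
#  (1) formate-adduct precursors confirmed by the sn-1 carboxylate, the
#      oxidized-acyl carboxylate and the demethylated [M-CH3]- ion;
#  (2) isobaric +2O functional isomers (hydroperoxide vs epoxy-hydroxide)
#      split in positive mode by H2O2- vs H2O-loss;
#  (3) carboxyl-terminal species as deprotonated anions confirmed by
#      trimethylamine loss and the methylated oxidized acyl.

#' Match compound m/z values against library precursors
#'
#' Finds all library entries with any adduct of the requested polarity within
#' `tol_ppm` of each compound m/z. Negative mode checks the entry's primary
#' negative adduct (formate, or `[M-H]-` for carboxyl-terminal species);
#' positive mode checks `[M+H]+`.
#'
#' @param compounds Tibble with an `mz` column (e.g. [align_runs()] output),
#'   or a bare numeric vector of m/z values.
#' @param library Library tibble ([expand_catalogue()]).
#' @param tol_ppm Precursor tolerance (default 5).
#' @param polarity `"neg"` or `"pos"`.
#' @return Tibble of candidate matches: the compound columns plus `name`,
#'   `adduct`, `theoretical_mz`, `ppm_error`, sorted by |ppm| within each
#'   compound.
#' @export
#' @examples
#' lib <- build_library()
#' match_precursor(834.5496, lib)
match_precursor <- function(compounds, library, tol_ppm = 5,
                            polarity = c("neg", "pos")) {
  polarity <- match.arg(polarity)
  if (nrow(library) == 0) stop("library is empty", call. = FALSE)
  if (is.numeric(compounds)) {
    compounds <- tibble::tibble(mz = compounds)
  }
  theo <- if (polarity == "pos") {
    library$mz_mh_pos
  } else {
    ifelse(library$primary_neg_adduct == "[M-H]-",
      library$mz_mh_neg, library$mz_formate
    )
  }
  adduct <- if (polarity == "pos") {
    rep("[M+H]+", nrow(library))
  } else {
    library$primary_neg_adduct
  }
  hits <- lapply(seq_len(nrow(compounds)), function(i) {
    mz <- compounds$mz[i]
    ppm <- ppm_error(mz, theo)
    sel <- which(abs(ppm) <= tol_ppm)
    if (length(sel) == 0) {
      return(NULL)
    }
    sel <- sel[order(abs(ppm[sel]))]
    dplyr::bind_cols(
      compounds[rep(i, length(sel)), , drop = FALSE],
      tibble::tibble(
        name = library$name[sel],
        adduct = adduct[sel],
        theoretical_mz = theo[sel],
        ppm_error = ppm[sel]
      )
    )
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    out <- dplyr::bind_cols(
      compounds[0, , drop = FALSE],
      tibble::tibble(
        name = character(0), adduct = character(0),
        theoretical_mz = numeric(0), ppm_error = numeric(0)
      )
    )
  }
  out
}

#' Annotate an MS/MS spectrum against candidate library entries
#'
#' Scores each candidate by counting its predicted diagnostic fragments in
#' the spectrum (within `frag_tol_ppm`). A candidate is accepted only with
#' sn-1 acyl evidence AND at least one of oxidized-acyl or head-group
#' evidence; the best candidate maximizes the score, ties broken by smaller
#' |precursor ppm error|. The functional-class call is CARBOXYL when both
#' the trimethylamine loss and the methylated oxidized acyl are present,
#' otherwise UNRESOLVED (negative mode cannot split the isobaric
#' hydroperoxide / epoxy-hydroxide pair; see
#' [discriminate_functional_isomer()]).
#'
#' @param ms2 Spectrum tibble with `mz`, `intensity` (and optionally
#'   `polarity`).
#' @param candidates Candidate rows from [match_precursor()] joined to the
#'   library, or any tibble of library rows with a `ppm_error` column
#'   (missing `ppm_error` is treated as 0).
#' @param library Library tibble used to resolve candidate names.
#' @param frag_tol_ppm Fragment tolerance; wider than the precursor
#'   tolerance because printed fragment values deviate up to ~6 ppm from
#'   theory (default 10).
#' @param polarity Spectrum polarity.
#' @param functional_class_call Optional positive-mode class call from
#'   [discriminate_functional_isomer()]; when `"HYDROPEROXIDE"` or
#'   `"EPOXIDE_OR_HYDROXIDE"`, candidates of the conflicting isobaric class
#'   are excluded and the accepted annotation carries the call.
#' @return One-row annotation tibble: `name`, `ppm_error`, `score`, evidence
#'   flags (`headgroup_ion`, `sn1_ion`, `oxacyl_ion`, `trimethylamine_loss`,
#'   `methylated_oxfa`), `functional_class`, `accepted`. When no candidate
#'   reaches the evidence floor the annotation is UNRESOLVED with score 0.
#' @export
annotate_msms <- function(ms2, candidates, library, frag_tol_ppm = 10,
                          polarity = c("neg", "pos"),
                          functional_class_call = NULL) {
  polarity <- match.arg(polarity)
  if ("polarity" %in% names(ms2) &&
    any(ms2$polarity != polarity)) {
    stop("spectrum polarity does not match the requested polarity",
      call. = FALSE
    )
  }
  unresolved <- tibble::tibble(
    name = NA_character_, ppm_error = NA_real_, score = 0L,
    headgroup_ion = FALSE, sn1_ion = FALSE, oxacyl_ion = FALSE,
    trimethylamine_loss = FALSE, methylated_oxfa = FALSE,
    functional_class = "UNRESOLVED", accepted = FALSE
  )
  if (is.null(candidates) || nrow(candidates) == 0 || nrow(ms2) == 0) {
    return(unresolved)
  }

  splittable <- c("HYDROPEROXIDE", "EPOXIDE_OR_HYDROXIDE")
  best <- NULL
  for (i in seq_len(nrow(candidates))) {
    nm <- candidates$name[i]
    if (!is.null(functional_class_call) &&
      functional_class_call %in% splittable) {
      cls <- library$sn2_class[library$name == nm]
      if (length(cls) == 1 && cls %in% splittable &&
        cls != functional_class_call) {
        next
      }
    }
    ppm_i <- if ("ppm_error" %in% names(candidates)) {
      candidates$ppm_error[i]
    } else {
      0
    }
    frags <- predict_fragments(nm, polarity, library = library)
    if (nrow(frags) == 0) next
    present <- vapply(frags$mz, function(m) {
      any(abs(ppm_error(ms2$mz, m)) <= frag_tol_ppm)
    }, logical(1))
    matched <- frags[present, ]
    flags <- list(
      sn1_ion = "R1" %in% matched$rule,
      oxacyl_ion = any(matched$rule %in% c("R2", "R3", "CAT")),
      headgroup_ion = any(matched$rule %in% c("R4", "R5")),
      trimethylamine_loss = "R5" %in% matched$rule,
      methylated_oxfa = "R6" %in% matched$rule
    )
    accepted <- flags$sn1_ion && (flags$oxacyl_ion || flags$headgroup_ion)
    score <- as.integer(nrow(matched))
    cand <- tibble::tibble(
      name = nm, ppm_error = ppm_i, score = score,
      headgroup_ion = flags$headgroup_ion, sn1_ion = flags$sn1_ion,
      oxacyl_ion = flags$oxacyl_ion,
      trimethylamine_loss = flags$trimethylamine_loss,
      methylated_oxfa = flags$methylated_oxfa,
      functional_class = if (flags$trimethylamine_loss &&
        flags$methylated_oxfa) {
        "CARBOXYL"
      } else if (!is.null(functional_class_call) &&
        functional_class_call %in% splittable) {
        functional_class_call
      } else {
        "UNRESOLVED"
      },
      accepted = accepted
    )
    if (accepted && (is.null(best) || score > best$score ||
      (score == best$score && abs(ppm_i) < abs(best$ppm_error)))) {
      best <- cand
    }
  }
  if (is.null(best)) unresolved else best
}

#' Discriminate hydroperoxide vs epoxy-hydroxide functional isomers
#'
#' Positive-mode MS/MS of the protonated precursor: a hydrogen-peroxide
#' neutral loss (-34.0055 Da) calls HYDROPEROXIDE; otherwise a water loss
#' (-18.0106 Da) calls EPOXIDE_OR_HYDROXIDE; otherwise UNRESOLVED. The H2O2
#' loss takes precedence because hydroperoxides can also dehydrate, so the
#' more specific loss wins; the call is independent of peak ordering.
#'
#' @param pos_ms2 Positive-mode spectrum tibble (`mz`, `intensity`, optional
#'   `polarity`).
#' @param precursor_mz The `[M+H]+` precursor m/z.
#' @param tol_ppm Fragment tolerance (default 10).
#' @return `"HYDROPEROXIDE"`, `"EPOXIDE_OR_HYDROXIDE"` or `"UNRESOLVED"`.
#' @export
#' @examples
#' sp <- tibble::tibble(mz = 756.5544, intensity = 1e5, polarity = "pos")
#' discriminate_functional_isomer(sp, 790.5598)
discriminate_functional_isomer <- function(pos_ms2, precursor_mz,
                                           tol_ppm = 10) {
  if ("polarity" %in% names(pos_ms2) && any(pos_ms2$polarity != "pos")) {
    stop("functional-isomer discrimination needs a positive-mode spectrum",
      call. = FALSE
    )
  }
  has_loss <- function(delta) {
    target <- precursor_mz - delta
    any(abs(ppm_error(pos_ms2$mz, target)) <= tol_ppm)
  }
  if (nrow(pos_ms2) == 0) {
    return("UNRESOLVED")
  }
  if (has_loss(mass_delta("h2o2"))) {
    "HYDROPEROXIDE"
  } else if (has_loss(mass_delta("h2o"))) {
    "EPOXIDE_OR_HYDROXIDE"
  } else {
    "UNRESOLVED"
  }
}
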