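# Elemental-composition bookkeeping and exact-mass arithmetic.
#
# Compositions are named integer vectors over the symbols in `isotope_masses()`.
# Heavy isotopes are tracked as their own symbols: "D" (written "[2H]" in
# formula strings) and "O18" (written "[18O]").

.iso_mass <- c(
  C   = 12.0000000,
  H   = 1.0078250,
  D   = 2.0141018,
  N   = 14.0030740,
  O   = 15.9949146,
  O18 = 17.9991596,
  P   = 30.9737615
)

.electron_mass <- 0.0005486
.proton_mass <- .iso_mass[["H"]] - .electron_mass # 1.0072764

# ionic / neutral mass deltas used by adduct and fragmentation rules
.mass_delta <- list(
  formate_anion  = .iso_mass[["C"]] + .iso_mass[["H"]] + 2 * .iso_mass[["O"]] +
    .electron_mass,                                        # HCOO- : 44.99820
  h2o            = 2 * .iso_mass[["H"]] + .iso_mass[["O"]],        # 18.01056
  h2o2           = 2 * .iso_mass[["H"]] + 2 * .iso_mass[["O"]],    # 34.00548
  h2o18          = 2 * .iso_mass[["H"]] + .iso_mass[["O18"]],      # 20.01481
  methyl_formate = 2 * .iso_mass[["C"]] + 4 * .iso_mass[["H"]] +
    2 * .iso_mass[["O"]],                                          # 60.02113
  trimethylamine = 3 * .iso_mass[["C"]] + 9 * .iso_mass[["H"]] +
    .iso_mass[["N"]],                                              # 59.07350
  ch2            = .iso_mass[["C"]] + 2 * .iso_mass[["H"]],        # 14.01565
  hcooh          = .iso_mass[["C"]] + 2 * .iso_mass[["H"]] +
    2 * .iso_mass[["O"]],                                          # 46.00548
  c13_shift      = 1.0033548,
  o18_shift      = .iso_mass[["O18"]] - .iso_mass[["O"]]           # 2.00425
)

#' Monoisotopic isotope mass table
#'
#' Masses (Da) of the isotopes handled by the package, from IUPAC/CODATA.
#' Heavy isotopes are distinct symbols: `D` (deuterium, `[2H]` in formula
#' strings) and `O18` (`[18O]`).
#'
#' @return Named numeric vector of isotope masses in Da.
#' @export
#' @examples
#' isotope_masses()
isotope_masses <- function() .iso_mass

#' Assemble an element composition
#'
#' @param ... Named integer counts, e.g. `comp(C = 42, H = 80, N = 1, O = 8,
#'   P = 1)`. All counts must be non-negative; unknown symbols are an error.
#' @return Named integer vector over the symbols of [isotope_masses()],
#'   zero-count elements dropped.
#' @export
#' @examples
#' comp(H = 2, O = 1)
comp <- function(...) {
  x <- c(...)
  if (length(x) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  as_composition(x)
}

# validate an arbitrary named numeric vector as a composition
as_composition <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("composition counts must be named by element symbol", call. = FALSE)
  }
  bad <- setdiff(names(x), names(.iso_mass))
  if (length(bad) > 0) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(x < 0)) {
    neg <- names(x)[x < 0]
    stop("negative element count for: ", paste(neg, collapse = ", "),
      call. = FALSE
    )
  }
  x <- tapply(as.integer(round(x)), names(x), sum)
  x <- x[x > 0]
  # keep canonical element order
  out <- x[intersect(names(.iso_mass), names(x))]
  stats::setNames(as.integer(out), names(out))
}

#' Add or subtract element compositions
#'
#' Element-wise arithmetic on compositions. Subtraction that would drive any
#' count negative is an error (a fragment cannot remove atoms the precursor
#' does not have).
#'
#' @param a,b Compositions (named integer vectors or formula strings).
#' @return A composition.
#' @export
#' @examples
#' comp_add(parse_formula("C16H32O2"), comp(O = 1))
comp_add <- function(a, b) {
  a <- as_comp_arg(a)
  b <- as_comp_arg(b)
  as_composition(c(a, b))
}

#' @rdname comp_add
#' @export
comp_subtract <- function(a, b) {
  a <- as_comp_arg(a)
  b <- as_comp_arg(b)
  els <- union(names(a), names(b))
  d <- stats::setNames(numeric(length(els)), els)
  d[names(a)] <- d[names(a)] + a
  d[names(b)] <- d[names(b)] - b
  if (any(d < 0)) {
    neg <- els[d < 0]
    stop("subtraction yields negative count for: ",
      paste(neg, collapse = ", "),
      call. = FALSE
    )
  }
  as_composition(d[d > 0])
}

as_comp_arg <- function(x) {
  if (is.character(x)) parse_formula(x) else as_composition(x)
}

#' Parse a molecular formula string
#'
#' Accepts Hill-style formulas such as `"C42H80NO8P"`. Heavy isotopes use
#' bracket notation: `"[2H]"` for deuterium and `"[18O]"` for oxygen-18,
#' e.g. `"C42H80NO8[18O]2P"`.
#'
#' @param formula Single formula string.
#' @return A composition (named integer vector).
#' @export
#' @examples
#' parse_formula("C42H80NO8P")
#' parse_formula("C41H73[2H]7NO8P")
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  s <- gsub("\\s", "", formula)
  if (!nzchar(s)) {
    return(comp())
  }
  pat <- "\\[(\\d+)([A-Z][a-z]?)\\]|([A-Z][a-z]?)"
  m <- gregexpr(paste0("(", pat, ")(\\d*)"), s, perl = TRUE)
  toks <- regmatches(s, m)[[1]]
  if (sum(nchar(toks)) != nchar(s)) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  counts <- list()
  for (tok in toks) {
    n <- sub("^(\\[[^]]+\\]|[A-Za-z]+)", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    el <- sub("\\d+$", "", tok)
    if (grepl("^\\[", el)) {
      el <- switch(el,
        "[2H]" = "D", "[18O]" = "O18",
        stop("unknown isotope token: ", el, call. = FALSE)
      )
    }
    counts[[length(counts) + 1L]] <- stats::setNames(n, el)
  }
  as_composition(unlist(counts))
}

#' Format a composition as a formula string
#'
#' Inverse of [parse_formula()]; heavy isotopes print as `[2H]` and `[18O]`.
#'
#' @param x A composition.
#' @return Formula string.
#' @export
format_formula <- function(x) {
  x <- as_comp_arg(x)
  if (length(x) == 0) {
    return("")
  }
  sym <- names(x)
  disp <- ifelse(sym == "D", "[2H]", ifelse(sym == "O18", "[18O]", sym))
  paste0(disp, ifelse(x > 1, x, ""), collapse = "")
}

#' Monoisotopic mass of a composition
#'
#' @param x A composition (named integer vector) or formula string.
#' @return Mass in Da. The empty composition has mass 0.
#' @export
#' @examples
#' monoisotopic_mass("H2O")
#' monoisotopic_mass("C42H80NO8P") # PC 34:2
monoisotopic_mass <- function(x) {
  x <- as_comp_arg(x)
  if (length(x) == 0) {
    return(0)
  }
  sum(.iso_mass[names(x)] * x)
}

#' Adduct ion m/z from a neutral mass
#'
#' Singly charged adducts only, matching negative-mode formate chemistry of
#' phosphatidylcholines and positive-mode protonation. The electron mass is
#' included in the ion mass (anions gain an electron, cations lose one), so
#' the proton constant is 1.00728 Da.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (> 0). Vectorized.
#' @param adduct One of `"[M+HCOO]-"`, `"[M-H]-"`, `"[M+H]+"` (aliases
#'   `"formate"`, `"deprotonated"`, `"protonated"`).
#' @return m/z value(s).
#' @export
#' @examples
#' adduct_mz(789.55199, "[M+HCOO]-") # PC16:0_18:2;O2 formate adduct
adduct_mz <- function(neutral_mass, adduct) {
  stopifnot(all(neutral_mass > 0))
  adduct <- normalize_adduct(adduct)
  switch(adduct,
    "[M+HCOO]-" = neutral_mass + .mass_delta$formate_anion,
    "[M-H]-"    = neutral_mass - .proton_mass,
    "[M+H]+"    = neutral_mass + .proton_mass
  )
}

#' @rdname adduct_mz
#' @param mz Observed or theoretical ion m/z.
#' @return For `neutral_from_mz()`, the neutral mass recovering the input of
#'   [adduct_mz()] exactly.
#' @export
neutral_from_mz <- function(mz, adduct) {
  adduct <- normalize_adduct(adduct)
  switch(adduct,
    "[M+HCOO]-" = mz - .mass_delta$formate_anion,
    "[M-H]-"    = mz + .proton_mass,
    "[M+H]+"    = mz - .proton_mass
  )
}

#' @rdname adduct_mz
#' @export
adduct_polarity <- function(adduct) {
  adduct <- normalize_adduct(adduct)
  if (adduct == "[M+H]+") "pos" else "neg"
}

normalize_adduct <- function(adduct) {
  stopifnot(is.character(adduct), length(adduct) == 1)
  key <- gsub("[^a-z0-9+-]", "", tolower(adduct))
  out <- switch(adduct,
    "[M+HCOO]-" = ,
    "[M-H]-" = ,
    "[M+H]+" = adduct,
    switch(key,
      "formate" = "[M+HCOO]-",
      "deprotonated" = "[M-H]-",
      "protonated" = "[M+H]+",
      "m+hcoo-" = "[M+HCOO]-",
      "m-h-" = "[M-H]-",
      "m+h+" = "[M+H]+",
      NA_character_
    )
  )
  if (is.na(out)) {
    stop("unknown adduct: ", adduct,
      " (use [M+HCOO]-, [M-H]- or [M+H]+)",
      call. = FALSE
    )
  }
  out
}

#' Substitute oxidation-added oxygens with oxygen-18
#'
#' Replaces `n_labels` light oxygens by `O18` in a composition. Only oxygens
#' added by the oxidative modification are exchangeable under in-vivo
#' 18O2 labeling (ester and phosphate oxygens are not), so callers must say
#' how many oxygens are exchangeable; for a library entry that is its
#' `added_o` count. Each label adds 2.00425 Da.
#'
#' @param x Composition or formula string.
#' @param n_labels Number of oxygens to replace (>= 0).
#' @param exchangeable Number of exchangeable oxygens in `x`.
#' @return Labeled composition.
#' @export
#' @examples
#' apply_heavy_oxygen(parse_formula("C42H80NO10P"), 2, exchangeable = 2)
apply_heavy_oxygen <- function(x, n_labels, exchangeable) {
  x <- as_comp_arg(x)
  stopifnot(length(n_labels) == 1, n_labels >= 0)
  if (n_labels > exchangeable) {
    stop(
      "n_labels (", n_labels, ") exceeds exchangeable oxygens (",
      exchangeable, ")",
      call. = FALSE
    )
  }
  if (n_labels == 0) {
    return(x)
  }
  n_o <- if ("O" %in% names(x)) x[["O"]] else 0L
  if (n_labels > n_o) {
    stop("composition has only ", n_o, " light oxygens", call. = FALSE)
  }
  comp_add(comp_subtract(x, comp(O = n_labels)), comp(O18 = n_labels))
}

#' Signed relative mass error in parts-per-million
#'
#' @param observed,theoretical m/z values (vectorized).
#' @param observed_polarity,theoretical_polarity Optional polarity strings
#'   (`"pos"`/`"neg"`); when both are given they must agree.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
#' @examples
#' ppm_error(834.5538, 834.5496)
ppm_error <- function(observed, theoretical,
                      observed_polarity = NULL, theoretical_polarity = NULL) {
  if (!is.null(observed_polarity) && !is.null(theoretical_polarity) &&
    any(observed_polarity != theoretical_polarity)) {
    stop("polarity mismatch between observed and theoretical m/z",
      call. = FALSE
    )
  }
  1e6 * (observed - theoretical) / theoretical
}

#' Round m/z values by the two display conventions
#'
#' High-resolution m/z values display with 4 decimals; nominal MALDI ion-trap
#' transition values truncate to 1 decimal (the printed transition pairs,
#' e.g. 794.5 -> 774.5, are floor-truncated, not rounded).
#'
#' @param mz Numeric m/z value(s).
#' @return Rounded value(s).
#' @export
mz_hrms <- function(mz) round(mz, 4)

#' @rdname mz_hrms
#' @export
mz_nominal <- function(mz) floor(mz * 10) / 10

# internal accessor used across modules
mass_delta <- function(name) .mass_delta[[name]]
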