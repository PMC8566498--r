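# Shorthand nomenclature for diacyl PCs and oxidized acyl chains.
#
# Grammar: PC<c1>:<d1>[/|_]<c2>:<d2>[;suffix[;suffix...]]
#   "/" = sn-positions known, "_" = unknown.
# Suffix tokens on the (oxidized) second chain:
#   O, O2, O3, ...  added oxygens (epoxide and/or hydroxide when functional
#                   detail is asserted)
#   On-H2           added oxygens with two fewer hydrogens (dehydro class)
#   OOH             hydroperoxide (2 added O)
#   oxo             ketone (1 added O, 2 fewer H)
#   CHO             truncated chain with aldehyde terminus (1 added O, -2 H)
#   COOH            truncated chain with carboxyl terminus (2 added O, -2 H)
# Acyl composition (free acid): C(c) H(2c - 2*db + h_delta) O(2 + added_o).

.functional_classes <- c(
  "NONE", "HYDROPEROXIDE", "EPOXIDE_OR_HYDROXIDE", "OXO",
  "CARBOXYL_TERMINAL", "ALDEHYDE_TERMINAL"
)

# glycerophosphocholine backbone (choline + glycerol + phosphate, free OH)
.gpc_backbone <- c(C = 8L, H = 20L, N = 1L, O = 6L, P = 1L)

new_acyl <- function(carbons, double_bonds, added_o = 0L, h_delta = 0L,
                     functional_class = "NONE", truncated = FALSE) {
  stopifnot(
    carbons >= 2, double_bonds >= 0, added_o >= 0,
    h_delta %% 2 == 0, h_delta <= 0,
    functional_class %in% .functional_classes
  )
  if (functional_class == "HYDROPEROXIDE" && added_o < 2) {
    stop("a hydroperoxide acyl needs at least 2 added oxygens", call. = FALSE)
  }
  if (functional_class %in% c("CARBOXYL_TERMINAL", "ALDEHYDE_TERMINAL") &&
    !truncated) {
    stop("terminal carboxyl/aldehyde classes imply a truncated chain",
      call. = FALSE
    )
  }
  list(
    carbons = as.integer(carbons),
    double_bonds = as.integer(double_bonds),
    added_o = as.integer(added_o),
    h_delta = as.integer(h_delta),
    functional_class = functional_class,
    truncated = isTRUE(truncated)
  )
}

#' Free-acid composition of a fatty-acyl chain
#'
#' @param acyl An acyl spec (list with `carbons`, `double_bonds`, `added_o`,
#'   `h_delta`), e.g. one side of [parse_shorthand()].
#' @return Composition of the corresponding free fatty acid.
#' @export
#' @examples
#' acyl_composition(parse_acyl("18:2;O2"))
acyl_composition <- function(acyl) {
  n_h <- 2L * acyl$carbons - 2L * acyl$double_bonds + acyl$h_delta
  if (n_h < 2) stop("acyl spec implies fewer than 2 hydrogens", call. = FALSE)
  comp(C = acyl$carbons, H = n_h, O = 2L + acyl$added_o)
}

# map a suffix string (";"-separated tokens, no leading ";") to modification
parse_suffix <- function(suffix) {
  added_o <- 0L
  h_delta <- 0L
  class <- "NONE"
  truncated <- FALSE
  if (!nzchar(suffix)) {
    return(list(
      added_o = added_o, h_delta = h_delta,
      functional_class = class, truncated = truncated
    ))
  }
  for (tok in strsplit(suffix, ";", fixed = TRUE)[[1]]) {
    if (tok == "OOH") {
      added_o <- added_o + 2L
      class <- "HYDROPEROXIDE"
    } else if (tok == "oxo") {
      added_o <- added_o + 1L
      h_delta <- h_delta - 2L
      if (class == "NONE") class <- "OXO"
    } else if (tok == "COOH") {
      added_o <- added_o + 2L
      h_delta <- h_delta - 2L
      class <- "CARBOXYL_TERMINAL"
      truncated <- TRUE
    } else if (tok == "CHO") {
      added_o <- added_o + 1L
      h_delta <- h_delta - 2L
      class <- "ALDEHYDE_TERMINAL"
      truncated <- TRUE
    } else if (grepl("^O(\\d*)(-H2)?$", tok)) {
      n <- sub("^O(\\d*).*$", "\\1", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      added_o <- added_o + n
      if (grepl("-H2$", tok)) {
        h_delta <- h_delta - 2L
      } else if (class == "NONE") {
        # a bare ;On names the epoxide/hydroxide series (the hydroperoxide
        # functional isomer is written ;OOH)
        class <- "EPOXIDE_OR_HYDROXIDE"
      }
    } else {
      stop("malformed suffix token: \"", tok, "\"", call. = FALSE)
    }
  }
  list(
    added_o = added_o, h_delta = h_delta,
    functional_class = class, truncated = truncated
  )
}

# inverse of parse_suffix for specs generated by this package
acyl_suffix <- function(acyl) {
  parts <- character(0)
  o_left <- acyl$added_o
  h_left <- acyl$h_delta
  if (acyl$functional_class == "CARBOXYL_TERMINAL") {
    parts <- c(parts, "COOH")
    o_left <- o_left - 2L
    h_left <- h_left + 2L
  } else if (acyl$functional_class == "ALDEHYDE_TERMINAL") {
    parts <- c(parts, "CHO")
    o_left <- o_left - 1L
    h_left <- h_left + 2L
  }
  if (acyl$functional_class == "HYDROPEROXIDE" && o_left == 2L &&
    h_left == 0L) {
    parts <- c(parts, "OOH")
    o_left <- 0L
  } else if (acyl$functional_class == "OXO" && o_left == 1L &&
    h_left == -2L) {
    parts <- c(parts, "oxo")
    o_left <- 0L
    h_left <- 0L
  } else if (o_left > 0L && h_left == -2L) {
    if (acyl$truncated && o_left == 1L) {
      parts <- c(parts, "oxo") # keto decoration on a truncated chain
    } else {
      parts <- c(parts, paste0("O", if (o_left > 1) o_left else "", "-H2"))
    }
    o_left <- 0L
    h_left <- 0L
  } else if (o_left > 0L) {
    parts <- c(parts, paste0("O", if (o_left > 1) o_left else ""))
    o_left <- 0L
  }
  if (o_left != 0L || h_left != 0L) {
    stop("cannot express modification as a shorthand suffix", call. = FALSE)
  }
  if (length(parts) == 0) "" else paste(parts, collapse = ";")
}

#' Parse one acyl token such as "18:2;O2"
#'
#' @param token Acyl shorthand: `<carbons>:<double bonds>` plus optional
#'   `;`-separated modification suffixes.
#' @return Acyl spec list (`carbons`, `double_bonds`, `added_o`, `h_delta`,
#'   `functional_class`, `truncated`).
#' @export
parse_acyl <- function(token) {
  m <- regmatches(
    token,
    regexec("^(\\d+):(\\d+)((?:;[^;]+)*)$", token)
  )[[1]]
  if (length(m) == 0) {
    stop("malformed acyl token: \"", token, "\"", call. = FALSE)
  }
  suffix <- sub("^;", "", m[4])
  mod <- parse_suffix(suffix)
  new_acyl(
    carbons = as.integer(m[2]), double_bonds = as.integer(m[3]),
    added_o = mod$added_o, h_delta = mod$h_delta,
    functional_class = mod$functional_class, truncated = mod$truncated
  )
}

#' Parse shorthand oxPC names
#'
#' Parses names such as `"PC16:0_18:2;O2"` or `"PC16:0/18:2"`. A `/`
#' separator marks known sn-positions, `_` marks unknown positions; the
#' modification suffix always belongs to the second (oxidized) chain.
#'
#' @param name Character vector of shorthand names.
#' @return A tibble with one row per name: `name`, `linkage` (`"known"` or
#'   `"unknown"`) and the two acyl specs unpacked into `sn1_*`/`sn2_*`
#'   columns.
#' @export
#' @examples
#' parse_shorthand(c("PC16:0_18:2;O2", "PC16:0_9:0;COOH"))
parse_shorthand <- function(name) {
  stopifnot(is.character(name))
  rows <- lapply(name, function(nm) {
    body <- sub("^PC", "", nm)
    if (identical(body, nm)) {
      stop("malformed name (no PC prefix): \"", nm, "\"", call. = FALSE)
    }
    sep <- if (grepl("/", body, fixed = TRUE)) {
      "/"
    } else if (grepl("_", body, fixed = TRUE)) {
      "_"
    } else {
      stop("malformed name (no / or _ chain separator): \"", nm, "\"",
        call. = FALSE
      )
    }
    halves <- strsplit(body, sep, fixed = TRUE)[[1]]
    if (length(halves) != 2) {
      stop("malformed name (expected two acyl chains): \"", nm, "\"",
        call. = FALSE
      )
    }
    sn1 <- parse_acyl(halves[1])
    sn2 <- parse_acyl(halves[2])
    tibble::tibble(
      name = nm,
      linkage = if (sep == "/") "known" else "unknown",
      sn1_carbons = sn1$carbons, sn1_double_bonds = sn1$double_bonds,
      sn1_added_o = sn1$added_o, sn1_h_delta = sn1$h_delta,
      sn1_class = sn1$functional_class, sn1_truncated = sn1$truncated,
      sn2_carbons = sn2$carbons, sn2_double_bonds = sn2$double_bonds,
      sn2_added_o = sn2$added_o, sn2_h_delta = sn2$h_delta,
      sn2_class = sn2$functional_class, sn2_truncated = sn2$truncated
    )
  })
  dplyr::bind_rows(rows)
}

# acyl spec list from unpacked columns of a parsed/library row; modification
# columns may be absent for the unmodified sn-1 chain
acyl_from_row <- function(row, prefix) {
  get <- function(field, default) {
    col <- paste0(prefix, "_", field)
    if (col %in% names(row)) row[[col]] else default
  }
  new_acyl(
    carbons = get("carbons", NA),
    double_bonds = get("double_bonds", NA),
    added_o = get("added_o", 0L),
    h_delta = get("h_delta", 0L),
    functional_class = get("class", "NONE"),
    truncated = get("truncated", FALSE)
  )
}

#' Neutral elemental composition of a diacyl PC species
#'
#' Glycerophosphocholine backbone (C8H20NO6P) plus the two acyl free acids,
#' minus two waters for the ester bonds.
#'
#' @param sn1,sn2 Acyl specs (see [parse_acyl()]).
#' @return Composition of the neutral species.
#' @export
#' @examples
#' species_composition(parse_acyl("16:0"), parse_acyl("18:2;O2"))
species_composition <- function(sn1, sn2) {
  x <- comp_add(.gpc_backbone, acyl_composition(sn1))
  x <- comp_add(x, acyl_composition(sn2))
  comp_subtract(x, comp(H = 4, O = 2))
}

#' @rdname species_composition
#' @param name Shorthand name.
#' @param which `"sn1"` or `"sn2"`.
#' @return For `acyl_from_name()`, the acyl spec of one chain of a parsed
#'   name.
#' @export
acyl_from_name <- function(name, which = c("sn1", "sn2")) {
  which <- match.arg(which)
  acyl_from_row(parse_shorthand(name[1]), which)
}

#' Build a shorthand species name from two acyl specs
#'
#' @param sn1,sn2 Acyl specs.
#' @param linkage `"unknown"` (separator `_`) or `"known"` (`/`).
#' @return Shorthand name that re-parses to the same specs.
#' @export
species_name <- function(sn1, sn2, linkage = c("unknown", "known")) {
  linkage <- match.arg(linkage)
  sep <- if (linkage == "known") "/" else "_"
  suf <- acyl_suffix(sn2)
  paste0(
    "PC", sn1$carbons, ":", sn1$double_bonds, sep,
    sn2$carbons, ":", sn2$double_bonds,
    if (nzchar(suf)) paste0(";", suf) else ""
  )
}
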