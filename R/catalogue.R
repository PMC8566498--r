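# Oxidized-acyl modification catalogue.
#
# A catalogue row describes one oxidized sn-2 acyl chain (an AcylSpec plus
# annotation metadata). The bundled default catalogue enumerates the
# oxidation products of the three major PUFAs (18:2, 20:4, 22:6):
#   * nine full-length classes per PUFA: O-H2, O, oxo, O2-H2, OOH,
#     O2 (epoxy and/or hydroxide), O3-H2, O3, O4;
#   * chain-truncated products from beta-scission around each parent double
#     bond (lengths p-1, p, p+1 for a double bond at carbon p), with
#     aldehyde (CHO) and carboxyl (COOH) termini and the double bonds fully
#     contained in the shortened chain retained;
#   * hydroxylated (;O) variants of truncated chains with >= 6 carbons, and
#     keto (;oxo) variants of the carboxyl series with >= 6 carbons.
# The enumeration totals 155 distinct entries.

.catalogue_cols <- c(
  "name_suffix", "carbons", "double_bonds", "added_O", "h_delta",
  "functional_class", "truncated", "fragments", "rt_class", "provenance"
)

.pufa_double_bond_positions <- list(
  "18:2" = c(9L, 12L),
  "20:4" = c(5L, 8L, 11L, 14L),
  "22:6" = c(4L, 7L, 10L, 13L, 16L, 19L)
)

catalogue_row <- function(name_suffix, carbons, double_bonds, added_o,
                          h_delta, functional_class, truncated,
                          fragments = "", rt_class = "", provenance = "") {
  tibble::tibble(
    name_suffix = name_suffix,
    carbons = as.integer(carbons),
    double_bonds = as.integer(double_bonds),
    added_O = as.integer(added_o),
    h_delta = as.integer(h_delta),
    functional_class = functional_class,
    truncated = truncated,
    fragments = fragments,
    rt_class = rt_class,
    provenance = provenance
  )
}

full_length_classes <- function() {
  tibble::tribble(
    ~suffix,   ~added_o, ~h_delta, ~class,                  ~rt_class,         ~provenance,
    "O-H2",    1L,       -2L,      "NONE",                  "12.0-14.0 min",   "AAPH+hemin",
    "O",       1L,        0L,      "EPOXIDE_OR_HYDROXIDE",  "12.0-14.0 min",   "AAPH+hemin",
    "oxo",     1L,       -2L,      "OXO",                   "12.0-14.0 min",   "AAPH+hemin",
    "O2-H2",   2L,       -2L,      "NONE",                  "9.0-12.0 min",    "AAPH+hemin",
    "OOH",     2L,        0L,      "HYDROPEROXIDE",         "11.0-12.0 min",   "AAPH",
    "O2",      2L,        0L,      "EPOXIDE_OR_HYDROXIDE",  "9.0-10.5 min",    "AAPH+hemin",
    "O3-H2",   3L,       -2L,      "NONE",                  "7.0-9.0 min",     "AAPH+hemin",
    "O3",      3L,        0L,      "EPOXIDE_OR_HYDROXIDE",  "7.0-9.0 min",     "AAPH+hemin",
    "O4",      4L,        0L,      "EPOXIDE_OR_HYDROXIDE",  "7.0-9.0 min",     "AAPH"
  )
}

# truncated-chain (carbons, double_bonds) pairs from beta-scission around
# each parent double bond; deduplicated across the three parent PUFAs
truncation_specs <- function() {
  specs <- lapply(.pufa_double_bond_positions, function(pos) {
    lens <- sort(unique(c(pos - 1L, pos, pos + 1L)))
    lens <- lens[lens >= 3L]
    tibble::tibble(
      carbons = lens,
      double_bonds = vapply(
        lens, function(l) sum(pos + 1L <= l), integer(1)
      )
    )
  })
  dplyr::distinct(dplyr::bind_rows(specs))
}

#' The bundled default modification catalogue
#'
#' Enumerates 155 oxidized sn-2 acyl modifications of the three major PUFAs
#' (linoleate 18:2, arachidonate 20:4, docosahexaenoate 22:6): full-length
#' oxygenation/dehydro/keto classes plus truncated aldehyde- and
#' carboxyl-terminal series with hydroxy/keto variants. See the methods
#' vignette for the enumeration convention.
#'
#' @return A catalogue tibble with columns `name_suffix`, `carbons`,
#'   `double_bonds`, `added_O`, `h_delta`, `functional_class`, `truncated`,
#'   `fragments` (semicolon-separated extra diagnostic ion formulas),
#'   `rt_class`, `provenance`.
#' @export
#' @examples
#' nrow(default_catalogue()) # 155
default_catalogue <- function() {
  cls <- full_length_classes()
  full <- dplyr::bind_rows(lapply(names(.pufa_double_bond_positions), function(p) {
    cd <- as.integer(strsplit(p, ":")[[1]])
    dplyr::bind_rows(lapply(seq_len(nrow(cls)), function(i) {
      r <- cls[i, ]
      # regiochemistry-informative product ions are catalogued only where
      # characterized (linoleate epoxy-hydroxide; C9-C10 cleavage series)
      extra <- if (p == "18:2" && r$suffix == "O2") "C9H15O;C9H15O2" else ""
      catalogue_row(
        name_suffix = paste0(p, ";", r$suffix),
        carbons = cd[1], double_bonds = cd[2],
        added_o = r$added_o, h_delta = r$h_delta,
        functional_class = r$class, truncated = FALSE,
        fragments = extra, rt_class = r$rt_class, provenance = r$provenance
      )
    }))
  }))

  tr <- truncation_specs()
  trunc <- dplyr::bind_rows(lapply(seq_len(nrow(tr)), function(i) {
    c_i <- tr$carbons[i]
    d_i <- tr$double_bonds[i]
    base <- paste0(c_i, ":", d_i)
    rows <- list(
      catalogue_row(
        paste0(base, ";CHO"), c_i, d_i, 1L, -2L,
        "ALDEHYDE_TERMINAL", TRUE,
        rt_class = "2.5-6.5 min", provenance = "AAPH+hemin"
      ),
      catalogue_row(
        paste0(base, ";COOH"), c_i, d_i, 2L, -2L,
        "CARBOXYL_TERMINAL", TRUE,
        rt_class = "2.5-6.5 min", provenance = "AAPH+hemin"
      )
    )
    if (c_i >= 6L) {
      rows <- c(rows, list(
        catalogue_row(
          paste0(base, ";CHO;O"), c_i, d_i, 2L, -2L,
          "ALDEHYDE_TERMINAL", TRUE,
          rt_class = "2.5-6.5 min", provenance = "AAPH+hemin"
        ),
        catalogue_row(
          paste0(base, ";COOH;O"), c_i, d_i, 3L, -2L,
          "CARBOXYL_TERMINAL", TRUE,
          rt_class = "2.5-6.5 min", provenance = "AAPH+hemin"
        ),
        catalogue_row(
          paste0(base, ";COOH;oxo"), c_i, d_i, 3L, -4L,
          "CARBOXYL_TERMINAL", TRUE,
          rt_class = "2.5-6.5 min", provenance = "AAPH+hemin"
        )
      ))
    }
    dplyr::bind_rows(rows)
  }))

  out <- dplyr::bind_rows(full, trunc)
  validate_catalogue(out)
  out
}

#' Validate a modification catalogue
#'
#' Checks the schema, the AcylSpec invariants of each row, and uniqueness of
#' entries by (AcylSpec, functional class).
#'
#' @param catalogue Catalogue tibble (see [default_catalogue()]).
#' @return The catalogue, invisibly; errors describe the offending rows.
#' @export
validate_catalogue <- function(catalogue) {
  missing <- setdiff(.catalogue_cols, names(catalogue))
  if (length(missing) > 0) {
    stop("catalogue is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(catalogue) == 0) {
    stop("catalogue is empty", call. = FALSE)
  }
  for (i in seq_len(nrow(catalogue))) {
    r <- catalogue[i, ]
    ok <- tryCatch(
      {
        a <- new_acyl(
          r$carbons, r$double_bonds, r$added_O, r$h_delta,
          r$functional_class, r$truncated
        )
        acyl_composition(a)
        # the suffix must round-trip through the shorthand grammar
        reparsed <- parse_suffix(sub("^[0-9]+:[0-9]+;", "", r$name_suffix))
        stopifnot(
          reparsed$added_o == r$added_O,
          reparsed$h_delta == r$h_delta,
          reparsed$functional_class == r$functional_class,
          reparsed$truncated == r$truncated
        )
        TRUE
      },
      error = function(e) e
    )
    if (!isTRUE(ok)) {
      stop("invalid catalogue row ", i, " (", r$name_suffix, "): ",
        conditionMessage(ok),
        call. = FALSE
      )
    }
  }
  key <- paste(catalogue$carbons, catalogue$double_bonds, catalogue$added_O,
    catalogue$h_delta, catalogue$functional_class,
    sep = "/"
  )
  if (anyDuplicated(key)) {
    dup <- unique(catalogue$name_suffix[duplicated(key)])
    stop("duplicate catalogue entries: ", paste(dup, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(catalogue)
}

#' Read / write a modification catalogue as CSV
#'
#' The CSV schema matches [default_catalogue()]. `load_catalogue()`
#' validates on read and reports the offending row on schema violations.
#'
#' @param path File path.
#' @return `load_catalogue()` returns the catalogue tibble.
#' @export
load_catalogue <- function(path) {
  if (!file.exists(path)) {
    stop("catalogue file not found: ", path, call. = FALSE)
  }
  header <- readLines(path, n = 1)
  have <- strsplit(header, ",")[[1]]
  missing <- setdiff(.catalogue_cols, have)
  if (length(missing) > 0) {
    stop("catalogue file is missing column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  x <- readr::read_csv(path,
    col_types = readr::cols(
      name_suffix = readr::col_character(),
      carbons = readr::col_integer(),
      double_bonds = readr::col_integer(),
      added_O = readr::col_integer(),
      h_delta = readr::col_integer(),
      functional_class = readr::col_character(),
      truncated = readr::col_logical(),
      fragments = readr::col_character(),
      rt_class = readr::col_character(),
      provenance = readr::col_character()
    )
  )
  x$fragments[is.na(x$fragments)] <- ""
  x$rt_class[is.na(x$rt_class)] <- ""
  x$provenance[is.na(x$provenance)] <- ""
  validate_catalogue(x)
  x
}

#' @rdname load_catalogue
#' @param catalogue Catalogue tibble.
#' @export
write_catalogue <- function(catalogue, path) {
  validate_catalogue(catalogue)
  readr::write_csv(catalogue, path)
  invisible(path)
}
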