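# Structural library: catalogue x sn-1 chains -> library entries with
# precursor adducts and rule-predicted diagnostic fragments.

.element_bounds <- list(
  min = c(C = 26L, H = 48L, N = 1L, O = 6L, P = 1L),
  max = c(C = 60L, H = 130L, N = 1L, O = 30L, P = 1L)
)

#' Expand a modification catalogue across sn-1 chains
#'
#' Crosses every catalogue entry (an oxidized sn-2 acyl) with every sn-1
#' chain, producing one library entry per combination with the neutral
#' composition and the three precursor adduct m/z values. Species whose
#' oxidized chain carries a free carboxyl terminus ionize as deprotonated
#' anions in negative mode; all others as formate adducts.
#'
#' @param catalogue Catalogue tibble (see [default_catalogue()]).
#' @param sn1_chains Character vector of sn-1 acyl tokens, e.g.
#'   `c("16:0", "18:0", "18:1")`. Must be duplicate-free.
#' @return A library tibble with one row per (catalogue entry, sn-1 chain):
#'   shorthand `name`, unpacked acyl specs, `formula`, `neutral_mass`,
#'   `mz_formate`, `mz_mh_neg`, `mz_mh_pos`, `primary_neg_adduct`,
#'   `rt_class`, `provenance`, `extra_fragments`.
#' @export
#' @examples
#' lib <- expand_catalogue(default_catalogue())
#' nrow(lib) # 465
expand_catalogue <- function(catalogue,
                             sn1_chains = c("16:0", "18:0", "18:1")) {
  validate_catalogue(catalogue)
  if (length(sn1_chains) == 0) {
    stop("sn1_chains must be nonempty", call. = FALSE)
  }
  if (anyDuplicated(sn1_chains)) {
    stop("duplicate sn-1 chains: ",
      paste(unique(sn1_chains[duplicated(sn1_chains)]), collapse = ", "),
      call. = FALSE
    )
  }
  sn1_specs <- lapply(sn1_chains, parse_acyl)

  rows <- lapply(seq_along(sn1_specs), function(j) {
    sn1 <- sn1_specs[[j]]
    dplyr::bind_rows(lapply(seq_len(nrow(catalogue)), function(i) {
      r <- catalogue[i, ]
      sn2 <- new_acyl(
        r$carbons, r$double_bonds, r$added_O, r$h_delta,
        r$functional_class, r$truncated
      )
      cmp <- species_composition(sn1, sn2)
      mass <- monoisotopic_mass(cmp)
      tibble::tibble(
        name = species_name(sn1, sn2),
        linkage = "unknown",
        sn1_carbons = sn1$carbons, sn1_double_bonds = sn1$double_bonds,
        sn2_carbons = sn2$carbons, sn2_double_bonds = sn2$double_bonds,
        sn2_added_o = sn2$added_o, sn2_h_delta = sn2$h_delta,
        sn2_class = sn2$functional_class, sn2_truncated = sn2$truncated,
        formula = format_formula(cmp),
        neutral_mass = mass,
        mz_formate = adduct_mz(mass, "[M+HCOO]-"),
        mz_mh_neg = adduct_mz(mass, "[M-H]-"),
        mz_mh_pos = adduct_mz(mass, "[M+H]+"),
        primary_neg_adduct = if (sn2$functional_class == "CARBOXYL_TERMINAL") {
          "[M-H]-"
        } else {
          "[M+HCOO]-"
        },
        rt_class = r$rt_class,
        provenance = r$provenance,
        extra_fragments = r$fragments
      )
    }))
  })
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$name)) {
    stop("expansion produced duplicate names: ",
      paste(unique(out$name[duplicated(out$name)]), collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' Build the default 465-entry oxPC library
#'
#' Convenience wrapper: [default_catalogue()] expanded over sn-1 chains
#' 16:0, 18:0 and 18:1.
#'
#' @inheritParams expand_catalogue
#' @return Library tibble (see [expand_catalogue()]).
#' @export
build_library <- function(sn1_chains = c("16:0", "18:0", "18:1")) {
  expand_catalogue(default_catalogue(), sn1_chains)
}

carboxylate_anion_mz <- function(acid_comp) {
  monoisotopic_mass(acid_comp) - .proton_mass
}

#' Build a standalone library entry from a shorthand name
#'
#' Constructs the same row [expand_catalogue()] would produce for an ad-hoc
#' species that need not be in any catalogue, e.g. `"PC16:0_8:1;O"`. The
#' functional class is taken from the suffix grammar.
#'
#' @param name Shorthand species name.
#' @return One-row library tibble.
#' @export
#' @examples
#' library_entry("PC16:0_8:1;O")$mz_formate # 680.4144
library_entry <- function(name) {
  p <- parse_shorthand(name)
  sn1 <- acyl_from_row(p, "sn1")
  sn2 <- acyl_from_row(p, "sn2")
  cmp <- species_composition(sn1, sn2)
  mass <- monoisotopic_mass(cmp)
  tibble::tibble(
    name = p$name,
    linkage = p$linkage,
    sn1_carbons = sn1$carbons, sn1_double_bonds = sn1$double_bonds,
    sn2_carbons = sn2$carbons, sn2_double_bonds = sn2$double_bonds,
    sn2_added_o = sn2$added_o, sn2_h_delta = sn2$h_delta,
    sn2_class = sn2$functional_class, sn2_truncated = sn2$truncated,
    formula = format_formula(cmp),
    neutral_mass = mass,
    mz_formate = adduct_mz(mass, "[M+HCOO]-"),
    mz_mh_neg = adduct_mz(mass, "[M-H]-"),
    mz_mh_pos = adduct_mz(mass, "[M+H]+"),
    primary_neg_adduct = if (sn2$functional_class == "CARBOXYL_TERMINAL") {
      "[M-H]-"
    } else {
      "[M+HCOO]-"
    },
    rt_class = "",
    provenance = "unspecified",
    extra_fragments = ""
  )
}

#' Predict diagnostic MS/MS fragments for a library entry
#'
#' Applies the head-group and fatty-acyl fragmentation rules:
#' \describe{
#'   \item{R1}{sn-1 carboxylate anion, e.g. `[16:0]-` at 255.2330.}
#'   \item{R2}{oxidized-acyl carboxylate anion `[oxFA]-`.}
#'   \item{R3}{`[oxFA - H2O]-` (full-length species from the formate adduct).}
#'   \item{R4}{demethylated ion `[M-CH3]-` = formate adduct minus methyl
#'     formate (60.0211 Da).}
#'   \item{R5}{trimethylamine loss `[M-H-N(CH3)3]-` (carboxyl-terminal
#'     species, from the deprotonated precursor; -59.0735 Da).}
#'   \item{R6}{methylated oxidized acyl `[oxFA + CH2]-` (carboxyl-terminal
#'     species).}
#'   \item{R7}{water loss `[M+H-H2O]+` (epoxide/hydroxide species).}
#'   \item{R8}{hydrogen-peroxide loss `[M+H-H2O2]+` (hydroperoxides).}
#'   \item{CAT}{extra catalogue-supplied diagnostic anions (regiochemistry
#'     markers), computed as composition + electron.}
#' }
#' Classes without applicable rules return the applicable subset.
#'
#' @param entry One library row ([expand_catalogue()]), or a shorthand name
#'   present in `library`.
#' @param polarity `"neg"` or `"pos"`.
#' @param library Library tibble, required when `entry` is a name.
#' @return Tibble with columns `label`, `mz`, `rule`, `polarity`.
#' @export
#' @examples
#' lib <- build_library()
#' predict_fragments("PC16:0_9:0;COOH", "neg", library = lib)
predict_fragments <- function(entry, polarity = c("neg", "pos"),
                              library = NULL) {
  polarity <- match.arg(polarity)
  entry <- resolve_entry(entry, library)
  sn1 <- acyl_from_row(entry, "sn1")
  sn2 <- acyl_from_row(entry, "sn2")
  out <- list()
  add <- function(label, mz, rule) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      label = label, mz = mz, rule = rule, polarity = polarity
    )
  }

  if (polarity == "neg") {
    add(
      paste0("[", sn1$carbons, ":", sn1$double_bonds, "]-"),
      carboxylate_anion_mz(acyl_composition(sn1)), "R1"
    )
    oxfa_mz <- carboxylate_anion_mz(acyl_composition(sn2))
    oxfa_lab <- sub("^PC[0-9]+:[0-9]+[/_]", "", entry$name)
    add(paste0("[", oxfa_lab, "]-"), oxfa_mz, "R2")
    if (entry$sn2_class == "CARBOXYL_TERMINAL") {
      add(
        "[M-H-N(CH3)3]-", entry$mz_mh_neg - mass_delta("trimethylamine"),
        "R5"
      )
      add(paste0("[", oxfa_lab, "+CH2]-"), oxfa_mz + mass_delta("ch2"), "R6")
    } else {
      add(
        paste0("[", oxfa_lab, "-H2O]-"), oxfa_mz - mass_delta("h2o"),
        "R3"
      )
      add("[M-CH3]-", entry$mz_formate - mass_delta("methyl_formate"), "R4")
    }
    extra <- entry$extra_fragments
    if (!is.null(extra) && !is.na(extra) && nzchar(extra)) {
      for (f in strsplit(extra, ";", fixed = TRUE)[[1]]) {
        add(
          paste0("[", f, "]-"),
          monoisotopic_mass(f) + .electron_mass, "CAT"
        )
      }
    }
  } else {
    if (entry$sn2_class == "EPOXIDE_OR_HYDROXIDE") {
      add("[M+H-H2O]+", entry$mz_mh_pos - mass_delta("h2o"), "R7")
    }
    if (entry$sn2_class == "HYDROPEROXIDE") {
      add("[M+H-H2O2]+", entry$mz_mh_pos - mass_delta("h2o2"), "R8")
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      label = character(0), mz = numeric(0),
      rule = character(0), polarity = character(0)
    ))
  }
  dplyr::bind_rows(out)
}

resolve_entry <- function(entry, library = NULL) {
  if (is.character(entry)) {
    if (is.null(library)) {
      stop("a library is required to look an entry up by name", call. = FALSE)
    }
    hit <- library[library$name == entry, ]
    if (nrow(hit) != 1) {
      stop("entry not found (or ambiguous) in library: ", entry,
        call. = FALSE
      )
    }
    return(hit)
  }
  stopifnot(is.data.frame(entry), nrow(entry) == 1)
  entry
}

#' Element-count plausibility bounds
#'
#' Checks a composition against the PC-space element-count window used by
#' the nontargeted workflow: minimum C26 H48 N O6 P, maximum C60 H130 N O30
#' P, inclusive, element-wise. Deuterium counts as H and oxygen-18 as O.
#'
#' @param x Composition or formula string.
#' @return `TRUE` iff every element count lies within the bounds.
#' @export
#' @examples
#' within_element_bounds("C42H80NO10P")
within_element_bounds <- function(x) {
  x <- as_comp_arg(x)
  counts <- c(C = 0, H = 0, N = 0, O = 0, P = 0)
  for (el in names(x)) {
    key <- switch(el, D = "H", O18 = "O", el)
    counts[key] <- counts[key] + x[[el]]
  }
  all(counts >= .element_bounds$min[names(counts)]) &&
    all(counts <= .element_bounds$max[names(counts)])
}

#' Export / read a structural library
#'
#' CSV and JSON exports round-trip exactly through [read_library()]. The MGF
#' export writes one ions block per entry (negative-mode primary precursor as
#' PEPMASS, predicted fragments as the peak list) for use as a spectral
#' library; it is read back with [read_mgf()] as spectra, not as a library.
#'
#' @param entries Library tibble.
#' @param path Output file.
#' @param format `"csv"`, `"json"` or `"mgf"`.
#' @return `path`, invisibly.
#' @export
export_library <- function(entries, path, format = c("csv", "json", "mgf")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_csv(entries, path)
  } else if (format == "json") {
    jsonlite::write_json(entries, path, digits = NA, auto_unbox = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(entries))) {
      e <- entries[i, ]
      neg <- predict_fragments(e, "neg")
      pre <- if (e$primary_neg_adduct == "[M-H]-") e$mz_mh_neg else e$mz_formate
      writeLines(c(
        "BEGIN IONS",
        paste0("TITLE=", e$name),
        paste0("PEPMASS=", format(round(pre, 5), nsmall = 5)),
        "CHARGE=1-",
        paste0(
          format(round(neg$mz, 5), nsmall = 5), " ",
          rep("100.0", nrow(neg))
        ),
        "END IONS", ""
      ), con)
    }
  }
  invisible(path)
}

#' @rdname export_library
#' @export
read_library <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    x <- readr::read_csv(path,
      col_types = readr::cols(
        name = readr::col_character(),
        linkage = readr::col_character(),
        sn2_class = readr::col_character(),
        sn2_truncated = readr::col_logical(),
        formula = readr::col_character(),
        primary_neg_adduct = readr::col_character(),
        rt_class = readr::col_character(),
        provenance = readr::col_character(),
        extra_fragments = readr::col_character(),
        .default = readr::col_double()
      )
    )
    int_cols <- c(
      "sn1_carbons", "sn1_double_bonds", "sn2_carbons",
      "sn2_double_bonds", "sn2_added_o", "sn2_h_delta"
    )
    x[int_cols] <- lapply(x[int_cols], as.integer)
    for (cc in c("rt_class", "provenance", "extra_fragments")) {
      x[[cc]][is.na(x[[cc]])] <- ""
    }
    x
  } else {
    x <- tibble::as_tibble(jsonlite::fromJSON(path))
    int_cols <- c(
      "sn1_carbons", "sn1_double_bonds", "sn2_carbons",
      "sn2_double_bonds", "sn2_added_o", "sn2_h_delta"
    )
    x[int_cols] <- lapply(x[int_cols], as.integer)
    x
  }
}
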