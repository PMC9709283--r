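#' Monoisotopic element masses
#'
#' IUPAC monoisotopic atomic masses (Da) of the elements handled by the
#' formula parser, plus the proton and electron masses as named constants
#' (`proton`, `electron`).
#'
#' @return named numeric vector; immutable copy on every call.
#' @export
element_masses <- function() {
  c(C = 12.0, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
    P = 30.97376151, S = 31.97207069, Na = 22.98976928, Cl = 34.96885271,
    F = 18.99840320, K = 38.9637064864, Br = 78.9183376, I = 126.9044719,
    Si = 27.9769265327, Se = 73.9224766,
    proton = 1.00727646688, electron = 0.00054857990)
}

#' Positive-mode adduct mass shifts
#'
#' Charged-species shifts (Da) relating neutral monoisotopic mass to
#' observed m/z at charge +1: `M+H` adds a proton, `M+Na` adds a sodium
#' atom minus an electron, `M+H-H2O` adds a proton and removes water. The
#' electron-corrected (charged-species) convention is used throughout; it
#' differs from the atom-mass convention by ~0.5 mDa.
#'
#' @param adducts adduct names, subset of `M+H`, `M+Na`, `M+H-H2O`.
#' @return named numeric vector of shifts (Da).
#' @export
adduct_shifts <- function(adducts = c("M+H", "M+Na", "M+H-H2O")) {
  em <- element_masses()
  water <- 2 * em[["H"]] + em[["O"]]
  all <- c("M+H" = em[["proton"]],
           "M+Na" = em[["Na"]] - em[["electron"]],
           "M+H-H2O" = em[["proton"]] - water)
  unknown <- setdiff(adducts, names(all))
  if (length(unknown)) stop("unknown adduct(s): ", paste(unknown, collapse = ", "))
  all[adducts]
}

#' Parse a molecular formula
#'
#' Hill-style element+count tokens (`C9H9NO3`); bare symbols count 1.
#' Subscript markup (underscores, as in `C_4_H_7_N_3_O`) and Unicode
#' subscript digits are normalized away before parsing.
#'
#' @param text formula string.
#' @return named integer vector (element -> count) with the source string
#'   as attribute `source`.
#' @export
parse_formula <- function(text) {
  src <- text
  text <- gsub("_", "", text)
  subs <- c("\u2080", "\u2081", "\u2082", "\u2083", "\u2084",
            "\u2085", "\u2086", "\u2087", "\u2088", "\u2089")
  for (i in seq_along(subs)) text <- gsub(subs[i], as.character(i - 1), text)
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text)) stop("empty formula string")
  known <- setdiff(names(element_masses()), c("proton", "electron"))
  counts <- integer(0)
  pos <- 1L
  while (pos <= nchar(text)) {
    m <- regmatches(substr(text, pos, nchar(text)),
                    regexpr("^([A-Z][a-z]?)([0-9]*)", substr(text, pos, nchar(text))))
    if (length(m) == 0 || !nzchar(m))
      stop("cannot parse formula '", src, "' at position ", pos)
    el <- gsub("[0-9]", "", m)
    n <- gsub("[^0-9]", "", m)
    # two-letter candidate not in the table may be a one-letter element
    # followed by another element (e.g. "NO" is N then O)
    if (nchar(el) == 2 && !(el %in% known) && substr(el, 1, 1) %in% known) {
      el <- substr(el, 1, 1)
      m <- el
      n <- ""
    }
    if (!(el %in% known))
      stop("unknown element '", el, "' in formula '", src, "' at position ", pos)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (n <= 0) stop("zero count for element '", el, "' in formula '", src, "'")
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
    pos <- pos + nchar(m)
  }
  structure(counts, source = src)
}

#' Monoisotopic mass of a formula
#'
#' @param formula parsed formula from [parse_formula()], or a formula
#'   string. An empty (zero-element) formula has mass 0.
#' @return monoisotopic mass (Da).
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (length(formula) == 0) return(0)
  em <- element_masses()
  sum(em[names(formula)] * as.numeric(formula))
}

#' Adduct m/z from neutral mass
#'
#' `(neutral_mass + shift) / |charge|` at charge +1.
#'
#' @param neutral_mass neutral monoisotopic mass (Da, > 0).
#' @param adduct adduct name (see [adduct_shifts()]).
#' @return theoretical m/z.
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  stopifnot(all(neutral_mass > 0))
  shift <- adduct_shifts(adduct)
  mz <- neutral_mass + shift
  if (any(mz <= 0))
    stop("adduct '", adduct, "' gives non-positive m/z (mass below water loss?)")
  unname(mz)
}

#' Signed mass error in parts per million
#'
#' `1e6 * (observed - theoretical) / theoretical`.
#'
#' @param observed,theoretical m/z values (theoretical > 0).
#' @return signed ppm error.
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  1e6 * (observed - theoretical) / theoretical
}

#' Read a compound library from delimited text
#'
#' Columns: `name`, `formula`, optional `class`, optional logical evidence
#' flags `standard_confirmed` and `msms_match` used for MSI confidence
#' levels. The delimiter is sniffed (comma or tab).
#'
#' @param path library file.
#' @return data.frame with normalized columns.
#' @export
read_compound_library <- function(path) {
  lib <- utils::read.table(path, header = TRUE, sep = sniff_delim(path),
                           stringsAsFactors = FALSE, quote = "")
  if (!all(c("name", "formula") %in% names(lib)))
    stop("compound library needs 'name' and 'formula' columns")
  if (is.null(lib$class)) lib$class <- NA_character_
  for (fl in c("standard_confirmed", "msms_match"))
    lib[[fl]] <- if (is.null(lib[[fl]])) FALSE else as.logical(lib[[fl]])
  lib
}

#' Match an observed m/z against a compound library
#'
#' Forms every (compound, adduct) theoretical m/z and returns those within
#' the ppm tolerance, sorted by absolute ppm error (ties by compound name).
#' All matches are reported; candidate annotations are not collapsed to a
#' single winner.
#'
#' @param observed_mz observed m/z (single value).
#' @param library compound data.frame (see [read_compound_library()]).
#' @param adducts adduct names to try.
#' @param tolerance_ppm match window (default +/- 10 ppm).
#' @return data.frame: name, formula, class, adduct, theoretical_mz,
#'   observed_mz, ppm_error, msi_level (3 for these mass-only hits unless
#'   evidence flags upgrade them).
#' @export
match_library <- function(observed_mz, library,
                          adducts = c("M+H", "M+Na", "M+H-H2O"),
                          tolerance_ppm = 10) {
  stopifnot(length(observed_mz) == 1, observed_mz > 0)
  empty <- data.frame(name = character(), formula = character(),
                      class = character(), adduct = character(),
                      theoretical_mz = numeric(), observed_mz = numeric(),
                      ppm_error = numeric(), msi_level = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(library) == 0) {
    warning("empty compound library")
    return(empty)
  }
  masses <- vapply(library$formula, function(f) monoisotopic_mass(f), numeric(1))
  hits <- empty
  for (ad in adducts) {
    ok <- masses + adduct_shifts(ad) > 0
    theo <- masses[ok] + adduct_shifts(ad)
    ppm <- ppm_error(observed_mz, theo)
    within <- abs(ppm) <= tolerance_ppm
    if (!any(within)) next
    idx <- which(ok)[within]
    hits <- rbind(hits, data.frame(
      name = library$name[idx], formula = library$formula[idx],
      class = library$class[idx], adduct = ad,
      theoretical_mz = theo[within], observed_mz = observed_mz,
      ppm_error = ppm[within],
      msi_level = vapply(idx, function(i) assign_msi_level(
        hit = TRUE,
        standard_confirmed = isTRUE(library$standard_confirmed[i]),
        msms_match = isTRUE(library$msms_match[i])), integer(1)),
      stringsAsFactors = FALSE))
  }
  hits[order(abs(hits$ppm_error), hits$name), , drop = FALSE]
}

#' MSI identification confidence level
#'
#' Metabolomics Standards Initiative levels: 1 = confirmed against a
#' chemical standard (m/z, RT and MS/MS agree), 2 = putatively annotated
#' (m/z and MS/MS spectra match a database), 3 = putatively characterized
#' (m/z only), 4 = unknown (no database hit). MS/MS comparison itself is
#' out of scope here and enters as boolean evidence flags.
#'
#' @param hit was there a mass match at all?
#' @param standard_confirmed agreement with a commercial standard.
#' @param msms_match MS/MS spectral match in a database.
#' @return integer level 1-4.
#' @export
assign_msi_level <- function(hit, standard_confirmed = FALSE,
                             msms_match = FALSE) {
  if (!hit) return(4L)
  if (standard_confirmed) return(1L)
  if (msms_match) return(2L)
  3L
}

#' Annotate a list of features against a compound library
#'
#' Runs [match_library()] per feature; features without any hit are
#' reported as `Unknown` at MSI level 4.
#'
#' @param features data.frame with columns `mz` and optionally `feature_id`,
#'   `rt`.
#' @param library compound data.frame.
#' @param adducts,tolerance_ppm as in [match_library()].
#' @return data.frame: one row per (feature, hit) plus one `Unknown` row
#'   per unmatched feature.
#' @export
annotate_features <- function(features, library,
                              adducts = c("M+H", "M+Na", "M+H-H2O"),
                              tolerance_ppm = 10) {
  stopifnot("mz" %in% names(features))
  if (is.null(features$feature_id))
    features$feature_id <- sprintf("F%04d", seq_len(nrow(features)))
  if (is.null(features$rt)) features$rt <- NA_real_
  out <- lapply(seq_len(nrow(features)), function(i) {
    hits <- match_library(features$mz[i], library, adducts, tolerance_ppm)
    if (nrow(hits) == 0)
      hits <- data.frame(name = "Unknown", formula = NA_character_,
                         class = NA_character_, adduct = NA_character_,
                         theoretical_mz = NA_real_,
                         observed_mz = features$mz[i],
                         ppm_error = NA_real_, msi_level = 4L,
                         stringsAsFactors = FALSE)
    cbind(feature_id = features$feature_id[i], rt = features$rt[i], hits,
          stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
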