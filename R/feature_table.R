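#' Construct a feature table
#'
#' The central container of the package: an LC-MS feature-by-injection
#' intensity matrix keyed by accurate mass and retention time, together with
#' per-injection metadata (subject, timepoint, crossover arm, sample type,
#' injection order) and a free-text provenance log.
#'
#' @param features data.frame with columns `feature_id` (unique character),
#'   `mz` (accurate mass, Da, > 0) and `rt` (retention time, min, >= 0).
#' @param injections data.frame with columns `injection_id` (unique),
#'   `subject_id`, `timepoint` (`"pre"`, `"mid"`, `"post"`, `"rebound"` or NA),
#'   `arm` (`"AD"`, `"CD"` or NA), `sample_type` (`"study"`, `"qc"` or
#'   `"blank"`) and `injection_order` (unique positive integer). Subject,
#'   timepoint and arm must be present for every study injection.
#' @param intensities numeric matrix, `nrow(features)` x `nrow(injections)`,
#'   non-negative relative intensities; zeros mark missing/below-detection.
#' @param provenance character vector of processing-log lines.
#'
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, injections, intensities,
                          provenance = character()) {
  features <- as.data.frame(features)
  injections <- as.data.frame(injections)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  rownames(intensities) <- features$feature_id
  colnames(intensities) <- injections$injection_id
  obj <- structure(
    list(features = features, injections = injections,
         intensities = intensities, provenance = as.character(provenance)),
    class = "feature_table")
  validate_feature_table(obj)
  obj
}

#' Validate a feature table
#'
#' Checks every structural invariant: matching dimensions, unique feature and
#' injection identifiers, unique injection order, positive m/z, non-negative
#' retention times and intensities, and complete metadata (subject, timepoint,
#' arm) for study injections.
#'
#' @param x a `feature_table`.
#' @return `x`, invisibly; errors with a message naming the offending
#'   row/column otherwise.
#' @export
validate_feature_table <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  f <- x$features; m <- x$injections; mat <- x$intensities
  need_f <- c("feature_id", "mz", "rt")
  if (!all(need_f %in% names(f)))
    stop("features is missing column(s): ",
         paste(setdiff(need_f, names(f)), collapse = ", "))
  need_m <- c("injection_id", "sample_type", "injection_order")
  if (!all(need_m %in% names(m)))
    stop("injections is missing column(s): ",
         paste(setdiff(need_m, names(m)), collapse = ", "))
  for (col in c("subject_id", "timepoint", "arm"))
    if (is.null(m[[col]])) m[[col]] <- NA_character_
  if (anyDuplicated(f$feature_id))
    stop("duplicate feature_id: ",
         paste(unique(f$feature_id[duplicated(f$feature_id)]), collapse = ", "))
  if (anyDuplicated(m$injection_id))
    stop("duplicate injection_id: ",
         paste(unique(m$injection_id[duplicated(m$injection_id)]), collapse = ", "))
  if (anyDuplicated(m$injection_order))
    stop("duplicate injection_order values")
  if (any(!is.finite(f$mz)) || any(f$mz <= 0))
    stop("mz must be positive for every feature; offending feature(s): ",
         paste(f$feature_id[!is.finite(f$mz) | f$mz <= 0], collapse = ", "))
  if (any(!is.finite(f$rt)) || any(f$rt < 0))
    stop("rt must be >= 0 for every feature")
  if (!all(m$sample_type %in% c("study", "qc", "blank")))
    stop("sample_type must be one of study/qc/blank")
  bad_tp <- !is.na(m$timepoint) & !(m$timepoint %in% c("pre", "mid", "post", "rebound"))
  if (any(bad_tp)) stop("invalid timepoint for injection(s): ",
                        paste(m$injection_id[bad_tp], collapse = ", "))
  st <- m$sample_type == "study"
  incomplete <- st & (is.na(m$subject_id) | is.na(m$timepoint) | is.na(m$arm))
  if (any(incomplete))
    stop("study injection(s) missing subject_id/timepoint/arm: ",
         paste(m$injection_id[incomplete], collapse = ", "))
  if (nrow(mat) != nrow(f) || ncol(mat) != nrow(m))
    stop(sprintf("intensity matrix is %d x %d but features/injections are %d/%d",
                 nrow(mat), ncol(mat), nrow(f), nrow(m)))
  if (any(!is.finite(mat)) || any(mat < 0))
    stop("intensities must be finite and non-negative")
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(x$injections$sample_type)
  cat(sprintf("<feature_table> %d features x %d injections (%s)\n",
              nrow(x$features), nrow(x$injections),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  if (length(x$provenance))
    cat("provenance:\n", paste(" -", utils::tail(x$provenance, 5), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

log_stage <- function(table, msg) {
  table$provenance <- c(table$provenance, msg)
  table
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a feature table from delimited text
#'
#' Reads an intensity table (features as rows; columns `feature_id`
#' (optional), `mz`, `rt`, then one column per injection) and a metadata
#' sheet (columns `injection_id`, `subject_id`, `timepoint`, `arm`,
#' `sample_type`, `injection_order`). The delimiter (comma or tab) is
#' sniffed from the first line of each file.
#'
#' @param table_path path to the intensity table.
#' @param metadata_path path to the injection metadata sheet.
#' @param zero_invalid if `TRUE`, unparseable numeric cells become 0;
#'   otherwise they are an error naming the offending column.
#' @return a validated [feature_table()].
#' @export
read_feature_table <- function(table_path, metadata_path, zero_invalid = FALSE) {
  for (p in c(table_path, metadata_path))
    if (!file.exists(p)) stop("file does not exist: ", p)
  tab <- utils::read.table(table_path, header = TRUE, sep = sniff_delim(table_path),
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta <- utils::read.table(metadata_path, header = TRUE, sep = sniff_delim(metadata_path),
                            stringsAsFactors = FALSE, check.names = FALSE,
                            colClasses = "character")
  if (!all(c("mz", "rt") %in% names(tab)))
    stop("intensity table must have 'mz' and 'rt' columns")
  if (!"feature_id" %in% names(tab))
    tab$feature_id <- sprintf("M%sT%s", tab$mz, tab$rt)
  feat_cols <- c("feature_id", "mz", "rt")
  inj_cols <- setdiff(names(tab), feat_cols)
  need <- c("injection_id", "sample_type", "injection_order")
  if (!all(need %in% names(meta)))
    stop("metadata is missing column(s): ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  missing_meta <- setdiff(inj_cols, meta$injection_id)
  if (length(missing_meta))
    stop("metadata has no row for injection column(s): ",
         paste(missing_meta, collapse = ", "))
  meta <- meta[match(inj_cols, meta$injection_id), , drop = FALSE]
  for (col in c("subject_id", "timepoint", "arm"))
    if (is.null(meta[[col]])) meta[[col]] <- NA_character_
  meta$subject_id[meta$subject_id %in% c("", "NA")] <- NA_character_
  meta$timepoint[meta$timepoint %in% c("", "NA")] <- NA_character_
  meta$arm[meta$arm %in% c("", "NA")] <- NA_character_
  meta$injection_order <- as.integer(meta$injection_order)
  num <- function(v, col) {
    x <- suppressWarnings(as.numeric(v))
    bad <- is.na(x) & !is.na(v)
    if (any(bad)) {
      if (!zero_invalid)
        stop("unparseable numeric value(s) in column '", col, "'")
      x[bad] <- 0
    }
    x
  }
  features <- data.frame(feature_id = tab$feature_id,
                         mz = num(tab$mz, "mz"), rt = num(tab$rt, "rt"),
                         stringsAsFactors = FALSE)
  mat <- vapply(inj_cols, function(cn) num(tab[[cn]], cn), numeric(nrow(tab)))
  mat <- matrix(mat, nrow = nrow(tab),
                dimnames = list(features$feature_id, inj_cols))
  feature_table(features, meta, mat,
                provenance = sprintf("read %d features x %d injections from %s",
                                     nrow(features), length(inj_cols), table_path))
}

#' Write a feature table to delimited text
#'
#' Writes `<prefix>_table.tsv` (feature_id, mz, rt, one column per injection)
#' and `<prefix>_metadata.tsv`, the dialect read back by
#' [read_feature_table()].
#'
#' @param table a `feature_table`.
#' @param prefix output path prefix (directories are created).
#' @return invisibly, the two file paths.
#' @export
write_feature_table <- function(table, prefix) {
  validate_feature_table(table)
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  tp <- paste0(prefix, "_table.tsv")
  mp <- paste0(prefix, "_metadata.tsv")
  out <- data.frame(table$features, table$intensities,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table$injections, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(table = tp, metadata = mp))
}
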