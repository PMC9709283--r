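#' Define a paired two-group comparison
#'
#' A comparison selects two disjoint groups of study injections by simple
#' metadata equality filters and pairs them by a metadata key (normally
#' `subject_id`). Example: pre- vs post-dialysis within the citrate arm is
#' `comparison_spec(list(arm = "CD", timepoint = "pre"),
#'                  list(arm = "CD", timepoint = "post"))`.
#'
#' @param group_a,group_b named lists of metadata filters
#'   (field = required value) applied to study injections.
#' @param pairing_key metadata column defining pairs (default `subject_id`).
#' @param name optional label used in reports.
#' @return an object of class `comparison_spec`.
#' @export
comparison_spec <- function(group_a, group_b, pairing_key = "subject_id",
                            name = NULL) {
  stopifnot(is.list(group_a), is.list(group_b),
            length(names(group_a)) == length(group_a),
            length(names(group_b)) == length(group_b))
  structure(list(group_a = group_a, group_b = group_b,
                 pairing_key = pairing_key,
                 name = name %||% "custom"),
            class = "comparison_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Named preset comparisons of the crossover design
#'
#' The four comparisons of the two-dialysate crossover study: pre vs post
#' within each arm, and acetate vs citrate at the post-dialysis and rebound
#' timepoints.
#'
#' @return named list of [comparison_spec()] objects with names
#'   `pre_vs_post_AD`, `pre_vs_post_CD`, `AD_vs_CD_post`, `AD_vs_CD_rebound`.
#' @export
comparison_presets <- function() {
  list(
    pre_vs_post_AD = comparison_spec(list(arm = "AD", timepoint = "pre"),
                                     list(arm = "AD", timepoint = "post"),
                                     name = "pre_vs_post_AD"),
    pre_vs_post_CD = comparison_spec(list(arm = "CD", timepoint = "pre"),
                                     list(arm = "CD", timepoint = "post"),
                                     name = "pre_vs_post_CD"),
    AD_vs_CD_post = comparison_spec(list(arm = "AD", timepoint = "post"),
                                    list(arm = "CD", timepoint = "post"),
                                    name = "AD_vs_CD_post"),
    AD_vs_CD_rebound = comparison_spec(list(arm = "AD", timepoint = "rebound"),
                                       list(arm = "CD", timepoint = "rebound"),
                                       name = "AD_vs_CD_rebound"))
}

match_group <- function(injections, filt) {
  keep <- injections$sample_type == "study"
  for (field in names(filt)) {
    if (is.null(injections[[field]]))
      stop("comparison filter refers to unknown metadata field: ", field)
    keep <- keep & !is.na(injections[[field]]) & injections[[field]] == filt[[field]]
  }
  keep
}

#' Extract paired per-subject intensity vectors for a comparison
#'
#' Selects the two groups, pairs them by the pairing key, drops (and logs)
#' subjects lacking either member of the pair, and returns per-feature paired
#' intensity matrices in deterministic (sorted-subject) order. A subject
#' contributing more than one injection to a group is an error: the crossover
#' design has one sampled session per arm and timepoint.
#'
#' @param table a `feature_table`.
#' @param spec a [comparison_spec()].
#' @return list of class `paired_data`: `a`, `b` (features x subjects
#'   matrices), `subjects`, `features`, `dropped` (subjects missing a pair),
#'   `spec`.
#' @export
subset_comparison <- function(table, spec) {
  validate_feature_table(table)
  stopifnot(inherits(spec, "comparison_spec"))
  inj <- table$injections
  sel_a <- match_group(inj, spec$group_a)
  sel_b <- match_group(inj, spec$group_b)
  if (any(sel_a & sel_b))
    stop("comparison groups overlap: ",
         paste(inj$injection_id[sel_a & sel_b], collapse = ", "))
  key <- spec$pairing_key
  if (is.null(inj[[key]])) stop("unknown pairing key: ", key)
  ka <- inj[[key]][sel_a]; kb <- inj[[key]][sel_b]
  if (anyDuplicated(ka) || anyDuplicated(kb))
    stop("a subject contributes more than one injection to a group; ",
         "the design expects exactly one per group")
  subjects <- sort(intersect(ka, kb))
  dropped <- sort(setdiff(union(ka, kb), subjects))
  if (length(subjects) == 0)
    stop("no complete pairs for comparison '", spec$name, "'")
  ia <- which(sel_a)[match(subjects, ka)]
  ib <- which(sel_b)[match(subjects, kb)]
  structure(list(
    a = table$intensities[, ia, drop = FALSE],
    b = table$intensities[, ib, drop = FALSE],
    subjects = subjects,
    features = table$features,
    dropped = dropped,
    spec = spec), class = "paired_data")
}

#' @export
print.paired_data <- function(x, ...) {
  cat(sprintf("<paired_data> '%s': %d features, %d pairs", x$spec$name,
              nrow(x$a), length(x$subjects)))
  if (length(x$dropped))
    cat(sprintf(" (%d subject(s) dropped: %s)", length(x$dropped),
                paste(x$dropped, collapse = ", ")))
  cat("\n")
  invisible(x)
}
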