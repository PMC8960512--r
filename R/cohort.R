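#' Subject-by-region grey-matter-fraction cohort
#'
#' The analysis input: a numeric matrix of regional grey-matter fractions
#' (subjects in rows, regions in columns, values in \[0, 1\]) plus a group
#' label per subject. Optionally carries a per-subject lesion load (ml) and an
#' arm label distinguishing cohorts derived from original versus lesion-filled
#' images.
#'
#' @param values numeric matrix, subjects x regions, entries in \[0, 1\].
#' @param group character or factor of group labels, one per subject.
#' @param region_names character vector naming the regions (columns).
#' @param lesion_load optional nonnegative numeric vector, one per subject.
#' @param arm arm label, `"original"` or `"filled"`.
#' @param subject_id optional character vector of subject identifiers.
#'
#' @return An object of class `scn_cohort`: a list with elements `values`,
#'   `group`, `region_names`, `lesion_load`, `arm`, `subject_id`.
#' @examples
#' x <- matrix(runif(40, 0.3, 0.6), 10, 4)
#' coh <- scn_cohort(x, rep(c("HC", "MS"), each = 5))
#' coh
#' @export
scn_cohort <- function(values, group, region_names = NULL, lesion_load = NULL,
                       arm = "original", subject_id = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  p <- ncol(values)
  if (anyNA(values)) stopf("cohort values contain missing entries")
  if (any(values < 0 | values > 1))
    stopf("grey-matter fractions must lie in [0, 1]")
  group <- as.character(group)
  if (length(group) != n)
    stopf("length(group) (%d) != number of subjects (%d)", length(group), n)
  if (anyNA(group)) stopf("group labels contain NA")
  region_names <- region_names %||% colnames(values) %||%
    sprintf("region_%d", seq_len(p))
  if (length(region_names) != p)
    stopf("region_names length (%d) != number of regions (%d)",
          length(region_names), p)
  if (!is.null(lesion_load)) {
    if (length(lesion_load) != n) stopf("lesion_load must have one value per subject")
    if (any(lesion_load < 0)) stopf("lesion_load must be nonnegative")
  }
  arm <- match.arg(arm, c("original", "filled"))
  subject_id <- subject_id %||% sprintf("S%03d", seq_len(n))
  colnames(values) <- region_names
  rownames(values) <- subject_id
  structure(
    list(values = values, group = group, region_names = region_names,
         lesion_load = lesion_load, arm = arm, subject_id = subject_id),
    class = "scn_cohort")
}

#' @export
print.scn_cohort <- function(x, ...) {
  cat(sprintf("Structural covariance cohort (%s arm)\n", x$arm))
  cat(sprintf("  %d subjects x %d regions\n", nrow(x$values), ncol(x$values)))
  tab <- table(x$group)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$lesion_load))
    cat(sprintf("  lesion load: mean %.1f, max %.1f\n",
                mean(x$lesion_load), max(x$lesion_load)))
  invisible(x)
}

#' @export
summary.scn_cohort <- function(object, ...) {
  v <- object$values
  out <- data.frame(
    group = names(table(object$group)),
    n = as.integer(table(object$group)),
    mean_gm = vapply(split(seq_len(nrow(v)), object$group),
                     function(i) mean(v[i, , drop = FALSE]), 0),
    sd_gm = vapply(split(seq_len(nrow(v)), object$group),
                   function(i) stats::sd(as.vector(v[i, , drop = FALSE])), 0),
    row.names = NULL)
  out
}

#' @export
as.data.frame.scn_cohort <- function(x, ...) {
  data.frame(subject_id = x$subject_id, group = x$group, arm = x$arm,
             lesion_load = x$lesion_load %||% NA_real_,
             x$values, check.names = FALSE, row.names = NULL)
}

#' Read or write a cohort as CSV
#'
#' One row per subject with columns `subject_id`, `group`, `arm`,
#' `lesion_load`, then one column per region.
#'
#' @param cohort an [scn_cohort] object.
#' @param path file path.
#' @return `read_cohort_csv()` returns an [scn_cohort]; `write_cohort_csv()`
#'   returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- c("subject_id", "group", "arm", "lesion_load")
  missing_cols <- setdiff(c("subject_id", "group"), names(df))
  if (length(missing_cols))
    stopf("cohort CSV lacks column(s): %s", paste(missing_cols, collapse = ", "))
  regions <- setdiff(names(df), meta)
  ll <- if ("lesion_load" %in% names(df) && !all(is.na(df$lesion_load)))
    df$lesion_load else NULL
  scn_cohort(as.matrix(df[regions]), df$group, region_names = regions,
             lesion_load = ll,
             arm = if ("arm" %in% names(df)) df$arm[1] else "original",
             subject_id = as.character(df$subject_id))
}

#' Subset a cohort to one or more groups
#'
#' @param cohort an [scn_cohort].
#' @param groups character vector of group labels to keep.
#' @param relabel optional single label applied to all kept subjects (used to
#'   pool, e.g., relapsing-remitting and progressive MS into "MS total").
#' @return An [scn_cohort] containing only the selected subjects.
#' @export
cohort_subset <- function(cohort, groups, relabel = NULL) {
  keep <- cohort$group %in% groups
  if (!any(keep)) stopf("no subjects in group(s) %s", paste(groups, collapse = ", "))
  g <- cohort$group[keep]
  if (!is.null(relabel)) g <- rep(relabel, sum(keep))
  scn_cohort(cohort$values[keep, , drop = FALSE], g,
             region_names = cohort$region_names,
             lesion_load = cohort$lesion_load[keep],
             arm = cohort$arm, subject_id = cohort$subject_id[keep])
}
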