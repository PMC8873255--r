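#' Normalised histogram of feature values
#'
#' Equal-width bins over `[lo, hi]`, half-open on the left (`[b, b+width)`)
#' with the last bin closed so that `hi` itself is counted; values outside
#' the range are clipped into the terminal bins.  Counts are divided by
#' the total so the vector sums to one — the fixed-length representation
#' used to feed per-segment (and per-node) feature distributions to the
#' classifiers.
#'
#' @param values Nonempty numeric vector.
#' @param bins Number of bins (default 10).
#' @param range Numeric `c(lo, hi)` with `lo < hi`.
#' @return Numeric vector of length `bins` summing to 1.
#' @export
make_histogram <- function(values, bins = 10, range) {
  stopifnot(length(values) > 0, range[1] < range[2])
  width <- (range[2] - range[1]) / bins
  idx <- floor((values - range[1]) / width)
  idx <- pmin(pmax(idx, 0), bins - 1)
  tabulate(idx + 1, nbins = bins) / length(values)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The KS statistic is the maximum separation of the two empirical
#' cumulative distribution functions; the p-value is the asymptotic
#' two-sided one.  Group comparisons pool the raw per-segment (or
#' per-node) values across the participants of each group.
#'
#' @param a,b Nonempty numeric vectors.
#' @return List with `statistic` and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Cohen's d effect size
#'
#' Difference of means over the pooled standard deviation
#' \eqn{s_p = \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}}.
#'
#' @param a,b Numeric vectors with at least 2 values each.
#' @return Signed effect size `(mean(a) - mean(b)) / s_pooled`.
#' @export
cohens_d <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Apply the task-specific cohort filters
#'
#' The patient-versus-control spatiotemporal task uses only the segments
#' patients produced while moving alone, restricted to patients with
#' strictly more than `min_alone` such segments (controls keep all their
#' segments).  The graph task keeps all segments but restricts to
#' participants whose mobility graphs have at least `min_nodes` nodes.
#'
#' @param participants Named list of participant records, each a list with
#'   at least `group` and a `segments` data frame carrying a
#'   `companionship` column; records for the graph task additionally need
#'   `node_count`.
#' @param task `"spatiotemporal"` or `"graph"`.
#' @param min_alone Alone-segment threshold for patients (default 5,
#'   strict inequality).
#' @param min_nodes Graph-size threshold (default 10).
#' @return The filtered list; for the spatiotemporal task patient records
#'   have their `segments` reduced to alone segments.
#' @export
apply_cohort_filters <- function(participants, task = c("spatiotemporal", "graph"),
                                 min_alone = 5, min_nodes = 10) {
  task <- match.arg(task)
  out <- list()
  for (id in names(participants)) {
    p <- participants[[id]]
    if (task == "spatiotemporal") {
      if (p$group == "patient") {
        keep <- p$segments$companionship == "alone"
        if (sum(keep) <= min_alone) next
        p$segments <- p$segments[keep, , drop = FALSE]
      }
    } else {
      if (is.null(p$node_count) || p$node_count < min_nodes) next
    }
    out[[id]] <- p
  }
  out
}

#' Group comparison table (KS test and Cohen's d per feature)
#'
#' For each named feature, pools the raw values across the participants of
#' each group and reports the two-sample KS statistic, its p-value, and
#' Cohen's d (control minus patient, so the sign gives the direction of
#' the group difference).
#'
#' @param values_by_group A named list of features; each feature is a list
#'   with numeric vectors `control` and `patient` of pooled values.
#' @return Data frame with columns `feature`, `ks_statistic`, `p_value`,
#'   `cohens_d`.
#' @export
group_comparison <- function(values_by_group) {
  rows <- lapply(names(values_by_group), function(f) {
    a <- values_by_group[[f]]$control
    b <- values_by_group[[f]]$patient
    if (length(a) == 0 || length(b) == 0) {
      return(data.frame(feature = f, ks_statistic = NA_real_,
                        p_value = NA_real_, cohens_d = NA_real_,
                        stringsAsFactors = FALSE))
    }
    ks <- ks_two_sample(a, b)
    d <- tryCatch(cohens_d(a, b), error = function(e) NA_real_)
    data.frame(feature = f, ks_statistic = ks$statistic,
               p_value = ks$p_value, cohens_d = d,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
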