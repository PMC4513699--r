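#' Aggregate per-line slopes into a per-sample result
#'
#' Averages the valid per-line slopes of one tissue sample. Lines flagged
#' invalid (non-positive basal segment mean) are excluded and counted.
#' Following the original protocol, more than 20 lines per sample are
#' expected; fewer than 20 triggers a warning but not an error.
#'
#' @param line_results list of `slope_result` objects from [score_line].
#' @param sample_id sample identifier.
#' @param group histology group label (e.g. `"Normal"`, `"CIN_I"`,
#'   `"CIN_III"`).
#' @return one-row data frame with `sample_id`, `group`, `n_lines` (valid
#'   lines), `excluded_lines`, `mean_raw_slope`, `mean_normalized_slope`.
#' @export
aggregate_sample <- function(line_results, sample_id, group) {
  valid <- vapply(line_results, `[[`, TRUE, "valid")
  if (!any(valid))
    stop("sample '", sample_id, "': no valid lines to aggregate")
  if (sum(valid) < 20)
    warning("sample '", sample_id, "': only ", sum(valid),
            " valid lines (> 20 expected)")
  raw <- vapply(line_results[valid], `[[`, 0, "raw_slope")
  nrm <- vapply(line_results[valid], `[[`, 0, "normalized_slope")
  data.frame(sample_id = as.character(sample_id), group = as.character(group),
             n_lines = sum(valid), excluded_lines = sum(!valid),
             mean_raw_slope = mean(raw), mean_normalized_slope = mean(nrm),
             stringsAsFactors = FALSE)
}

#' Per-group summary: mean and SEM of per-sample slopes
#'
#' The units of analysis are per-sample mean slopes (not pooled lines, which
#' would pseudo-replicate). SEM = sd / sqrt(n); with a single sample the SEM
#' is undefined and flagged `NA` with a warning.
#'
#' @param samples data frame of per-sample results (rows from
#'   [aggregate_sample]), possibly spanning several groups.
#' @param value column to summarise; default `"mean_normalized_slope"`.
#' @return data frame with one row per group: `group`, `n_samples`, `mean`,
#'   `sem`.
#' @export
group_summary <- function(samples, value = "mean_normalized_slope") {
  stopifnot(value %in% names(samples))
  out <- lapply(split(samples, samples$group), function(g) {
    v <- g[[value]]
    n <- length(v)
    if (n < 2)
      warning("group '", g$group[1], "': SEM undefined with ", n, " sample")
    data.frame(group = g$group[1], n_samples = n, mean = mean(v),
               sem = if (n >= 2) stats::sd(v) / sqrt(n) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Tukey HSD across histology groups
#'
#' Compares per-sample mean slopes between groups with a one-way ANOVA
#' followed by Tukey's multiple-comparison test. Degenerate data (zero
#' variance everywhere and equal means) reports F = 0 and p = 1 rather than
#' failing.
#'
#' @param samples data frame of per-sample results with `group` and the
#'   `value` column; at least 2 groups of at least 2 samples.
#' @param value column to compare; default `"mean_normalized_slope"`.
#' @return an object of class `comparison_report`: list with `anova_F`,
#'   `anova_p`, and `tukey`, a data frame of pairwise `diff` and adjusted
#'   `p_adj` per group pair.
#' @export
compare_groups <- function(samples, value = "mean_normalized_slope") {
  stopifnot(value %in% names(samples))
  grp <- factor(samples$group)
  if (nlevels(grp) < 2) stop("need at least 2 groups")
  if (any(table(grp) < 2)) stop("each group needs at least 2 samples")
  v <- samples[[value]]
  if (stats::var(v) == 0) {
    # all values identical across and within groups: no effect by definition
    pairs <- utils::combn(levels(grp), 2)
    tk <- data.frame(pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
                     diff = 0, p_adj = 1, stringsAsFactors = FALSE)
    return(structure(list(anova_F = 0, anova_p = 1, tukey = tk),
                     class = "comparison_report"))
  }
  fit <- stats::aov(v ~ grp)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$grp
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  structure(list(anova_F = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
                 tukey = tukey),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F = %.4g, p = %.3g\n", x$anova_F, x$anova_p))
  cat("Tukey HSD:\n")
  print(x$tukey, row.names = FALSE)
  invisible(x)
}

#' Cross-cohort t-test for one histology group
#'
#' Tests whether the same histology group measured in two cohorts
#' (institutions) has the same mean slope, i.e. whether basal normalization
#' removed between-site scale differences. Welch's unequal-variance t-test
#' by default; set `var_equal = TRUE` for the classical pooled-variance
#' Student test. Two identical degenerate cohorts report p = 1.
#'
#' @param cohort_a,cohort_b data frames of per-sample results for the same
#'   group label, at least 2 samples each.
#' @param value column to compare; default `"mean_normalized_slope"`.
#' @param var_equal pooled-variance test if `TRUE`; default Welch.
#' @return list with `group`, `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
compare_cohorts <- function(cohort_a, cohort_b,
                            value = "mean_normalized_slope",
                            var_equal = FALSE) {
  ga <- unique(cohort_a$group); gb <- unique(cohort_b$group)
  if (length(ga) != 1L || length(gb) != 1L || !identical(ga, gb))
    stop("cohorts must each contain exactly one, identical, group label")
  a <- cohort_a[[value]]; b <- cohort_b[[value]]
  if (length(a) < 2L || length(b) < 2L)
    stop("each cohort needs at least 2 samples")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    return(list(group = ga, t = if (p == 1) 0 else Inf, df = NA_real_,
                p = p, mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(group = ga, t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Reference signature set
#'
#' Expected normalized slope per histology class, against which a new sample
#' can be classified. Defaults are the derivation-set signatures (Normal
#' 0.37, CIN I 0.19, CIN III 0.02).
#'
#' @param signatures named numeric vector of pairwise-distinct normalized
#'   slopes.
#' @return an object of class `signature_set`.
#' @export
signature_set <- function(signatures = c(Normal = 0.37, CIN_I = 0.19,
                                         CIN_III = 0.02)) {
  if (is.null(names(signatures)) || any(!nzchar(names(signatures))))
    stop("signatures must be named")
  if (anyDuplicated(signatures))
    stop("signature values must be pairwise distinct")
  structure(as.list(signatures), class = "signature_set")
}

#' Classify a sample against reference signatures
#'
#' Nearest-signature rule on the sample's mean normalized slope; the margin
#' is the gap between the distances to the nearest and second-nearest
#' signatures. A margin below `delta` (default 0.04, roughly one reported
#' SEM) flags the call as uncertain. The flag is a reporting aid only; the
#' numeric slope is always returned untouched.
#'
#' @param slope a per-sample mean normalized slope, or a one-row data frame
#'   from [aggregate_sample].
#' @param signatures a [signature_set].
#' @param delta uncertainty margin; default 0.04.
#' @return list with `label`, `margin`, `uncertain`, `slope`, `distances`.
#' @export
classify_sample <- function(slope, signatures = signature_set(),
                            delta = 0.04) {
  stopifnot(inherits(signatures, "signature_set"))
  if (is.data.frame(slope)) slope <- slope$mean_normalized_slope
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope))
    stop("`slope` must be a single finite number")
  refs <- unlist(signatures)
  d <- abs(slope - refs)
  ord <- order(d)
  margin <- unname(d[ord[2]] - d[ord[1]])
  list(label = names(refs)[ord[1]], margin = margin,
       uncertain = margin < delta, slope = slope,
       distances = d)
}
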