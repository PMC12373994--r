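#' Group summary (n, mean, SD)
#' @param label Group label.
#' @param n Sample size (>= 2).
#' @param mean,sd Summary statistics (sd > 0).
#' @return Object of class \code{group_summary}.
#' @export
group_summary <- function(label, n, mean, sd) {
  if (n < 2) stop("group summary needs n >= 2", call. = FALSE)
  if (sd <= 0) stop("group summary needs sd > 0", call. = FALSE)
  structure(list(label = label, n = n, mean = mean, sd = sd),
            class = "group_summary")
}

#' Welch two-sample t statistic from summary data
#'
#' \eqn{t = (m_1 - m_2) / \sqrt{s_1^2/n_1 + s_2^2/n_2}} with
#' Welch-Satterthwaite degrees of freedom. The unequal-variance form is the
#' one whose df reproduce the published trauma-history comparisons.
#'
#' @param a,b [group_summary()] objects.
#' @return List with \code{t} and \code{df}.
#' @export
welch_t <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
  t <- (a$mean - b$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  list(t = t, df = df)
}

#' One-way ANOVA F statistic from summary data
#'
#' Reconstructs between/within sums of squares from group means, SDs and
#' sizes: \eqn{SSB = \sum n_i (m_i - \bar m)^2},
#' \eqn{SSW = \sum (n_i - 1) s_i^2}.
#'
#' @param groups List of [group_summary()] objects (>= 2).
#' @return List with \code{F}, \code{df_between}, \code{df_within}.
#' @export
anova_f <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  stopifnot(all(vapply(groups, inherits, logical(1), "group_summary")))
  n <- vapply(groups, `[[`, numeric(1), "n")
  m <- vapply(groups, `[[`, numeric(1), "mean")
  s <- vapply(groups, `[[`, numeric(1), "sd")
  N <- sum(n); k <- length(n)
  if (N <= k) stop("no within-group degrees of freedom", call. = FALSE)
  gm <- sum(n * m) / N
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum((n - 1) * s^2)
  list(F = (ssb / (k - 1)) / (ssw / (N - k)),
       df_between = k - 1, df_within = N - k)
}

#' Pearson chi-squared statistic for a contingency table
#'
#' \eqn{\chi^2 = \sum (O - E)^2 / E} with expected counts from the margins;
#' no continuity correction, matching the published group-by-category tests.
#'
#' @param counts Matrix of non-negative counts (groups x categories).
#' @return List with \code{chisq} and \code{df}.
#' @export
pearson_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  rs <- rowSums(counts); cs <- colSums(counts); N <- sum(counts)
  if (any(rs == 0) || any(cs == 0))
    stop("zero row or column margin", call. = FALSE)
  E <- outer(rs, cs) / N
  if (any(E <= 0)) stop("expected counts must be positive", call. = FALSE)
  list(chisq = sum((counts - E)^2 / E),
       df = (nrow(counts) - 1) * (ncol(counts) - 1))
}

#' Published cohort-table summary data
#'
#' Reads the packaged transcription of the cohort characteristics table:
#' per-group means/SDs for the continuous rows and per-group counts for the
#' categorical rows, together with the published test statistics. Rows whose
#' printed statistic is not reproducible from the printed summaries are
#' flagged \code{reproducible = FALSE}.
#'
#' @return List with data.frames \code{continuous}, \code{counts},
#'   \code{printed}.
#' @export
cohort_table_summaries <- function() {
  p <- function(f) system.file("extdata", f, package = "cb1pet", mustWork = TRUE)
  list(continuous = utils::read.csv(p("cohort_table_continuous.csv"),
                                    stringsAsFactors = FALSE),
       counts = utils::read.csv(p("cohort_table_counts.csv"),
                                stringsAsFactors = FALSE),
       printed = utils::read.csv(p("cohort_table_printed_stats.csv"),
                                 stringsAsFactors = FALSE))
}

#' Recompute the cohort table's group-difference statistics
#'
#' For every reproducible row of the published cohort table, recomputes the
#' test statistic from the printed summary data (ANOVA F for three-group
#' continuous rows, Welch t for two-group rows, Pearson chi-squared for
#' categorical rows) and compares it to the printed value under the
#' tolerance \code{|computed - printed| <= max(0.02, 1\% of printed)}, which
#' absorbs rounding of the printed means/SDs.
#'
#' @param include_nonreproducible If TRUE, also recompute rows known not to
#'   match their printed statistics (reported with \code{pass = NA}).
#' @return Data.frame: variable, test, computed, printed, tolerance, pass.
#' @export
cohort_table_checks <- function(include_nonreproducible = FALSE) {
  tab <- cohort_table_summaries()
  out <- list()
  for (i in seq_len(nrow(tab$printed))) {
    row <- tab$printed[i, ]
    if (!row$reproducible && !include_nonreproducible) next
    if (row$test == "anova_f") {
      cc <- tab$continuous[tab$continuous$variable == row$variable, ]
      gs <- lapply(seq_len(nrow(cc)), function(j)
        group_summary(cc$group[j], cc$n[j], cc$mean[j], cc$sd[j]))
      computed <- anova_f(gs)$F
    } else if (row$test == "welch_t") {
      cc <- tab$continuous[tab$continuous$variable == row$variable, ]
      gs <- lapply(seq_len(nrow(cc)), function(j)
        group_summary(cc$group[j], cc$n[j], cc$mean[j], cc$sd[j]))
      computed <- abs(welch_t(gs[[1]], gs[[2]])$t)
    } else {
      cc <- tab$counts[tab$counts$variable == row$variable, ]
      computed <- pearson_chi2(as.matrix(cc[, c("yes", "no")]))$chisq
    }
    tol <- max(0.02, 0.01 * abs(row$printed_value))
    out[[length(out) + 1]] <- data.frame(
      variable = row$variable, test = row$test, computed = computed,
      printed = row$printed_value, tolerance = tol,
      pass = if (row$reproducible) abs(computed - row$printed_value) <= tol
             else NA, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
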