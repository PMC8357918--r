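#' Kolmogorov-Smirnov distance between two normalized spectra
#'
#' Treats each area-normalized spectrum as a probability mass over its
#' frequency bins and returns \eqn{D = \max_k |P(k) - Q(k)|} of the
#' cumulative masses — the two-sample KS statistic applied to binned
#' spectral shape. An optional p-value uses the asymptotic KS distribution
#' with effective n = number of bins / 2 and is approximate (the bins are
#' not independent samples).
#'
#' @param p,q \code{power_spectrum} objects on identical frequency grids.
#' @param return_p also attach the approximate p-value as an attribute?
#' @return D in [0, 1]; with attribute \code{p_approx} if requested.
#' @export
ks_spectral_distance <- function(p, q, return_p = FALSE) {
  stopifnot(inherits(p, "power_spectrum"), inherits(q, "power_spectrum"))
  if (length(p$freqs) != length(q$freqs) ||
      max(abs(p$freqs - q$freqs)) > 1e-9 ||
      max(abs(p$band - q$band)) > 1e-9)
    stop("frequency grid/band mismatch between spectra")
  pm <- cumsum(p$power / sum(p$power))
  qm <- cumsum(q$power / sum(q$power))
  D <- max(abs(pm - qm))
  if (return_p) {
    ne <- length(p$freqs) / 2
    lam <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
    k <- 1:100
    attr(D, "p_approx") <- max(0, min(1, 2 * sum((-1)^(k - 1) *
                                                   exp(-2 * k^2 * lam^2))))
  }
  D
}

#' Spearman consistency of two connectivity matrices
#'
#' Vectorizes the upper triangle (diagonal excluded; symmetry makes the full
#' off-diagonal equivalent) and returns the Spearman rank correlation with
#' average ranks for ties.
#'
#' @param a,b \code{connectivity_matrix} objects of the same band and shape.
#' @return Spearman rho in [-1, 1].
#' @export
spearman_matrix_consistency <- function(a, b) {
  stopifnot(inherits(a, "connectivity_matrix"),
            inherits(b, "connectivity_matrix"))
  if (!identical(dim(a$values), dim(b$values)))
    stop("matrix shape mismatch")
  if (max(abs(a$band_limits - b$band_limits)) > 1e-9)
    stop("band mismatch")
  ut <- upper.tri(a$values)
  va <- a$values[ut]; vb <- b$values[ut]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("constant connectivity vector: Spearman undefined")
  cor(va, vb, method = "spearman")
}

#' Within- and between-subject consistency table
#'
#' Within-subject: each metric evaluated between a subject's own sessions
#' for the three ordered timepoint pairs. Between-subject: for each
#' timepoint, the average of a subject's cross-sectional consistency with
#' every other subject. Metrics: \code{ks_d} on spectra,
#' \code{spearman_alpha} and \code{spearman_beta} on connectivity matrices.
#'
#' @param spectra list (by subject) of lists (by timepoint) of
#'   \code{power_spectrum}.
#' @param conn list (by subject) of lists (by timepoint) of
#'   \code{list(alpha =, beta =)} \code{connectivity_matrix} objects.
#' @param timepoints ordered timepoint labels (default from the data).
#' @return data.frame of class \code{consistency_table} with columns
#'   subject, kind (within/between), key (pair or timepoint label), metric,
#'   value.
#' @export
build_consistency_table <- function(spectra, conn,
                                    timepoints = names(spectra[[1]])) {
  ns <- length(spectra)
  if (length(conn) != ns) stop("spectra/conn subject count mismatch")
  for (i in seq_len(ns))
    if (!all(timepoints %in% names(spectra[[i]])) ||
        !all(timepoints %in% names(conn[[i]])))
      stop("missing session: subject ", i)
  k <- length(timepoints)
  pairs <- utils::combn(k, 2)
  metric_val <- function(metric, i, ti, j, tj) {
    switch(metric,
           ks_d = ks_spectral_distance(spectra[[i]][[ti]], spectra[[j]][[tj]]),
           spearman_alpha = spearman_matrix_consistency(
             conn[[i]][[ti]]$alpha, conn[[j]][[tj]]$alpha),
           spearman_beta = spearman_matrix_consistency(
             conn[[i]][[ti]]$beta, conn[[j]][[tj]]$beta))
  }
  rows <- list()
  for (metric in c("ks_d", "spearman_alpha", "spearman_beta")) {
    for (i in seq_len(ns)) {
      for (pc in seq_len(ncol(pairs))) {
        ta <- timepoints[pairs[1, pc]]; tb <- timepoints[pairs[2, pc]]
        rows[[length(rows) + 1L]] <- data.frame(
          subject = i, kind = "within", key = paste0(ta, "-", tb),
          metric = metric, value = metric_val(metric, i, ta, i, tb),
          stringsAsFactors = FALSE)
      }
      for (tp in timepoints) {
        vals <- vapply(setdiff(seq_len(ns), i), function(j)
          metric_val(metric, i, tp, j, tp), numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = i, kind = "between", key = tp,
          metric = metric, value = mean(vals), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("consistency_table", "data.frame")
  out
}

.stat_result <- function(name, statistic, df, p, effect_size = NULL,
                         method = NULL, note = NULL) {
  structure(list(name = name, statistic = statistic, df = df, p = p,
                 effect_size = effect_size, method = method, note = note),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(x$df, collapse = ", ")
  stat <- if (length(x$df) == 2) sprintf("F(%s) = %.4g", dfs, x$statistic)
  else sprintf("t(%s) = %.4g", dfs, x$statistic)
  eff <- if (!is.null(x$effect_size))
    sprintf(", partial eta^2 = %.3f", x$effect_size) else ""
  cat(sprintf("%s: %s, p = %.4g%s\n", x$name, stat, x$p, eff))
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' One-way repeated-measures ANOVA
#'
#' Textbook decomposition for n subjects x k conditions:
#' \eqn{F = MS_{cond} / MS_{cond \times subj}} with df \code{(k-1,
#' (k-1)(n-1))}, and partial eta squared
#' \eqn{SS_{cond} / (SS_{cond} + SS_{error})}. A zero error sum of squares
#' with a nonzero condition effect is reported as \code{F = Inf, p = 0}.
#'
#' @param values n_subjects x k matrix (complete cases).
#' @param name label for the result.
#' @return \code{stat_result} with F, df pair, p and partial eta squared.
#' @export
rm_anova <- function(values, name = "rm_anova") {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 conditions")
  if (anyNA(values)) stop("complete cases required")
  grand <- mean(values)
  ss_cond <- n * sum((colMeans(values) - grand)^2)
  ss_subj <- k * sum((rowMeans(values) - grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_err <- max(ss_tot - ss_cond - ss_subj, 0)
  df <- c(k - 1L, (k - 1L) * (n - 1L))
  tiny <- 1e-12 * max(ss_tot, .Machine$double.xmin)
  if (ss_cond <= tiny) {
    return(.stat_result(name, 0, df, 1, effect_size = 0,
                        method = "one-way repeated-measures ANOVA"))
  }
  if (ss_err <= tiny) {
    return(.stat_result(name, Inf, df, 0, effect_size = 1,
                        method = "one-way repeated-measures ANOVA",
                        note = "zero error sum of squares"))
  }
  F <- (ss_cond / df[1]) / (ss_err / df[2])
  .stat_result(name, F, df, pf(F, df[1], df[2], lower.tail = FALSE),
               effect_size = ss_cond / (ss_cond + ss_err),
               method = "one-way repeated-measures ANOVA")
}

#' Unpaired t-test of within- versus between-subject consistency
#'
#' Two-sample pooled-variance two-tailed t-test on all within values (one
#' per subject per timepoint pair) against all between values (one per
#' subject per timepoint); with 8 subjects and 3 timepoints this is 24
#' versus 24 values, df = 46.
#'
#' @param table \code{consistency_table}.
#' @param metric \code{"ks_d"}, \code{"spearman_alpha"} or
#'   \code{"spearman_beta"}.
#' @return \code{stat_result}.
#' @export
compare_within_between <- function(table, metric) {
  w <- table$value[table$kind == "within" & table$metric == metric]
  b <- table$value[table$kind == "between" & table$metric == metric]
  if (length(w) < 2 || length(b) < 2) stop("need >= 2 values per group")
  if (stats::sd(c(w - mean(w), b - mean(b))) == 0)
    stop("zero pooled variance")
  tt <- t.test(w, b, var.equal = TRUE)
  .stat_result(paste0("within vs between (", metric, ")"),
               unname(tt$statistic), unname(tt$parameter), tt$p.value,
               method = "two-sample pooled-variance t-test")
}

#' Paired t-test
#'
#' Two-tailed paired t-test (df = n - 1); used post hoc for timepoint
#' contrasts. A zero-variance difference with nonzero mean is degenerate and
#' flagged.
#'
#' @param values_a,values_b paired numeric vectors of equal length >= 2.
#' @param name label for the result.
#' @return \code{stat_result}.
#' @export
paired_t <- function(values_a, values_b, name = "paired t") {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  d <- values_a - values_b
  n <- length(d)
  # same degeneracy criterion as stats::t.test ("essentially constant")
  if (stats::sd(d) / sqrt(n) <= 10 * .Machine$double.eps * abs(mean(d)) ||
      stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(.stat_result(name, 0, n - 1L, 1, method = "paired t-test"))
    return(.stat_result(name, sign(mean(d)) * Inf, n - 1L, 0,
                        method = "paired t-test",
                        note = "degenerate: zero variance of differences"))
  }
  tt <- t.test(values_a, values_b, paired = TRUE)
  .stat_result(name, unname(tt$statistic), unname(tt$parameter), tt$p.value,
               method = "paired t-test")
}

#' ROI-wise consistency map between two connectivity matrices
#'
#' For each ROI, the Spearman correlation between its connectivity profile
#' (matrix row, element (r, r) excluded) in the two matrices — the
#' region-resolved version of \code{\link{spearman_matrix_consistency}}.
#'
#' @param a,b \code{connectivity_matrix} objects of the same band.
#' @return numeric vector of 90 (n_roi) Spearman values.
#' @export
roiwise_consistency_map <- function(a, b) {
  stopifnot(inherits(a, "connectivity_matrix"),
            inherits(b, "connectivity_matrix"))
  if (max(abs(a$band_limits - b$band_limits)) > 1e-9) stop("band mismatch")
  n <- nrow(a$values)
  vapply(seq_len(n), function(r) {
    va <- a$values[r, -r]; vb <- b$values[r, -r]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0)
      stop("constant connectivity row: ROI ", r)
    cor(va, vb, method = "spearman")
  }, numeric(1))
}
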