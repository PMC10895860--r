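#' @title Two-group statistics for marker gene selection
#' @description
#' The functions documented here form the computational kernel shared by all
#' selection methods: given the expression of one gene in two groups of cells
#' they return a test statistic, a p-value (where the method defines one) and
#' an effect direction. p-values are computed and carried in natural-log
#' space (`log_p`) so that ordering is meaningful even where the
#' double-precision `p_value` underflows to exactly zero; the underflow
#' behaviour itself can be studied with the diagnostics module.
#' @name stat_tests
NULL

mb_test <- function(statistic, log_p = NA_real_, df = NA_real_,
                    direction = 0, converged = TRUE) {
  structure(list(statistic = statistic,
                 p_value = if (is.na(log_p)) NA_real_ else exp(log_p),
                 log_p = log_p, df = df,
                 effect_direction = direction, converged = converged),
            class = "mb_test")
}

#' @export
print.mb_test <- function(x, ...) {
  cat(sprintf("statistic = %.4g, p = %.4g (log p = %.4g), df = %.4g\n",
              x$statistic, x$p_value, x$log_p, x$df))
  invisible(x)
}

log_two_sided_norm <- function(z) {
  ifelse(z == 0, 0,
         log(2) + stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE))
}

log_two_sided_t <- function(t, df) {
  ifelse(t == 0, 0,
         log(2) + stats::pt(abs(t), df, lower.tail = FALSE, log.p = TRUE))
}

# Wilcoxon rank-sum over the rows of a genes x cells matrix.
# Returns U, z (normal approximation without continuity correction so that
# |z| order and p order agree exactly), log p and AUC = U / (n1 n2).
mat_wilcoxon <- function(M, i1, i2, tie_correct = TRUE) {
  n1 <- length(i1); n2 <- length(i2); n <- n1 + n2
  if (n < 2) stop("group_too_small: need at least two cells", call. = FALSE)
  G <- nrow(M)
  U <- numeric(G); z <- numeric(G)
  base_var <- n1 * n2 / 12
  for (g in seq_len(G)) {
    v <- c(M[g, i1], M[g, i2])
    r <- rank(v)
    U[g] <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    if (tie_correct) {
      tcount <- rle(sort(v))$lengths
      tie_term <- sum(tcount^3 - tcount) / (n * (n - 1))
    } else {
      tie_term <- 0
    }
    v_u <- base_var * ((n + 1) - tie_term)
    z[g] <- if (v_u <= 0) 0 else (U[g] - n1 * n2 / 2) / sqrt(v_u)
  }
  list(statistic = z, log_p = log_two_sided_norm(z), U = U,
       auc = U / (n1 * n2), df = rep(NA_real_, G))
}

# Welch / Student / overestimated-variance t statistics over matrix rows.
mat_t_test <- function(M, i1, i2,
                       type = c("welch", "student", "overestim")) {
  type <- match.arg(type)
  n1 <- length(i1); n2 <- length(i2)
  if (type == "student") {
    if (n1 + n2 < 3) stop("group_too_small: need n1 + n2 >= 3",
                          call. = FALSE)
  } else if (n1 < 2 || n2 < 2) {
    stop("group_too_small: need at least two cells per group", call. = FALSE)
  }
  M1 <- M[, i1, drop = FALSE]; M2 <- M[, i2, drop = FALSE]
  m1 <- rowMeans(M1); m2 <- rowMeans(M2)
  v1 <- row_vars(M1); v2 <- row_vars(M2)
  if (type == "student") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, nrow(M))
  } else {
    # the overestimated-variance variant replaces the rest-group size by the
    # size of the cluster of interest in the second variance term
    n2_eff <- if (type == "overestim") n1 else n2
    a1 <- v1 / n1; a2 <- v2 / n2_eff
    se2 <- a1 + a2
    df <- se2^2 / (a1^2 / (n1 - 1) + a2^2 / (n2_eff - 1))
  }
  delta <- m1 - m2
  t <- ifelse(se2 > 0, delta / sqrt(se2),
              ifelse(delta == 0, 0, sign(delta) * 1e3))
  df[!(se2 > 0)] <- n1 + n2 - 2
  df[df <= 0 | !is.finite(df)] <- n1 + n2 - 2
  list(statistic = t, log_p = log_two_sided_t(t, df), df = df)
}

# Two-sided exact conditional (hypergeometric) test on the 2x2 table of
# detected / undetected cells, computed in log space per gene.
mat_detection_test <- function(X, i1, i2, threshold = 1) {
  if (threshold <= 0) stop("invalid_threshold: detection threshold must be ",
                           "a positive count", call. = FALSE)
  n1 <- length(i1); n2 <- length(i2)
  x1 <- rowSums(X[, i1, drop = FALSE] >= threshold)
  x2 <- rowSums(X[, i2, drop = FALSE] >= threshold)
  log_p <- mapply(function(a, b) {
    m <- a + b
    k <- max(0, m - n2):min(n1, m)
    ld <- stats::dhyper(k, n1, n2, m, log = TRUE)
    lobs <- stats::dhyper(a, n1, n2, m, log = TRUE)
    sel <- ld <= lobs + 1e-7
    min(0, log_sum_exp(ld[sel]))
  }, x1, x2)
  list(statistic = x1 / n1 - x2 / n2, log_p = log_p,
       df = rep(NA_real_, nrow(X)), x1 = x1, x2 = x2)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Gene-wise logistic regression of cluster membership on expression;
# likelihood-ratio statistic against the intercept-only model.
mat_logistic_lrt <- function(M, i1, i2, maxit = 100, epsilon = 1e-8) {
  n1 <- length(i1); n2 <- length(i2); n <- n1 + n2
  resp <- c(rep(1, n1), rep(0, n2))
  null_dev <- 2 * (n1 * log(n / n1) + n2 * log(n / n2))
  G <- nrow(M)
  stat <- numeric(G); dir <- numeric(G); conv <- logical(G)
  ctrl <- stats::glm.control(maxit = maxit, epsilon = epsilon)
  for (g in seq_len(G)) {
    x <- c(M[g, i1], M[g, i2])
    if (stats::var(x) == 0) {
      stat[g] <- 0; dir[g] <- 0; conv[g] <- TRUE
      next
    }
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, x), resp, family = stats::binomial(),
                     control = ctrl))
    stat[g] <- max(0, null_dev - fit$deviance)
    dir[g] <- sign(fit$coefficients[2])
    conv[g] <- isTRUE(fit$converged)
  }
  log_p <- ifelse(stat == 0, 0,
                  stats::pchisq(stat, df = 1, lower.tail = FALSE,
                                log.p = TRUE))
  list(statistic = stat, log_p = log_p, df = rep(1, G), direction = dir,
       converged = conv)
}

# Two-group Poisson GLM with library-size offsets; closed-form MLEs and
# likelihood-ratio statistic against a common rate.
mat_poisson_test <- function(X, i1, i2, lib_sizes) {
  if (any(lib_sizes <= 0)) stop("zero_library_size: library sizes must be ",
                                "positive", call. = FALSE)
  s1 <- rowSums(X[, i1, drop = FALSE]); s2 <- rowSums(X[, i2, drop = FALSE])
  L1 <- sum(lib_sizes[i1]); L2 <- sum(lib_sizes[i2])
  lam1 <- s1 / L1; lam2 <- s2 / L2; lam0 <- (s1 + s2) / (L1 + L2)
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  stat <- pmax(0, 2 * (xlogy(s1, lam1) + xlogy(s2, lam2) -
                         xlogy(s1 + s2, lam0)))
  log_p <- ifelse(stat == 0, 0,
                  stats::pchisq(stat, df = 1, lower.tail = FALSE,
                                log.p = TRUE))
  list(statistic = stat, log_p = log_p, df = rep(1, nrow(X)),
       direction = sign(lam1 - lam2), lambda1 = lam1, lambda2 = lam2)
}

# Cohen's d with the (n - 2)-weighted pooled standard deviation.
mat_cohens_d <- function(M, i1, i2) {
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2 || n2 < 2) stop("group_too_small: need at least two cells per ",
                             "group", call. = FALSE)
  M1 <- M[, i1, drop = FALSE]; M2 <- M[, i2, drop = FALSE]
  delta <- rowMeans(M1) - rowMeans(M2)
  sp <- sqrt(((n1 - 1) * row_vars(M1) + (n2 - 1) * row_vars(M2)) /
               (n1 + n2 - 2))
  ifelse(sp > 0, delta / sp, ifelse(delta == 0, 0, sign(delta) * 1e3))
}

# Log2 fold-change in detection proportion with pseudo-count c.
mat_detection_lfc <- function(X, i1, i2, threshold = 1, pseudo = 0.5) {
  n1 <- length(i1); n2 <- length(i2)
  x1 <- rowSums(X[, i1, drop = FALSE] >= threshold)
  x2 <- rowSums(X[, i2, drop = FALSE] >= threshold)
  log2((x1 + pseudo) / (n1 + 2 * pseudo)) -
    log2((x2 + pseudo) / (n2 + 2 * pseudo))
}

# Cosine similarity between each gene's expression vector and the 0/1
# cluster-membership indicator.
mat_cosine_score <- function(M, in_cluster) {
  nk <- sum(in_cluster)
  num <- rowSums(M[, in_cluster, drop = FALSE])
  den <- sqrt(rowSums(M^2)) * sqrt(nk)
  ifelse(den > 0, num / den, 0)
}

# Log2 fold-change, framework dialects. `seurat` averages de-logged values
# before taking logs; `scanpy` de-logs the average, which blows up when one
# group has zero expression. `counts` uses means of raw counts (the dialect
# count-based GLM methods report).
mat_lfc <- function(M, i1, i2, formula = c("seurat", "scanpy", "counts"),
                    eps = 1e-9) {
  formula <- match.arg(formula)
  M1 <- M[, i1, drop = FALSE]; M2 <- M[, i2, drop = FALSE]
  switch(formula,
    seurat = log2(rowMeans(expm1(M1)) + 1) - log2(rowMeans(expm1(M2)) + 1),
    scanpy = log2(pmax(expm1(rowMeans(M1)), 0) + eps) -
             log2(pmax(expm1(rowMeans(M2)), 0) + eps),
    counts = log2(rowMeans(M1) + 1) - log2(rowMeans(M2) + 1))
}

as_row <- function(x, y) rbind(c(x, y))

#' Wilcoxon rank-sum test with optional tie correction
#'
#' Midrank-based rank-sum statistic `U = R1 - n1 (n1 + 1) / 2`, normal
#' approximation `z = (U - n1 n2 / 2) / sqrt(Var)` without continuity
#' correction, where the variance optionally includes the tie term
#' `sum(t^3 - t) / (n (n - 1))`. Two-sided p-value `2 (1 - Phi(|z|))`.
#' When every value is identical the tie-corrected variance is zero and the
#' result is defined as `z = 0`, `p = 1`.
#'
#' @param x,y Numeric expression values for the two groups.
#' @param tie_correct Apply the conventional tie correction (default `TRUE`;
#'   one widely used framework omits it by default).
#' @return An `mb_test` with the z-score as statistic; the `U` statistic and
#'   `auc = U / (n1 n2)` are attached as attributes.
#' @export
wilcoxon_test <- function(x, y, tie_correct = TRUE) {
  r <- mat_wilcoxon(as_row(x, y), seq_along(x),
                    length(x) + seq_along(y), tie_correct)
  out <- mb_test(r$statistic, r$log_p, direction = sign(r$auc - 0.5))
  attr(out, "U") <- r$U
  attr(out, "auc") <- r$auc
  out
}

#' Welch's t-test, optionally with overestimated variance
#'
#' `t = (m1 - m2) / sqrt(s1^2 / n1 + s2^2 / n2)` with Welch-Satterthwaite
#' degrees of freedom. With `overestim_var = TRUE` the size of the second
#' (rest) group is replaced by the size of the first group in the second
#' variance term, deliberately inflating the standard error for large rest
#' groups. Zero pooled spread with equal means gives `t = 0, p = 1`; with
#' unequal means the statistic is capped at `±1000`.
#'
#' @inheritParams wilcoxon_test
#' @param overestim_var Use the overestimated-variance variant.
#' @return An `mb_test` with `df` set to the Welch-Satterthwaite value.
#' @export
welch_t_test <- function(x, y, overestim_var = FALSE) {
  r <- mat_t_test(as_row(x, y), seq_along(x), length(x) + seq_along(y),
                  type = if (overestim_var) "overestim" else "welch")
  mb_test(r$statistic, r$log_p, df = r$df, direction = sign(r$statistic))
}

#' Student's t-test (pooled variance)
#'
#' Pooled-variance two-sample t statistic with `n1 + n2 - 2` degrees of
#' freedom; degenerate inputs follow the same contract as [welch_t_test()].
#'
#' @inheritParams wilcoxon_test
#' @export
student_t_test <- function(x, y) {
  r <- mat_t_test(as_row(x, y), seq_along(x), length(x) + seq_along(y),
                  type = "student")
  mb_test(r$statistic, r$log_p, df = r$df, direction = sign(r$statistic))
}

#' Exact detection test on binarized counts
#'
#' Counts are binarized at a detection threshold and the two-sided exact
#' conditional (hypergeometric) p-value of the resulting 2x2
#' detected/undetected table is computed, summing the probabilities of all
#' tables at most as likely as the observed one. Degenerate tables give
#' `p = 1`.
#'
#' @param x,y Raw count vectors for the two groups.
#' @param threshold Positive count at or above which a gene counts as
#'   detected (default 1).
#' @return An `mb_test` whose statistic is the difference in detection
#'   proportions.
#' @export
detection_test <- function(x, y, threshold = 1) {
  r <- mat_detection_test(as_row(x, y), seq_along(x),
                          length(x) + seq_along(y), threshold)
  mb_test(r$statistic, r$log_p, direction = sign(r$statistic))
}

#' Gene-wise logistic regression likelihood-ratio test
#'
#' Fits a logistic model of group-1 membership on the gene's expression and
#' compares its deviance to the intercept-only model; the statistic is
#' referred to a chi-squared distribution with one degree of freedom. Fits
#' are capped at 100 IRLS iterations with a deviance tolerance of 1e-8;
#' under perfect separation the capped fit is returned with
#' `converged = FALSE`.
#'
#' @inheritParams wilcoxon_test
#' @export
logistic_lrt <- function(x, y) {
  r <- mat_logistic_lrt(as_row(x, y), seq_along(x),
                        length(x) + seq_along(y))
  mb_test(r$statistic, r$log_p, df = 1, direction = r$direction,
          converged = r$converged)
}

#' Two-group Poisson GLM likelihood-ratio test
#'
#' Models counts as Poisson with a library-size offset and a group-specific
#' rate; the maximum-likelihood rates are `lambda_k = sum(counts_k) /
#' sum(libsize_k)` and the statistic is twice the log-likelihood-ratio
#' against a shared rate, referred to chi-squared with one degree of
#' freedom. Both groups all-zero gives statistic 0, `p = 1`.
#'
#' @param x,y Raw count vectors for the two groups.
#' @param lib_x,lib_y Positive library sizes for the cells in each group.
#' @return An `mb_test`; the fitted group rates are attached as attributes.
#' @export
poisson_two_group <- function(x, y, lib_x, lib_y) {
  stopifnot(length(x) == length(lib_x), length(y) == length(lib_y))
  r <- mat_poisson_test(as_row(x, y), seq_along(x),
                        length(x) + seq_along(y), c(lib_x, lib_y))
  out <- mb_test(r$statistic, r$log_p, df = 1, direction = r$direction)
  attr(out, "lambda") <- c(r$lambda1, r$lambda2)
  out
}

#' ROC / AUC statistic
#'
#' `AUC = U / (n1 n2)` with midrank tie handling, and the associated
#' predictive power `2 |AUC - 0.5|`. No p-value is defined.
#'
#' @inheritParams wilcoxon_test
#' @return An `mb_test` with the AUC as statistic and the predictive power
#'   attached as an attribute.
#' @export
auc_statistic <- function(x, y) {
  r <- mat_wilcoxon(as_row(x, y), seq_along(x), length(x) + seq_along(y),
                    tie_correct = TRUE)
  out <- mb_test(r$auc, direction = sign(r$auc - 0.5))
  attr(out, "power") <- 2 * abs(r$auc - 0.5)
  out
}

#' Cohen's d effect size
#'
#' Standardized mean difference with the `(n - 2)`-weighted pooled standard
#' deviation. When the pooled SD is zero the value is 0 for equal means and
#' capped at `±1000` otherwise.
#'
#' @inheritParams wilcoxon_test
#' @return Numeric effect size.
#' @export
cohens_d <- function(x, y) {
  mat_cohens_d(as_row(x, y), seq_along(x), length(x) + seq_along(y))
}

#' Log fold-change in detection proportion
#'
#' `log2((x1 + c) / (n1 + 2c)) - log2((x2 + c) / (n2 + 2c))` where `x_k` is
#' the number of cells with counts at or above the detection threshold and
#' `c = 0.5` is a pseudo-count.
#'
#' @inheritParams detection_test
#' @param pseudo Pseudo-count `c` (default 0.5).
#' @return Numeric effect size; antisymmetric in the two groups.
#' @export
detection_lfc <- function(x, y, threshold = 1, pseudo = 0.5) {
  mat_detection_lfc(as_row(x, y), seq_along(x), length(x) + seq_along(y),
                    threshold, pseudo)
}

#' Cosine score of a gene against a cluster indicator
#'
#' Cosine similarity between the gene's expression over all cells and the
#' 0/1 indicator of cluster membership. An all-zero gene scores 0 by
#' definition; a gene expressed uniformly and exclusively inside the cluster
#' scores 1.
#'
#' @param expression Numeric vector of the gene's expression over all cells.
#' @param in_cluster Logical vector marking the cluster's cells.
#' @return Numeric score in `[0, 1]` for non-negative expression.
#' @export
cosine_score <- function(expression, in_cluster) {
  stopifnot(length(expression) == length(in_cluster))
  unname(mat_cosine_score(rbind(expression), as.logical(in_cluster)))
}

#' Log2 fold-change, framework dialects
#'
#' Two formulas in circulation for the log2 fold-change of natural-log
#' normalized expression `Y` between groups `G1` and `G2`:
#' `lfc_seurat()` computes
#' `log2(mean(exp(Y) - 1) + 1) - log2(mean(exp(Y) - 1) + 1)` (de-log, then
#' average), while `lfc_scanpy()` computes
#' `log2(exp(mean(Y)) - 1 + eps) - log2(exp(mean(Y)) - 1 + eps)` with
#' `eps = 1e-9` (average, then de-log). The second formula diverges sharply
#' when a group has zero expression, where the `eps` floor dominates; see
#' [lfc_divergence_report()].
#'
#' @param x,y Natural-log normalized expression values for the two groups.
#' @param eps Floor constant of the average-then-de-log formula.
#' @return Numeric log2 fold-change.
#' @export
lfc_seurat <- function(x, y) {
  mat_lfc(as_row(x, y), seq_along(x), length(x) + seq_along(y), "seurat")
}

#' @rdname lfc_seurat
#' @export
lfc_scanpy <- function(x, y, eps = 1e-9) {
  mat_lfc(as_row(x, y), seq_along(x), length(x) + seq_along(y), "scanpy",
          eps = eps)
}
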