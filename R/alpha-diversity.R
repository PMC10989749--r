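#' Shannon diversity index
#'
#' `H = -sum(p_i * ln p_i)` over positive entries, natural logarithm.
#'
#' @param p Relative-abundance vector (non-negative, sums to 1).
#' @return Non-negative real; `NA` for an all-zero vector.
#' @export
shannon <- function(p) {
  p <- check_rel(p)
  if (sum(p) == 0) return(NA_real_)
  q <- p[p > 0]
  -sum(q * log(q))
}

#' Gini-Simpson diversity index
#'
#' `D = 1 - sum(p_i^2)`, the probability that two random draws are different
#' taxa; lies in `[0, 1]`.
#'
#' @inheritParams shannon
#' @return Real in `[0, 1]`; `NA` for an all-zero vector.
#' @export
simpson <- function(p) {
  p <- check_rel(p)
  if (sum(p) == 0) return(NA_real_)
  1 - sum(p^2)
}

# tolerance 1e-6: tables re-read from TSV carry 6-significant-digit reals
check_rel <- function(p) {
  if (any(p < 0)) stop("relative abundances must be non-negative")
  s <- sum(p)
  if (s > 0 && abs(s - 1) > 1e-6) {
    stop("relative abundances must sum to 1 (got ", format(s, digits = 10), ")")
  }
  if (s > 0) p <- p / s
  invisible(p)
}

#' Chao1 richness estimator (bias-corrected)
#'
#' `S_chao1 = S_obs + F1 (F1 - 1) / (2 (F2 + 1))` where `F1`/`F2` are the
#' numbers of singleton and doubleton taxa. Requires raw sampling counts:
#' the estimator models how many taxa were missed at the achieved depth,
#' which is meaningless for relative abundances, so non-integer input is
#' rejected.
#'
#' @param counts Non-negative integer count vector.
#' @return Estimated richness, `>= S_obs`.
#' @export
chao1 <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-9)) {
    stop("chao1 requires integer read counts, not relative abundances")
  }
  counts <- round(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Exact two-sided Mann-Whitney test by enumeration
#'
#' Enumerates all `choose(n1+n2, n1)` assignments of the pooled mid-ranks to
#' group 1 and computes the two-sided p as `2 * min(P(W <= w), P(W >= w))`
#' capped at 1. Handles ties through mid-ranks.
#'
#' @param x,y Numeric samples.
#' @return list(statistic = U for group x, p).
#' @keywords internal
mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  splits <- utils::combn(n1 + n2, n1)
  ws <- colSums(matrix(r[splits], nrow = n1))
  p <- min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
  list(statistic = w_obs - n1 * (n1 + 1) / 2, p = p)
}

#' Rank-sum association of per-sample values with a discrete variable
#'
#' Two groups: two-sided Mann-Whitney/Wilcoxon rank-sum, exact by full
#' enumeration when both groups have at most 8 samples, otherwise the normal
#' approximation with tie and continuity correction. More than two groups:
#' Kruskal-Wallis with tie correction (chi-square approximation). Samples
#' with a missing group label are dropped (count reported).
#'
#' @param values Named numeric vector (names = sample ids) or plain vector.
#' @param variable Group labels aligned with `values`.
#' @return list(statistic, p, method, n_dropped).
#' @export
alpha_group_test <- function(values, variable) {
  keep <- !is.na(values) & !is.na(variable)
  v <- values[keep]; g <- as.character(variable[keep])
  tab <- table(g)
  if (length(tab) < 2L) stop("need at least 2 non-empty groups, got: ",
                             paste(names(tab), collapse = ", "))
  if (any(tab == 0L)) stop("empty group level: ", names(tab)[tab == 0L][1L])
  if (length(tab) == 2L) {
    x <- v[g == names(tab)[1L]]
    y <- v[g == names(tab)[2L]]
    if (length(x) <= 8L && length(y) <= 8L) {
      ex <- mw_exact(x, y)
      res <- list(statistic = ex$statistic, p = ex$p,
                  method = "wilcoxon-exact")
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                correct = TRUE))
      res <- list(statistic = unname(wt$statistic), p = wt$p.value,
                  method = "wilcoxon-approx")
    }
  } else {
    kt <- stats::kruskal.test(v, factor(g))
    res <- list(statistic = unname(kt$statistic), p = kt$p.value,
                method = "kruskal-wallis")
  }
  res$n_dropped <- sum(!keep)
  res
}

#' Linear regression of per-sample values on a numeric variable
#'
#' Ordinary least squares with a two-sided t-test on the slope.
#'
#' @param values Numeric response per sample.
#' @param variable Numeric predictor per sample.
#' @return list(slope, intercept, r2, p, n_dropped).
#' @export
alpha_numeric_regression <- function(values, variable) {
  keep <- !is.na(values) & !is.na(variable)
  y <- values[keep]; x <- variable[keep]
  if (length(x) < 3L) stop("need at least 3 paired non-missing points")
  if (stats::sd(x) == 0) stop("zero variance in predictor")
  fit <- stats::lm(y ~ x)
  # exact fits are legitimate here; silence the perfect-fit note
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2L])
  p <- if (stats::sd(y) == 0) 1 else unname(sm$coefficients[2L, 4L])
  list(slope = slope, intercept = unname(stats::coef(fit)[1L]),
       r2 = if (stats::sd(y) == 0) 0 else sm$r.squared,
       p = p, n_dropped = sum(!keep))
}

#' Alpha-diversity table for a cohort
#'
#' Shannon and Simpson from copy-number-corrected relative abundances;
#' Chao1 from raw classified-read counts.
#'
#' @param rel Relative-abundance matrix (samples x features).
#' @param counts Count matrix (samples x features), for Chao1.
#' @return Matrix samples x c(shannon, simpson, chao1).
#' @export
alpha_table <- function(rel, counts) {
  stopifnot(identical(rownames(rel), rownames(counts)))
  m <- cbind(shannon = apply(rel, 1L, shannon),
             simpson = apply(rel, 1L, simpson),
             chao1 = apply(round(counts), 1L, chao1))
  rownames(m) <- rownames(rel)
  m
}
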