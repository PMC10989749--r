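#' Rank-sum screen for group-separating features
#'
#' Features present in fewer than `min_prevalence` of samples are removed,
#' each remaining feature is tested for a group difference with the rank-sum
#' machinery of [alpha_group_test()] (Wilcoxon for 2 groups, Kruskal-Wallis
#' for more), p-values are Benjamini-Hochberg corrected, and features with
#' `q <= q_threshold` are kept.
#'
#' @param t Abundance matrix (samples x features).
#' @param variable Discrete group labels per sample.
#' @param q_threshold BH q-value cutoff.
#' @param min_prevalence Minimum fraction of samples with a non-zero value.
#' @return data.frame(feature, p, q) of surviving features, ordered by p;
#'   attribute `tested` holds the full table. Empty (zero-row) when nothing
#'   passes.
#' @export
ranksum_screen <- function(t, variable, q_threshold = 0.05,
                           min_prevalence = 0.1) {
  t <- as.matrix(t)
  keep_s <- !is.na(variable)
  t <- t[keep_s, , drop = FALSE]
  g <- as.character(variable[keep_s])
  prev <- colMeans(t > 0)
  feats <- colnames(t)[prev >= min_prevalence]
  if (!length(feats)) {
    out <- data.frame(feature = character(0), p = numeric(0), q = numeric(0))
    attr(out, "tested") <- out
    return(out)
  }
  p <- vapply(feats, function(f) {
    alpha_group_test(t[, f], g)$p
  }, 0)
  q <- stats::p.adjust(p, method = "BH")
  full <- data.frame(feature = feats, p = unname(p), q = unname(q),
                     stringsAsFactors = FALSE)
  full <- full[order(full$p, full$feature), , drop = FALSE]
  rownames(full) <- NULL
  out <- full[full$q <= q_threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tested") <- full
  out
}

#' Random-Forest importance ranking of screened features
#'
#' Fits a bagged-tree ensemble classifier (Random Forest) on the screened
#' features with a fixed seed and ranks them by out-of-bag permutation
#' importance (mean decrease in accuracy). The out-of-bag error rate is the
#' model's internal cross-validation estimate.
#'
#' @param t Abundance matrix restricted to screened features.
#' @param variable Discrete group labels per sample.
#' @param trees Number of trees.
#' @param seed RNG seed (fixed seeding makes importances reproducible).
#' @return data.frame(feature, importance, direction) sorted by importance
#'   descending, with attribute `model_error` (OOB error rate in `[0, 1]`).
#' @export
rf_rank <- function(t, variable, trees = 500L, seed = 1L) {
  t <- as.matrix(t)
  keep <- !is.na(variable)
  x <- as.data.frame(t[keep, , drop = FALSE])
  colnames(x) <- make.names(colnames(t))
  y <- factor(as.character(variable[keep]))
  if (nlevels(y) < 2L) stop("labels are single-class; nothing to separate")
  if (ncol(x) < 2L) stop("need at least 2 screened features")
  if (any(table(y) < 5L)) stop("need at least 5 samples per group")
  rf <- with_seed(seed, {
    randomForest::randomForest(x = x, y = y, ntree = trees, importance = TRUE)
  })
  imp <- randomForest::importance(rf, type = 1L, scale = FALSE)[, 1L]
  direction <- vapply(seq_len(ncol(t)), function(j) {
    med <- tapply(t[keep, j], y, stats::median)
    names(med)[which.max(med)]
  }, "")
  out <- data.frame(feature = colnames(t), importance = unname(imp),
                    direction = direction, stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "model_error") <- unname(rf$err.rate[trees, "OOB"])
  out
}

spearman_test <- function(x, y) {
  n <- sum(stats::complete.cases(x, y))
  rho <- suppressWarnings(stats::cor(x, y, method = "spearman",
                                     use = "complete.obs"))
  if (is.na(rho) || n < 3L) return(list(rho = NA_real_, p = NA_real_))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Biomarkers tracking a numeric variable
#'
#' Spearman rank correlation of each feature with the variable (t
#' approximation for p), BH correction, keep `q <= q_threshold`, sorted by
#' `|rho|` descending.
#'
#' @param t Abundance matrix (samples x features).
#' @param variable Numeric variable per sample.
#' @param q_threshold BH q-value cutoff.
#' @param min_prevalence Minimum fraction of samples with a non-zero value.
#' @return data.frame(feature, rho, p, q); attribute `tested` = full table.
#' @export
numeric_biomarkers <- function(t, variable, q_threshold = 0.05,
                               min_prevalence = 0.1) {
  t <- as.matrix(t)
  keep_s <- !is.na(variable)
  t <- t[keep_s, , drop = FALSE]
  x <- as.numeric(variable[keep_s])
  if (stats::sd(x) == 0) stop("zero variance in numeric variable")
  prev <- colMeans(t > 0)
  feats <- colnames(t)[prev >= min_prevalence]
  res <- lapply(feats, function(f) spearman_test(x, t[, f]))
  rho <- vapply(res, `[[`, 0, "rho")
  p <- vapply(res, `[[`, 0, "p")
  ok <- !is.na(rho)
  full <- data.frame(feature = feats[ok], rho = rho[ok], p = p[ok],
                     stringsAsFactors = FALSE)
  full$q <- stats::p.adjust(full$p, method = "BH")
  full <- full[order(-abs(full$rho), full$feature), , drop = FALSE]
  rownames(full) <- NULL
  out <- full[full$q <= q_threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tested") <- full
  out
}
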