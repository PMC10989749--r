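planted_table <- function(n_per_group = 10, n_noise = 8, seed = 31) {
  set.seed(seed)
  n <- 2 * n_per_group
  shift <- c(stats::runif(n_per_group, 0, 1), stats::runif(n_per_group, 2, 3))
  t <- cbind(planted = shift,
             matrix(stats::runif(n * n_noise), n,
                    dimnames = list(NULL, paste0("noise", seq_len(n_noise)))))
  rownames(t) <- paste0("s", seq_len(n))
  list(t = t, g = rep(c("a", "b"), each = n_per_group))
}

test_that("the screen keeps a planted shift with its exact rank-sum p", {
  # one group [1..5], the other [11..15]: complete separation
  t <- cbind(planted = c(1:5, 11:15),
             flat = rep(2, 10),
             matrix(stats::runif(30, 1, 2), 10,
                    dimnames = list(NULL, paste0("n", 1:3))))
  rownames(t) <- paste0("s", 1:10)
  g <- rep(c("a", "b"), each = 5)
  res <- ranksum_screen(t, g, q_threshold = 0.05)
  expect_true("planted" %in% res$feature)
  ref <- stats::wilcox.test(1:5, 11:15, exact = TRUE)$p.value
  expect_equal(res$p[res$feature == "planted"], ref)
  # identical-across-groups feature: p = 1, never kept
  full <- attr(res, "tested")
  expect_equal(full$p[full$feature == "flat"], 1)
  expect_false("flat" %in% res$feature)
})

test_that("q-values follow the Benjamini-Hochberg ladder", {
  t <- planted_table()$t
  g <- planted_table()$g
  res <- attr(ranksum_screen(t, g, q_threshold = 1), "tested")
  expect_equal(res$q, stats::p.adjust(res$p, method = "BH"))
  # the hand ladder: p = [0.01, 0.02, 0.03] with m = 3 -> all q = 0.03
  expect_equal(unname(stats::p.adjust(c(0.01, 0.02, 0.03), "BH")),
               c(0.03, 0.03, 0.03))
})

test_that("low-prevalence features are excluded before testing", {
  set.seed(32)
  t <- cbind(rare = c(1, rep(0, 19)),
             common = stats::runif(20))
  rownames(t) <- paste0("s", 1:20)
  g <- rep(c("a", "b"), each = 10)
  res <- attr(ranksum_screen(t, g), "tested")
  expect_false("rare" %in% res$feature)
  expect_true("common" %in% res$feature)
  # the filter and the screen commute: filtering first changes nothing
  res2 <- attr(ranksum_screen(t[, "common", drop = FALSE], g), "tested")
  expect_equal(res$p[res$feature == "common"],
               res2$p[res2$feature == "common"])
})

test_that("Random Forest ranks a perfectly separating feature first", {
  pt <- planted_table(n_per_group = 30, n_noise = 20, seed = 33)
  rep_ <- rf_rank(pt$t, pt$g, seed = 5)
  expect_equal(rep_$feature[1], "planted")
  expect_lte(attr(rep_, "model_error"), 0.05)
  expect_true(all(diff(rep_$importance) <= 0))
  expect_equal(rep_$direction[rep_$feature == "planted"], "b")
})

test_that("the forest is reproducible under a fixed seed", {
  pt <- planted_table(n_per_group = 8, n_noise = 5, seed = 34)
  r1 <- rf_rank(pt$t, pt$g, trees = 100, seed = 9)
  r2 <- rf_rank(pt$t, pt$g, trees = 100, seed = 9)
  expect_identical(r1, r2)
})

test_that("permuted labels push the OOB error to the chance baseline", {
  pt <- planted_table(n_per_group = 20, n_noise = 10, seed = 35)
  set.seed(36)
  g_null <- sample(pt$g)
  rep_ <- rf_rank(pt$t, g_null, seed = 5)
  expect_gt(attr(rep_, "model_error"), 0.5 - 0.25)  # majority baseline 0.5
})

test_that("duplicated features share their importance across seeds", {
  pt <- planted_table(n_per_group = 15, n_noise = 4, seed = 37)
  t2 <- cbind(pt$t, planted_copy = pt$t[, "planted"])
  imps <- vapply(1:5, function(s) {
    r <- rf_rank(t2, pt$g, trees = 300, seed = s)
    c(r$importance[r$feature == "planted"],
      r$importance[r$feature == "planted_copy"])
  }, numeric(2))
  # averaged over seeds the twins carry comparable importance
  expect_lt(abs(mean(imps[1, ]) - mean(imps[2, ])),
            0.5 * max(mean(imps[1, ]), mean(imps[2, ])))
})

test_that("degenerate labels and tiny groups are rejected", {
  pt <- planted_table(n_per_group = 6, n_noise = 3, seed = 38)
  expect_error(rf_rank(pt$t, rep("a", 12)), "single-class")
  expect_error(rf_rank(pt$t, c(rep("a", 2), rep("b", 10))), "5 samples")
  expect_error(rf_rank(pt$t[, 1, drop = FALSE], pt$g), "2 screened")
})

test_that("numeric biomarkers rank by Spearman correlation", {
  set.seed(39)
  x <- stats::runif(12)
  t <- cbind(mono = x^3,                      # rho exactly 1
             inv = max(x) + 0.1 - x,          # rho exactly -1, stays positive
             noise = stats::runif(12))
  rownames(t) <- paste0("s", 1:12)
  res <- numeric_biomarkers(t, x, q_threshold = 0.05)
  expect_equal(res$rho[res$feature == "mono"], 1)
  expect_equal(res$rho[res$feature == "inv"], -1)
  full <- attr(res, "tested")
  expect_true(all(abs(full$rho[1:2]) >= abs(full$rho[-(1:2)])))
})

test_that("the hand-computed Spearman value comes out at -0.5", {
  # x=[1,2,3] vs y=[3,1,2]: sum d^2 = 6 -> rho = 1 - 36/24 = -0.5
  st <- ampliflow:::spearman_test(c(1, 2, 3), c(3, 1, 2))
  expect_equal(st$rho, -0.5)
})
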