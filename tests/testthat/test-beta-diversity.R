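two_leaf_pack <- function(bl = 1) {
  tree <- ape::read.tree(text = sprintf("((A:%g,B:%g):0);", bl, bl))
  structure(list(tree = tree, leaf_ids = c("A", "B"),
                 copy_number = c(A = 1, B = 1)),
            class = "reference_pack")
}

pure_profile <- function(leaf, pack, id = leaf) {
  counts <- stats::setNames(numeric(length(pack$leaf_ids)), pack$leaf_ids)
  counts[leaf] <- 1
  list(sample_id = id, counts = counts, normalized = counts / sum(counts),
       empty = FALSE)
}

test_that("the tree distance matches the hand-traced two-leaf recursion", {
  pack <- two_leaf_pack(1)
  a <- pure_profile("A", pack); b <- pure_profile("B", pack)
  expect_equal(metastorms_distance(a, b, pack), 1 - exp(-1), tolerance = 1e-9)
  expect_equal(metastorms_distance(a, a, pack), 0)
  # zero branch lengths: siblings become equivalent
  pack0 <- two_leaf_pack(0)
  expect_equal(metastorms_distance(pure_profile("A", pack0),
                                   pure_profile("B", pack0), pack0), 0)
})

test_that("empty samples give distance 1 to others, 0 (degenerate) together", {
  pack <- two_leaf_pack(1)
  a <- pure_profile("A", pack)
  e <- list(sample_id = "e", counts = c(A = 0, B = 0),
            normalized = c(A = 0, B = 0), empty = TRUE)
  expect_equal(metastorms_distance(a, e, pack), 1)
  d <- metastorms_distance(e, e, pack)
  expect_equal(as.numeric(d), 0)
  expect_true(attr(d, "degenerate"))
})

test_that("tree distances are symmetric, in [0,1], zero iff identical masses", {
  pack <- simulate_reference_pack(16, seed = 6)
  set.seed(10)
  profs <- random_profiles(pack, 12)
  for (i in 1:10) {
    p <- sample(12, 2)
    d1 <- metastorms_distance(profs[[p[1]]], profs[[p[2]]], pack)
    d2 <- metastorms_distance(profs[[p[2]]], profs[[p[1]]], pack)
    expect_equal(d1, d2, tolerance = 1e-12)
    expect_gte(d1, 0); expect_lte(d1, 1)
    expect_equal(metastorms_distance(profs[[p[1]]], profs[[p[1]]], pack), 0,
                 tolerance = 1e-12)
  }
})

test_that("distance grows as mass moves to more distant clades", {
  # ladder tree: L1 closest to L2, then L3, L4, L5
  tree <- ape::read.tree(
    text = "((((L1:1,L2:1):1,L3:1):1,L4:1):1,L5:1);")
  pack <- structure(list(tree = tree, leaf_ids = tree$tip.label,
                         copy_number = stats::setNames(rep(1, 5), tree$tip.label)),
                    class = "reference_pack")
  base <- pure_profile("L1", pack)
  d <- vapply(c("L2", "L3", "L4", "L5"), function(l) {
    metastorms_distance(base, pure_profile(l, pack), pack)
  }, 0)
  expect_true(all(diff(d) > 0))
})

test_that("the unweighted flavour ignores abundance rescaling", {
  pack <- simulate_reference_pack(8, seed = 6)
  c1 <- stats::setNames(c(5, 0, 3, 0, 2, 0, 0, 1), pack$leaf_ids)
  c2 <- stats::setNames(c(50, 0, 300, 0, 2, 0, 0, 100), pack$leaf_ids)  # same support
  c3 <- stats::setNames(c(0, 4, 0, 1, 0, 2, 2, 0), pack$leaf_ids)
  p1 <- profile_of(pack, c1[c1 > 0], "p1")
  p2 <- profile_of(pack, c2[c2 > 0], "p2")
  p3 <- profile_of(pack, c3[c3 > 0], "p3")
  expect_equal(metastorms_distance(p1, p3, pack, weighted = FALSE),
               metastorms_distance(p2, p3, pack, weighted = FALSE),
               tolerance = 1e-12)
})

test_that("the hierarchy distance matches its hand-traced cases", {
  pack <- tiny_pack()
  a <- fprofile_of(c(K1 = 1)); b <- fprofile_of(c(K2 = 1))
  # K1, K2 share the L2 node (one 0.5 edge each from the KO leaf... they
  # differ at L3, meet at L2: two edges per side -> 0.25 matched)
  expect_equal(hierarchical_metastorms(a, b, pack), 1 - 0.25)
  expect_equal(hierarchical_metastorms(a, a, pack), 0)
  # sharing only the root: 4 edges per side
  c_ <- fprofile_of(c(K3 = 1))
  expect_equal(hierarchical_metastorms(a, c_, pack), 1 - 0.5^4)
})

test_that("two KOs sharing an L3 parent sit one attenuating edge away", {
  pack <- tiny_pack()
  pack$hierarchy <- data.frame(ko = c("Kx", "Ky"), L1 = "A", L2 = "A1",
                               L3 = "a", stringsAsFactors = FALSE)
  d <- hierarchical_metastorms(fprofile_of(c(Kx = 1)), fprofile_of(c(Ky = 1)),
                               pack)
  expect_equal(d, 0.5)
})

test_that("distance matrices are symmetric, zero-diagonal, thread-invariant", {
  pack <- simulate_reference_pack(12, seed = 13)
  set.seed(14)
  profs <- random_profiles(pack, 8)
  d1 <- distance_matrix(profs, pack, "metastorms-weighted", threads = 1)
  d8 <- distance_matrix(profs, pack, "metastorms-weighted", threads = 8)
  expect_identical(d1, d8)
  expect_equal(d1, t(d1))
  expect_equal(unname(diag(d1)), rep(0, 8))
  same <- list(profs[[1]], profs[[1]], profs[[1]])
  same <- lapply(seq_along(same), function(i) {
    p <- same[[i]]; p$sample_id <- paste0("s", i); p
  })
  expect_equal(max(distance_matrix(same, pack, "metastorms-weighted")), 0)
})

test_that("PCoA reconstructs collinear configurations exactly", {
  pts <- c(0, 1, 2)
  d <- as.matrix(stats::dist(pts))
  dimnames(d) <- list(letters[1:3], letters[1:3])
  ord <- pcoa(d)
  ax1 <- ord$coordinates[, 1]
  expect_equal(unname(abs(ax1["b"] - ax1["a"])), 1, tolerance = 1e-8)
  expect_equal(unname(abs(ax1["c"] - ax1["a"])), 2, tolerance = 1e-8)
  expect_true(all(diff(ord$explained) <= 1e-12))
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(pcoa(z)$coordinates == 0))
})

test_that("PCoA on Euclidean distances reproduces the Gram geometry", {
  set.seed(21)
  x <- matrix(stats::rnorm(8 * 3), 8, dimnames = list(paste0("s", 1:8), NULL))
  d <- as.matrix(stats::dist(x))
  ord <- pcoa(d, axes = 7)
  rec <- as.matrix(stats::dist(ord$coordinates))
  expect_lt(max(abs(rec - d)), 1e-8)
  # cross-check against classical scaling in stats
  cs <- stats::cmdscale(d, k = 2)
  expect_lt(max(abs(abs(ord$coordinates[, 1:2]) - abs(cs))), 1e-8)
})

test_that("PCA matches PCoA on Euclidean distances and centers columns", {
  set.seed(22)
  x <- matrix(stats::rnorm(9 * 4), 9, dimnames = list(paste0("s", 1:9), paste0("f", 1:4)))
  d <- as.matrix(stats::dist(x)); dimnames(d) <- list(rownames(x), rownames(x))
  p1 <- pca(x); p2 <- pcoa(d)
  expect_lt(max(abs(abs(p1$coordinates) - abs(p2$coordinates))), 1e-8)
  # adding a constant feature changes nothing
  p3 <- pca(cbind(x, const = 5))
  expect_equal(p1$coordinates, p3$coordinates, tolerance = 1e-12)
  # samples on a line: first axis explains everything
  line <- outer(1:6, c(1, 2, 3))
  rownames(line) <- paste0("s", 1:6)
  expect_equal(pca(line)$explained[1], 1, tolerance = 1e-12)
})

test_that("PERMANOVA pseudo-F matches the partition formula by hand", {
  # 4 samples, within-pair distance 1, between 2:
  # SS_T = (1+1+4*4)/4 = 4.5, SS_W = 1/2 + 1/2 = 1, F = 3.5/0.5 = 7
  d <- matrix(2, 4, 4); d[1, 2] <- d[2, 1] <- 1; d[3, 4] <- d[4, 3] <- 1
  diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  r <- permanova(d, c("g1", "g1", "g2", "g2"), permutations = 99, seed = 2)
  expect_equal(r$pseudo_F, 7)
})

test_that("PERMANOVA agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(23)
  x <- matrix(stats::runif(10 * 5), 10)
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(paste0("s", 1:10), paste0("s", 1:10))
  g <- rep(c("a", "b"), each = 5)
  r <- permanova(d, g, permutations = 99, seed = 2)
  ref <- vegan::adonis2(stats::as.dist(d) ~ g, permutations = 99)
  expect_equal(r$pseudo_F, ref$F[1], tolerance = 1e-10)
})

test_that("permutation p at n=6 matches exhaustive label enumeration", {
  set.seed(24)
  x <- c(stats::rnorm(3), stats::rnorm(3, 1.5))
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- rep(c("a", "b"), each = 3)
  f_obs <- permanova(d, g, permutations = 9, seed = 1)$pseudo_F
  combs <- utils::combn(6, 3)
  f_all <- apply(combs, 2, function(idx) {
    gg <- rep("b", 6); gg[idx] <- "a"
    ampliflow:::permanova_F(d^2, gg)
  })
  p_exact <- mean(f_all >= f_obs - 1e-12)
  perms <- 999
  r <- permanova(d, g, permutations = perms, seed = 7)
  mc_se <- sqrt(p_exact * (1 - p_exact) / perms)
  expect_lt(abs(r$p - p_exact), 2 * mc_se + 2 / perms)
})

test_that("ANOSIM hits its extreme values and a brute-force oracle", {
  # perfectly separated: all within < all between -> R = 1
  d <- matrix(5, 6, 6)
  d[1:3, 1:3] <- 1; d[4:6, 4:6] <- 1; diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- rep(c("a", "b"), each = 3)
  expect_equal(anosim(d, g, permutations = 19, seed = 1)$R, 1)
  # all distances equal -> R = 0
  d0 <- matrix(1, 6, 6); diag(d0) <- 0
  dimnames(d0) <- dimnames(d)
  expect_equal(anosim(d0, g, permutations = 19, seed = 1)$R, 0)
  # random 6-sample instance vs an independent rank computation
  set.seed(25)
  for (i in 1:5) {
    x <- stats::rnorm(6)
    dr <- as.matrix(stats::dist(x)); dimnames(dr) <- dimnames(d)
    rk <- rank(dr[upper.tri(dr)])
    w <- outer(g, g, "==")[upper.tri(dr)]
    oracle <- (mean(rk[!w]) - mean(rk[w])) / (length(rk) / 2)
    expect_equal(anosim(dr, g, permutations = 9, seed = 1)$R, oracle,
                 tolerance = 1e-12)
  }
})

test_that("ANOSIM R agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(26)
  x <- matrix(stats::runif(12 * 4), 12)
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(paste0("s", 1:12), paste0("s", 1:12))
  g <- rep(c("a", "b", "c"), each = 4)
  r <- anosim(d, g, permutations = 49, seed = 3)
  ref <- vegan::anosim(stats::as.dist(d), g, permutations = 49)
  expect_equal(r$R, unname(ref$statistic), tolerance = 1e-10)
})

test_that("distance regression finds perfect gradients and rejects tiny n", {
  x <- c(1, 3, 6, 10)
  d <- abs(outer(x, x, "-")) * 0.07
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  r <- distance_numeric_regression(d, x, permutations = 99, seed = 1)
  expect_equal(r$r2, 1, tolerance = 1e-12)
  expect_equal(r$slope, 0.07, tolerance = 1e-12)
  expect_error(distance_numeric_regression(d[1:2, 1:2], x[1:2]),
               "insufficient pairs")
  expect_error(distance_numeric_regression(d, rep(1, 4)), "zero variance")
})

test_that("permutation tests are reproducible under their seed", {
  set.seed(27)
  x <- matrix(stats::runif(8 * 3), 8)
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(paste0("s", 1:8), paste0("s", 1:8))
  g <- rep(c("a", "b"), each = 4)
  expect_identical(permanova(d, g, 99, seed = 5), permanova(d, g, 99, seed = 5))
  expect_identical(anosim(d, g, 99, seed = 5), anosim(d, g, 99, seed = 5))
})
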