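# --- mass-tree machinery -----------------------------------------------------
# A "mass tree" is the minimal structure the bottom-up matching needs:
# node parents, per-node attenuation applied when residual mass moves to the
# parent, a child-before-parent node ordering, and a leaf-id -> node map.

mass_tree_from_phylo <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  parent <- rep(NA_integer_, nnode)
  atten <- rep(1, nnode)
  po <- ape::reorder.phylo(tree, "postorder")
  parent[po$edge[, 2L]] <- po$edge[, 1L]
  atten[po$edge[, 2L]] <- exp(-po$edge.length)
  ord <- c(po$edge[, 2L], ntip + 1L)  # children in postorder, then root
  list(n = nnode, parent = parent, atten = atten, order = ord,
       leaf_index = stats::setNames(seq_len(ntip), tree$tip.label))
}

mass_tree_from_hierarchy <- function(hier, atten = 0.5) {
  # root -> L1 -> L2 -> L3 -> KO; one leaf per (KO, path) row
  l1 <- unique(hier$L1)
  l2 <- unique(paste(hier$L1, hier$L2, sep = "|"))
  l3 <- unique(paste(hier$L1, hier$L2, hier$L3, sep = "|"))
  nleaf <- nrow(hier)
  ids <- list(root = 1L,
              L1 = stats::setNames(1L + seq_along(l1), l1),
              L2 = stats::setNames(1L + length(l1) + seq_along(l2), l2),
              L3 = stats::setNames(1L + length(l1) + length(l2) + seq_along(l3), l3))
  leaf0 <- 1L + length(l1) + length(l2) + length(l3)
  n <- leaf0 + nleaf
  parent <- rep(NA_integer_, n)
  for (lab in l1) parent[ids$L1[[lab]]] <- 1L
  for (lab in l2) parent[ids$L2[[lab]]] <- ids$L1[[sub("\\|.*$", "", lab)]]
  for (lab in l3) parent[ids$L3[[lab]]] <- ids$L2[[sub("\\|[^|]*$", "", lab)]]
  leafnode <- leaf0 + seq_len(nleaf)
  parent[leafnode] <- ids$L3[paste(hier$L1, hier$L2, hier$L3, sep = "|")]
  att <- rep(atten, n)
  # children before parents: leaves, L3, L2, L1, root
  ord <- c(leafnode, unname(ids$L3), unname(ids$L2), unname(ids$L1), 1L)
  list(n = n, parent = parent, atten = att, order = ord,
       leaf_rows = leafnode, hier = hier)
}

# Bottom-up mass matching on a mass tree, vectorized over pairs.
# massA/massB: n_nodes x n_pairs matrices of initial (leaf) mass.
# Returns the matched-similarity vector S per pair; distance = 1 - S.
mass_tree_match <- function(mt, massA, massB) {
  S <- numeric(ncol(massA))
  for (nd in mt$order) {
    a <- massA[nd, ]; b <- massB[nd, ]
    m <- pmin(a, b)
    S <- S + m
    pa <- mt$parent[nd]
    if (!is.na(pa)) {
      att <- mt$atten[nd]
      massA[pa, ] <- massA[pa, ] + (a - m) * att
      massB[pa, ] <- massB[pa, ] + (b - m) * att
    }
    # unmatched mass at the root is discarded
  }
  S
}

leaf_mass <- function(profile, pack, weighted) {
  a <- profile$normalized[pack$leaf_ids]
  if (!weighted) {
    pres <- a > 0
    a <- ifelse(pres, 1 / sum(pres), 0)
    names(a) <- pack$leaf_ids
  }
  a
}

#' Phylogeny-aware community distance between two samples
#'
#' Matches abundance mass bottom-up along the reference tree: identical mass
#' at a leaf is credited to similarity immediately; unmatched residuals
#' propagate to the parent attenuated by `exp(-branch_length)`, are matched
#' again where lineages meet, and whatever reaches past the root unmatched is
#' lost. The distance is `1 - total matched similarity`, in `[0, 1]`: closely
#' related communities lose little mass to attenuation, phylogenetically
#' distant ones lose most of it.
#'
#' @param a,b `taxonomic_profile` objects mapped onto `pack`'s leaves.
#' @param pack A `reference_pack`.
#' @param weighted Use copy-number-corrected abundances (`TRUE`) or equal
#'   mass `1/n` on present leaves (`FALSE`, presence/absence flavour).
#' @return Distance in `[0, 1]`.
#' @export
metastorms_distance <- function(a, b, pack, weighted = TRUE) {
  if (isTRUE(a$empty) && isTRUE(b$empty)) return(structure(0, degenerate = TRUE))
  if (isTRUE(a$empty) || isTRUE(b$empty)) return(1)
  mt <- mass_tree_from_phylo(pack$tree)
  ma <- mb <- matrix(0, nrow = mt$n, ncol = 1L)
  ma[mt$leaf_index[pack$leaf_ids], 1L] <- leaf_mass(a, pack, weighted)
  mb[mt$leaf_index[pack$leaf_ids], 1L] <- leaf_mass(b, pack, weighted)
  max(0, 1 - mass_tree_match(mt, ma, mb))
}

#' Hierarchy-aware functional distance between two samples
#'
#' The same bottom-up matching recursion run on the 4-level pathway hierarchy
#' tree (root - Level1 - Level2 - Level3 - KO) with a fixed attenuation of
#' 0.5 per edge, since hierarchy edges carry no branch lengths. A KO with
#' several hierarchy paths splits its mass equally across them.
#'
#' @param a,b `functional_profile` objects.
#' @param pack A `reference_pack`.
#' @return Distance in `[0, 1]`.
#' @export
hierarchical_metastorms <- function(a, b, pack) {
  ea <- length(a$ko_abundance) == 0 || sum(a$ko_abundance) == 0
  eb <- length(b$ko_abundance) == 0 || sum(b$ko_abundance) == 0
  if (ea && eb) return(structure(0, degenerate = TRUE))
  if (ea || eb) return(1)
  mt <- mass_tree_from_hierarchy(pack$hierarchy)
  ko_leaf_mass <- function(fp) {
    m <- numeric(mt$n)
    paths_per_ko <- table(mt$hier$ko)
    for (i in seq_along(mt$leaf_rows)) {
      ko <- mt$hier$ko[i]
      ab <- fp$ko_abundance[ko]
      if (!is.na(ab) && ab > 0) {
        m[mt$leaf_rows[i]] <- ab / paths_per_ko[[ko]]
      }
    }
    m
  }
  ma <- matrix(ko_leaf_mass(a), ncol = 1L)
  mb <- matrix(ko_leaf_mass(b), ncol = 1L)
  max(0, 1 - mass_tree_match(mt, ma, mb))
}

#' Pairwise distance matrix over a cohort
#'
#' Computes all unordered pairs with the chosen metric. Pairs are evaluated
#' in blocks vectorized over the mass-tree recursion; the result is
#' independent of block/thread decomposition by construction (each pair is an
#' independent pure computation assembled in fixed sample order).
#'
#' @param profiles List of `taxonomic_profile` (taxonomic metrics) or
#'   `functional_profile` (functional metric) objects.
#' @param pack A `reference_pack`.
#' @param metric One of `"metastorms-weighted"`, `"metastorms-unweighted"`,
#'   `"hierarchical-metastorms"`.
#' @param threads Worker processes for pair blocks (result is identical for
#'   any value).
#' @return Symmetric distance matrix with sample ids as dimnames.
#' @export
distance_matrix <- function(profiles, pack,
                            metric = c("metastorms-weighted",
                                       "metastorms-unweighted",
                                       "hierarchical-metastorms"),
                            threads = 1L) {
  metric <- match.arg(metric)
  ns <- length(profiles)
  if (ns < 2L) stop("need at least 2 samples")
  ids <- vapply(profiles, `[[`, "", "sample_id")
  if (metric == "hierarchical-metastorms") {
    mt <- mass_tree_from_hierarchy(pack$hierarchy)
    paths_per_ko <- table(mt$hier$ko)
    mass <- matrix(0, nrow = mt$n, ncol = ns)
    for (j in seq_len(ns)) {
      ab <- profiles[[j]]$ko_abundance
      for (i in seq_along(mt$leaf_rows)) {
        ko <- mt$hier$ko[i]
        v <- ab[ko]
        if (!is.na(v) && v > 0) mass[mt$leaf_rows[i], j] <- v / paths_per_ko[[ko]]
      }
    }
    empty <- colSums(mass) == 0
  } else {
    mt <- mass_tree_from_phylo(pack$tree)
    weighted <- metric == "metastorms-weighted"
    mass <- matrix(0, nrow = mt$n, ncol = ns)
    for (j in seq_len(ns)) {
      if (!isTRUE(profiles[[j]]$empty)) {
        mass[mt$leaf_index[pack$leaf_ids], j] <-
          leaf_mass(profiles[[j]], pack, weighted)
      }
    }
    empty <- vapply(profiles, function(p) isTRUE(p$empty), TRUE)
  }
  pairs <- utils::combn(ns, 2L)
  compute_block <- function(cols) {
    S <- mass_tree_match(mt, mass[, pairs[1L, cols], drop = FALSE],
                         mass[, pairs[2L, cols], drop = FALSE])
    pmax(0, 1 - S)
  }
  npair <- ncol(pairs)
  nblock <- max(1L, min(as.integer(threads), npair))
  blocks <- if (nblock == 1L) list(seq_len(npair)) else
    split(seq_len(npair), cut(seq_len(npair), nblock, labels = FALSE))
  if (nblock > 1L && .Platform$OS.type == "unix") {
    dvals <- unlist(parallel::mclapply(blocks, compute_block,
                                       mc.cores = nblock), use.names = FALSE)
  } else {
    dvals <- unlist(lapply(blocks, compute_block), use.names = FALSE)
  }
  d <- matrix(0, ns, ns, dimnames = list(ids, ids))
  for (k in seq_len(npair)) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    v <- dvals[k]
    if (empty[i] && empty[j]) v <- 0 else if (empty[i] || empty[j]) v <- 1
    d[i, j] <- d[j, i] <- v
  }
  d
}

# --- ordination --------------------------------------------------------------

fix_axis_signs <- function(coords) {
  for (j in seq_len(ncol(coords))) {
    col <- coords[, j]
    if (any(col != 0) && col[which.max(abs(col))] < 0) coords[, j] <- -col
  }
  coords
}

#' Principal co-ordinate analysis (classical scaling)
#'
#' Gower double-centering `B = -1/2 * J D^2 J`, eigendecomposition, and
#' coordinates `v_i * sqrt(lambda_i)` over positive eigenvalues. Explained
#' fractions are eigenvalues over the positive-eigenvalue total. Axis signs
#' are fixed by making the largest-magnitude loading positive.
#'
#' @param d Symmetric distance matrix.
#' @param axes Number of axes requested.
#' @return list(sample_ids, coordinates, explained, deficient) of class
#'   `ordination`; `deficient` flags fewer positive eigenvalues than `axes`.
#' @export
pcoa <- function(d, axes = 2L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 samples")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- eg$values > 1e-10 * max(abs(eg$values), 1e-300)
  npos <- sum(pos)
  keep <- seq_len(min(axes, npos))
  if (npos == 0L) {
    coords <- matrix(0, n, axes,
                     dimnames = list(rownames(d), paste0("Axis", seq_len(axes))))
    res <- list(sample_ids = rownames(d), coordinates = coords,
                explained = rep(0, axes), deficient = TRUE)
    class(res) <- "ordination"
    return(res)
  }
  lam <- eg$values[pos]
  coords <- eg$vectors[, which(pos)[keep], drop = FALSE] %*%
    diag(sqrt(lam[keep]), length(keep))
  coords <- fix_axis_signs(coords)
  dimnames(coords) <- list(rownames(d), paste0("Axis", keep))
  res <- list(sample_ids = rownames(d), coordinates = coords,
              explained = lam[keep] / sum(lam),
              deficient = npos < axes)
  class(res) <- "ordination"
  res
}

#' Principal component analysis of an abundance table
#'
#' Column-mean centering (no variance scaling) followed by singular value
#' decomposition; explained fractions are squared singular values over their
#' total. Same sign convention as [pcoa()].
#'
#' @param t Abundance matrix (samples x features).
#' @param axes Number of axes requested.
#' @return An `ordination` object.
#' @export
pca <- function(t, axes = 2L) {
  t <- as.matrix(t)
  if (nrow(t) < 3L) stop("need at least 3 samples")
  x <- scale(t, center = TRUE, scale = FALSE)
  sv <- svd(x)
  tot <- sum(sv$d^2)
  if (tot < 1e-24) {
    coords <- matrix(0, nrow(t), axes,
                     dimnames = list(rownames(t), paste0("PC", seq_len(axes))))
    res <- list(sample_ids = rownames(t), coordinates = coords,
                explained = rep(0, axes), deficient = TRUE)
    class(res) <- "ordination"
    return(res)
  }
  pos <- sv$d^2 > 1e-12 * tot
  keep <- seq_len(min(axes, sum(pos)))
  coords <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep))
  coords <- fix_axis_signs(coords)
  dimnames(coords) <- list(rownames(t), paste0("PC", keep))
  res <- list(sample_ids = rownames(t), coordinates = coords,
              explained = sv$d[keep]^2 / tot,
              deficient = sum(pos) < axes)
  class(res) <- "ordination"
  res
}

# --- permutation statistics --------------------------------------------------

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

permanova_F <- function(d2, groups) {
  n <- length(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ss_within <- ss_within +
      sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  g <- length(unique(groups))
  num <- (ss_total - ss_within) / (g - 1)
  den <- ss_within / (n - g)
  if (den == 0) Inf else num / den
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions the squared-distance sums into within- and between-group parts:
#' `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within = sum_g sum_{i<j in g}
#' d_ij^2 / n_g`, `pseudo-F = ((SS_total - SS_within)/(g-1)) /
#' (SS_within/(N-g))`. Significance by permuting group labels;
#' `p = (#{F_perm >= F_obs} + 1) / (permutations + 1)`.
#'
#' @param d Symmetric distance matrix.
#' @param variable Discrete group labels aligned with rows of `d`.
#' @param permutations Number of label permutations.
#' @param seed RNG seed for the permutations (required for reproducibility).
#' @return list(pseudo_F, p, n_dropped).
#' @export
permanova <- function(d, variable, permutations = 999L, seed = 1L) {
  d <- as.matrix(d)
  keep <- !is.na(variable)
  groups <- as.character(variable[keep])
  dk <- d[keep, keep, drop = FALSE]
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L)) stop("every group needs at least 2 samples; too small: ",
                          names(tab)[tab < 2L][1L])
  d2 <- dk^2
  f_obs <- permanova_F(d2, groups)
  ge <- with_seed(seed, {
    sum(vapply(seq_len(permutations), function(i) {
      permanova_F(d2, sample(groups)) >= f_obs - 1e-12
    }, TRUE))
  })
  list(pseudo_F = f_obs, p = (ge + 1) / (permutations + 1),
       n_dropped = sum(!keep))
}

anosim_R <- function(rk, within) {
  m <- length(within)
  rb <- mean(rk[!within]); rw <- mean(rk[within])
  (rb - rw) / (m / 2)
}

#' ANOSIM: analysis of similarities
#'
#' Ranks all pairwise distances (mid-ranks on ties) and compares mean
#' between-group to mean within-group rank:
#' `R = (mean_rank_between - mean_rank_within) / (M/2)`, `M = N(N-1)/2`.
#' Permutation p as in [permanova()].
#'
#' @inheritParams permanova
#' @return list(R, p, n_dropped).
#' @export
anosim <- function(d, variable, permutations = 999L, seed = 1L) {
  d <- as.matrix(d)
  keep <- !is.na(variable)
  groups <- as.character(variable[keep])
  dk <- d[keep, keep, drop = FALSE]
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L)) stop("every group needs at least 2 samples")
  n <- length(groups)
  ut <- upper.tri(dk)
  rk <- rank(dk[ut])
  pair_i <- row(dk)[ut]; pair_j <- col(dk)[ut]
  within_for <- function(g) g[pair_i] == g[pair_j]
  r_obs <- anosim_R(rk, within_for(groups))
  ge <- with_seed(seed, {
    sum(vapply(seq_len(permutations), function(i) {
      anosim_R(rk, within_for(sample(groups))) >= r_obs - 1e-12
    }, TRUE))
  })
  list(R = r_obs, p = (ge + 1) / (permutations + 1), n_dropped = sum(!keep))
}

#' Distance regression on a numeric variable (Mantel-style)
#'
#' OLS of pairwise distance `d_ij` on `|x_i - x_j|` over all sample pairs;
#' significance by permuting the sample labels of `x`, recomputing `r2`, and
#' counting permuted values at or above the observed (`(b+1)/(m+1)`).
#'
#' @param d Symmetric distance matrix.
#' @param variable Numeric variable aligned with rows of `d`.
#' @param permutations Number of permutations.
#' @param seed RNG seed.
#' @return list(slope, r2, p, n_dropped).
#' @export
distance_numeric_regression <- function(d, variable, permutations = 999L,
                                        seed = 1L) {
  d <- as.matrix(d)
  keep <- !is.na(variable)
  x <- as.numeric(variable[keep])
  dk <- d[keep, keep, drop = FALSE]
  if (length(x) < 3L) stop("insufficient pairs: need at least 3 samples")
  if (stats::sd(x) == 0) stop("zero variance in numeric variable")
  ut <- upper.tri(dk)
  dv <- dk[ut]
  pair_i <- row(dk)[ut]; pair_j <- col(dk)[ut]
  r2_of <- function(xx) {
    dx <- abs(xx[pair_i] - xx[pair_j])
    if (stats::sd(dx) == 0 || stats::sd(dv) == 0) return(0)
    stats::cor(dx, dv)^2
  }
  dx <- abs(x[pair_i] - x[pair_j])
  slope <- if (stats::sd(dx) == 0) 0 else
    stats::cov(dx, dv) / stats::var(dx)
  r2_obs <- r2_of(x)
  ge <- with_seed(seed, {
    sum(vapply(seq_len(permutations), function(i) {
      r2_of(sample(x)) >= r2_obs - 1e-12
    }, TRUE))
  })
  list(slope = slope, r2 = r2_obs, p = (ge + 1) / (permutations + 1),
       n_dropped = sum(!keep))
}
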