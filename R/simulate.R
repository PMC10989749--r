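# Deterministic generators for every fixture the pipeline consumes:
# a reference pack, group-structured cohorts with planted effect taxa,
# and error-bearing reads. Everything is seeded; no downloads.

mutate_seq <- function(seq, p) {
  if (p <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < p)
  if (length(hit)) {
    alts <- c("A", "C", "G", "T")
    for (i in hit) {
      chars[i] <- sample(setdiff(alts, chars[i]), 1L)
    }
  }
  paste(chars, collapse = "")
}

#' Simulate a reference pack
#'
#' Builds a rooted bifurcating tree by successive random pair joins with
#' branch lengths ~ Exponential(mean 0.1); 7-rank taxonomy labels derived
#' from each leaf's root-to-leaf ancestor path (nested by construction); 16S
#' copy numbers ~ uniform integers 1-10; KO content of 30 KOs over a 2/4/8
#' three-level pathway hierarchy with gene counts ~ Poisson(2); distances to
#' the nearest sequenced relative ~ Exponential(mean 0.03); and length-200
#' representative sequences evolved from a random root sequence with per-base
#' substitution probability proportional to branch length.
#'
#' @param n_taxa Number of reference leaves (>= 2).
#' @param seed RNG seed; the pack is fully determined by it.
#' @return A `reference_pack` including representative sequences.
#' @export
simulate_reference_pack <- function(n_taxa, seed = 1L) {
  if (n_taxa < 2L) stop("need at least 2 taxa")
  with_seed(seed, {
    leaves <- sprintf("L%02d", seq_len(n_taxa))
    # successive random pair joins
    clust <- as.list(leaves)
    while (length(clust) > 1L) {
      pick <- sample(length(clust), 2L)
      bl <- stats::rexp(2L, rate = 10)  # mean 0.1
      joined <- sprintf("(%s:%.6f,%s:%.6f)",
                        clust[[pick[1L]]], bl[1L], clust[[pick[2L]]], bl[2L])
      clust[pick] <- NULL
      clust[[length(clust) + 1L]] <- joined
    }
    tree <- ape::read.tree(text = paste0(clust[[1L]], ";"))

    # taxonomy from ancestor paths: rank r (phylum..genus) labels the
    # ancestor at fraction (r-1)/6 of the leaf's path depth
    ntip <- length(tree$tip.label)
    parent_of <- rep(NA_integer_, ntip + tree$Nnode)
    parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
    prefix <- c("k", "p", "c", "o", "f", "g", "s")
    taxonomy <- vapply(seq_len(ntip), function(tip) {
      path <- integer(0)
      nd <- parent_of[tip]
      while (!is.na(nd)) {
        path <- c(nd, path)  # root first
        nd <- parent_of[nd]
      }
      L <- length(path)
      ranks <- vapply(2:6, function(r) {
        pos <- max(1L, min(L, ceiling((r - 1) / 6 * L)))
        sprintf("%s__N%d", prefix[r], path[pos])
      }, "")
      paste(c("k__Bacteria", ranks,
              sprintf("s__%s", tree$tip.label[tip])), collapse = ";")
    }, "")
    names(taxonomy) <- tree$tip.label

    copy_number <- stats::setNames(
      as.numeric(sample(1:10, ntip, replace = TRUE)), tree$tip.label)

    kos <- sprintf("K%05d", seq_len(30L))
    l1 <- sprintf("L1_%s", LETTERS[1:2])
    l2 <- sprintf("L2_%s", LETTERS[1:4])
    l3 <- sprintf("L3_%s", LETTERS[1:8])
    hier <- data.frame(
      ko = kos,
      L1 = l1[((seq_len(30L) - 1L) %% 8L) %/% 4L + 1L],
      L2 = l2[((seq_len(30L) - 1L) %% 8L) %/% 2L + 1L],
      L3 = l3[(seq_len(30L) - 1L) %% 8L + 1L],
      stringsAsFactors = FALSE)
    ko_content <- matrix(stats::rpois(ntip * 30L, 2), nrow = ntip,
                         dimnames = list(tree$tip.label, kos))

    nsti <- stats::setNames(stats::rexp(ntip, rate = 1 / 0.03),
                            tree$tip.label)

    # representative sequences evolved down the tree
    root_seq <- paste(sample(c("A", "C", "G", "T"), 200L, replace = TRUE),
                      collapse = "")
    nnode <- ntip + tree$Nnode
    seqs <- character(nnode)
    seqs[ntip + 1L] <- root_seq
    pre <- ape::reorder.phylo(tree, "cladewise")  # parents before children
    for (k in seq_len(nrow(pre$edge))) {
      child <- pre$edge[k, 2L]
      par <- pre$edge[k, 1L]
      seqs[child] <- mutate_seq(seqs[par], min(0.3, pre$edge.length[k]))
    }
    ref_seqs <- stats::setNames(seqs[seq_len(ntip)], tree$tip.label)

    pack <- list(tree = tree, leaf_ids = tree$tip.label, taxonomy = taxonomy,
                 copy_number = copy_number, ko_content = ko_content,
                 hierarchy = hier, nsti_distance = nsti, ref_seqs = ref_seqs)
    class(pack) <- "reference_pack"
    pack
  })
}

#' Simulate a two-group cohort with planted effect taxa
#'
#' Dirichlet-multinomial cohort model: each sample's taxon proportions are
#' drawn from a symmetric Dirichlet(0.5) (realistically sparse and
#' overdispersed, so between-sample biological variation dominates counting
#' noise), and counts follow a Multinomial with `reads_per_sample` draws.
#' In group B the effect taxa's Dirichlet weights are multiplied by their
#' fold changes (the proportions renormalize by construction), shifting
#' those taxa's expected abundance while leaving the rest exchangeable up to
#' compositional closure. The metadata carries the group column plus one
#' numeric covariate, Normal(50, 10), independent of the communities so that
#' numeric-association null behaviour is testable.
#'
#' @param pack A `reference_pack`.
#' @param n_samples_per_group Samples per group (groups "A" and "B").
#' @param group_effects Named numeric vector: taxon id -> fold change (> 0)
#'   applied in group B. `NULL` for a null (exchangeable) cohort.
#' @param reads_per_sample Multinomial depth per sample.
#' @param seed RNG seed.
#' @return list(counts = samples x taxa count matrix, metadata = data.frame
#'   with `group` (discrete) and `covariate` (numeric), truth = list with
#'   the per-group Dirichlet weights, expected proportions and the effect
#'   vector). All-zero tables (depth 0) carry attribute `empty = TRUE`.
#' @export
simulate_cohort <- function(pack, n_samples_per_group = 30L,
                            group_effects = NULL, reads_per_sample = 10000L,
                            seed = 1L) {
  if (!is.null(group_effects)) {
    bad <- setdiff(names(group_effects), pack$leaf_ids)
    if (length(bad)) stop("effect taxon not in pack: ", bad[1L])
    if (any(group_effects <= 0)) stop("fold changes must be positive")
  }
  with_seed(seed, {
    ntax <- length(pack$leaf_ids)
    alpha_a <- stats::setNames(rep(0.5, ntax), pack$leaf_ids)
    alpha_b <- alpha_a
    if (!is.null(group_effects)) {
      alpha_b[names(group_effects)] <-
        alpha_b[names(group_effects)] * group_effects
    }
    n <- 2L * n_samples_per_group
    ids <- sprintf("S%03d", seq_len(n))
    group <- rep(c("A", "B"), each = n_samples_per_group)
    counts <- matrix(0, nrow = n, ncol = ntax,
                     dimnames = list(ids, pack$leaf_ids))
    if (reads_per_sample > 0) {
      for (i in seq_len(n)) {
        a <- if (group[i] == "A") alpha_a else alpha_b
        p <- stats::rgamma(ntax, shape = a)
        p <- p / sum(p)
        counts[i, ] <- stats::rmultinom(1L, reads_per_sample, p)
      }
    } else {
      attr(counts, "empty") <- TRUE
    }
    attr(counts, "unit") <- "counts"
    meta <- data.frame(row.names = ids,
                       group = group,
                       covariate = stats::rnorm(n, 50, 10),
                       stringsAsFactors = FALSE)
    attr(meta, "kinds") <- c(group = "discrete", covariate = "numeric")
    list(counts = counts, metadata = meta,
         truth = list(alpha_a = alpha_a, alpha_b = alpha_b,
                      mean_a = alpha_a / sum(alpha_a),
                      mean_b = alpha_b / sum(alpha_b),
                      effects = group_effects))
  })
}

#' Simulate error-bearing reads and write a ready-to-run input directory
#'
#' Each read is its source taxon's representative sequence with i.i.d.
#' substitutions at `error_rate`. Per-sample FASTA files, the `seqs.list`
#' manifest and `meta.txt` metadata are written in the exact dialects the
#' readers expect, so the directory can be fed straight to [run_pipeline()].
#'
#' @param true_counts Samples x taxa count matrix ([simulate_cohort()]).
#' @param pack A `reference_pack` with representative sequences.
#' @param error_rate Per-base substitution probability.
#' @param seed RNG seed.
#' @param dir Output directory.
#' @param metadata Optional metadata data.frame (rownames = sample ids) to
#'   write as `meta.txt`.
#' @return list(manifest, metadata, truth) invisibly; `truth` is a
#'   data.frame(read_id, sample_id, leaf) giving each read's source taxon.
#' @export
simulate_reads <- function(true_counts, pack, error_rate = 0.005, seed = 1L,
                           dir = tempfile("cohort"), metadata = NULL) {
  if (is.null(pack$ref_seqs)) stop("pack has no representative sequences")
  dir.create(file.path(dir, "samples"), recursive = TRUE, showWarnings = FALSE)
  truth <- list()
  with_seed(seed, {
    for (s in rownames(true_counts)) {
      cnt <- round(true_counts[s, ])
      cnt <- cnt[cnt > 0]
      lines <- character(0)
      rid <- 0L
      rows <- list()
      for (leaf in names(cnt)) {
        for (j in seq_len(cnt[[leaf]])) {
          rid <- rid + 1L
          id <- sprintf("%s_r%04d", s, rid)
          lines <- c(lines, paste0(">", id),
                     mutate_seq(pack$ref_seqs[[leaf]], error_rate))
          rows[[length(rows) + 1L]] <- data.frame(
            read_id = id, sample_id = s, leaf = leaf,
            stringsAsFactors = FALSE)
        }
      }
      if (!length(lines)) {
        lines <- character(0)
      }
      writeLines(lines, file.path(dir, "samples", paste0(s, ".fa")))
      if (length(rows)) truth[[s]] <- do.call(rbind, rows)
    }
  })
  manifest_path <- file.path(dir, "seqs.list")
  writeLines(paste(rownames(true_counts),
                   file.path("samples", paste0(rownames(true_counts), ".fa")),
                   sep = "\t"),
             manifest_path)
  meta_path <- file.path(dir, "meta.txt")
  if (!is.null(metadata)) {
    hdr <- paste(c("#SampleID", colnames(metadata)), collapse = "\t")
    body <- vapply(rownames(metadata), function(s) {
      paste(c(s, vapply(metadata[s, , drop = FALSE], as.character, "")),
            collapse = "\t")
    }, "")
    writeLines(c(hdr, body), meta_path)
  }
  invisible(list(manifest = manifest_path,
                 metadata = if (is.null(metadata)) NULL else meta_path,
                 truth = do.call(rbind, c(truth, list(make.row.names = FALSE)))))
}
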