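revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

kmer_counts <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(integer(0))
  kmers <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
  tab <- table(kmers)
  stats::setNames(as.integer(tab), names(tab))
}

#' Build a k-mer index over reference sequences
#'
#' Precomputes the k-mer count matrix and vector norms for the pack's
#' representative sequences so per-read scoring is a single matrix product.
#'
#' @param pack A `reference_pack` carrying representative sequences.
#' @param k K-mer length.
#' @return An object of class `kmer_index`.
#' @export
build_kmer_index <- function(pack, k = 8L) {
  if (is.null(pack$ref_seqs)) {
    stop("reference pack has no representative sequences (refs.fasta)")
  }
  counts <- lapply(pack$ref_seqs, kmer_counts, k = k)
  kmers <- sort(unique(unlist(lapply(counts, names), use.names = FALSE)))
  M <- matrix(0, nrow = length(kmers), ncol = length(counts),
              dimnames = list(kmers, names(counts)))
  for (j in seq_along(counts)) M[names(counts[[j]]), j] <- counts[[j]]
  structure(list(k = as.integer(k), M = M,
                 norms = sqrt(colSums(M^2)),
                 leaf_ids = names(counts)),
            class = "kmer_index")
}

score_strand <- function(index, seq) {
  rk <- kmer_counts(seq, index$k)
  if (!length(rk)) return(rep(0, ncol(index$M)))
  idx <- match(names(rk), rownames(index$M))
  ok <- !is.na(idx)
  if (!any(ok)) return(rep(0, ncol(index$M)))
  dots <- colSums(index$M[idx[ok], , drop = FALSE] * rk[ok])
  dots / (sqrt(sum(rk^2)) * index$norms)
}

# shared lineage prefix of a set of leaves; returns list(rank_index, label)
shared_rank <- function(pack, leaves) {
  lins <- lapply(pack$taxonomy[leaves], split_lineage)
  depth <- 0L
  for (r in seq_len(7L)) {
    labs <- vapply(lins, `[[`, "", r)
    if (length(unique(labs)) == 1L && nzchar(sub("^[kpcofgs]__", "", labs[1L]))) {
      depth <- r
    } else {
      break
    }
  }
  if (depth == 0L) list(rank = NA_integer_, label = "root")
  else list(rank = depth, label = lins[[1L]][depth])
}

#' Assign a read to its best-matching reference leaf
#'
#' Scores the read (both strands) against every representative sequence by
#' cosine similarity of k-mer count vectors and converts the best cosine to a
#' sequence-identity estimate (`1 - (1 - cosine)/k`, since one substitution
#' disturbs about k of the read's k-mers). The best leaf is returned when the
#' identity estimate reaches `min_identity`; exact ties are confined to the
#' lowest taxonomic rank shared by all tied leaves and later split equally.
#'
#' @param read One row of [read_fasta()] output, or a list with `id` and
#'   `sequence`.
#' @param pack A `reference_pack` with representative sequences.
#' @param min_identity Identity threshold below which the read is
#'   `UNCLASSIFIED` (default 0.97, the classical OTU radius).
#' @param k K-mer length (default 8).
#' @param index Optional prebuilt [build_kmer_index()] (must match `k`).
#' @return A data.frame row: `read_id`, `leaf_id` (comma-joined when tied, or
#'   `"UNCLASSIFIED"`), `identity`, `rank` (shared rank label for ties).
#' @export
assign_best_hit <- function(read, pack, min_identity = 0.97, k = 8L,
                            index = NULL) {
  if (is.null(index)) index <- build_kmer_index(pack, k)
  out <- function(leaf, ident, rank = NA_character_) {
    data.frame(read_id = read$id, leaf_id = leaf, identity = ident,
               rank = rank, stringsAsFactors = FALSE)
  }
  if (nchar(read$sequence) < index$k) {
    warning("read '", read$id, "' shorter than k=", index$k, "; unclassified")
    return(out("UNCLASSIFIED", 0))
  }
  cs <- pmax(score_strand(index, read$sequence),
             score_strand(index, revcomp(read$sequence)))
  ident <- pmax(0, 1 - (1 - cs) / index$k)
  best <- max(ident)
  if (best < min_identity) return(out("UNCLASSIFIED", best))
  tied <- index$leaf_ids[ident >= best - 1e-12]
  if (length(tied) == 1L) return(out(tied, best))
  sr <- shared_rank(pack, tied)
  out(paste(sort(tied), collapse = ","), best, sr$label)
}

#' Assign every read of a sample
#'
#' Vectorized driver around [assign_best_hit()] reusing one k-mer index.
#'
#' @param reads data.frame from [read_fasta()].
#' @inheritParams assign_best_hit
#' @return data.frame of assignments, one row per read.
#' @export
assign_reads <- function(reads, pack, min_identity = 0.97, k = 8L,
                         index = NULL) {
  if (is.null(index)) index <- build_kmer_index(pack, k)
  rows <- lapply(seq_len(nrow(reads)), function(i) {
    assign_best_hit(reads[i, ], pack, min_identity, k, index)
  })
  do.call(rbind, rows)
}

#' Read a precomputed read-to-leaf assignment TSV
#'
#' Import path for external aligners: `read_id<TAB>leaf_id<TAB>identity`.
#'
#' @param path Assignment TSV (no header).
#' @param pack Reference pack used to validate leaf ids.
#' @return Assignment data.frame as from [assign_reads()].
#' @export
read_assignments <- function(path, pack) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 3L) stop("assignment file must be read_id\tleaf_id\tidentity")
  colnames(tab) <- c("read_id", "leaf_id", "identity")
  leaves <- unlist(strsplit(tab$leaf_id[tab$leaf_id != "UNCLASSIFIED"], ",",
                            fixed = TRUE))
  bad <- setdiff(leaves, pack$leaf_ids)
  if (length(bad)) stop("unknown reference leaf in assignments: ", bad[1L])
  tab$identity <- as.numeric(tab$identity)
  tab$rank <- NA_character_
  tab
}

#' Build a per-sample taxonomic profile from read assignments
#'
#' Counts classified reads per leaf (ties contribute equal fractions) and
#' applies marker-gene copy-number correction: each leaf's count is divided by
#' its 16S copy number before normalization, so relative abundances reflect
#' organisms rather than gene copies.
#'
#' @param assignments Assignment data.frame ([assign_reads()]).
#' @param pack A `reference_pack`.
#' @param sample_id Sample label stored in the profile.
#' @return An object of class `taxonomic_profile` with `counts` (reals; ties
#'   may yield fractions) and `normalized` (copy-number-corrected relative
#'   abundances summing to 1), plus an `empty` flag.
#' @export
build_profile <- function(assignments, pack, sample_id = "sample") {
  counts <- stats::setNames(numeric(length(pack$leaf_ids)), pack$leaf_ids)
  cls <- assignments[assignments$leaf_id != "UNCLASSIFIED", , drop = FALSE]
  if (nrow(cls)) {
    for (i in seq_len(nrow(cls))) {
      leaves <- strsplit(cls$leaf_id[i], ",", fixed = TRUE)[[1L]]
      counts[leaves] <- counts[leaves] + 1 / length(leaves)
    }
  }
  total <- sum(counts)
  if (total == 0) {
    prof <- list(sample_id = sample_id, counts = counts,
                 normalized = counts, empty = TRUE)
  } else {
    w <- counts / pack$copy_number[names(counts)]
    prof <- list(sample_id = sample_id, counts = counts,
                 normalized = w / sum(w), empty = FALSE)
  }
  class(prof) <- "taxonomic_profile"
  prof
}

#' Construct a taxonomic profile directly from leaf counts
#'
#' Used when abundances come from a precomputed taxon-count table rather than
#' raw reads.
#'
#' @param counts Named numeric vector of per-leaf counts.
#' @param pack A `reference_pack`.
#' @param sample_id Sample label.
#' @return A `taxonomic_profile`.
#' @export
profile_from_counts <- function(counts, pack, sample_id = "sample") {
  bad <- setdiff(names(counts), pack$leaf_ids)
  if (length(bad)) stop("counts name unknown leaf: ", bad[1L])
  full <- stats::setNames(numeric(length(pack$leaf_ids)), pack$leaf_ids)
  full[names(counts)] <- counts
  df <- data.frame(read_id = character(0), leaf_id = character(0),
                   identity = numeric(0), rank = character(0))
  prof <- build_profile(df, pack, sample_id)
  prof$counts <- full
  if (sum(full) > 0) {
    w <- full / pack$copy_number[names(full)]
    prof$normalized <- w / sum(w)
    prof$empty <- FALSE
  }
  prof
}

#' Collapse leaf-level profiles to a taxonomy level
#'
#' Features are lineage prefixes truncated at `level`; abundances of leaves
#' sharing a prefix are summed. Leaves whose lineage is empty at `level`
#' (e.g. `g__`) are pooled into `Unclassified_<parent>` where parent is the
#' last named rank above.
#'
#' @param profiles List of `taxonomic_profile` objects.
#' @param pack A `reference_pack`.
#' @param level One of kingdom, phylum, class, order, family, genus, species.
#' @return Relative-abundance matrix (samples x taxa) with `unit` attribute.
#' @export
collapse_to_level <- function(profiles, pack, level = "genus") {
  li <- match(level, rank_names)
  if (is.na(li)) stop("unknown taxonomy level: ", level)
  lins <- lapply(pack$taxonomy, split_lineage)
  feat_of_leaf <- vapply(pack$leaf_ids, function(leaf) {
    lin <- lins[[leaf]]
    lab <- lin[li]
    if (!nzchar(sub("^[kpcofgs]__", "", lab))) {
      named <- lin[seq_len(li - 1L)]
      named <- named[nzchar(sub("^[kpcofgs]__", "", named))]
      parent <- if (length(named)) named[length(named)] else "root"
      paste0("Unclassified_", parent)
    } else {
      paste(lin[seq_len(li)], collapse = ";")
    }
  }, "")
  feats <- unique(feat_of_leaf)
  m <- matrix(0, nrow = length(profiles), ncol = length(feats),
              dimnames = list(vapply(profiles, `[[`, "", "sample_id"), feats))
  for (i in seq_along(profiles)) {
    v <- profiles[[i]]$normalized[pack$leaf_ids]
    m[i, ] <- vapply(feats, function(f) sum(v[feat_of_leaf == f]), 0)
  }
  attr(m, "unit") <- "relative"
  m
}

#' Leaf-level count table across samples
#'
#' Raw (uncorrected) classified-read counts, the input Chao1 expects.
#'
#' @param profiles List of `taxonomic_profile` objects.
#' @param pack A `reference_pack`.
#' @return Count matrix (samples x leaves) with `unit = "counts"`.
#' @export
profile_counts_table <- function(profiles, pack) {
  m <- do.call(rbind, lapply(profiles, function(p) p$counts[pack$leaf_ids]))
  rownames(m) <- vapply(profiles, `[[`, "", "sample_id")
  colnames(m) <- pack$leaf_ids
  attr(m, "unit") <- "counts"
  m
}

#' Leaf-level relative abundance table across samples
#'
#' Copy-number-corrected relative abundances, row per sample.
#'
#' @inheritParams profile_counts_table
#' @return Relative matrix (samples x leaves).
#' @export
profile_abundance_table <- function(profiles, pack) {
  m <- do.call(rbind, lapply(profiles, function(p) p$normalized[pack$leaf_ids]))
  rownames(m) <- vapply(profiles, `[[`, "", "sample_id")
  colnames(m) <- pack$leaf_ids
  attr(m, "unit") <- "relative"
  m
}
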