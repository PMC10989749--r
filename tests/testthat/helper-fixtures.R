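# Hand-built fixtures shared across test files. Everything is constructed in
# code; nothing is read from disk except through the package's own writers.

# Four-leaf pack with controlled taxonomy (D has an empty genus), copy
# numbers chosen so the copy-number-correction examples come out to round
# values, and a hierarchy containing one dual-path KO (K4).
tiny_pack <- function() {
  tree <- ape::read.tree(text = "((A:0.1,B:0.2):0.1,(C:0.3,D:0.1):0.2);")
  pack <- list(
    tree = tree,
    leaf_ids = tree$tip.label,
    taxonomy = c(
      A = "k__Bacteria;p__P1;c__C1;o__O1;f__F1;g__G1;s__A",
      B = "k__Bacteria;p__P1;c__C1;o__O1;f__F1;g__G1;s__B",
      C = "k__Bacteria;p__P2;c__C2;o__O2;f__F2;g__G2;s__C",
      D = "k__Bacteria;p__P2;c__C2;o__O2;f__F2;g__;s__D")[tree$tip.label],
    copy_number = c(A = 1, B = 4, C = 2, D = 1)[tree$tip.label],
    ko_content = matrix(
      c(2, 0, 1, 0,
        1, 3, 0, 0,
        0, 0, 2, 1,
        0, 1, 0, 2),
      nrow = 4, byrow = TRUE,
      dimnames = list(c("A", "B", "C", "D"), paste0("K", 1:4)))[tree$tip.label, ],
    hierarchy = data.frame(
      ko = c("K1", "K2", "K3", "K4", "K4"),
      L1 = c("M", "M", "G", "M", "G"),
      L2 = c("M1", "M1", "G1", "M2", "G1"),
      L3 = c("m_a", "m_b", "g_a", "m_c", "g_b"),
      stringsAsFactors = FALSE),
    nsti_distance = c(A = 0.02, B = 0.04, C = 0.07, D = 0)[tree$tip.label],
    ref_seqs = NULL)
  class(pack) <- "reference_pack"
  pack
}

# a taxonomic_profile from named leaf counts against a pack
profile_of <- function(pack, counts, id = "sample") {
  ampliflow::profile_from_counts(counts, pack, id)
}

# a functional_profile from named KO relative abundances
fprofile_of <- function(ko, id = "sample") {
  fp <- list(sample_id = id, ko_abundance = ko, nsti = NA_real_)
  class(fp) <- "functional_profile"
  fp
}

# random relative-abundance profiles over a pack (fixed seed upstream)
random_profiles <- function(pack, n, sparsity = 0.5) {
  lapply(seq_len(n), function(i) {
    a <- stats::rexp(length(pack$leaf_ids))
    a[stats::runif(length(a)) < sparsity] <- 0
    if (sum(a) == 0) a[1] <- 1
    counts <- stats::setNames(round(a / sum(a) * 1000), pack$leaf_ids)
    if (sum(counts) == 0) counts[1] <- 1
    profile_of(pack, counts, sprintf("R%03d", i))
  })
}

# write a minimal FASTA from named sequences
write_fasta_tmp <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

# a network object from an explicit edge list (for graph-statistic tests)
net_of <- function(nodes, edges) {
  ed <- if (length(edges)) {
    data.frame(u = vapply(edges, `[[`, "", 1L),
               v = vapply(edges, `[[`, "", 2L),
               rho = 1, q = 0, stringsAsFactors = FALSE)
  } else {
    data.frame(u = character(0), v = character(0), rho = numeric(0),
               q = numeric(0))
  }
  structure(list(nodes = nodes, edges = ed), class = "cooccurrence_network")
}

# independent all-pairs BFS oracle for eccentricities (adjacency matrix)
bfs_ecc_oracle <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(adj[u, ] > 0)) {
          if (d[v] > d[u] + 1) { d[v] <- d[u] + 1; nxt <- c(nxt, v) }
        }
      }
      frontier <- unique(nxt)
    }
    dist[s, ] <- d
  }
  dist
}

# tiny ready-to-run demo inputs: returns list(manifest, metadata, refpack)
demo_inputs <- function(n_per_group = 4, reads = 40, n_taxa = 8, seed = 11,
                        effects = c(L01 = 6), error_rate = 0.005) {
  pack <- ampliflow::simulate_reference_pack(n_taxa, seed = seed)
  pdir <- tempfile("pack")
  ampliflow::write_reference_pack(pack, pdir)
  coh <- ampliflow::simulate_cohort(pack, n_samples_per_group = n_per_group,
                                    group_effects = effects,
                                    reads_per_sample = reads, seed = seed + 1)
  res <- ampliflow::simulate_reads(coh$counts, pack, error_rate = error_rate,
                                   seed = seed + 2, dir = tempfile("in"),
                                   metadata = coh$metadata)
  list(manifest = res$manifest, metadata = res$metadata, refpack = pdir,
       pack = pack, truth = res$truth, cohort = coh)
}
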