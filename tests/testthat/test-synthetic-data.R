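test_that("the generator is deterministic under its seed and seed-sensitive", {
  p1 <- simulate_reference_pack(10, seed = 51)
  p2 <- simulate_reference_pack(10, seed = 51)
  p3 <- simulate_reference_pack(10, seed = 52)
  expect_identical(p1, p2)
  expect_false(identical(p1$ref_seqs, p3$ref_seqs))
})

test_that("a two-taxon pack is minimal but valid for every reader", {
  pack <- simulate_reference_pack(2, seed = 53)
  expect_equal(length(pack$leaf_ids), 2L)
  expect_equal(pack$tree$Nnode, 1L)
  dir <- tempfile()
  write_reference_pack(pack, dir)
  expect_s3_class(read_reference_pack(dir), "reference_pack")
})

test_that("generated packs satisfy the reference-pack invariants", {
  pack <- simulate_reference_pack(12, seed = 54)
  expect_true(all(pack$copy_number >= 1 & pack$copy_number <= 10))
  expect_true(all(pack$nsti_distance >= 0))
  expect_true(all(pack$ko_content >= 0))
  expect_true(all(nchar(pack$ref_seqs) == 200))
  lin <- strsplit(pack$taxonomy, ";")
  expect_true(all(lengths(lin) == 7))
  # ranks are nested: equal genus implies equal family
  gs <- vapply(lin, `[[`, "", 6); fs <- vapply(lin, `[[`, "", 5)
  for (g in unique(gs)) expect_equal(length(unique(fs[gs == g])), 1L)
})

test_that("sister leaves diverge less than distant leaves on average", {
  hamming <- function(a, b) {
    mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  diffs <- vapply(1:20, function(s) {
    pack <- simulate_reference_pack(8, seed = 100 + s)
    d <- ape::cophenetic.phylo(pack$tree)
    pairs <- utils::combn(rownames(d), 2)
    seqd <- apply(pairs, 2, function(pr) {
      hamming(pack$ref_seqs[[pr[1]]], pack$ref_seqs[[pr[2]]])
    })
    treed <- apply(pairs, 2, function(pr) d[pr[1], pr[2]])
    close_ <- treed <= stats::median(treed)
    mean(seqd[!close_]) - mean(seqd[close_])
  }, 0)
  expect_gt(mean(diffs), 0)
})

test_that("null cohorts are exchangeable and planted effects are visible", {
  pack <- simulate_reference_pack(16, seed = 55)
  coh0 <- simulate_cohort(pack, n_samples_per_group = 10,
                          reads_per_sample = 2000, seed = 56)
  expect_equal(dim(coh0$counts), c(20L, 16L))
  expect_true(all(rowSums(coh0$counts) == 2000))
  # same baseline for both groups when no effect is planted
  expect_equal(coh0$truth$baseline, coh0$truth$group_b)

  eff <- stats::setNames(rep(8, 2), pack$leaf_ids[1:2])
  coh1 <- simulate_cohort(pack, n_samples_per_group = 10,
                          group_effects = eff, reads_per_sample = 2000,
                          seed = 56)
  gb <- coh1$metadata$group == "B"
  for (tx in names(eff)) {
    expect_gt(mean(coh1$counts[gb, tx]), mean(coh1$counts[!gb, tx]))
  }
  expect_error(simulate_cohort(pack, group_effects = c(ZZZ = 2)), "ZZZ")
  expect_error(simulate_cohort(pack, group_effects = stats::setNames(-1, pack$leaf_ids[1])),
               "positive")
})

test_that("zero sequencing depth yields a flagged all-zero table", {
  pack <- simulate_reference_pack(4, seed = 57)
  coh <- simulate_cohort(pack, n_samples_per_group = 2, reads_per_sample = 0,
                         seed = 58)
  expect_true(all(coh$counts == 0))
  expect_true(attr(coh$counts, "empty"))
})

test_that("error-free reads are recovered perfectly end to end", {
  pack <- simulate_reference_pack(8, seed = 59)
  coh <- simulate_cohort(pack, n_samples_per_group = 2, reads_per_sample = 30,
                         seed = 60)
  res <- simulate_reads(coh$counts, pack, error_rate = 0, seed = 61,
                        dir = tempfile(), metadata = coh$metadata)
  mf <- read_manifest(res$manifest)
  expect_equal(mf$sample_id, rownames(coh$counts))
  meta <- read_metadata(res$metadata, mf)
  expect_equal(metadata_kinds(meta),
               c(group = "discrete", covariate = "numeric"))
  idx <- build_kmer_index(pack)
  asn <- assign_reads(read_fasta(mf$fasta_path[1]), pack, index = idx)
  truth <- res$truth[res$truth$sample_id == mf$sample_id[1], ]
  expect_equal(asn$leaf_id[match(truth$read_id, asn$read_id)], truth$leaf)
})

test_that("the generated files satisfy the readers' invariants untouched", {
  pack <- simulate_reference_pack(6, seed = 62)
  coh <- simulate_cohort(pack, n_samples_per_group = 3, reads_per_sample = 25,
                         seed = 63)
  res <- simulate_reads(coh$counts, pack, error_rate = 0.01, seed = 64,
                        dir = tempfile(), metadata = coh$metadata)
  mf <- read_manifest(res$manifest)
  for (f in mf$fasta_path) {
    fa <- read_fasta(f)
    expect_false(any(duplicated(fa$id)))
    expect_true(all(grepl("^[ACGTN]+$", fa$sequence)))
  }
})
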