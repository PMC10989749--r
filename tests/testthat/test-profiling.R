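make_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("a read identical to a representative maps to it with identity 1", {
  pack <- simulate_reference_pack(8, seed = 2)
  idx <- build_kmer_index(pack)
  a <- assign_best_hit(list(id = "r", sequence = pack$ref_seqs[["L04"]]),
                       pack, index = idx)
  expect_equal(a$leaf_id, "L04")
  expect_equal(a$identity, 1)
})

test_that("reads matching nothing above the threshold are UNCLASSIFIED", {
  pack <- simulate_reference_pack(4, seed = 2)
  alien <- make_seq(200, seed = 99)
  a <- assign_best_hit(list(id = "r", sequence = alien), pack)
  expect_equal(a$leaf_id, "UNCLASSIFIED")
  expect_lt(a$identity, 0.97)
})

test_that("reads shorter than k are unclassified with a warning, identity 0", {
  pack <- simulate_reference_pack(4, seed = 2)
  idx <- build_kmer_index(pack)
  expect_warning(
    a <- assign_best_hit(list(id = "r", sequence = "ACGT"), pack, index = idx),
    "shorter")
  expect_equal(a$leaf_id, "UNCLASSIFIED")
  expect_equal(a$identity, 0)
})

test_that("the reverse complement strand is scored too", {
  pack <- simulate_reference_pack(8, seed = 2)
  idx <- build_kmer_index(pack)
  fwd <- pack$ref_seqs[["L02"]]
  rc <- ampliflow:::revcomp(fwd)
  a <- assign_best_hit(list(id = "r", sequence = rc), pack, index = idx)
  expect_equal(a$leaf_id, "L02")
  expect_equal(a$identity, 1)
})

test_that("ties between leaves sharing a genus split the count equally", {
  # two references identical in the read's window, different outside it
  core <- make_seq(100, seed = 7)
  tailA <- make_seq(20, seed = 8)
  tailB <- make_seq(20, seed = 9)
  pack <- tiny_pack()
  pack$ref_seqs <- c(A = paste0(core, tailA), B = paste0(core, tailB),
                     C = make_seq(120, seed = 10),
                     D = make_seq(120, seed = 11))
  a <- assign_best_hit(list(id = "r", sequence = core), pack)
  expect_equal(a$leaf_id, "A,B")
  expect_equal(a$rank, "g__G1")
  expect_gte(a$identity, 0.97)

  prof <- build_profile(a, pack, "s")
  expect_equal(unname(prof$counts[c("A", "B")]), c(0.5, 0.5))
})

test_that("copy-number correction divides counts by gene copies", {
  pack <- tiny_pack()  # copies A=1, B=4
  prof <- profile_of(pack, c(A = 100, B = 100))
  expect_equal(unname(prof$normalized[c("A", "B")]), c(0.8, 0.2))
  expect_equal(sum(prof$normalized), 1)

  single <- profile_of(pack, c(A = 50))
  expect_equal(unname(single$normalized["A"]), 1)
})

test_that("profiles with zero classified reads are flagged empty", {
  pack <- tiny_pack()
  asn <- data.frame(read_id = c("r1", "r2"),
                    leaf_id = c("UNCLASSIFIED", "UNCLASSIFIED"),
                    identity = c(0.5, 0.2), rank = NA_character_)
  prof <- build_profile(asn, pack, "s")
  expect_true(prof$empty)
  expect_equal(sum(prof$normalized), 0)
})

test_that("correction is scale-invariant and trivial at copy number 1", {
  pack <- tiny_pack()
  p1 <- profile_of(pack, c(A = 10, B = 20, C = 5))
  p2 <- profile_of(pack, c(A = 30, B = 60, C = 15))
  expect_equal(p1$normalized, p2$normalized)

  pack1 <- pack
  pack1$copy_number[] <- 1
  p3 <- profile_of(pack1, c(A = 10, B = 20, C = 5, D = 15))
  expect_equal(unname(p3$normalized), c(10, 20, 5, 15)[match(names(p3$normalized), c("A","B","C","D"))] / 50)
})

test_that("collapsing sums abundances at every level and preserves mass", {
  pack <- tiny_pack()
  profs <- list(profile_of(pack, c(A = 30, B = 20, C = 40, D = 10), "s1"))
  sp <- collapse_to_level(profs, pack, "species")
  for (lev in c("kingdom", "phylum", "class", "order", "family", "genus")) {
    tab <- collapse_to_level(profs, pack, lev)
    expect_equal(sum(tab), sum(sp), tolerance = 1e-12)
  }
  gen <- collapse_to_level(profs, pack, "genus")
  a <- profs[[1]]$normalized
  expect_equal(gen[1, "k__Bacteria;p__P1;c__C1;o__O1;f__F1;g__G1"],
               unname(a["A"] + a["B"]))
  king <- collapse_to_level(profs, pack, "kingdom")
  expect_equal(ncol(king), 1L)
  expect_equal(unname(king[1, 1]), 1)
})

test_that("leaves with an empty rank pool into Unclassified_<parent>", {
  pack <- tiny_pack()  # D has g__
  profs <- list(profile_of(pack, c(C = 50, D = 50), "s1"))
  gen <- collapse_to_level(profs, pack, "genus")
  expect_true("Unclassified_f__F2" %in% colnames(gen))
  expect_equal(unname(gen[1, "Unclassified_f__F2"]),
               unname(profs[[1]]$normalized["D"]))
})

test_that("precomputed assignment TSVs import and validate leaf ids", {
  pack <- tiny_pack()
  p <- tempfile()
  writeLines(c("r1\tA\t0.99", "r2\tUNCLASSIFIED\t0.5", "r3\tA,B\t0.98"), p)
  asn <- read_assignments(p, pack)
  expect_equal(nrow(asn), 3L)
  prof <- build_profile(asn, pack, "s")
  expect_equal(unname(prof$counts[c("A", "B")]), c(1.5, 0.5))

  writeLines("r1\tZZ\t0.99", p)
  expect_error(read_assignments(p, pack), "ZZ")
})
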