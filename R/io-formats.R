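#' Read a FASTA file of marker-gene reads
#'
#' Parses a (possibly multi-line) FASTA file into a data frame of sequence
#' records. Sequences are uppercased, `U` is mapped to `T` (RNA input), and
#' any character outside `A/C/G/T/N` is rejected with an informative error.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("no sequences in '", path, "'")
  # FASTA headers: id = first whitespace-delimited token
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("empty sequence id in '", path, "'")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id '", dup[1L], "' in '", path, "'")
  seqs <- chartr("u", "U", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    i <- which(bad)[1L]
    ch <- regmatches(seqs[i], regexpr("[^ACGTN]", seqs[i]))
    stop("invalid character '", ch, "' in sequence '", ids[i], "'")
  }
  if (any(nchar(seqs) < 1L)) {
    stop("empty sequence for id '", ids[which(nchar(seqs) < 1L)[1L]], "'")
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Read a sample manifest ("seqs.list")
#'
#' The manifest is a two-column TSV, one line per sample:
#' `sample_id<TAB>fasta_path`. Relative paths are resolved against the
#' directory containing the manifest. Lines starting with `#` are ignored.
#' The manifest order defines the sample order of every downstream table.
#'
#' @param path Path to the manifest file.
#' @param check_exists Verify that every referenced FASTA file exists.
#' @return A data.frame with columns `sample_id` and `fasta_path`.
#' @export
read_manifest <- function(path, check_exists = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(keep)) stop("manifest '", path, "' has no entries")
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 2L)) {
    bad <- keep[which(nfield < 2L)[1L]]
    stop("manifest parse error at line ", bad, ": expected 'sample_id<TAB>path'")
  }
  ids <- vapply(parts, `[[`, "", 1L)
  paths <- vapply(parts, `[[`, "", 2L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sample_id '", dup[1L], "' in manifest")
  base <- dirname(normalizePath(path, mustWork = TRUE))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", paths), paths, file.path(base, paths))
  if (check_exists) {
    miss <- !file.exists(abs)
    if (any(miss)) {
      stop("sequence file missing for sample '", ids[which(miss)[1L]],
           "': ", abs[which(miss)[1L]])
    }
  }
  data.frame(sample_id = ids, fasta_path = abs, stringsAsFactors = FALSE)
}

#' Read a sample metadata table ("meta.txt")
#'
#' Tab-separated with a header row; the first column holds sample ids (header
#' `#SampleID` is accepted). A column is typed numeric iff every non-missing
#' value parses as a finite real; otherwise it is discrete. Missing values are
#' empty cells or `NA`.
#'
#' @param path Path to the metadata TSV.
#' @param manifest Optional manifest data.frame; when given, every manifest
#'   sample must be present and rows are reordered to manifest order.
#' @return A data.frame with rownames = sample ids and an attribute
#'   `kinds` (named character vector, `"numeric"` or `"discrete"` per column).
#' @export
read_metadata <- function(path, manifest = NULL) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("metadata '", path, "' needs a header and data rows")
  split_row <- function(x) strsplit(x, "\t", fixed = TRUE)[[1L]]
  header <- split_row(lines[1L])
  ncol_ <- length(header)
  if (ncol_ < 2L) stop("metadata needs at least one variable column")
  rows <- lapply(lines[-1L], split_row)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) < ncol_) r <- c(r, rep("", ncol_ - length(r)))
    if (length(r) > ncol_) {
      stop("metadata parse error at line ", i + 1L, ": ", length(r),
           " fields, header has ", ncol_)
    }
    rows[[i]] <- r
  }
  mat <- do.call(rbind, rows)
  ids <- mat[, 1L]
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sample id '", dup[1L], "' in metadata")
  vars <- header[-1L]
  out <- data.frame(row.names = ids, check.names = FALSE,
                    stringsAsFactors = FALSE)
  kinds <- character(0)
  for (j in seq_along(vars)) {
    raw <- mat[, j + 1L]
    raw[raw %in% c("", "NA")] <- NA_character_
    num <- suppressWarnings(as.numeric(raw))
    ok <- is.na(raw) | (!is.na(num) & is.finite(num))
    if (all(ok) && any(!is.na(raw))) {
      out[[vars[j]]] <- num
      kinds[vars[j]] <- "numeric"
    } else {
      out[[vars[j]]] <- raw
      kinds[vars[j]] <- "discrete"
    }
  }
  if (!is.null(manifest)) {
    miss <- setdiff(manifest$sample_id, ids)
    if (length(miss)) {
      stop("samples missing from metadata: ", paste(miss, collapse = ", "))
    }
    out <- out[manifest$sample_id, , drop = FALSE]
  }
  attr(out, "kinds") <- kinds
  out
}

#' Variable kinds of a metadata table
#'
#' @param meta A metadata data.frame from [read_metadata()].
#' @return Named character vector (`"numeric"`/`"discrete"`).
#' @export
metadata_kinds <- function(meta) {
  k <- attr(meta, "kinds")
  if (is.null(k)) {
    k <- vapply(meta, function(col) if (is.numeric(col)) "numeric" else "discrete",
                "")
    names(k) <- colnames(meta)
  }
  k
}

rank_prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
rank_names <- c("kingdom", "phylum", "class", "order", "family", "genus",
                "species")

split_lineage <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1L]]
  trimws(parts)
}

#' Read a reference pack directory
#'
#' A reference pack bundles everything profiling and downstream prediction
#' need: `tree.nwk` (rooted Newick, non-negative branch lengths),
#' `taxonomy.tsv` (leaf, 7-rank lineage string), `copy_number.tsv` (leaf,
#' positive 16S copy number), `ko_content.tsv` (leaves x KO gene counts),
#' `hierarchy.tsv` (KO, Level1, Level2, Level3; a KO may have several rows =
#' several pathway paths), `nsti.tsv` (leaf, non-negative distance to nearest
#' sequenced relative) and optionally `refs.fasta` (representative sequences).
#'
#' @param dir Directory containing the pack files.
#' @return An object of class `reference_pack`.
#' @export
read_reference_pack <- function(dir) {
  need <- c("tree.nwk", "taxonomy.tsv", "copy_number.tsv", "ko_content.tsv",
            "hierarchy.tsv", "nsti.tsv")
  paths <- file.path(dir, need)
  miss <- need[!file.exists(paths)]
  if (length(miss)) stop("reference pack incomplete, missing: ",
                         paste(miss, collapse = ", "))
  tree <- ape::read.tree(file.path(dir, "tree.nwk"))
  if (is.null(tree)) stop("cannot parse tree.nwk")
  if (is.null(tree$edge.length)) stop("tree.nwk has no branch lengths")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("negative or missing branch length in tree.nwk")
  }
  leaves <- tree$tip.label

  read2 <- function(file, what) {
    tab <- utils::read.delim(file.path(dir, file), header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE)
    if (ncol(tab) < 2L) stop(file, ": expected at least 2 columns")
    tab
  }
  tax_tab <- read2("taxonomy.tsv")
  taxonomy <- stats::setNames(as.character(tax_tab[[2L]]),
                              as.character(tax_tab[[1L]]))
  cn_tab <- read2("copy_number.tsv")
  copy_number <- stats::setNames(as.numeric(cn_tab[[2L]]),
                                 as.character(cn_tab[[1L]]))
  nsti_tab <- read2("nsti.tsv")
  nsti <- stats::setNames(as.numeric(nsti_tab[[2L]]),
                          as.character(nsti_tab[[1L]]))
  ko_tab <- utils::read.delim(file.path(dir, "ko_content.tsv"), header = TRUE,
                              row.names = 1L, check.names = FALSE)
  ko_content <- as.matrix(ko_tab)
  hier <- utils::read.delim(file.path(dir, "hierarchy.tsv"), header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(hier) != 4L) stop("hierarchy.tsv: expected columns KO, L1, L2, L3")
  colnames(hier) <- c("ko", "L1", "L2", "L3")

  for (leaf in leaves) {
    if (is.na(taxonomy[leaf])) stop("leaf without taxonomy: ", leaf)
    if (is.na(copy_number[leaf])) stop("leaf without copy number: ", leaf)
    if (!leaf %in% rownames(ko_content)) stop("leaf without KO content row: ", leaf)
    if (is.na(nsti[leaf])) stop("leaf without NSTI distance: ", leaf)
  }
  if (any(copy_number[leaves] <= 0)) {
    stop("non-positive copy number for leaf: ",
         leaves[which(copy_number[leaves] <= 0)[1L]])
  }
  if (any(nsti[leaves] < 0)) stop("negative NSTI distance")
  if (any(ko_content < 0)) stop("negative KO gene count")
  nranks <- vapply(taxonomy[leaves], function(x) length(split_lineage(x)), 0L)
  if (any(nranks != 7L)) {
    stop("taxonomy for leaf '", leaves[which(nranks != 7L)[1L]],
         "' does not have 7 semicolon-separated ranks")
  }

  ref_seqs <- NULL
  fp <- file.path(dir, "refs.fasta")
  if (file.exists(fp)) {
    fa <- read_fasta(fp)
    ref_seqs <- stats::setNames(fa$sequence, fa$id)
    miss <- setdiff(leaves, names(ref_seqs))
    if (length(miss)) stop("leaf without representative sequence: ", miss[1L])
  }

  pack <- list(tree = tree, leaf_ids = leaves,
               taxonomy = taxonomy[leaves],
               copy_number = copy_number[leaves],
               ko_content = ko_content[leaves, , drop = FALSE],
               hierarchy = hier,
               nsti_distance = nsti[leaves],
               ref_seqs = ref_seqs)
  class(pack) <- "reference_pack"
  pack
}

#' @export
print.reference_pack <- function(x, ...) {
  cat("Reference pack:", length(x$leaf_ids), "leaves,",
      ncol(x$ko_content), "KOs,",
      length(unique(x$hierarchy$L3)), "L3 pathway labels",
      if (is.null(x$ref_seqs)) "(no representative sequences)" else "", "\n")
  invisible(x)
}

#' Write a reference pack to a directory
#'
#' Inverse of [read_reference_pack()]; used by the synthetic-data generator.
#'
#' @param pack A `reference_pack`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_reference_pack <- function(pack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(pack$tree, file.path(dir, "tree.nwk"))
  w <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  w(data.frame(leaf = names(pack$taxonomy), taxonomy = pack$taxonomy),
    "taxonomy.tsv")
  w(data.frame(leaf = names(pack$copy_number),
               copy_number = fmt_real(pack$copy_number)), "copy_number.tsv")
  w(data.frame(leaf = names(pack$nsti_distance),
               nsti = fmt_real(pack$nsti_distance)), "nsti.tsv")
  ko <- data.frame(leaf = rownames(pack$ko_content), pack$ko_content,
                   check.names = FALSE)
  w(ko, "ko_content.tsv")
  w(stats::setNames(pack$hierarchy, c("KO", "L1", "L2", "L3")), "hierarchy.tsv")
  if (!is.null(pack$ref_seqs)) {
    writeLines(paste0(">", names(pack$ref_seqs), "\n", pack$ref_seqs),
               file.path(dir, "refs.fasta"))
  }
  invisible(dir)
}

# 8 significant digits: per-entry round-trip error <= 5e-9, so even a
# 100-feature relative row still re-sums to 1 within 1e-6 after re-reading
fmt_real <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == floor(v) && abs(v) < 1e15) return(format(v, scientific = FALSE))
    format(signif(v, 8L), scientific = FALSE, trim = TRUE)
  }, "")
  out
}

#' Write an abundance table or distance matrix as TSV
#'
#' Rows are samples (first column header names the id column), columns are
#' features or samples. Reals are written with eight significant digits so a
#' write/read round trip agrees to `1e-6` per value and relative rows still
#' re-sum to 1 within `1e-6`.
#'
#' @param table A numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Header for the row-name column.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, id_col = "#SampleID") {
  table <- as.matrix(table)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(table)), collapse = "\t"), con)
  if (nrow(table)) {
    body <- apply(table, 1L, function(r) paste(fmt_real(r), collapse = "\t"))
    writeLines(paste(rownames(table), body, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path Input path.
#' @param unit For abundance tables: `"counts"`, `"relative"`, or `"auto"`
#'   (rows summing to 1 within 1e-6 are tagged relative).
#' @param nonneg Reject negative entries (abundances and distances are
#'   non-negative; ordination coordinates are not).
#' @return Numeric matrix with a `unit` attribute.
#' @export
read_table <- function(path, unit = "auto", nonneg = TRUE) {
  if (!file.exists(path)) stop("table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, row.names = 1L,
                           check.names = FALSE, comment.char = "")
  m <- as.matrix(tab)
  if (nrow(m) && !is.numeric(m)) stop("non-numeric values in table '", path, "'")
  if (nonneg && length(m) && any(!is.na(m) & m < 0)) {
    stop("negative entry in table '", path, "'")
  }
  storage.mode(m) <- "double"
  if (unit == "auto") {
    rs <- if (nrow(m)) rowSums(m) else numeric(0)
    unit <- if (nrow(m) && all(abs(rs - 1) < 1e-6 | rs == 0)) "relative" else "counts"
  }
  attr(m, "unit") <- unit
  m
}

#' Read a distance matrix TSV
#'
#' Validates symmetry, zero diagonal and non-negativity.
#'
#' @param path Input path.
#' @return Symmetric numeric matrix.
#' @export
read_distance_matrix <- function(path) {
  m <- read_table(path, unit = "counts")
  attr(m, "unit") <- NULL
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop("distance matrix '", path, "' is not square with matching labels")
  }
  if (any(abs(m - t(m)) > 1e-8)) stop("distance matrix not symmetric")
  if (any(abs(diag(m)) > 1e-8)) stop("distance matrix has non-zero diagonal")
  (m + t(m)) / 2
}
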