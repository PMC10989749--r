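#' Predict a KO-level functional profile from a taxonomic profile
#'
#' Weights each reference taxon by its copy-number-corrected abundance
#' `w_i = counts_i / copy_number_i` and sums KO gene counts across taxa:
#' `raw_k = sum_i w_i * ko_content[i, k]`, then normalizes to relative
#' abundance. The Nearest Sequenced Taxon Index of the sample is attached as
#' a prediction-reliability score.
#'
#' @param profile A `taxonomic_profile`.
#' @param pack A `reference_pack`.
#' @return An object of class `functional_profile` with `ko_abundance`
#'   (relative, sums to 1) and `nsti`.
#' @export
predict_ko <- function(profile, pack) {
  if (isTRUE(profile$empty)) {
    fp <- list(sample_id = profile$sample_id,
               ko_abundance = stats::setNames(numeric(0), character(0)),
               nsti = NA_real_)
    class(fp) <- "functional_profile"
    return(fp)
  }
  w <- profile$counts[pack$leaf_ids] / pack$copy_number[pack$leaf_ids]
  raw <- drop(w %*% pack$ko_content[pack$leaf_ids, , drop = FALSE])
  total <- sum(raw)
  ko <- if (total > 0) raw / total else raw
  fp <- list(sample_id = profile$sample_id, ko_abundance = ko,
             nsti = compute_nsti(profile, pack))
  class(fp) <- "functional_profile"
  fp
}

#' Nearest Sequenced Taxon Index of a sample
#'
#' Abundance-weighted mean of each community member's phylogenetic distance
#' to its nearest sequenced relative: `NSTI = sum_i a_i * d_i` with relative
#' abundances `a_i` summing to 1. Low values mean the functional prediction
#' rests on closely sequenced genomes and is therefore more trustworthy.
#'
#' @param profile A `taxonomic_profile`.
#' @param pack A `reference_pack`.
#' @return A non-negative real, or `NA` for an empty sample.
#' @export
compute_nsti <- function(profile, pack) {
  if (isTRUE(profile$empty)) return(NA_real_)
  a <- profile$normalized[pack$leaf_ids]
  sum(a * pack$nsti_distance[pack$leaf_ids])
}

#' Aggregate a KO profile through the pathway hierarchy
#'
#' Sums KO relative abundances over the pathway label each KO maps to at the
#' requested hierarchy level (1 = broadest). A KO with several hierarchy
#' paths contributes equal fractions to each; a KO absent from the hierarchy
#' is pooled under `"Unannotated"`. The result is re-normalized to sum 1.
#'
#' @param fp A `functional_profile`.
#' @param pack A `reference_pack`.
#' @param level Hierarchy level, 1, 2 or 3.
#' @return A `pathway_profile` with `level` and `abundance`.
#' @export
aggregate_pathways <- function(fp, pack, level = 2L) {
  if (!level %in% 1:3) stop("level must be 1, 2 or 3")
  col <- c("L1", "L2", "L3")[level]
  hier <- pack$hierarchy
  acc <- list()
  add <- function(lab, val) acc[[lab]] <<- (acc[[lab]] %||% 0) + val
  for (ko in names(fp$ko_abundance)) {
    a <- fp$ko_abundance[[ko]]
    if (a == 0) next
    rows <- which(hier$ko == ko)
    if (!length(rows)) {
      add("Unannotated", a)
    } else {
      share <- a / length(rows)
      for (r in rows) add(hier[[col]][r], share)
    }
  }
  abun <- unlist(acc)
  if (length(abun) && sum(abun) > 0) abun <- abun / sum(abun)
  pp <- list(sample_id = fp$sample_id, level = as.integer(level),
             abundance = abun)
  class(pp) <- "pathway_profile"
  pp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' KO abundance table across samples
#'
#' @param fps List of `functional_profile` objects.
#' @param pack A `reference_pack`.
#' @return Relative matrix (samples x KOs).
#' @export
ko_table <- function(fps, pack) {
  kos <- colnames(pack$ko_content)
  m <- matrix(0, nrow = length(fps), ncol = length(kos),
              dimnames = list(vapply(fps, `[[`, "", "sample_id"), kos))
  for (i in seq_along(fps)) {
    a <- fps[[i]]$ko_abundance
    m[i, names(a)] <- a
  }
  attr(m, "unit") <- "relative"
  m
}

#' Pathway abundance table across samples
#'
#' @param fps List of `functional_profile` objects.
#' @param pack A `reference_pack`.
#' @param level Hierarchy level, 1, 2 or 3.
#' @return Relative matrix (samples x pathway labels).
#' @export
pathway_table <- function(fps, pack, level = 2L) {
  pps <- lapply(fps, aggregate_pathways, pack = pack, level = level)
  labs <- sort(unique(unlist(lapply(pps, function(p) names(p$abundance)))))
  m <- matrix(0, nrow = length(pps), ncol = length(labs),
              dimnames = list(vapply(pps, `[[`, "", "sample_id"), labs))
  for (i in seq_along(pps)) {
    a <- pps[[i]]$abundance
    m[i, names(a)] <- a
  }
  attr(m, "unit") <- "relative"
  m
}
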