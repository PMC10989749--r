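pipeline_stages <- c("profiling", "function", "alpha", "beta", "markers",
                     "network")

log_line <- function(outdir, ...) {
  dir.create(file.path(outdir, "logs"), recursive = TRUE, showWarnings = FALSE)
  line <- paste0("[", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "] ", ...)
  cat(line, "\n", sep = "", file = file.path(outdir, "logs", "pipeline.log"),
      append = TRUE)
  invisible(line)
}

read_config <- function(outdir) {
  path <- file.path(outdir, "config.json")
  if (!file.exists(path)) stop("no config.json under ", outdir)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$outdir <- outdir
  cfg
}

#' Run the whole analysis pipeline
#'
#' Orchestrates profiling, functional prediction, alpha and beta diversity,
#' biomarker selection, network construction and the HTML report over a
#' dependency-aware task graph executed by [schedule()]. All stage outputs
#' are plain TSV files under a fixed directory layout; every random step is
#' seeded from `seed`, so re-running with the same inputs reproduces every
#' table bit-for-bit regardless of `threads`. Samples that fail profiling
#' (e.g. an empty FASTA) are quarantined and logged; the pipeline continues
#' with the survivors.
#'
#' @param manifest Path to the `seqs.list` sample manifest.
#' @param metadata Path to the `meta.txt` metadata table.
#' @param refpack Path to the reference pack directory.
#' @param outdir Output directory (created).
#' @param level Taxonomy level for downstream analyses.
#' @param threads Worker processes for independent tasks.
#' @param seed Pipeline seed (mandatory source of all randomness).
#' @param skip Stages to skip (subset of profiling, function, alpha, beta,
#'   markers, network).
#' @param min_identity,k Read-assignment parameters ([assign_best_hit()]).
#' @param permutations Permutations for PERMANOVA/ANOSIM/distance regression.
#' @param report Render the `index.html` result viewer.
#' @return `outdir`, invisibly; stage errors are collected in
#'   `logs/pipeline.log` and `summary.txt`.
#' @export
run_pipeline <- function(manifest, metadata, refpack, outdir,
                         level = "genus", threads = 1L, seed = 1L,
                         skip = character(), min_identity = 0.97, k = 8L,
                         permutations = 999L, report = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fail <- function(msg) {
    log_line(outdir, "ERROR: ", msg)
    stop(errorCondition(msg, class = c("ampliflow_input_error", "error")))
  }
  if (!file.exists(manifest)) fail(paste0("manifest not found: ", manifest))
  if (!file.exists(metadata)) fail(paste0("metadata file not found: ", metadata))
  if (!dir.exists(refpack)) fail(paste0("reference pack not found: ", refpack))
  bad <- setdiff(skip, pipeline_stages)
  if (length(bad)) fail(paste0("unknown stage in skip: ", bad[1L]))
  stages <- setdiff(pipeline_stages, skip)
  if ("profiling" %in% skip && length(stages)) {
    fail("all analysis stages require profiling; cannot skip it alone")
  }
  if (!level %in% rank_names) fail(paste0("unknown taxonomy level: ", level))
  mf <- tryCatch(read_manifest(manifest),
                 error = function(e) fail(conditionMessage(e)))
  tryCatch(read_metadata(metadata, mf),
           error = function(e) fail(conditionMessage(e)))
  tryCatch(read_reference_pack(refpack),
           error = function(e) fail(conditionMessage(e)))

  cfg <- list(manifest = normalizePath(manifest),
              metadata = normalizePath(metadata),
              refpack = normalizePath(refpack),
              level = level, seed = as.integer(seed), skip = skip,
              min_identity = min_identity, k = as.integer(k),
              permutations = as.integer(permutations))
  jsonlite::write_json(cfg, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(outdir, "pipeline start: ", length(mf$sample_id), " samples, ",
           "stages: ", paste(stages, collapse = ", "))

  tasks <- list()
  add_stage <- function(name, deps) {
    tasks[[name]] <<- list(deps = intersect(deps, stages),
                           fun = function(res) {
                             log_line(outdir, "stage ", name, " start")
                             out <- run_stage(outdir, name, threads = threads)
                             log_line(outdir, "stage ", name, " done")
                             out
                           })
  }
  for (st in stages) {
    deps <- switch(st, profiling = character(0),
                   `function` = "profiling", alpha = "profiling",
                   beta = c("profiling", "function"),
                   markers = "profiling", network = "profiling")
    add_stage(st, deps)
  }
  write_workflow_script(outdir, stages, report)
  sched <- schedule(tasks, threads = threads)
  utils::write.table(sched$log, file.path(outdir, "logs", "schedule.log"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (id in names(sched$errors)) {
    log_line(outdir, "stage ", id, " FAILED: ", sched$errors[id])
  }
  write_summary(outdir, cfg, stages, sched)
  # rendered last so it can link the summary; marks failed stages "not run"
  if (report) {
    rep_err <- tryCatch({generate_report(outdir); NULL},
                        error = function(e) conditionMessage(e))
    if (!is.null(rep_err)) {
      log_line(outdir, "stage report FAILED: ", rep_err)
      sched$errors["report"] <- rep_err
    }
  }
  log_line(outdir, "pipeline finished")
  if (length(sched$errors)) {
    warning("pipeline finished with failed stages: ",
            paste(names(sched$errors), collapse = ", "))
  }
  invisible(outdir)
}

#' Run one pipeline stage against an existing output directory
#'
#' Stages communicate exclusively through files under `outdir`, so any stage
#' can be re-run stand-alone once its inputs exist (this is what the emitted
#' `script.sh` does, step by step).
#'
#' @param outdir Pipeline output directory containing `config.json`.
#' @param stage One of profiling, function, alpha, beta, markers, network,
#'   report.
#' @param threads Worker processes for the stage's internal tasks.
#' @return Stage summary list, invisibly.
#' @export
run_stage <- function(outdir, stage, threads = 1L) {
  cfg <- read_config(outdir)
  cfg$threads <- threads
  out <- switch(stage,
                profiling = stage_profiling(cfg),
                `function` = stage_function(cfg),
                alpha = stage_alpha(cfg),
                beta = stage_beta(cfg),
                markers = stage_markers(cfg),
                network = stage_network(cfg),
                report = generate_report(outdir),
                stop("unknown stage: ", stage))
  invisible(out)
}

# --- stages ------------------------------------------------------------------

stage_profiling <- function(cfg) {
  pack <- read_reference_pack(cfg$refpack)
  mf <- read_manifest(cfg$manifest)
  meta <- read_metadata(cfg$metadata, mf)
  index <- build_kmer_index(pack, cfg$k)
  dir.create(file.path(cfg$outdir, "classification"), recursive = TRUE,
             showWarnings = FALSE)

  tasks <- list()
  for (i in seq_len(nrow(mf))) {
    local({
      sid <- mf$sample_id[i]; fp <- mf$fasta_path[i]
      tasks[[sid]] <<- list(deps = character(0), fun = function(res) {
        reads <- read_fasta(fp)
        asn <- assign_reads(reads, pack, cfg$min_identity, cfg$k, index)
        utils::write.table(asn,
                           file.path(cfg$outdir, "classification",
                                     paste0(sid, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        build_profile(asn, pack, sid)
      })
    })
  }
  sched <- schedule(tasks, threads = cfg$threads)
  dropped <- names(sched$errors)
  for (sid in dropped) {
    log_line(cfg$outdir, "sample ", sid, " quarantined: ", sched$errors[sid])
  }
  kept <- mf$sample_id[!mf$sample_id %in% dropped]
  if (!length(kept)) stop("no sample survived profiling")
  profiles <- sched$results[kept]

  ab_dir <- file.path(cfg$outdir, "Abundance_Tables")
  write_table(profile_counts_table(profiles, pack),
              file.path(ab_dir, "taxa.leaf.count.tsv"))
  for (rk in rank_names) {
    write_table(collapse_to_level(profiles, pack, rk),
                file.path(ab_dir, paste0("taxa.", rk, ".tsv")))
  }
  # metadata restricted to surviving samples, for downstream stages
  keep_meta <- meta[kept, , drop = FALSE]
  meta_out <- data.frame(id = kept, keep_meta, check.names = FALSE)
  colnames(meta_out)[1L] <- "#SampleID"
  utils::write.table(meta_out, file.path(cfg$outdir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(n_samples = length(kept), dropped = dropped,
       empty = kept[vapply(profiles, function(p) isTRUE(p$empty), TRUE)])
}

load_profiles <- function(cfg, pack) {
  counts <- read_table(file.path(cfg$outdir, "Abundance_Tables",
                                 "taxa.leaf.count.tsv"), unit = "counts")
  lapply(rownames(counts), function(s) {
    profile_from_counts(counts[s, ], pack, s)
  })
}

load_meta <- function(cfg) {
  read_metadata(file.path(cfg$outdir, "metadata.tsv"))
}

stage_function <- function(cfg) {
  pack <- read_reference_pack(cfg$refpack)
  profiles <- load_profiles(cfg, pack)
  fps <- lapply(profiles, predict_ko, pack = pack)
  ab_dir <- file.path(cfg$outdir, "Abundance_Tables")
  write_table(ko_table(fps, pack), file.path(ab_dir, "ko.tsv"))
  for (lv in 1:3) {
    write_table(pathway_table(fps, pack, lv),
                file.path(ab_dir, paste0("pathway.L", lv, ".tsv")))
  }
  nsti <- vapply(fps, `[[`, 0, "nsti")
  write_table(matrix(nsti, ncol = 1L,
                     dimnames = list(vapply(fps, `[[`, "", "sample_id"),
                                     "NSTI")),
              file.path(cfg$outdir, "nsti.tsv"))
  list(mean_nsti = mean(nsti, na.rm = TRUE))
}

stage_alpha <- function(cfg) {
  rel <- read_table(file.path(cfg$outdir, "Abundance_Tables",
                              paste0("taxa.", cfg$level, ".tsv")))
  counts <- read_table(file.path(cfg$outdir, "Abundance_Tables",
                                 "taxa.leaf.count.tsv"), unit = "counts")
  meta <- load_meta(cfg)
  alpha <- alpha_table(rel, counts)
  adir <- file.path(cfg$outdir, "Alpha_Diversity")
  write_table(alpha, file.path(adir, "alpha.tsv"))
  kinds <- metadata_kinds(meta)
  rows <- list()
  for (idx in colnames(alpha)) {
    for (var in names(kinds)) {
      res <- tryCatch({
        if (kinds[var] == "discrete") {
          r <- alpha_group_test(alpha[, idx], meta[[var]])
          data.frame(index = idx, variable = var, method = r$method,
                     statistic = r$statistic, p = r$p,
                     stringsAsFactors = FALSE)
        } else {
          r <- alpha_numeric_regression(alpha[, idx], meta[[var]])
          data.frame(index = idx, variable = var, method = "ols-slope",
                     statistic = r$slope, p = r$p, stringsAsFactors = FALSE)
        }
      }, error = function(e) {
        log_line(cfg$outdir, "alpha test skipped (", idx, " ~ ", var, "): ",
                 conditionMessage(e))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  tests <- do.call(rbind, rows)
  if (is.null(tests)) {
    tests <- data.frame(index = character(0), variable = character(0),
                        method = character(0), statistic = numeric(0),
                        p = numeric(0))
  }
  utils::write.table(tests, file.path(adir, "tests.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(n_tests = nrow(tests))
}

load_functional_profiles <- function(cfg) {
  ko <- read_table(file.path(cfg$outdir, "Abundance_Tables", "ko.tsv"))
  lapply(rownames(ko), function(s) {
    fp <- list(sample_id = s, ko_abundance = ko[s, ], nsti = NA_real_)
    class(fp) <- "functional_profile"
    fp
  })
}

stage_beta <- function(cfg) {
  pack <- read_reference_pack(cfg$refpack)
  profiles <- load_profiles(cfg, pack)
  meta <- load_meta(cfg)
  ddir <- file.path(cfg$outdir, "Distance_Matrix")
  dw <- distance_matrix(profiles, pack, "metastorms-weighted",
                        threads = cfg$threads)
  write_table(dw, file.path(ddir, "taxa.dist.tsv"))
  write_table(distance_matrix(profiles, pack, "metastorms-unweighted",
                              threads = cfg$threads),
              file.path(ddir, "taxa.unweighted.dist.tsv"))
  ko_path <- file.path(cfg$outdir, "Abundance_Tables", "ko.tsv")
  matrices <- list(taxa.weighted = dw)
  if (file.exists(ko_path)) {
    fps <- load_functional_profiles(cfg)
    df <- distance_matrix(fps, pack, "hierarchical-metastorms",
                          threads = cfg$threads)
    write_table(df, file.path(ddir, "func.dist.tsv"))
    matrices$func <- df
  } else {
    log_line(cfg$outdir, "function stage outputs absent; functional distance skipped")
  }

  odir <- file.path(cfg$outdir, "Ordination")
  ord <- pcoa(dw, axes = 2L)
  write_table(ord$coordinates, file.path(odir, "pcoa.tsv"))
  write_table(matrix(ord$explained, ncol = 1L,
                     dimnames = list(colnames(ord$coordinates), "explained")),
              file.path(odir, "pcoa.explained.tsv"), id_col = "axis")
  rel <- read_table(file.path(cfg$outdir, "Abundance_Tables",
                              paste0("taxa.", cfg$level, ".tsv")))
  pc <- pca(rel, axes = 2L)
  write_table(pc$coordinates, file.path(odir, "pca.tsv"))
  write_table(matrix(pc$explained, ncol = 1L,
                     dimnames = list(colnames(pc$coordinates), "explained")),
              file.path(odir, "pca.explained.tsv"), id_col = "axis")

  kinds <- metadata_kinds(meta)
  rows <- list()
  for (mn in names(matrices)) {
    d <- matrices[[mn]]
    for (var in names(kinds)) {
      res <- tryCatch({
        if (kinds[var] == "discrete") {
          pm <- permanova(d, meta[[var]], cfg$permutations,
                          seed = cfg$seed + 101L)
          an <- anosim(d, meta[[var]], cfg$permutations,
                       seed = cfg$seed + 102L)
          rbind(data.frame(matrix_ = mn, variable = var, method = "permanova",
                           statistic = pm$pseudo_F, p = pm$p),
                data.frame(matrix_ = mn, variable = var, method = "anosim",
                           statistic = an$R, p = an$p))
        } else {
          rg <- distance_numeric_regression(d, meta[[var]], cfg$permutations,
                                            seed = cfg$seed + 103L)
          data.frame(matrix_ = mn, variable = var, method = "mantel-ols",
                     statistic = rg$r2, p = rg$p)
        }
      }, error = function(e) {
        log_line(cfg$outdir, "beta test skipped (", mn, " ~ ", var, "): ",
                 conditionMessage(e))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  tests <- do.call(rbind, rows)
  if (is.null(tests)) {
    tests <- data.frame(matrix_ = character(0), variable = character(0),
                        method = character(0), statistic = numeric(0),
                        p = numeric(0))
  }
  colnames(tests)[1L] <- "matrix"
  tdir <- file.path(cfg$outdir, "Beta_Tests")
  dir.create(tdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(tests, file.path(tdir, "tests.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(n_tests = nrow(tests))
}

stage_markers <- function(cfg) {
  rel <- read_table(file.path(cfg$outdir, "Abundance_Tables",
                              paste0("taxa.", cfg$level, ".tsv")))
  meta <- load_meta(cfg)
  kinds <- metadata_kinds(meta)
  mdir <- file.path(cfg$outdir, "Markers")
  dir.create(mdir, showWarnings = FALSE, recursive = TRUE)
  notes <- list()
  for (var in names(kinds)[kinds == "discrete"]) {
    res <- tryCatch({
      screen <- ranksum_screen(rel, meta[[var]])
      if (nrow(screen) >= 2L) {
        rf <- rf_rank(rel[, screen$feature, drop = FALSE], meta[[var]],
                      seed = cfg$seed + 202L)
        tab <- merge(screen, rf, by = "feature", sort = FALSE)
        tab <- tab[order(-tab$importance, tab$feature), , drop = FALSE]
        notes[[var]] <- list(model_error = attr(rf, "model_error"),
                             n_markers = nrow(tab))
        log_line(cfg$outdir, "markers ~ ", var, ": OOB error ",
                 format(attr(rf, "model_error")))
      } else {
        tab <- cbind(screen, importance = numeric(nrow(screen)),
                     direction = character(nrow(screen)))
        notes[[var]] <- list(model_error = NA_real_, n_markers = nrow(tab))
        log_line(cfg$outdir, "markers ~ ", var, ": ", nrow(screen),
                 " features pass the screen; Random Forest skipped")
      }
      tab
    }, error = function(e) {
      log_line(cfg$outdir, "marker selection skipped (", var, "): ",
               conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      utils::write.table(res,
                         file.path(mdir, paste0("markers.", cfg$level, ".",
                                                var, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  for (var in names(kinds)[kinds == "numeric"]) {
    res <- tryCatch(numeric_biomarkers(rel, meta[[var]]),
                    error = function(e) {
                      log_line(cfg$outdir, "numeric biomarkers skipped (",
                               var, "): ", conditionMessage(e))
                      NULL
                    })
    if (!is.null(res)) {
      utils::write.table(res,
                         file.path(mdir, paste0("markers.numeric.", var,
                                                ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  notes
}

stage_network <- function(cfg) {
  rel <- read_table(file.path(cfg$outdir, "Abundance_Tables",
                              paste0("taxa.", cfg$level, ".tsv")))
  net <- build_network(rel)
  st <- network_stats(net)
  ndir <- file.path(cfg$outdir, "Network")
  dir.create(ndir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(net$edges, file.path(ndir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(nodes = length(net$nodes),
                                edges = nrow(net$edges),
                                density = st$density, diameter = st$diameter,
                                radius = st$radius,
                                centralization = st$centralization,
                                components = st$component_count),
                     file.path(ndir, "stats.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  st
}

# --- summary and workflow script --------------------------------------------

write_summary <- function(outdir, cfg, stages, sched) {
  lines <- c("Analysis summary", "================", "",
             paste0("taxonomy level: ", cfg$level),
             paste0("seed: ", cfg$seed),
             paste0("stages run: ", paste(stages, collapse = ", ")),
             if (length(cfg$skip)) paste0("stages skipped: ",
                                          paste(cfg$skip, collapse = ", ")))
  prof <- sched$results[["profiling"]]
  if (!is.null(prof)) {
    lines <- c(lines, paste0("samples profiled: ", prof$n_samples),
               if (length(prof$dropped))
                 paste0("samples quarantined: ",
                        paste(prof$dropped, collapse = ", ")),
               if (length(prof$empty))
                 paste0("empty samples (no classified reads): ",
                        paste(prof$empty, collapse = ", ")))
  }
  mk <- sched$results[["markers"]]
  if (!is.null(mk)) {
    for (var in names(mk)) {
      lines <- c(lines,
                 paste0("markers ~ ", var, ": ", mk[[var]]$n_markers,
                        " features, model OOB error ",
                        ifelse(is.na(mk[[var]]$model_error), "NA",
                               format(round(mk[[var]]$model_error, 4)))))
    }
  }
  nt <- sched$results[["network"]]
  if (!is.null(nt)) {
    lines <- c(lines, paste0("network: density ",
                             format(round(nt$density, 4)),
                             ", diameter ", nt$diameter,
                             ", radius ", nt$radius,
                             ", centralization ",
                             format(round(nt$centralization, 4))))
  }
  if (length(sched$errors)) {
    lines <- c(lines, "", paste0("FAILED stages: ",
                                 paste(names(sched$errors), collapse = ", ")))
  }
  writeLines(lines, file.path(outdir, "summary.txt"))
}

write_workflow_script <- function(outdir, stages, report) {
  steps <- c(stages, if (report) "report")
  lines <- c("#!/bin/sh",
             "# Step-by-step workflow: re-runs each stage of the analysis",
             "# against this output directory (inputs per config.json).",
             "set -e",
             'OUT="$(cd "$(dirname "$0")" && pwd)"',
             vapply(steps, function(st) {
               sprintf("Rscript -e \"ampliflow::run_stage('$OUT', '%s')\"", st)
             }, ""))
  path <- file.path(outdir, "script.sh")
  writeLines(lines, path)
  Sys.chmod(path, "0755")
  invisible(path)
}
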