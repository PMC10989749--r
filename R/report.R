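# Static HTML result viewer: one dependency-free page linking every table
# the pipeline produced and embedding the rendered figures.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

render_png <- function(path, expr, width = 720, height = 480) {
  ok <- tryCatch({
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
    expr()
    TRUE
  }, error = function(e) FALSE)
  if (!ok && file.exists(path)) unlink(path)
  ok
}

report_palette <- function(n) grDevices::hcl.colors(max(n, 2L), "Dark 3")[seq_len(n)]

plot_taxa_bars <- function(outdir, file) {
  src <- file.path(outdir, "Abundance_Tables", "taxa.phylum.tsv")
  if (!file.exists(src)) return(FALSE)
  m <- read_table(src)
  if (!nrow(m)) return(FALSE)
  top <- head(order(-colMeans(m)), 8L)
  other <- 1 - rowSums(m[, top, drop = FALSE])
  mm <- t(cbind(m[, top, drop = FALSE], Other = pmax(0, other)))
  labs <- sub("^.*;", "", rownames(mm))
  render_png(file, function() {
    graphics::par(mar = c(6, 4, 2, 10), xpd = TRUE)
    graphics::barplot(mm, col = report_palette(nrow(mm)), border = NA,
                      las = 2, cex.names = 0.6,
                      ylab = "relative abundance",
                      main = "Taxonomic composition (phylum)")
    graphics::legend("topright", inset = c(-0.28, 0), legend = labs,
                     fill = report_palette(nrow(mm)), cex = 0.6, bty = "n")
  })
}

report_meta <- function(outdir) {
  mp <- file.path(outdir, "metadata.tsv")
  if (!file.exists(mp)) return(NULL)
  tryCatch(read_metadata(mp), error = function(e) NULL)
}

first_discrete <- function(meta) {
  if (is.null(meta)) return(NULL)
  k <- metadata_kinds(meta)
  v <- names(k)[k == "discrete"]
  if (length(v)) v[1L] else NULL
}

plot_alpha <- function(outdir, file) {
  src <- file.path(outdir, "Alpha_Diversity", "alpha.tsv")
  if (!file.exists(src)) return(FALSE)
  alpha <- read_table(src, unit = "counts")
  meta <- report_meta(outdir)
  gv <- first_discrete(meta)
  render_png(file, function() {
    graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
    for (idx in colnames(alpha)) {
      if (!is.null(gv)) {
        g <- factor(meta[rownames(alpha), gv])
        graphics::boxplot(alpha[, idx] ~ g, col = report_palette(nlevels(g)),
                          xlab = gv, ylab = idx, main = idx)
      } else {
        graphics::hist(alpha[, idx], col = "grey70", xlab = idx, main = idx)
      }
    }
  })
}

plot_heatmap <- function(outdir, file) {
  src <- file.path(outdir, "Distance_Matrix", "taxa.dist.tsv")
  if (!file.exists(src)) return(FALSE)
  d <- read_distance_matrix(src)
  render_png(file, function() {
    n <- nrow(d)
    graphics::par(mar = c(6, 6, 3, 1))
    graphics::image(seq_len(n), seq_len(n), t(d[n:1, , drop = FALSE]),
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    axes = FALSE, xlab = "", ylab = "",
                    main = "Weighted taxonomic distance")
    graphics::axis(1, seq_len(n), colnames(d), las = 2, cex.axis = 0.5)
    graphics::axis(2, seq_len(n), rev(rownames(d)), las = 2, cex.axis = 0.5)
  }, width = 640, height = 600)
}

plot_ordination <- function(outdir, file) {
  src <- file.path(outdir, "Ordination", "pcoa.tsv")
  if (!file.exists(src)) return(FALSE)
  co <- read_table(src, unit = "counts", nonneg = FALSE)
  ex <- tryCatch(read_table(file.path(outdir, "Ordination",
                                      "pcoa.explained.tsv"), unit = "counts"),
                 error = function(e) NULL)
  meta <- report_meta(outdir)
  gv <- first_discrete(meta)
  render_png(file, function() {
    col <- "grey30"; leg <- NULL
    if (!is.null(gv)) {
      g <- factor(meta[rownames(co), gv])
      col <- report_palette(nlevels(g))[g]
      leg <- levels(g)
    }
    lab <- function(i) {
      if (!is.null(ex) && nrow(ex) >= i) {
        sprintf("%s (%.1f%%)", colnames(co)[i], 100 * ex[i, 1])
      } else colnames(co)[i]
    }
    graphics::plot(co[, 1], co[, 2], pch = 19, col = col,
                   xlab = lab(1), ylab = lab(2), main = "PCoA")
    if (!is.null(leg)) {
      graphics::legend("topright", legend = leg, col = report_palette(length(leg)),
                       pch = 19, bty = "n")
    }
  })
}

plot_markers <- function(outdir, file) {
  mdir <- file.path(outdir, "Markers")
  files <- list.files(mdir, pattern = "^markers\\..*\\.tsv$", full.names = TRUE)
  files <- files[!grepl("numeric", files)]
  if (!length(files)) return(FALSE)
  tab <- utils::read.delim(files[1L], stringsAsFactors = FALSE)
  if (!nrow(tab) || !"importance" %in% colnames(tab)) return(FALSE)
  tab <- utils::head(tab[order(-tab$importance), ], 15L)
  render_png(file, function() {
    graphics::par(mar = c(4, 16, 3, 1))
    graphics::barplot(rev(tab$importance),
                      names.arg = rev(html_escape(substr(tab$feature, 1, 45))),
                      horiz = TRUE, las = 1, cex.names = 0.6,
                      col = "steelblue", border = NA,
                      xlab = "importance (mean decrease in accuracy)",
                      main = "Biomarker ranking")
  })
}

plot_network <- function(outdir, file) {
  src <- file.path(outdir, "Network", "edges.tsv")
  if (!file.exists(src)) return(FALSE)
  edges <- utils::read.delim(src, stringsAsFactors = FALSE)
  if (!nrow(edges)) return(FALSE)
  g <- igraph::graph_from_data_frame(edges[, c("u", "v")], directed = FALSE)
  lay <- with_seed(7L, igraph::layout_with_fr(g))
  render_png(file, function() {
    graphics::par(mar = c(1, 1, 3, 1))
    igraph::plot.igraph(g, layout = lay, vertex.size = 6,
                        vertex.label.cex = 0.55,
                        vertex.color = "lightsteelblue",
                        edge.color = ifelse(edges$rho > 0, "grey40",
                                            "indianred"),
                        main = "Co-occurrence network")
  }, width = 640, height = 640)
}

#' Generate the static HTML result viewer
#'
#' Scans a pipeline output directory, renders one figure per completed stage
#' (taxonomy stacked bars, alpha boxplots, distance heatmap, PCoA scatter,
#' biomarker importance bars, network view) into `plots/`, and writes a
#' self-contained `index.html` linking every produced table. Stages without
#' outputs are shown as "not run". Regeneration is idempotent: identical
#' inputs give identical bytes.
#'
#' @param outdir Pipeline output directory.
#' @return Path to `index.html`, invisibly.
#' @export
generate_report <- function(outdir) {
  if (!dir.exists(outdir)) stop("output directory not found: ", outdir)
  pdir <- file.path(outdir, "plots")
  dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
  figs <- list(
    Taxonomy = plot_taxa_bars(outdir, file.path(pdir, "taxa_bars.png")),
    `Alpha diversity` = plot_alpha(outdir, file.path(pdir, "alpha.png")),
    `Beta diversity (heatmap)` = plot_heatmap(outdir, file.path(pdir, "heatmap.png")),
    `Beta diversity (PCoA)` = plot_ordination(outdir, file.path(pdir, "pcoa.png")),
    Biomarkers = plot_markers(outdir, file.path(pdir, "markers.png")),
    Network = plot_network(outdir, file.path(pdir, "network.png")))
  fig_file <- c("taxa_bars.png", "alpha.png", "heatmap.png", "pcoa.png",
                "markers.png", "network.png")

  sections <- list(
    Taxonomy = c("classification", "Abundance_Tables"),
    `Alpha diversity` = "Alpha_Diversity",
    `Beta diversity (heatmap)` = "Distance_Matrix",
    `Beta diversity (PCoA)` = c("Ordination", "Beta_Tests"),
    Biomarkers = "Markers",
    Network = "Network")

  html <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
            "<title>Microbiome analysis results</title>",
            "<style>body{font-family:sans-serif;margin:2em;max-width:70em}",
            "h2{border-bottom:1px solid #ccc;padding-bottom:0.2em}",
            "ul{columns:2}li{font-size:0.85em}",
            ".notrun{color:#999;font-style:italic}</style></head><body>",
            "<h1>Microbiome analysis results</h1>")
  for (f in c("summary.txt", "script.sh", "config.json", "metadata.tsv",
              "nsti.tsv")) {
    if (file.exists(file.path(outdir, f))) {
      html <- c(html, sprintf("<p><a href='%s'>%s</a></p>", f, f))
    }
  }
  for (i in seq_along(sections)) {
    name <- names(sections)[i]
    html <- c(html, sprintf("<h2>%s</h2>", html_escape(name)))
    files <- unlist(lapply(sections[[i]], function(d) {
      if (dir.exists(file.path(outdir, d))) {
        file.path(d, list.files(file.path(outdir, d)))
      } else character(0)
    }))
    if (!length(files)) {
      html <- c(html, "<p class='notrun'>not run</p>")
      next
    }
    if (isTRUE(figs[[name]])) {
      html <- c(html, sprintf("<p><img src='plots/%s' alt='%s'></p>",
                              fig_file[i], html_escape(name)))
    }
    html <- c(html, "<ul>",
              sprintf("<li><a href='%s'>%s</a></li>", files,
                      html_escape(files)),
              "</ul>")
  }
  if (all(!vapply(sections, function(d) any(dir.exists(file.path(outdir, d))),
                  TRUE))) {
    html <- c(html, "<p class='notrun'>No stage outputs were found in this",
              " directory; run the pipeline first.</p>")
  }
  html <- c(html, "</body></html>")
  out <- file.path(outdir, "index.html")
  writeLines(html, out)
  invisible(out)
}
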