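# Output writers: ordered similarity/distance matrix (TSV), composite
# heatmap (PDF), per-pair and per-direction intermediates (TSV).
# Convention: files keep >= 3 decimals; only heatmap cell labels round to
# the first decimal. Rounding is display-only and never feeds computation.

format_sim_value <- function(x, digits = 3L) sprintf(paste0("%.", digits, "f"), x)

format_sim_label <- function(x) sprintf("%.1f", x)

#' Write a similarity or distance matrix as TSV
#'
#' Square tab-separated table with genome ids as the first row and first
#' column, `.` as decimal separator, no quoting; values are written with a
#' fixed number of decimals (default 3: enough to reveal minute differences
#' that the heatmap's one-decimal labels hide). `type = "dist"` writes
#' `100 - sim` cellwise.
#'
#' @param m similarity matrix (typically ordered via [order_matrix()]).
#' @param path output path.
#' @param type `"sim"` (default) or `"dist"`.
#' @param digits decimals to keep (>= 3).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, type = c("sim", "dist"), digits = 3L) {
  type <- match.arg(type)
  check_sim_matrix(m)
  if (digits < 3L) input_stop("matrix files keep at least 3 decimals")
  vals <- if (type == "dist") 100 - m else m
  out <- matrix(format_sim_value(vals, digits), nrow(m), ncol(m))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("genome", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], out[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read back a matrix written by [write_matrix()]
#'
#' @param path TSV path.
#' @return Numeric matrix with genome-id dimnames.
#' @export
read_matrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                           check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(tab)
}

#' Write per-pair and per-direction intermediate tables
#'
#' The long-format pair table (similarity, distance, the three indicators,
#' directional identical-base sums and aligned-base counts, lengths) and the
#' cluster table, as tab-separated text for pipeline integration.
#'
#' @param result an `igsim_result` from [compute_matrix()].
#' @param dir output directory (created if needed).
#' @param cluster_table optional `igsim_cluster_table` from
#'   [assign_clusters()].
#' @return Character vector of written paths (the manifest), invisibly.
#' @export
write_intermediates <- function(result, dir, cluster_table = NULL) {
  if (!inherits(result, "igsim_result")) {
    input_stop("'result' must come from compute_matrix()")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "pairs.tsv")
  utils::write.table(result$pairs, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(cluster_table)) {
    p <- file.path(dir, "cluster_table.tsv")
    utils::write.table(as.data.frame(cluster_table), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Assemble a heatmap specification
#'
#' Bundles and cross-checks everything the composite heatmap needs: the
#' ordered similarity matrix, the directional aligned-fraction matrix, and
#' the genome lengths. Ids must agree across the three.
#'
#' @param m ordered similarity matrix.
#' @param af aligned-fraction matrix (`af[i, j]` = fraction of genome `i`
#'   aligned against genome `j`), any id order.
#' @param lengths named vector of genome lengths.
#' @param label_threshold suppress in-cell numbers above this many genomes
#'   (legibility; default 80).
#' @return List of class `heatmap_spec`.
#' @export
heatmap_spec <- function(m, af, lengths, label_threshold = 80L) {
  check_sim_matrix(m)
  ids <- rownames(m)
  if (!setequal(rownames(af), ids) || !identical(rownames(af), colnames(af))) {
    input_stop("aligned-fraction matrix ids do not match the similarity matrix")
  }
  if (!setequal(names(lengths), ids)) {
    input_stop("genome lengths ids do not match the similarity matrix")
  }
  structure(
    list(m = m, af = af[ids, ids, drop = FALSE],
         lengths = lengths[ids], label_threshold = label_threshold),
    class = "heatmap_spec"
  )
}

#' Render the composite similarity heatmap to PDF
#'
#' One square heatmap in the clustering order. The upper-right half (and the
#' diagonal) shows intergenomic similarity, darker for more related, labelled
#' to the first decimal. Each lower-left cell shows, top to bottom, three
#' indicator bands: aligned fraction of the row genome, genome length ratio
#' of the pair, aligned fraction of the column genome — orange-to-white for
#' the fractions and black-to-white for the ratio, darker emphasizing low
#' values (partial alignments, unequal lengths). Genome length is drawn as a
#' bar annotation along the columns.
#'
#' @param spec a [heatmap_spec()] (or an `igsim_result` plus `order` below).
#' @param out_path output PDF path.
#' @param sim_colors two colors, low/high end of the similarity gradient.
#' @return `out_path`, invisibly.
#' @export
render_heatmap <- function(spec, out_path,
                           sim_colors = c("white", "#1F6E64")) {
  if (!inherits(spec, "heatmap_spec")) {
    input_stop("'spec' must come from heatmap_spec()")
  }
  m <- spec$m
  af <- spec$af
  lens <- spec$lengths
  n <- nrow(m)
  ids <- rownames(m)
  show_num <- n <= spec$label_threshold

  sim_col <- circlize::colorRamp2(c(0, 100), sim_colors)
  af_col <- circlize::colorRamp2(c(0, 1), c("#E66100", "white"))
  lr_col <- circlize::colorRamp2(c(0, 1), c("black", "white"))
  lr <- outer(lens, lens, function(a, b) pmin(a, b) / pmax(a, b))

  cell_fun <- function(j, i, x, y, w, h, fill) {
    if (j >= i) { # upper-right half + diagonal: similarity
      grid::grid.rect(x, y, w, h, gp = grid::gpar(
        fill = sim_col(m[i, j]), col = "grey70", lwd = 0.3))
      if (show_num) {
        grid::grid.text(format_sim_label(m[i, j]), x, y,
                        gp = grid::gpar(fontsize = min(10, 240 / n)))
      }
    } else {      # lower-left half: af(row) / length ratio / af(col)
      h3 <- h * (1 / 3)
      grid::grid.rect(x, y + h3, w, h3, gp = grid::gpar(
        fill = af_col(af[ids[i], ids[j]]), col = NA))
      grid::grid.rect(x, y, w, h3, gp = grid::gpar(
        fill = lr_col(lr[ids[i], ids[j]]), col = NA))
      grid::grid.rect(x, y - h3, w, h3, gp = grid::gpar(
        fill = af_col(af[ids[j], ids[i]]), col = NA))
      grid::grid.rect(x, y, w, h, gp = grid::gpar(fill = NA, col = "grey70",
                                                  lwd = 0.3))
    }
  }

  top_ann <- ComplexHeatmap::HeatmapAnnotation(
    `genome length` = ComplexHeatmap::anno_barplot(as.numeric(lens),
                                                   border = FALSE),
    annotation_name_side = "left",
    annotation_name_gp = grid::gpar(fontsize = 8)
  )
  ht <- ComplexHeatmap::Heatmap(
    m, name = "similarity", col = sim_col,
    cluster_rows = FALSE, cluster_columns = FALSE,
    rect_gp = grid::gpar(type = "none"), cell_fun = cell_fun,
    top_annotation = top_ann,
    row_names_gp = grid::gpar(fontsize = min(10, 400 / n)),
    column_names_gp = grid::gpar(fontsize = min(10, 400 / n))
  )
  size_in <- max(6, min(48, 0.28 * n + 3))
  grDevices::pdf(out_path, width = size_in + 2, height = size_in)
  on.exit(grDevices::dev.off())
  ComplexHeatmap::draw(ht, heatmap_legend_list = list(
    ComplexHeatmap::Legend(title = "aligned fraction", col_fun = af_col),
    ComplexHeatmap::Legend(title = "length ratio", col_fun = lr_col)
  ))
  invisible(out_path)
}
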