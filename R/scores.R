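# Score-plot export for the PCA-LDA analysis.

#' Export PC scores, the score plot, and the PC1-FBG correlation
#'
#' Projects samples onto a fitted PCA model (fitting one on the data when
#' none is supplied), writes a per-sample score table (id, group, PC1,
#' PC2, FBG) and a PC1/PC2 scatter plot, and reports the Pearson
#' correlation between PC1 scores and FBG when FBG values are available.
#'
#' @param x n x 36 response matrix.
#' @param labels Group label per row.
#' @param pca_model Optional fitted [pca_fit()] model; default fits on `x`.
#' @param fbg Optional FBG value per row.
#' @param file_csv,file_plot Optional output paths.  The plot is written as
#'   PNG (falling back to PDF if no PNG device is available).
#' @return List: `scores` (data frame), `pca_model`, `pc1_fbg` (list r/p/n
#'   or NULL), `files` written.
#' @export
export_scores <- function(x, labels, pca_model = NULL, fbg = NULL,
                          file_csv = NULL, file_plot = NULL) {
  if (is.null(pca_model)) pca_model <- pca_fit(x)
  sc <- pca_transform(pca_model, x)
  if (ncol(sc) < 2L) sc <- cbind(sc, 0)
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("sample%03d", seq_len(nrow(sc)))
  df <- data.frame(id = ids, group = as.character(labels),
                   PC1 = sc[, 1], PC2 = sc[, 2],
                   stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(fbg)) df$FBG <- fbg
  pc1_fbg <- NULL
  if (!is.null(fbg) && stats::sd(df$PC1) > 0 && stats::sd(fbg) > 0) {
    pc1_fbg <- pearson(df$PC1, fbg)
  }
  files <- character()
  if (!is.null(file_csv)) {
    utils::write.csv(df, file_csv, row.names = FALSE)
    files <- c(files, file_csv)
  }
  if (!is.null(file_plot)) {
    pct <- round(100 * pca_model$variance[1:2] / pca_model$total_variance, 1)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                          colour = .data$group)) +
      ggplot2::geom_point(size = 2, alpha = 0.8) +
      ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pct[1]),
                    y = sprintf("PC2 (%.1f%%)", pct[2]),
                    colour = "group",
                    title = "PCA score plot") +
      ggplot2::theme_bw()
    file_plot <- save_plot(p, file_plot)
    files <- c(files, file_plot)
  }
  list(scores = df, pca_model = pca_model, pc1_fbg = pc1_fbg, files = files)
}

# Write a ggplot; PNG when a bitmap device exists, PDF otherwise.
save_plot <- function(p, path, width = 6, height = 4.5) {
  ok <- tryCatch({
    grDevices::png(path, width = width * 100, height = height * 100, res = 100,
                   type = if (capabilities("cairo")) "cairo" else "quartz")
    print(p)
    grDevices::dev.off()
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    path <- sub("\\.png$", ".pdf", path)
    grDevices::pdf(path, width = width, height = height)
    print(p)
    grDevices::dev.off()
  }
  path
}
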