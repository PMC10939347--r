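## ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter plot of clone PCA coordinates
#'
#' @param object A [genotype_pca()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clone_pca <- function(object, ...) {
  sc <- object$scores
  lab <- function(i) {
    sprintf("PC%d (%.1f%%)", i, 100 * object$var_explained[i])
  }
  p <- ggplot(sc, aes(x = .data$PC1, y = if ("PC2" %in% names(sc)) .data$PC2 else 0)) +
    geom_point(size = 2) +
    geom_text(aes(label = .data$sample), vjust = -0.8, size = 3) +
    labs(x = lab(1),
         y = if (length(object$var_explained) >= 2) lab(2) else NULL) +
    theme_minimal()
  p
}

#' Heatmap of a kinship matrix
#'
#' @param object A [kinship_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kinship_matrix <- function(object, ...) {
  df <- as_tibble(as.data.frame(as.table(unclass(object))))
  names(df) <- c("sample_i", "sample_j", "kinship")
  ggplot(df, aes(.data$sample_i, .data$sample_j, fill = .data$kinship)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(min(0, min(df$kinship, na.rm = TRUE)), 0.5)) +
    labs(x = NULL, y = NULL, fill = "kinship") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Windowed diversity tracks
#'
#' Line tracks of per-window diversity per chromosome.
#'
#' @param windows A [windowed_diversity()] result.
#' @param stat Column to draw (`"pi_per_kbp"`, `"theta_per_kbp"`,
#'   `"tajima_d"`, `"S"`).
#' @return A ggplot faceted by chromosome.
#' @export
plot_diversity_windows <- function(windows, stat = "tajima_d") {
  ggplot(windows, aes(x = (.data$start + .data$end) / 2e6,
                      y = .data[[stat]])) +
    geom_line(linewidth = 0.3) +
    geom_hline(yintercept = 0, linetype = "dashed", linewidth = 0.2) +
    facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    labs(x = "position (Mbp)", y = stat) +
    theme_minimal()
}

#' Bar plot of a sharing or missingness spectrum
#'
#' @param spectra A [sharing_spectra()] result.
#' @param which `"valid_genotypes"` or `"nonref_carriers"`.
#' @return A ggplot.
#' @export
plot_sharing_spectrum <- function(spectra, which = "valid_genotypes") {
  df <- filter(spectra, .data$spectrum == which)
  ggplot(df, aes(factor(.data$k), .data$n_sites)) +
    geom_col() +
    labs(x = if (which == "valid_genotypes") "samples with a valid genotype"
         else "clones carrying the non-reference state",
         y = "sites") +
    theme_minimal()
}
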