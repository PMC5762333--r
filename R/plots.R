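# Static figure helpers: activity heatmap, sample dendrogram, K-M curves.

#' Heatmap of an activity profile
#'
#' Normalized activities with subpathways as rows and samples as columns;
#' both axes ordered by the package's own hierarchical clustering
#' (uncentered correlation, complete linkage) when more than one row/column.
#'
#' @param profile An \code{activity_profile}.
#' @param ... Passed to \code{\link[stats]{heatmap}}.
#' @export
plot_activity_heatmap <- function(profile, ...) {
  mat <- profile$spa_norm
  ord_r <- if (nrow(mat) > 1)
    hierarchical_cluster(profile, axis = "subpathways")$hclust else NA
  ord_c <- if (ncol(mat) > 1)
    hierarchical_cluster(profile, axis = "samples")$hclust else NA
  stats::heatmap(mat,
                 Rowv = if (is.na(ord_r[1])) NA else stats::as.dendrogram(ord_r),
                 Colv = if (is.na(ord_c[1])) NA else stats::as.dendrogram(ord_c),
                 scale = "none",
                 col = grDevices::hcl.colors(64, "Green-Orange"), ...)
  invisible(NULL)
}

#' Plot a clustering dendrogram
#'
#' @param clustering Result of \code{\link{hierarchical_cluster}}.
#' @param ... Passed to \code{plot.hclust}.
#' @export
plot_dendrogram <- function(clustering, ...) {
  graphics::plot(clustering$hclust, xlab = "", sub = "", ...)
  invisible(NULL)
}

#' Plot Kaplan-Meier curves per risk group
#'
#' @param km Result of \code{\link{km_logrank}}.
#' @param ... Passed to \code{plot.survfit}.
#' @export
plot_km_curves <- function(km, ...) {
  k <- length(km$n_per_group)
  cols <- grDevices::hcl.colors(max(k, 2), "Dark 3")[seq_len(k)]
  graphics::plot(km$fit, col = cols, xlab = "time (days)",
                 ylab = "survival probability", ...)
  graphics::legend("topright",
                   legend = sprintf("group %s (n=%d)",
                                    names(km$n_per_group), km$n_per_group),
                   col = cols, lty = 1, bty = "n")
  graphics::mtext(sprintf("log-rank p = %.3g", km$p), side = 3, line = 0.2,
                  cex = 0.9)
  invisible(NULL)
}
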