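#' Plate heatmap of a well-level value
#'
#' @param plate Tibble of one plate's wells with `row`, `col` and the
#'   column named by `value`.
#' @param value Column to map to fill (default `"nfs"`).
#' @return A ggplot in plate orientation (row A at the top).
#' @export
plot_plate <- function(plate, value = "nfs") {
  stopifnot(all(c("row", "col", value) %in% names(plate)))
  ggplot2::ggplot(plate, ggplot2::aes(x = .data$col, y = .data$row,
                                      fill = .data[[value]])) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_y_reverse(breaks = 1:16, labels = LETTERS[1:16]) +
    ggplot2::scale_x_continuous(breaks = seq(2, 24, 2)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Column", y = "Row", fill = value) +
    ggplot2::coord_fixed()
}

#' Run-versus-run concordance scatter of per-compound NFS
#'
#' @param compounds Per-compound tibble from [run_screen_pipeline()]
#'   (`nfs_run1`, `nfs_run2`, `confirmed`).
#' @return A ggplot with the identity line; confirmed hits highlighted.
#' @export
plot_concordance <- function(compounds) {
  stopifnot(all(c("nfs_run1", "nfs_run2") %in% names(compounds)))
  p <- ggplot2::ggplot(compounds,
                       ggplot2::aes(x = .data$nfs_run1, y = .data$nfs_run2)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey70") +
    ggplot2::labs(x = "NFS, run 1", y = "NFS, run 2")
  if ("confirmed" %in% names(compounds)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$confirmed),
                            alpha = 0.6) +
      ggplot2::scale_color_manual(values = c(`FALSE` = "grey30",
                                             `TRUE` = "firebrick"),
                                  name = "Both-run hit")
  } else {
    p + ggplot2::geom_point(alpha = 0.6)
  }
}

#' NFS distribution of test wells with the hit threshold
#'
#' @param normalized Normalized well tibble (role `TEST`, column `nfs`).
#' @param threshold Run hit threshold from [hit_threshold()].
#' @return A ggplot histogram with a vertical line at the threshold.
#' @export
plot_nfs_distribution <- function(normalized, threshold) {
  test <- normalized[normalized$role == "TEST" & !is.na(normalized$nfs), ]
  ggplot2::ggplot(test, ggplot2::aes(x = .data$nfs)) +
    ggplot2::geom_histogram(bins = 80, fill = "steelblue", color = "white") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                        color = "firebrick") +
    ggplot2::labs(x = "Normalized fluorescent signal",
                  y = "Test wells",
                  subtitle = sprintf("hit threshold (mean - 3 SD) = %.3f",
                                     threshold))
}

#' Selectivity-profile dot plot
#'
#' Per-compound mean efflux inhibition at each subtype, faceted by
#' selectivity group.
#'
#' @param profiles Tibble from [selectivity_profiles()].
#' @return A ggplot.
#' @export
plot_selectivity <- function(profiles) {
  long <- tidyr::pivot_longer(
    profiles[, c("compound_id", "group", "inh_a3b4", "inh_a4b2", "inh_a6")],
    dplyr::starts_with("inh_"), names_to = "subtype", values_to = "inhibition",
    names_prefix = "inh_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$compound_id,
                                     y = .data$inhibition,
                                     color = .data$subtype)) +
    ggplot2::geom_point() +
    ggplot2::facet_grid(. ~ group, scales = "free_x", space = "free_x") +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "Compound", y = "Specific-efflux inhibition (%)",
                  color = "Subtype")
}
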