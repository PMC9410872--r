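#' Plot an A/H/B genotype matrix
#'
#' Tile plot of genotype codes, markers on the y axis, individuals on x.
#'
#' @param object A `geno_matrix` tibble ([build_genotype_matrix()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.geno_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"marker_id",
                              names_to = "individual", values_to = "code")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$individual,
                                     y = .data$marker_id,
                                     fill = .data$code)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(A = "#1b9e77", H = "#7570b3",
                                          B = "#d95f02", `-` = "grey85"),
                               name = "genotype") +
    ggplot2::labs(x = "F2 individual", y = "marker") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot a two-point linkage scan
#'
#' LOD heatmap over marker pairs; markers ordered by linkage group.
#'
#' @param object A `linkage_scan` ([pairwise_linkage()]).
#' @param lod_threshold Threshold used for ordering groups.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.linkage_scan <- function(object, lod_threshold = 4.0, ...) {
  groups <- group_markers(object, lod_threshold)
  ord <- groups$marker_id
  pairs <- object$pairs |>
    mutate(marker1 = factor(.data$marker1, levels = ord),
           marker2 = factor(.data$marker2, levels = ord))
  both <- bind_rows(pairs,
                    pairs |> rename(marker1 = "marker2", marker2 = "marker1"))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$marker1, y = .data$marker2,
                                     fill = .data$lod)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "LOD") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Per-marker amplicon depth variability
#'
#' Mean and standard deviation of per-sample read depth for each marker,
#' the diagnostic view of between-marker amplification differences.
#'
#' @param depths Site-depth tibble ([read_depth_table()]).
#' @return A ggplot object.
#' @export
plot_marker_depths <- function(depths) {
  summ <- depths |>
    mutate(total = .data$ref_count + .data$alt_count) |>
    group_by(.data$marker_id) |>
    summarise(mean_depth = mean(.data$total), sd_depth = stats::sd(.data$total),
              .groups = "drop") |>
    arrange(desc(.data$mean_depth)) |>
    mutate(rank = row_number())
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$rank, y = .data$mean_depth)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$mean_depth - .data$sd_depth, 0),
      ymax = .data$mean_depth + .data$sd_depth), linewidth = 0.3, size = 0.2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "marker (ranked by mean depth)",
                  y = "reads per sample (mean ± SD)") +
    ggplot2::theme_minimal(base_size = 9)
}
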