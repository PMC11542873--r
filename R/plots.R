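#' Detection outcome against sequencing depth
#'
#' One bar per sample, height the sequencing depth (log scale), colored by
#' the joint MAG/rRNA screening outcome, faceted by taxon; samples ordered
#' by outcome then depth. The layout that shows at a glance that rRNA-only
#' detections concentrate at low depth while persistent non-detections at
#' high depth suggest true absence.
#'
#' @param outcomes Output of [classify_detection_outcome()] with depths.
#' @param taxa Optional subset of taxa to facet.
#' @return A ggplot object.
#' @export
plot_detection_depth <- function(outcomes, taxa = NULL) {
  stopifnot(all(c("taxon", "outcome", "total_depth_bp") %in% names(outcomes)))
  if (!is.null(taxa)) outcomes <- outcomes |> filter(.data$taxon %in% taxa)
  outcomes <- outcomes |>
    group_by(.data$taxon) |>
    arrange(.data$outcome, desc(.data$total_depth_bp), .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
  ggplot2::ggplot(outcomes,
                  ggplot2::aes(x = .data$rank, y = .data$total_depth_bp,
                               fill = .data$outcome)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$taxon)) +
    ggplot2::labs(x = "sample (sorted by outcome, depth)",
                  y = "sequencing depth (bp)", fill = "screening outcome") +
    ggplot2::theme_minimal()
}

#' Module completeness heatmap
#'
#' Genome-by-module tiles filled by the fraction of present blocks.
#'
#' @param completeness Output of [completeness_table()].
#' @return A ggplot object.
#' @export
plot_module_completeness <- function(completeness) {
  stopifnot(all(c("genome_id", "module_id", "fraction") %in% names(completeness)))
  ggplot2::ggplot(completeness,
                  ggplot2::aes(x = .data$module_id, y = .data$genome_id,
                               fill = .data$fraction)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue4",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "present blocks") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn build_cooccurrence Plot the network (Fruchterman-Reingold
#'   layout; edge width by shared-sample count, node color by class).
#' @param object A `cooccurrence_network`.
#' @method autoplot cooccurrence_network
#' @export
autoplot.cooccurrence_network <- function(object, ...) {
  g <- as_igraph(object)
  set.seed(igraph::vcount(g)) # layout reproducibility only
  xy <- igraph::layout_with_fr(g)
  nodes <- object$nodes |> mutate(x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    left_join(nodes |> select("lineage", xa = "x", ya = "y"),
              by = c(lineage_a = "lineage")) |>
    left_join(nodes |> select("lineage", xb = "x", yb = "y"),
              by = c(lineage_b = "lineage"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, linewidth = .data$weight),
      color = "grey70", alpha = 0.7) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$class,
                   size = .data$n_samples)) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::labs(color = "role", size = "samples",
                  linewidth = "shared samples") +
    ggplot2::theme_void()
}

#' MAG recovery against sequencing depth
#'
#' One point per sample: number of species called present against total
#' sequencing depth, with a smoother. The positive, saturating relationship
#' is the depth dependence that makes absence calls unsafe in shallow
#' metagenomes.
#'
#' @param run A `census_run`.
#' @param manifest The (deduplicated) manifest with `total_depth_bp`.
#' @return A ggplot object.
#' @export
plot_recovery_by_depth <- function(run, manifest = run$dedup$manifest) {
  stopifnot(inherits(run, "census_run"))
  counts <- present_calls(run$occurrence) |>
    count(.data$sample_id, name = "n_mags")
  df <- manifest |>
    select("sample_id", "total_depth_bp") |>
    left_join(counts, by = "sample_id") |>
    mutate(n_mags = dplyr::coalesce(.data$n_mags, 0L))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$total_depth_bp, y = .data$n_mags)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "gam", formula = y ~ s(x, k = 5),
                         se = FALSE, color = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "sequencing depth (bp)", y = "species recovered as MAGs") +
    ggplot2::theme_minimal()
}
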