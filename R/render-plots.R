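#' @import ggplot2
NULL

save_plot <- function(p, path, width = 7, height = 5.5) {
  grDevices::png(path, width = width, height = height, units = "in",
                 res = 110)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}

#' Write assessment plots
#'
#' Static PNG plots plus, for every plot, the numeric series behind it as a
#' TSV (so results remain testable without image comparison). Families:
#'
#' * spider (radar) plots of completeness and purity per rank (absolute),
#'   and of completeness, purity, false positives, L1 norm and weighted
#'   UniFrac normalized by the per-metric maximum across tools (relative);
#'   both need at least three profilers and are skipped with a notice
#'   otherwise;
#' * Shannon equitability versus rank per tool, with the gold standard;
#' * Bray-Curtis beta-diversity scatter per rank, facetted by tool;
#' * stacked ranking bar chart (weighted per-metric scores);
#' * gold taxa-proportion stacked bars per rank;
#' * rarefaction and accumulation curves, linear and log10 scale.
#'
#' @param bundle An `assessment_bundle` from [run_assessment()].
#' @param outdir Output directory; plots go to `<outdir>/plots`.
#' @return Invisibly, the paths written.
#' @export
render_plots <- function(bundle, outdir) {
  pdir <- file.path(outdir, "plots")
  dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  ranks_used <- intersect(MAJOR_RANKS, unique(bundle$metric_table$rank))
  tools <- bundle$provenance$tools

  spider_data <- spider_series(bundle, ranks_used)
  paths <- c(paths, write_tsv_det(spider_data,
                                  file.path(pdir, "spider_series.tsv")))
  if (length(tools) >= 3) {
    for (r in ranks_used) {
      abs_d <- spider_data[spider_data$rank == r &
                             spider_data$metric %in%
                               c("completeness", "purity"), ]
      paths <- c(paths, save_plot(
        spider_plot(abs_d, "value",
                    paste("Completeness and purity:", r)),
        file.path(pdir, paste0("spider_absolute_", r, ".png"))
      ))
      rel_d <- spider_data[spider_data$rank == r & !is.na(spider_data$relative), ]
      paths <- c(paths, save_plot(
        spider_plot(rel_d, "relative",
                    paste("Relative performance:", r)),
        file.path(pdir, paste0("spider_relative_", r, ".png"))
      ))
    }
  } else {
    message("fewer than three profilers: spider plots skipped")
  }

  eq <- bundle$diversity |>
    dplyr::group_by(.data$tool_label, .data$rank) |>
    dplyr::summarise(shannon_e = mean_or_na(.data$shannon_e),
                     richness = mean_or_na(.data$richness),
                     .groups = "drop")
  paths <- c(paths, write_tsv_det(eq, file.path(pdir, "shannon_equitability.tsv")))
  eq_plot <- eq[!is.na(eq$shannon_e), ]
  if (nrow(eq_plot) > 0) {
    eq_plot$rank <- factor(eq_plot$rank, levels = MAJOR_RANKS)
    paths <- c(paths, save_plot(
      ggplot(eq_plot, aes(x = .data$rank, y = .data$shannon_e,
                          group = .data$tool_label,
                          colour = .data$tool_label)) +
        geom_line() + geom_point() + ylim(0, 1) +
        labs(title = "Shannon equitability by rank", x = NULL,
             y = "Shannon equitability", colour = "tool") +
        theme_minimal() +
        theme(axis.text.x = element_text(angle = 45, hjust = 1)),
      file.path(pdir, "shannon_equitability.png")
    ))
  }

  if (nrow(bundle$beta_points) > 0) {
    paths <- c(paths, write_tsv_det(bundle$beta_points,
                                    file.path(pdir, "braycurtis_points.tsv")))
    for (r in intersect(ranks_used, unique(bundle$beta_points$rank))) {
      bp <- bundle$beta_points[bundle$beta_points$rank == r, ]
      paths <- c(paths, save_plot(
        ggplot(bp, aes(x = .data$d_pred, y = .data$d_gold)) +
          geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                      colour = "grey50") +
          geom_point(alpha = 0.6) +
          facet_wrap(~tool_label) +
          coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
          labs(title = paste("Bray-Curtis beta diversity:", r),
               x = "distance between predictions",
               y = "distance between gold standards") +
          theme_minimal(),
        file.path(pdir, paste0("braycurtis_", r, ".png"))
      ))
    }
  }

  sb <- bundle$scoreboard
  rank_bars <- sb$per_metric |>
    dplyr::mutate(weighted =
                    .data$score * sb$config$weights[.data$metric])
  paths <- c(paths, write_tsv_det(rank_bars,
                                  file.path(pdir, "ranking_scores.tsv")))
  paths <- c(paths, save_plot(
    ggplot(rank_bars, aes(x = stats::reorder(.data$tool_label,
                                             .data$weighted,
                                             function(x) sum(x)),
                          y = .data$weighted, fill = .data$metric)) +
      geom_col() +
      labs(title = "Ranking (weighted scores; lower is better)",
           x = NULL, y = "weighted score", fill = "metric") +
      theme_minimal() +
      theme(axis.text.x = element_text(angle = 45, hjust = 1)),
    file.path(pdir, "ranking_scores.png")
  ))

  if (nrow(bundle$proportions) > 0) {
    paths <- c(paths, write_tsv_det(bundle$proportions,
                                    file.path(pdir, "taxa_proportions.tsv")))
    for (r in intersect(ranks_used, unique(bundle$proportions$rank))) {
      pr <- bundle$proportions[bundle$proportions$rank == r, ]
      paths <- c(paths, save_plot(
        ggplot(pr, aes(x = .data$sample_id, y = .data$abundance,
                       fill = .data$taxid)) +
          geom_col() +
          labs(title = paste("Gold-standard taxa proportions:", r),
               x = NULL, y = "relative abundance") +
          theme_minimal() +
          theme(legend.position = if (length(unique(pr$taxid)) <= 12)
            "right" else "none",
            axis.text.x = element_text(angle = 45, hjust = 1)),
        file.path(pdir, paste0("taxa_proportions_", r, ".png"))
      ))
    }
  }

  if (nrow(bundle$curves) > 0) {
    paths <- c(paths, write_tsv_det(bundle$curves,
                                    file.path(pdir, "rarefaction_curves.tsv")))
    cv <- bundle$curves
    cv$rank <- factor(cv$rank, levels = MAJOR_RANKS)
    base <- ggplot(cv, aes(x = .data$k, y = .data$taxa, colour = .data$rank,
                           linetype = .data$curve)) +
      geom_line() + geom_point(size = 0.8) +
      labs(title = "Rarefaction and accumulation curves",
           x = "number of samples", y = "distinct taxa") +
      theme_minimal()
    paths <- c(paths, save_plot(base,
                                file.path(pdir, "rarefaction_curves.png")))
    paths <- c(paths, save_plot(
      base + scale_y_log10() +
        labs(title = "Rarefaction and accumulation curves (log10)"),
      file.path(pdir, "rarefaction_curves_log10.png")
    ))
  }
  invisible(paths)
}

# Per-rank per-tool mean metric values for the spider plots, with the
# relative variant normalized by the per-metric maximum across tools.
spider_series <- function(bundle, ranks_used) {
  rel_metrics <- c("completeness", "purity", "fp", "l1", "unifrac_w")
  means <- bundle$metric_table |>
    dplyr::filter(.data$metric %in% rel_metrics) |>
    dplyr::group_by(.data$tool_label, .data$rank, .data$metric) |>
    dplyr::summarise(value = mean_or_na(.data$value), .groups = "drop")
  # weighted UniFrac is a per-sample, whole-tree value (rank "all");
  # replicate it across ranks for the relative plots
  uf <- means[means$rank == "all", ]
  means <- means[means$rank != "all", ]
  if (nrow(uf) > 0) {
    means <- dplyr::bind_rows(means, dplyr::bind_rows(lapply(
      ranks_used, function(r) dplyr::mutate(uf, rank = r)
    )))
  }
  means |>
    dplyr::group_by(.data$rank, .data$metric) |>
    dplyr::mutate(relative = {
      mx <- max(.data$value, na.rm = TRUE)
      if (!is.finite(mx) || mx == 0) NA_real_ else .data$value / mx
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$rank, .data$metric, .data$tool_label)
}

# Radar chart: spokes are profilers, coloured polygons are metrics.
spider_plot <- function(d, value_col, title) {
  d <- d[!is.na(d[[value_col]]), ]
  d$tool_label <- factor(d$tool_label)
  d$spoke <- as.integer(d$tool_label)
  # close each polygon by repeating the first spoke one step past the last
  closing <- d[d$spoke == 1, ]
  closing$spoke <- nlevels(d$tool_label) + 1
  closed <- dplyr::bind_rows(d, closing)
  ggplot(closed, aes(x = .data$spoke, y = .data[[value_col]],
                     colour = .data$metric, group = .data$metric)) +
    geom_line() +
    geom_point(data = d) +
    scale_x_continuous(breaks = seq_along(levels(d$tool_label)),
                       labels = levels(d$tool_label),
                       limits = c(1, nlevels(d$tool_label) + 1)) +
    coord_polar() +
    labs(title = title, x = NULL, y = NULL, colour = "metric") +
    theme_minimal()
}
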