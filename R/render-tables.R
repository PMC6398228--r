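# Deterministic number formatting for flat files; NA is always "na", never 0.
fmt_num <- function(x) {
  ifelse(is.na(x), "na", sprintf("%.10g", x))
}

write_tsv_det <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- fmt_num(df[[col]])
    df[[col]][is.na(df[[col]])] <- "na"
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write assessment tables
#'
#' Writes (a) `results.tsv`, the long tidy table with one value per (tool,
#' sample, rank, metric); (b) `by_tool/<label>.tsv`, one wide rank-by-metric
#' table per tool with values averaged over samples; (c) `by_rank/<rank>.tsv`,
#' one wide tool-by-metric table per rank with cells "mean (standard error)"
#' across samples. NA cells are rendered as "na" and excluded from means and
#' from the n of the standard error.
#'
#' @param bundle An `assessment_bundle` from [run_assessment()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
render_tables <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "by_tool"), showWarnings = FALSE)
  dir.create(file.path(outdir, "by_rank"), showWarnings = FALSE)
  paths <- character()

  tidy <- bundle$metric_table |>
    dplyr::arrange(.data$tool_label, .data$sample_id,
                   match(.data$rank, c(MAJOR_RANKS, "all")), .data$metric)
  paths <- c(paths, write_tsv_det(tidy, file.path(outdir, "results.tsv")))

  for (tool in bundle$provenance$tools) {
    wide <- bundle$metric_table |>
      dplyr::filter(.data$tool_label == tool) |>
      dplyr::group_by(.data$rank, .data$metric) |>
      dplyr::summarise(value = mean_or_na(.data$value), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "metric", values_from = "value") |>
      dplyr::arrange(match(.data$rank, c(MAJOR_RANKS, "all")))
    paths <- c(paths, write_tsv_det(
      wide, file.path(outdir, "by_tool", paste0(sanitize_label(tool), ".tsv"))
    ))
  }

  for (r in unique(bundle$metric_table$rank)) {
    wide <- bundle$metric_table |>
      dplyr::filter(.data$rank == r) |>
      dplyr::group_by(.data$tool_label, .data$metric) |>
      dplyr::summarise(cell = mean_se_cell(.data$value), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "metric", values_from = "cell") |>
      dplyr::arrange(.data$tool_label)
    paths <- c(paths, write_tsv_det(
      wide, file.path(outdir, "by_rank", paste0(r, ".tsv"))
    ))
  }
  invisible(paths)
}

mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else mean(x)
}

# "mean (standard error)" across samples; se = sd/sqrt(n) over non-NA values.
mean_se_cell <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return("na")
  se <- if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else 0
  sprintf("%.3g (%.2g)", mean(x), se)
}

sanitize_label <- function(x) {
  gsub("[^A-Za-z0-9._-]", "_", x)
}
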