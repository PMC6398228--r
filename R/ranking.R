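#' Ranking configuration
#'
#' Weights for the ranked metrics. The default ranked set is completeness,
#' purity, L1 norm, and weighted UniFrac, each with weight 1. Weights range
#' from 0 to 10 in steps of 0.1 (values are quantized to the nearest step).
#'
#' @param weights Named numeric vector (metric name -> weight in [0, 10]).
#' @return Object of class `ranking_config` with elements `weights` and
#'   `directions`.
#' @export
ranking_config <- function(weights = c(completeness = 1, purity = 1,
                                       l1 = 1, unifrac_w = 1)) {
  if (length(weights) == 0 || is.null(names(weights)) ||
      any(!nzchar(names(weights)))) {
    stop("weights must be a named numeric vector")
  }
  unknown <- setdiff(names(weights), names(METRIC_DIRECTIONS))
  if (length(unknown) > 0) {
    stop("unknown or unrankable metric(s) in weights: ",
         paste(unknown, collapse = ", "))
  }
  if (any(weights < 0 | weights > 10)) {
    stop("weights must lie in [0, 10]")
  }
  weights <- round(weights * 10) / 10
  structure(list(weights = weights,
                 directions = METRIC_DIRECTIONS[names(weights)]),
            class = "ranking_config")
}

#' Score tools within one (metric, rank, sample) cell
#'
#' The best-performing tool gets score 0, the second best 1, and so on
#' (competition ranking: tied tools share the better, i.e. minimum, score;
#' a tool's score is the number of tools strictly better than it). NA values
#' are worst in the cell: every non-NA tool is strictly better.
#'
#' @param values Named numeric vector (tool label -> metric value, NA
#'   allowed).
#' @param direction "higher_better" or "lower_better".
#' @return Named integer vector of scores.
#' @export
cell_scores <- function(values,
                        direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  stopifnot(length(values) >= 1, !is.null(names(values)))
  v <- if (direction == "lower_better") -as.numeric(values)
       else as.numeric(values)
  n_better <- vapply(seq_along(v), function(i) {
    if (is.na(v[i])) return(sum(!is.na(v)))
    sum(v > v[i], na.rm = TRUE)
  }, 0L)
  stats::setNames(as.integer(n_better), names(values))
}

#' Aggregate per-cell scores into a weighted scoreboard
#'
#' For every ranked metric, scores from each (rank, sample) cell are summed
#' into a single per-metric score per tool, and the overall score is the
#' weighted sum of the per-metric scores. Lower is better throughout; a tool
#' that is best in every cell gets overall score 0.
#'
#' @param metric_table Tidy tibble with columns `tool_label`, `sample_id`,
#'   `rank`, `metric`, `value`, covering every tool in every cell of the
#'   ranked metrics (NA values allowed).
#' @param config A [ranking_config()].
#' @return Object of class `scoreboard`: list with `per_metric` (tibble
#'   `tool_label`, `metric`, `score`), `overall` (tibble `tool_label`,
#'   `score`, sorted best first, ties broken alphabetically for display),
#'   and `config`.
#' @export
aggregate_scores <- function(metric_table, config = ranking_config()) {
  stopifnot(inherits(config, "ranking_config"))
  tools <- sort(unique(metric_table$tool_label))
  per_metric <- list()
  for (m in names(config$weights)) {
    sub <- metric_table[metric_table$metric == m, ]
    total <- stats::setNames(rep(0L, length(tools)), tools)
    if (nrow(sub) > 0) {
      cells <- split(sub, paste(sub$rank, sub$sample_id, sep = "\r"))
      for (cell in cells) {
        values <- stats::setNames(rep(NA_real_, length(tools)), tools)
        values[cell$tool_label] <- cell$value
        total <- total + cell_scores(values, config$directions[[m]])
      }
    }
    per_metric[[m]] <- tibble(tool_label = tools, metric = m,
                              score = as.integer(total))
  }
  per_metric <- dplyr::bind_rows(per_metric)
  overall <- per_metric |>
    dplyr::mutate(weighted = .data$score * config$weights[.data$metric]) |>
    dplyr::group_by(.data$tool_label) |>
    dplyr::summarise(score = sum(.data$weighted), .groups = "drop") |>
    dplyr::arrange(.data$score, .data$tool_label)
  structure(list(per_metric = per_metric, overall = overall,
                 config = config),
            class = "scoreboard")
}

#' @export
print.scoreboard <- function(x, ...) {
  cat("<scoreboard> (lower is better)\n")
  print(x$overall, n = Inf)
  invisible(x)
}
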