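#' Write the self-contained HTML report
#'
#' One static page (opens from file:// with no network access) embedding the
#' ranking, per-rank metric tables with a best-to-worst colour scale per
#' metric column (dark blue best, dark red worst, grey for NA), and the
#' rendered plot images inlined as base64. Table columns are sortable
#' client-side, so the profilers can be re-ranked by any single metric.
#'
#' @param bundle An `assessment_bundle` from [run_assessment()].
#' @param outdir Output directory; the page is `<outdir>/report.html` and
#'   images are taken from `<outdir>/plots` (run [render_plots()] first).
#' @return Invisibly, the report path.
#' @export
render_html <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(outdir, "report.html")
  parts <- c(html_head(), "<body>",
             "<h1>Taxonomic profiler assessment</h1>",
             sprintf("<p>Tools: %s &mdash; %d sample(s) &mdash; profassess %s</p>",
                     paste(bundle$provenance$tools, collapse = ", "),
                     length(bundle$provenance$samples),
                     bundle$provenance$version))

  parts <- c(parts, "<h2>Ranking (lower score is better)</h2>",
             html_scoreboard(bundle$scoreboard),
             embed_image(file.path(outdir, "plots", "ranking_scores.png")))

  parts <- c(parts, "<h2>Per-rank results (mean over samples)</h2>")
  ranks_used <- intersect(c(MAJOR_RANKS, "all"),
                          unique(bundle$metric_table$rank))
  for (r in ranks_used) {
    parts <- c(parts, sprintf("<h3>%s</h3>", r), html_rank_table(bundle, r))
  }

  parts <- c(parts, "<h2>Plots</h2>")
  pngs <- sort(list.files(file.path(outdir, "plots"), pattern = "\\.png$",
                          full.names = TRUE))
  pngs <- setdiff(pngs, file.path(outdir, "plots", "ranking_scores.png"))
  for (f in pngs) parts <- c(parts, embed_image(f))

  parts <- c(parts, html_sort_script(), "</body></html>")
  writeLines(parts, path)
  invisible(path)
}

html_head <- function() {
  paste0(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\">",
    "<title>Taxonomic profiler assessment</title><style>",
    "body{font-family:sans-serif;margin:2em;max-width:1100px}",
    "table{border-collapse:collapse;margin:1em 0}",
    "th,td{border:1px solid #ccc;padding:4px 8px;text-align:right}",
    "th{background:#f0f0f0;cursor:pointer}",
    "td.label{text-align:left;font-weight:bold}",
    "img{max-width:100%;margin:0.5em 0}",
    "</style></head>"
  )
}

html_scoreboard <- function(sb) {
  wide <- sb$per_metric |>
    tidyr::pivot_wider(names_from = "metric", values_from = "score") |>
    dplyr::left_join(dplyr::rename(sb$overall, overall = "score"),
                     by = "tool_label") |>
    dplyr::arrange(.data$overall, .data$tool_label)
  cols <- setdiff(names(wide), "tool_label")
  header <- paste0("<tr><th>tool</th>",
                   paste0("<th>", cols, "</th>", collapse = ""), "</tr>")
  rows <- vapply(seq_len(nrow(wide)), function(i) {
    paste0("<tr><td class=\"label\">", wide$tool_label[i], "</td>",
           paste0("<td>", unlist(wide[i, cols]), "</td>", collapse = ""),
           "</tr>")
  }, "")
  paste0("<table class=\"sortable\"><thead>", header, "</thead><tbody>",
         paste(rows, collapse = ""), "</tbody></table>")
}

# Colour scale per metric column: dark blue (best) to dark red (worst).
metric_cell_colour <- function(values, direction) {
  ok <- !is.na(values)
  out <- rep("#dddddd", length(values))
  if (!any(ok)) return(out)
  v <- values
  if (identical(direction, "lower_better")) v <- -v
  lo <- min(v[ok])
  hi <- max(v[ok])
  frac <- if (hi > lo) (v - lo) / (hi - lo) else rep(1, length(v))
  ramp <- grDevices::colorRamp(c("#8b0000", "#f5f5f5", "#00008b"))
  cols <- ramp(pmin(pmax(frac[ok], 0), 1))
  out[ok] <- grDevices::rgb(cols[, 1], cols[, 2], cols[, 3],
                            maxColorValue = 255)
  out
}

html_rank_table <- function(bundle, r) {
  sub <- bundle$metric_table[bundle$metric_table$rank == r, ]
  agg <- sub |>
    dplyr::group_by(.data$tool_label, .data$metric) |>
    dplyr::summarise(mean = mean_or_na(.data$value),
                     cell = mean_se_cell(.data$value), .groups = "drop")
  metrics <- intersect(METRIC_REGISTRY, unique(agg$metric))
  tools <- sort(unique(agg$tool_label))
  header <- paste0("<tr><th>tool</th>",
                   paste0("<th>", metrics, "</th>", collapse = ""), "</tr>")
  cells <- matrix("", length(tools), length(metrics),
                  dimnames = list(tools, metrics))
  for (m in metrics) {
    am <- agg[agg$metric == m, ]
    means <- stats::setNames(rep(NA_real_, length(tools)), tools)
    means[am$tool_label] <- am$mean
    dirn <- METRIC_DIRECTIONS[m]
    colours <- metric_cell_colour(means, if (is.na(dirn)) "higher_better"
                                  else dirn)
    text <- stats::setNames(rep("na", length(tools)), tools)
    text[am$tool_label] <- am$cell
    cells[, m] <- sprintf("<td style=\"background:%s\">%s</td>",
                          colours, text)
  }
  rows <- vapply(tools, function(t) {
    paste0("<tr><td class=\"label\">", t, "</td>",
           paste(cells[t, ], collapse = ""), "</tr>")
  }, "")
  paste0("<table class=\"sortable\"><thead>", header, "</thead><tbody>",
         paste(rows, collapse = ""), "</tbody></table>")
}

embed_image <- function(path) {
  if (!file.exists(path)) return("")
  raw <- readBin(path, "raw", file.info(path)$size)
  sprintf("<img src=\"data:image/png;base64,%s\" alt=\"%s\">",
          jsonlite::base64_enc(raw), basename(path))
}

# Minimal client-side column sorting: click a header to sort by that column
# (numeric-aware, "x (se)" cells sorted by x, "na" always last).
html_sort_script <- function() {
  paste0(
    "<script>",
    "document.querySelectorAll('table.sortable th').forEach(function(th){",
    "th.addEventListener('click',function(){",
    "var table=th.closest('table');var tbody=table.querySelector('tbody');",
    "var idx=Array.prototype.indexOf.call(th.parentNode.children,th);",
    "var asc=!(th.dataset.asc==='true');th.dataset.asc=asc;",
    "var rows=Array.prototype.slice.call(tbody.querySelectorAll('tr'));",
    "rows.sort(function(a,b){",
    "var ta=a.children[idx].textContent.trim();",
    "var tb=b.children[idx].textContent.trim();",
    "var na=parseFloat(ta);var nb=parseFloat(tb);",
    "if(isNaN(na)&&isNaN(nb))return ta<tb?-1:1;",
    "if(isNaN(na))return 1;if(isNaN(nb))return -1;",
    "return asc?na-nb:nb-na;});",
    "rows.forEach(function(r){tbody.appendChild(r);});",
    "});});",
    "</script>"
  )
}

#' Render every output of an assessment
#'
#' Convenience wrapper: [render_tables()], [render_plots()],
#' [render_html()], plus a `run.log` echoing the inputs and configuration.
#'
#' @param bundle An `assessment_bundle`.
#' @param outdir Output directory.
#' @return Invisibly, `outdir`.
#' @export
render_all <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  render_tables(bundle, outdir)
  render_plots(bundle, outdir)
  render_html(bundle, outdir)
  cfg <- bundle$provenance$config
  writeLines(c(
    paste0("profassess ", bundle$provenance$version),
    paste0("tools: ", paste(bundle$provenance$tools, collapse = ", ")),
    paste0("samples: ", paste(bundle$provenance$samples, collapse = ", ")),
    if (!is.null(bundle$provenance$input_paths)) {
      paste0("input ", names(bundle$provenance$input_paths), ": ",
             bundle$provenance$input_paths)
    },
    paste0("normalize: ", cfg$normalize),
    paste0("ranks: ", paste(cfg$ranks, collapse = ",")),
    paste0("weights: ", paste(names(cfg$ranking$weights),
                              cfg$ranking$weights,
                              sep = "=", collapse = ",")),
    paste0("seed: ", cfg$seed)
  ), file.path(outdir, "run.log"))
  invisible(outdir)
}
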