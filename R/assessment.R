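#' Assessment configuration
#'
#' @param normalize Normalize all profiles per rank before computing metrics
#'   (default TRUE; disabling it biases results towards tools that predict
#'   only part of the sample).
#' @param ranks Ranks to assess (default all eight major ranks).
#' @param weights Named weights for the ranking, see [ranking_config()].
#' @param rarefaction_n_perm Permutations for the rarefaction curve.
#' @param seed Seed for the (only) stochastic step, rarefaction.
#' @param strict Strict profile parsing (see [parse_cami_profile()]).
#' @param format Input format, "cami" or "biom".
#' @return Object of class `assessment_config`.
#' @export
assessment_config <- function(normalize = TRUE, ranks = MAJOR_RANKS,
                              weights = c(completeness = 1, purity = 1,
                                          l1 = 1, unifrac_w = 1),
                              rarefaction_n_perm = 100, seed = 42,
                              strict = FALSE,
                              format = c("cami", "biom")) {
  stopifnot(all(ranks %in% MAJOR_RANKS))
  structure(list(normalize = normalize, ranks = ranks,
                 ranking = ranking_config(weights),
                 rarefaction_n_perm = rarefaction_n_perm, seed = seed,
                 strict = strict, format = match.arg(format)),
            class = "assessment_config")
}

#' Run the full profiler assessment
#'
#' Deterministic pipeline: parse, normalize (unless disabled), per-sample /
#' per-rank presence and abundance metrics, per-sample UniFrac, alpha
#' diversity, beta-diversity scatter data, gold accumulation/rarefaction
#' curves and taxa proportions, and the weighted ranking. Identical inputs
#' and configuration produce identical outputs.
#'
#' A tool with no profile for some gold sample is scored on that sample as
#' an all-empty prediction (completeness 0, purity NA), never excluded: the
#' ranking sums over all samples, so exclusion would reward non-reporting.
#' A tool whose (non-empty) profile has no entries at some rank gets NA for
#' every metric at that rank.
#'
#' @param gold Path to the gold-standard profile, or a named list of gold
#'   [sample_profile]s.
#' @param predictions Character vector of prediction file paths, or a named
#'   list (tool label -> named list of [sample_profile]s).
#' @param labels Tool labels aligned with `predictions` paths (default:
#'   file stems).
#' @param config An [assessment_config()].
#' @return Object of class `assessment_bundle`: list with `metric_table`
#'   (tidy tibble tool_label/sample_id/rank/metric/value), `diversity`
#'   (includes the gold standard), `beta_points`, `curves`, `proportions`,
#'   `scoreboard`, `profiles`, and `provenance`.
#' @export
run_assessment <- function(gold, predictions, labels = NULL,
                           config = assessment_config()) {
  parse_any <- function(path, label) {
    if (config$format == "biom") parse_biom(path, label)
    else parse_cami_profile(path, label, strict = config$strict)
  }
  input_paths <- NULL
  if (is.character(gold)) {
    input_paths <- c(gold = gold)
    gold <- parse_any(gold, "gold")
  }
  if (is.character(predictions)) {
    if (is.null(labels)) {
      labels <- sub("\\.[^.]*$", "", basename(predictions))
    }
    stopifnot(length(labels) == length(predictions))
    input_paths <- c(input_paths, stats::setNames(predictions, labels))
    predictions <- stats::setNames(
      lapply(seq_along(predictions),
             function(i) parse_any(predictions[i], labels[i])),
      labels
    )
  }
  if (length(predictions) == 0) stop("at least one prediction is required")
  gold_ids <- names(gold)
  for (tool in names(predictions)) {
    if (length(intersect(names(predictions[[tool]]), gold_ids)) == 0) {
      stop("tool '", tool, "' shares no sample ids with the gold standard")
    }
  }
  pset <- profile_set(gold, predictions)

  # fill missing samples with empty predictions
  for (tool in names(pset$predictions)) {
    for (sid in setdiff(gold_ids, names(pset$predictions[[tool]]))) {
      pset$predictions[[tool]][[sid]] <- sample_profile(sid, tool)
    }
  }
  if (config$normalize) {
    pset$gold <- lapply(pset$gold, normalize_profile)
    pset$predictions <- lapply(pset$predictions, function(ps) {
      lapply(ps, normalize_profile)
    })
  }

  metric_rows <- list()
  diversity_rows <- list()
  add_metrics <- function(tool, sid, rank, values) {
    metric_rows[[length(metric_rows) + 1]] <<- tibble(
      tool_label = tool, sample_id = sid, rank = rank,
      metric = names(values), value = as.numeric(values)
    )
  }
  add_diversity <- function(tool, sid, rank, d) {
    diversity_rows[[length(diversity_rows) + 1]] <<- tibble(
      tool_label = tool, sample_id = sid, rank = rank,
      richness = d$richness, shannon_h = d$shannon_h,
      shannon_e = d$shannon_e
    )
  }
  for (sid in gold_ids) {
    gp <- pset$gold[[sid]]
    for (r in config$ranks) {
      add_diversity("gold", sid, r, shannon(get_rank_vector(gp, r)))
    }
    for (tool in names(pset$predictions)) {
      pp <- pset$predictions[[tool]][[sid]]
      pred_empty <- nrow(pp$entries) == 0
      for (r in config$ranks) {
        gv <- get_rank_vector(gp, r)
        pv <- get_rank_vector(pp, r)
        if (!pred_empty && length(pv) == 0) {
          # tool reported nothing at this rank (e.g. truncated output)
          na <- NA_real_
          add_metrics(tool, sid, r, c(
            tp = na, fp = na, fn = na, purity = na, completeness = na,
            f1 = na, jaccard = na, l1 = na, braycurtis = na,
            richness = na, shannon_h = na, shannon_e = na
          ))
          next
        }
        cc <- confusion(gv, pv)
        p <- purity(cc)
        s <- completeness(cc)
        d <- shannon(pv)
        add_metrics(tool, sid, r, c(
          tp = cc$tp, fp = cc$fp, fn = cc$fn,
          purity = p, completeness = s, f1 = f1(p, s),
          jaccard = jaccard(gv, pv),
          l1 = l1_norm(gv, pv), braycurtis = bray_curtis(gv, pv),
          richness = d$richness, shannon_h = d$shannon_h,
          shannon_e = d$shannon_e
        ))
        add_diversity(tool, sid, r, d)
      }
      uf <- unifrac_pair(gp, pp)
      add_metrics(tool, sid, "all",
                  c(unifrac_w = uf[["weighted"]],
                    unifrac_uw = uf[["unweighted"]]))
    }
  }
  metric_table <- dplyr::bind_rows(metric_rows)
  diversity <- dplyr::bind_rows(diversity_rows)

  beta_points <- dplyr::bind_rows(lapply(names(pset$predictions), function(tool) {
    dplyr::bind_rows(lapply(config$ranks, function(r) {
      beta_scatter(pset$predictions[[tool]], pset$gold, r)
    }))
  }))
  gold_beta <- dplyr::bind_rows(lapply(config$ranks, function(r) {
    beta_scatter(pset$gold, pset$gold, r)
  }))
  if (nrow(gold_beta) > 0) gold_beta$tool_label <- "gold"

  curves <- dplyr::bind_rows(lapply(config$ranks, function(r) {
    acc <- accumulation_curve(pset$gold, r)
    rar <- rarefaction_curve(pset$gold, r,
                             n_perm = config$rarefaction_n_perm,
                             seed = config$seed)
    dplyr::bind_rows(
      tibble(rank = r, curve = "accumulation", k = acc$k,
             taxa = as.numeric(acc$distinct_taxa)),
      tibble(rank = r, curve = "rarefaction", k = rar$k,
             taxa = rar$mean_distinct_taxa)
    )
  }))
  proportions <- dplyr::bind_rows(lapply(config$ranks, function(r) {
    tp <- taxa_proportions(pset$gold, r)
    if (nrow(tp) > 0) tp$rank <- r
    tp
  }))

  scoreboard <- aggregate_scores(metric_table, config$ranking)

  structure(list(
    metric_table = metric_table, diversity = diversity,
    beta_points = beta_points, gold_beta = gold_beta,
    curves = curves, proportions = proportions,
    scoreboard = scoreboard, profiles = pset,
    provenance = list(
      tools = names(pset$predictions), samples = gold_ids,
      input_paths = input_paths, config = config,
      version = as.character(utils::packageVersion("profassess"))
    )
  ), class = "assessment_bundle")
}

#' @export
print.assessment_bundle <- function(x, ...) {
  cat("<assessment_bundle>\n",
      " tools:   ", paste(x$provenance$tools, collapse = ", "), "\n",
      " samples: ", length(x$provenance$samples), "\n",
      " metrics: ", nrow(x$metric_table), " tidy rows\n", sep = "")
  print(x$scoreboard)
  invisible(x)
}
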