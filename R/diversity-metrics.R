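#' Alpha diversity of one rank vector
#'
#' Richness S (number of taxa with positive abundance), Shannon diversity
#' H = -sum(p * ln p) over the support (taxa with zero abundance are ignored
#' in the sum), and Shannon equitability E = H / ln(S). H ranges from 0 to
#' ln(S); E from 0 to 1, with 1 indicating complete evenness. E is NA when
#' S <= 1 (ln 1 = 0).
#'
#' @param v A normalized [rank_vector].
#' @return List with `richness`, `shannon_h` (nats), `shannon_e`.
#' @export
shannon <- function(v) {
  p <- as.numeric(v[v > 0])
  s <- length(p)
  h <- if (s == 0) 0 else -sum(p * log(p))
  e <- if (s >= 2) h / log(s) else NA_real_
  list(richness = s, shannon_h = h, shannon_e = e)
}

#' Beta-diversity scatter points for one tool at one rank
#'
#' For every unordered pair of samples, the Bray-Curtis distance between the
#' tool's predictions on the pair (`d_pred`) and between the gold standards
#' of the same pair (`d_gold`). A perfect profiler puts every point on the
#' line y = x.
#'
#' @param pred_profiles Named list of the tool's [sample_profile]s.
#' @param gold_profiles Named list of gold [sample_profile]s.
#' @param rank Rank name.
#' @return Tibble with columns `tool_label`, `rank`, `sample_1`, `sample_2`,
#'   `d_pred`, `d_gold`; empty with fewer than 2 shared samples.
#' @export
beta_scatter <- function(pred_profiles, gold_profiles, rank) {
  ids <- intersect(names(gold_profiles), names(pred_profiles))
  empty <- tibble(tool_label = character(), rank = character(),
                  sample_1 = character(), sample_2 = character(),
                  d_pred = numeric(), d_gold = numeric())
  if (length(ids) < 2) return(empty)
  label <- pred_profiles[[ids[1]]]$tool_label
  pairs <- utils::combn(ids, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    s1 <- pairs[1, k]
    s2 <- pairs[2, k]
    tibble(
      tool_label = label, rank = rank, sample_1 = s1, sample_2 = s2,
      d_pred = bray_curtis(get_rank_vector(pred_profiles[[s1]], rank),
                           get_rank_vector(pred_profiles[[s2]], rank)),
      d_gold = bray_curtis(get_rank_vector(gold_profiles[[s1]], rank),
                           get_rank_vector(gold_profiles[[s2]], rank))
    )
  })
  dplyr::bind_rows(rows)
}

#' Taxa accumulation curve at one rank
#'
#' Number of distinct gold-standard taxa seen in the first k samples, in the
#' samples' input order; non-decreasing in k.
#'
#' @param gold_profiles Named list of gold [sample_profile]s (input order).
#' @param rank Rank name.
#' @return Tibble with columns `k` and `distinct_taxa`.
#' @export
accumulation_curve <- function(gold_profiles, rank) {
  seen <- character()
  counts <- integer(length(gold_profiles))
  for (k in seq_along(gold_profiles)) {
    seen <- union(seen, support(get_rank_vector(gold_profiles[[k]], rank)))
    counts[k] <- length(seen)
  }
  tibble(k = seq_along(gold_profiles), distinct_taxa = counts)
}

#' Rarefaction curve at one rank
#'
#' Mean number of distinct taxa among k samples, averaged over random
#' orderings of the samples (Monte-Carlo permutations of the accumulation
#' curve). Deterministic under a fixed seed; its value at k = n equals the
#' accumulation curve's final value.
#'
#' @param gold_profiles Named list of gold [sample_profile]s.
#' @param rank Rank name.
#' @param n_perm Number of random orderings (default 100).
#' @param seed RNG seed.
#' @return Tibble with columns `k` and `mean_distinct_taxa`.
#' @export
rarefaction_curve <- function(gold_profiles, rank, n_perm = 100, seed = 42) {
  stopifnot(n_perm >= 1)
  supports <- lapply(gold_profiles, function(p) {
    support(get_rank_vector(p, rank))
  })
  n <- length(supports)
  acc <- matrix(0, n_perm, n)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  for (b in seq_len(n_perm)) {
    ord <- sample.int(n)
    seen <- character()
    for (k in seq_len(n)) {
      seen <- union(seen, supports[[ord[k]]])
      acc[b, k] <- length(seen)
    }
  }
  tibble(k = seq_len(n), mean_distinct_taxa = colMeans(acc))
}

#' Gold-standard taxa proportions at one rank
#'
#' Long-form table of per-sample normalized abundances, the data behind the
#' stacked taxa-proportion bar charts.
#'
#' @param gold_profiles Named list of gold [sample_profile]s.
#' @param rank Rank name.
#' @return Tibble with columns `sample_id`, `taxid`, `abundance`; per-sample
#'   abundances sum to 1 (absent taxa have no row).
#' @export
taxa_proportions <- function(gold_profiles, rank) {
  rows <- lapply(gold_profiles, function(p) {
    v <- get_rank_vector(p, rank)
    v <- v[v > 0]
    if (length(v) == 0) return(NULL)
    tibble(sample_id = p$sample_id, taxid = names(v),
           abundance = as.numeric(v) / sum(v))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(sample_id = character(), taxid = character(),
                  abundance = numeric())
  }
  out
}
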