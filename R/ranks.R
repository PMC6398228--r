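#' The eight major taxonomic ranks
#'
#' Rank universe used throughout the package, ordered from shallowest
#' (superkingdom, depth 1) to deepest (strain, depth 8). Profile rows at any
#' other rank (e.g. "no rank") are ignored on input.
#'
#' @format Character vector of length 8.
#' @export
MAJOR_RANKS <- c(
  "superkingdom", "phylum", "class", "order",
  "family", "genus", "species", "strain"
)

#' Depth of a rank in the taxonomy tree
#'
#' Superkingdom is depth 1, strain depth 8; a virtual root sits at depth 0.
#'
#' @param rank Character vector of rank names.
#' @return Integer vector of depths; NA for ranks outside [MAJOR_RANKS].
#' @export
rank_depth <- function(rank) {
  match(rank, MAJOR_RANKS)
}

# Closed registry of metric names usable in tables and ranking.
METRIC_REGISTRY <- c(
  "purity", "completeness", "f1", "jaccard", "tp", "fp", "fn",
  "l1", "braycurtis", "unifrac_w", "unifrac_uw",
  "richness", "shannon_h", "shannon_e"
)

# Direction of "better" for each rankable metric. Diversity summaries have no
# universal direction (closeness to the gold standard is what matters), so
# they are deliberately absent and cannot be weighted in rankings.
METRIC_DIRECTIONS <- c(
  purity = "higher_better", completeness = "higher_better",
  f1 = "higher_better", jaccard = "higher_better", tp = "higher_better",
  fp = "lower_better", fn = "lower_better",
  l1 = "lower_better", braycurtis = "lower_better",
  unifrac_w = "lower_better", unifrac_uw = "lower_better"
)
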