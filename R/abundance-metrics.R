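#' L1 norm between true and predicted abundances at one rank
#'
#' Total absolute error over the union of taxa (taxa absent from one vector
#' count with abundance 0). Ranges from 0 (perfect reconstruction) to 2 for
#' normalized vectors with disjoint supports.
#'
#' @param gold,pred [rank_vector]s at the same rank.
#' @return Value in [0, 2] for normalized inputs.
#' @export
l1_norm <- function(gold, pred) {
  taxa <- union(names(gold), names(pred))
  if (length(taxa) == 0) return(0)
  g <- ifelse(is.na(gold[taxa]), 0, gold[taxa])
  p <- ifelse(is.na(pred[taxa]), 0, pred[taxa])
  sum(abs(g - p))
}

#' Bray-Curtis distance at one rank
#'
#' Sum of absolute abundance differences divided by the sum of all
#' abundances, bounded in [0, 1]. For two per-rank-normalized vectors this
#' equals half the L1 norm.
#'
#' @param gold,pred [rank_vector]s at the same rank.
#' @return Value in [0, 1]; NA when both vectors are empty.
#' @export
bray_curtis <- function(gold, pred) {
  denom <- sum(gold) + sum(pred)
  if (denom == 0) return(NA_real_)
  l1_norm(gold, pred) / denom
}

#' Weighted and unweighted UniFrac for a profile pair
#'
#' Builds the shared taxonomy tree once and evaluates both EMD UniFrac
#' variants. The tree spans all ranks, so the pair of values is reported
#' once per sample (at rank "all" in metric tables), not per rank.
#'
#' If exactly one of the two profiles is entirely empty the weighted
#' distance is undefined (no mass distribution to compare) and NA is
#' returned for it; the unweighted distance is still computed, with the
#' surplus indicator mass resolved at the root.
#'
#' @param gold,pred Normalized [sample_profile]s.
#' @return Named numeric vector `c(weighted = ..., unweighted = ...)`.
#' @export
unifrac_pair <- function(gold, pred) {
  tree <- build_tree(gold, pred)
  uw <- emd_unifrac(tree, "unweighted")
  gt <- sum(tree$gold_mass)
  pt <- sum(tree$pred_mass)
  w <- if ((gt == 0) != (pt == 0)) NA_real_ else emd_unifrac(tree, "weighted")
  c(weighted = w, unweighted = uw)
}
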