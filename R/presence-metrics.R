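#' Support of a rank vector
#'
#' The set of taxa with strictly positive abundance at a rank.
#'
#' @param v A [rank_vector] (or named numeric vector).
#' @return Character vector of taxids.
#' @export
support <- function(v) {
  names(v)[v > 0]
}

#' Detection confusion counts at one rank
#'
#' True/false positives and false negatives of taxon detection: a taxon is
#' "detected" when its predicted abundance is strictly positive, regardless
#' of the abundance value.
#'
#' @param gold,pred [rank_vector]s at the same rank.
#' @return List of class `confusion_counts` with `rank`, `tp`, `fp`, `fn`.
#' @export
confusion <- function(gold, pred) {
  rg <- attr(gold, "rank")
  rp <- attr(pred, "rank")
  if (!is.null(rg) && !is.null(rp) && rg != rp) {
    stop("rank mismatch: ", rg, " vs ", rp)
  }
  sg <- support(gold)
  sp <- support(pred)
  structure(
    list(rank = rg %||% rp,
         tp = length(intersect(sg, sp)),
         fp = length(setdiff(sp, sg)),
         fn = length(setdiff(sg, sp))),
    class = "confusion_counts"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Purity (precision) of taxon detection
#'
#' Fraction of predicted taxa that are truly present: tp / (tp + fp). When
#' nothing was predicted (tp + fp = 0) the ratio is 0/0 and NA is returned;
#' NA cells are excluded from averages and receive the worst score in
#' rankings.
#'
#' @param c A `confusion_counts`.
#' @return Value in [0, 1], or NA.
#' @export
purity <- function(c) {
  if (c$tp + c$fp == 0) NA_real_ else c$tp / (c$tp + c$fp)
}

#' Completeness (recall) of taxon detection
#'
#' Fraction of truly present taxa that were predicted: tp / (tp + fn). NA
#' when the gold standard has no taxa at the rank.
#'
#' @param c A `confusion_counts`.
#' @return Value in [0, 1], or NA.
#' @export
completeness <- function(c) {
  if (c$tp + c$fn == 0) NA_real_ else c$tp / (c$tp + c$fn)
}

#' F1 score (harmonic mean of purity and completeness)
#'
#' @param p Purity, in [0, 1] or NA.
#' @param s Completeness, in [0, 1] or NA.
#' @return Harmonic mean; 0 when both are 0; NA if either input is NA.
#' @export
f1 <- function(p, s) {
  if (is.na(p) || is.na(s)) return(NA_real_)
  if (p == 0 && s == 0) return(0)
  2 * p * s / (p + s)
}

#' Jaccard index of the true and predicted taxon sets
#'
#' Intersection over union of the supports at one rank.
#'
#' @param gold,pred [rank_vector]s at the same rank.
#' @return Value in [0, 1]; NA when both supports are empty.
#' @export
jaccard <- function(gold, pred) {
  sg <- support(gold)
  sp <- support(pred)
  u <- union(sg, sp)
  if (length(u) == 0) return(NA_real_)
  length(intersect(sg, sp)) / length(u)
}
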