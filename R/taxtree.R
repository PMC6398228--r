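#' Build the shared taxonomy tree for a gold/prediction pair
#'
#' Takes the union of both profiles' taxpaths over the eight major ranks and
#' builds a rooted tree (virtual root at depth 0, superkingdom at depth 1,
#' strain at depth 8). Edges spanning skipped ranks get length equal to the
#' number of rank levels crossed, so node depth always equals rank depth and
#' the maximum leaf-to-leaf distance is 16.
#'
#' Masses for the weighted UniFrac are assigned by the residual rule: a
#' node's mass is its own rank abundance minus the sum of its children's rank
#' abundances, clipped at zero (abundance already explained at deeper ranks
#' stays there; any shortfall remains at the shallowest ancestor). With both
#' profiles normalized per rank this gives total mass 1 per side; profiles
#' whose children exceed their parent are rescaled back to total 1 with a
#' warning.
#'
#' @param gold,pred [sample_profile] objects, normalized per rank.
#' @return An object of class `tax_tree`: a tibble of nodes (`taxid`,
#'   `parent`, `depth`, `edge_length`, `gold_mass`, `pred_mass`,
#'   `gold_present`, `pred_present`) ordered root-to-leaves, parent `NA` for
#'   depth-1-adjacent-to-root nodes.
#' @export
build_tree <- function(gold, pred) {
  parent_of <- character() # taxid -> parent taxid ("" = root)
  depth_of <- integer()
  register_paths <- function(p) {
    for (i in seq_len(nrow(p$entries))) {
      tp <- p$entries$taxpath[[i]]
      nonempty <- which(nzchar(tp))
      prev <- ""
      for (k in nonempty) {
        id <- tp[k]
        if (id %in% names(parent_of)) {
          if (parent_of[[id]] != prev || depth_of[[id]] != k) {
            stop("taxpath inconsistency: taxid '", id,
                 "' appears with two different parents or depths")
          }
        } else {
          parent_of[[id]] <<- prev
          depth_of[[id]] <<- k
        }
        prev <- id
      }
    }
  }
  register_paths(gold)
  register_paths(pred)
  ids <- names(parent_of)
  ord <- order(depth_of[ids], ids)
  ids <- ids[ord]
  nodes <- tibble(
    taxid = ids,
    parent = ifelse(nzchar(parent_of[ids]), parent_of[ids], NA_character_),
    depth = unname(depth_of[ids])
  )
  parent_depth <- ifelse(is.na(nodes$parent), 0L,
                         nodes$depth[match(nodes$parent, nodes$taxid)])
  nodes$edge_length <- nodes$depth - parent_depth

  abundance_at <- function(p, id, depth) {
    v <- p$ranks[[MAJOR_RANKS[depth]]]
    if (is.null(v)) return(0)
    a <- v[id]
    if (is.na(a)) 0 else unname(a)
  }
  side_masses <- function(p, who) {
    own <- vapply(seq_len(nrow(nodes)),
                  function(i) abundance_at(p, nodes$taxid[i], nodes$depth[i]),
                  0)
    child_sum <- rep(0, nrow(nodes))
    par_idx <- match(nodes$parent, nodes$taxid)
    for (j in which(!is.na(par_idx))) {
      child_sum[par_idx[j]] <- child_sum[par_idx[j]] + own[j]
    }
    mass <- pmax(0, own - child_sum)
    tot <- sum(mass)
    if (tot > 0 && abs(tot - 1) > 1e-9) {
      if (abs(tot - 1) > 1e-6) {
        warning("total ", who, " mass ", format(tot), " for sample '",
                p$sample_id, "' rescaled to 1 (inconsistent taxpath ",
                "abundances)", call. = FALSE)
      }
      mass <- mass / tot
    }
    list(mass = mass, present = own > 0)
  }
  g <- side_masses(gold, "gold")
  q <- side_masses(pred, "prediction")
  nodes$gold_mass <- g$mass
  nodes$pred_mass <- q$mass
  nodes$gold_present <- g$present
  nodes$pred_present <- q$present
  structure(nodes, class = c("tax_tree", class(nodes)))
}

#' Earth-mover's UniFrac distance on a taxonomy tree
#'
#' Single post-order pass: for every edge, the flow across it is the absolute
#' net (gold minus prediction) mass of the subtree below, and the distance is
#' the sum of flow times edge length. In weighted mode the node masses are
#' the residual abundances assigned by [build_tree()] and both sides must
#' carry equal total mass (1 after normalization); the result lies in
#' [0, 16]. In unweighted mode an indicator mass of 1 is placed on every
#' present node; unequal totals are allowed and any global surplus is created
#' or destroyed at the root (it pays for its full depth).
#'
#' @param tree A `tax_tree` from [build_tree()].
#' @param mode "weighted" or "unweighted".
#' @return Non-negative distance.
#' @export
emd_unifrac <- function(tree, mode = c("weighted", "unweighted")) {
  mode <- match.arg(mode)
  if (mode == "weighted") {
    gm <- tree$gold_mass
    pm <- tree$pred_mass
    if (abs(sum(gm) - sum(pm)) > 1e-6) {
      stop("weighted UniFrac requires equal total masses (got ",
           format(sum(gm)), " vs ", format(sum(pm)),
           "); profiles must be normalized")
    }
  } else {
    gm <- as.numeric(tree$gold_present)
    pm <- as.numeric(tree$pred_present)
  }
  net <- gm - pm
  # rows are ordered by depth, so reverse order is a valid post-order
  idx_of <- stats::setNames(seq_len(nrow(tree)), tree$taxid)
  dist <- 0
  for (i in rev(seq_len(nrow(tree)))) {
    dist <- dist + abs(net[i]) * tree$edge_length[i]
    if (!is.na(tree$parent[i])) {
      pi <- idx_of[[tree$parent[i]]]
      net[pi] <- net[pi] + net[i]
    }
    # net reaching the virtual root is surplus, resolved there at no
    # further cost (already paid for the depth travelled)
  }
  dist
}
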