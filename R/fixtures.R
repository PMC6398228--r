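#' Generate a synthetic multi-sample gold-standard profile set
#'
#' Builds a random but internally consistent taxonomy over the eight major
#' ranks (a nested random partition of the strains, so every strain has a
#' full root-to-strain lineage) and, for every sample, draws strain
#' abundances from a Dirichlet(alpha) distribution. Abundances are
#' aggregated up the tree, so at every internal node the parent's abundance
#' equals the sum of its children's and every rank sums to 100%.
#'
#' The Dirichlet concentration alpha = 0.5 produces the uneven,
#' few-dominant-taxa abundance distributions typical of microbial
#' communities; large alpha approaches evenness (equitability near 1).
#'
#' @param n_samples Number of samples.
#' @param n_strains Number of strains (leaves).
#' @param seed RNG seed; identical seeds give identical profiles.
#' @param alpha Dirichlet concentration parameter.
#' @return Named list of gold [sample_profile]s (sample ids "S1", "S2", ...).
#' @export
make_gold <- function(n_samples, n_strains, seed = 1, alpha = 0.5) {
  stopifnot(n_strains >= 1, n_samples >= 1)
  set.seed(seed)
  lineages <- random_taxonomy(n_strains)
  out <- list()
  for (s in seq_len(n_samples)) {
    w <- stats::rgamma(n_strains, shape = alpha, rate = 1)
    if (sum(w) == 0) w <- rep(1, n_strains)
    w <- w / sum(w)
    out[[paste0("S", s)]] <- lineage_profile(
      paste0("S", s), "gold", lineages, w
    )
  }
  out
}

# Nested random partition of n strains into taxa at each of the 8 ranks.
# Returns a character matrix (8 x n): row d = taxid of strain j's ancestor
# at depth d. Fresh taxids are drawn from the supplied counter environment
# (or a new one).
random_taxonomy <- function(n_strains, counter = NULL) {
  if (is.null(counter)) {
    counter <- new.env()
    counter$i <- 0L
  }
  lin <- matrix("", nrow = 8, ncol = n_strains)
  groups <- list(seq_len(n_strains))
  for (d in 1:8) {
    next_groups <- list()
    for (g in groups) {
      if (d == 8) {
        # every strain is its own leaf
        for (j in g) lin[8, j] <- new_taxid(counter)
        next
      }
      n_sub <- if (length(g) == 1) 1 else sample.int(min(3, length(g)), 1)
      assign_to <- sample.int(n_sub, length(g), replace = TRUE)
      # ensure every sub-group non-empty
      assign_to[sample.int(length(g), n_sub)] <- seq_len(n_sub)
      for (k in seq_len(n_sub)) {
        members <- g[assign_to == k]
        if (length(members) == 0) next
        id <- new_taxid(counter)
        lin[d, members] <- id
        next_groups[[length(next_groups) + 1]] <- members
      }
    }
    if (d < 8) groups <- next_groups
  }
  lin
}

new_taxid <- function(counter) {
  counter$i <- counter$i + 1L
  sprintf("t%05d", counter$i)
}

# Build a sample_profile from a lineage matrix and per-strain weights.
lineage_profile <- function(sample_id, tool_label, lineages, w) {
  rows <- list()
  for (d in 1:8) {
    agg <- tapply(w, lineages[d, ], sum)
    agg <- agg[agg > 0]
    for (id in names(agg)) {
      j <- which(lineages[d, ] == id)[1]
      tp <- lineages[1:d, j]
      rows[[length(rows) + 1]] <- tibble(
        taxid = id, rank = MAJOR_RANKS[d],
        taxpath = list(unname(tp)),
        taxpath_names = list(paste0("Taxon_", unname(tp))),
        percentage = unname(agg[id]) * 100
      )
    }
  }
  sample_profile(sample_id, tool_label, dplyr::bind_rows(rows))
}

#' Perturbation settings for synthetic predictions
#'
#' @param dropout_rate Probability that each gold taxon is dropped, applied
#'   independently at each rank.
#' @param spurious_rate Expected number of spurious taxa per rank, as a
#'   fraction of the gold taxa at that rank; spurious taxa are fresh
#'   lineages outside the gold taxonomy, so they are unambiguous false
#'   positives.
#' @param abundance_noise Sigma of multiplicative log-normal noise applied
#'   to each retained abundance.
#' @param rank_truncation Deepest rank the simulated tool reports.
#' @param seed RNG seed.
#' @return Object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(dropout_rate = 0, spurious_rate = 0,
                              abundance_noise = 0,
                              rank_truncation = "strain", seed = 1) {
  stopifnot(dropout_rate >= 0, dropout_rate <= 1,
            spurious_rate >= 0, spurious_rate <= 1,
            abundance_noise >= 0,
            rank_truncation %in% MAJOR_RANKS)
  structure(list(dropout_rate = dropout_rate, spurious_rate = spurious_rate,
                 abundance_noise = abundance_noise,
                 rank_truncation = rank_truncation, seed = seed),
            class = "perturbation_spec")
}

#' Perturb a gold profile into a synthetic prediction
#'
#' Applies, in order: rank truncation, per-rank taxon dropout, multiplicative
#' log-normal abundance noise, and spurious fresh lineages. The result is
#' deliberately left un-normalized (the assessment pipeline normalizes by
#' default).
#'
#' @param gold A gold [sample_profile], or a named list of them (each sample
#'   then gets an independent sub-seed).
#' @param spec A [perturbation_spec()].
#' @param tool_label Label for the simulated tool.
#' @return Perturbed [sample_profile] (or named list of them).
#' @export
perturb <- function(gold, spec, tool_label = "perturbed") {
  if (!inherits(gold, "sample_profile")) {
    out <- list()
    for (i in seq_along(gold)) {
      s2 <- spec
      s2$seed <- spec$seed + i - 1L
      out[[names(gold)[i]]] <- perturb(gold[[i]], s2, tool_label)
    }
    return(out)
  }
  set.seed(spec$seed)
  e <- gold$entries
  max_depth <- rank_depth(spec$rank_truncation)
  e <- e[rank_depth(e$rank) <= max_depth, ]
  if (nrow(e) > 0 && spec$dropout_rate > 0) {
    e <- e[stats::runif(nrow(e)) >= spec$dropout_rate, ]
  }
  if (nrow(e) > 0 && spec$abundance_noise > 0) {
    e$percentage <- e$percentage *
      exp(stats::rnorm(nrow(e), 0, spec$abundance_noise))
  }
  if (spec$spurious_rate > 0) {
    counter <- new.env()
    counter$i <- 0L
    gold_by_rank <- table(factor(gold$entries$rank, levels = MAJOR_RANKS))
    sp_rows <- list()
    for (d in seq_len(max_depth)) {
      r <- MAJOR_RANKS[d]
      n_sp <- stats::rpois(1, spec$spurious_rate * gold_by_rank[[r]])
      if (n_sp == 0) next
      mean_pct <- if (gold_by_rank[[r]] > 0) {
        mean(gold$entries$percentage[gold$entries$rank == r])
      } else 1
      for (k in seq_len(n_sp)) {
        tp <- vapply(seq_len(d), function(x) {
          sprintf("sp%s_%03d", new_taxid(counter), d)
        }, "")
        sp_rows[[length(sp_rows) + 1]] <- tibble(
          taxid = tp[d], rank = r,
          taxpath = list(tp), taxpath_names = list(paste0("Spurious_", tp)),
          percentage = mean_pct * stats::rlnorm(1, 0, 0.5)
        )
      }
    }
    if (length(sp_rows) > 0) e <- dplyr::bind_rows(e, dplyr::bind_rows(sp_rows))
  }
  sample_profile(gold$sample_id, tool_label, e)
}

#' Exact EMD oracle via the transportation linear program
#'
#' Independent cross-check for [emd_unifrac()]: solves the transportation
#' problem between the two mass placements on the tree, with costs equal to
#' tree-path lengths between nodes. In unweighted mode unequal totals are
#' balanced by a virtual node at the root (cost to any node = its depth).
#' Intended for small trees (tests); complexity is that of a dense simplex.
#'
#' @param tree A `tax_tree` from [build_tree()].
#' @param mode "weighted" or "unweighted".
#' @return The exact minimum transport cost.
#' @export
emd_oracle <- function(tree, mode = c("weighted", "unweighted")) {
  mode <- match.arg(mode)
  if (nrow(tree) > 50) stop("oracle restricted to trees with <= 50 nodes")
  if (mode == "weighted") {
    gm <- tree$gold_mass
    pm <- tree$pred_mass
  } else {
    gm <- as.numeric(tree$gold_present)
    pm <- as.numeric(tree$pred_present)
  }
  depth <- c(tree$depth, 0) # last entry: virtual root
  n_nodes <- nrow(tree)
  # pairwise tree distances via root-paths
  paths <- vector("list", n_nodes)
  idx_of <- stats::setNames(seq_len(n_nodes), tree$taxid)
  for (i in seq_len(n_nodes)) {
    anc <- integer()
    j <- i
    repeat {
      anc <- c(anc, j)
      if (is.na(tree$parent[j])) break
      j <- idx_of[[tree$parent[j]]]
    }
    paths[[i]] <- anc
  }
  node_dist <- function(i, j) {
    if (i > n_nodes || j > n_nodes) { # virtual root involved
      k <- min(i, j)
      return(if (k > n_nodes) 0 else depth[k])
    }
    common <- intersect(paths[[i]], paths[[j]])
    lca_depth <- if (length(common) == 0) 0 else max(depth[common])
    depth[i] + depth[j] - 2 * lca_depth
  }
  si <- which(gm > 0)
  di <- which(pm > 0)
  supply <- gm[si]
  demand <- pm[di]
  tot_s <- sum(supply)
  tot_d <- sum(demand)
  if (mode == "weighted" && abs(tot_s - tot_d) > 1e-6) {
    stop("weighted oracle requires equal totals")
  }
  root <- n_nodes + 1L
  if (tot_s < tot_d - 1e-12) {
    si <- c(si, root)
    supply <- c(supply, tot_d - tot_s)
  } else if (tot_d < tot_s - 1e-12) {
    di <- c(di, root)
    demand <- c(demand, tot_s - tot_d)
  }
  m <- length(supply)
  n <- length(demand)
  if (m == 0 || n == 0) return(0)
  cost <- outer(seq_len(m), seq_len(n),
                Vectorize(function(a, b) node_dist(si[a], di[b])))
  if (m == 1 || n == 1) return(sum(outer(supply, demand) / max(tot_s, tot_d) * cost))
  obj <- as.vector(t(cost)) # variables x[a, b] in row-major order
  a3 <- matrix(0, m + n - 1, m * n)
  for (a in seq_len(m)) a3[a, ((a - 1) * n + 1):(a * n)] <- 1
  for (b in seq_len(n - 1)) a3[m + b, seq(b, m * n, by = n)] <- 1
  b3 <- c(supply, demand[seq_len(n - 1)])
  sol <- boot::simplex(a = obj, A3 = a3, b3 = b3, maxi = FALSE)
  if (sol$solved != 1) stop("transportation LP did not solve")
  unname(sol$value)
}
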