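ids_a <- paste0("a", 1:8)
ids_b <- paste0("b", 1:8)

test_that("residual mass assignment puts consistent mass on the leaves", {
  g <- normalize_profile(single_lineage_profile("S1", ids_a))
  tree <- build_tree(g, g)
  expect_equal(sum(tree$gold_mass), 1, tolerance = 1e-9)
  leaf <- tree[tree$depth == 8, ]
  expect_equal(leaf$gold_mass, 1)
  expect_equal(tree$gold_mass[tree$depth < 8], rep(0, 7))
})

test_that("a phylum-only profile keeps its mass on the phylum node", {
  p <- normalize_profile(profile_from_ranks(
    "S1", list(phylum = c(P = 100)), list(P = c("", "P"))
  ))
  tree <- build_tree(p, p)
  expect_equal(nrow(tree), 1)
  expect_equal(tree$depth, 2)
  expect_equal(tree$edge_length, 2)
  expect_equal(tree$gold_mass, 1)
})

test_that("internal nodes keep only the residual not explained deeper", {
  taxpaths <- list(G = c("K", "", "", "", "", "G"),
                   A = c("K", "", "", "", "", "G", "A"),
                   B = c("K", "", "", "", "", "G", "B"),
                   K = "K")
  p <- normalize_profile(profile_from_ranks(
    "S1",
    list(superkingdom = c(K = 100), genus = c(G = 100),
         species = c(A = 60, B = 40)),
    taxpaths
  ))
  tree <- build_tree(p, p)
  mass <- stats::setNames(tree$gold_mass, tree$taxid)
  expect_equal(unname(mass[c("A", "B", "G", "K")]), c(0.6, 0.4, 0, 0))
})

test_that("conflicting taxpaths for one taxid are an error naming it", {
  a <- profile_from_ranks("S1", list(genus = c(G = 100)),
                          list(G = c("K1", "", "", "", "", "G")))
  b <- profile_from_ranks("S1", list(genus = c(G = 100)),
                          list(G = c("K2", "", "", "", "", "G")))
  expect_error(build_tree(normalize_profile(a), normalize_profile(b)),
               "taxid 'G'")
})

test_that("weighted UniFrac is 0 for identical placements and 16 at maximum", {
  g <- normalize_profile(single_lineage_profile("S1", ids_a))
  expect_equal(emd_unifrac(build_tree(g, g), "weighted"), 0)
  p <- normalize_profile(single_lineage_profile("S1", ids_b))
  expect_equal(emd_unifrac(build_tree(g, p), "weighted"), 16)
})

test_that("strains sharing a lineage through the genus are 4 apart", {
  shared <- paste0("c", 1:6)
  g <- normalize_profile(single_lineage_profile("S1", c(shared, "s7a", "s8a")))
  p <- normalize_profile(single_lineage_profile("S1", c(shared, "s7b", "s8b")))
  tree <- build_tree(g, p)
  expect_equal(emd_unifrac(tree, "weighted"), 4)
  expect_equal(emd_oracle(tree, "weighted"), 4, tolerance = 1e-9)
})

test_that("weighted UniFrac rejects unequal total masses", {
  g <- normalize_profile(single_lineage_profile("S1", ids_a))
  tree <- build_tree(g, g)
  tree$pred_mass <- tree$pred_mass / 2
  expect_error(emd_unifrac(tree, "weighted"), "equal total masses")
})

test_that("weighted UniFrac is symmetric and satisfies the triangle inequality", {
  gold <- make_gold(1, 6, seed = 5)[[1]]
  pa <- perturb(gold, perturbation_spec(dropout_rate = 0.3, seed = 2), "a")
  pb <- perturb(gold, perturbation_spec(abundance_noise = 0.8, seed = 3), "b")
  profs <- lapply(list(g = gold, a = pa, b = pb), normalize_profile)
  d <- function(x, y) emd_unifrac(build_tree(x, y), "weighted")
  dga <- d(profs$g, profs$a)
  dag <- d(profs$a, profs$g)
  expect_equal(dga, dag, tolerance = 1e-12)
  dgb <- d(profs$g, profs$b)
  dab <- d(profs$a, profs$b)
  expect_lte(dgb, dga + dab + 1e-12)
  expect_lte(dga, dgb + dab + 1e-12)
  expect_lte(dab, dga + dgb + 1e-12)
})

test_that("moving mass epsilon one extra edge adds exactly epsilon", {
  # gold: all mass on the strain; predictions place eps on ever-shallower
  # ancestors, each step one edge farther from the strain
  eps <- 0.125
  gold <- normalize_profile(single_lineage_profile("S1", ids_a))
  dist_to_depth <- function(d) {
    pcts <- list()
    pcts[[MAJOR_RANKS[8]]] <- stats::setNames(100 * (1 - eps), ids_a[8])
    # prediction still reports full abundance at every ancestor rank, but
    # at rank d a sibling taxon takes eps of it
    prof <- single_lineage_profile("S1", ids_a)
    e <- prof$entries
    e$percentage[rank_depth(e$rank) >= d] <- 100 * (1 - eps)
    sib <- lapply(d:8, function(k) {
      tibble::tibble(
        taxid = paste0("sib", k), rank = MAJOR_RANKS[k],
        taxpath = list(c(ids_a[seq_len(d - 1)], paste0("sib", d:k))),
        taxpath_names = list(rep("", k)), percentage = 100 * eps
      )
    })
    pred <- sample_profile("S1", "t", dplyr::bind_rows(c(list(e), sib)))
    emd_unifrac(build_tree(gold, normalize_profile(pred)), "weighted")
  }
  d8 <- dist_to_depth(8) # sibling strain: 2 edges
  d7 <- dist_to_depth(7) # sibling species: 4 edges
  d6 <- dist_to_depth(6)
  expect_equal(d8, 2 * eps, tolerance = 1e-12)
  expect_equal(d7 - d8, 2 * eps, tolerance = 1e-12)
  expect_equal(d6 - d7, 2 * eps, tolerance = 1e-12)
})

test_that("weighted UniFrac stays within [0, 16] and matches the LP oracle", {
  for (seed in 1:25) {
    tree <- random_small_tree(seed)
    if (nrow(tree) > 30) next
    w <- emd_unifrac(tree, "weighted")
    expect_gte(w, 0)
    expect_lte(w, 16 + 1e-12)
    expect_equal(w, emd_oracle(tree, "weighted"), tolerance = 1e-9)
    uw <- emd_unifrac(tree, "unweighted")
    expect_equal(uw, emd_oracle(tree, "unweighted"), tolerance = 1e-9)
  }
})

test_that("unweighted surplus is resolved at the root", {
  # gold has 3 present nodes (depths 1..3), prediction empty:
  # indicator masses travel to the root, paying their depths 1+2+3
  p <- profile_from_ranks(
    "S1",
    list(superkingdom = c(K = 100), phylum = c(P = 100), class = c(C = 100)),
    list(K = "K", P = c("K", "P"), C = c("K", "P", "C"))
  )
  empty <- sample_profile("S1", "none")
  tree <- build_tree(normalize_profile(p), empty)
  expect_equal(emd_unifrac(tree, "unweighted"), 6)
  expect_equal(emd_oracle(tree, "unweighted"), 6, tolerance = 1e-9)
})
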