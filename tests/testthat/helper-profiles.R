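# Shared fixture builders. All profiles are constructed in code; nothing is
# read from disk except files the tests themselves write to tempdir().

# Full 8-rank single-lineage profile: ids is a character vector of length 8
# (root-to-strain), each rank carrying `pct` percent.
single_lineage_profile <- function(sample_id, ids, pct = 100,
                                   tool_label = "test") {
  stopifnot(length(ids) == 8)
  rows <- lapply(1:8, function(d) {
    tibble::tibble(
      taxid = ids[d], rank = MAJOR_RANKS[d],
      taxpath = list(ids[1:d]), taxpath_names = list(ids[1:d]),
      percentage = pct
    )
  })
  sample_profile(sample_id, tool_label, dplyr::bind_rows(rows))
}

# Profile from a list rank -> named percentage vector, with explicit
# taxpaths supplied as a list taxid -> full character taxpath.
profile_from_ranks <- function(sample_id, rank_pcts, taxpaths,
                               tool_label = "test") {
  rows <- list()
  for (r in names(rank_pcts)) {
    v <- rank_pcts[[r]]
    for (id in names(v)) {
      tp <- taxpaths[[id]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        taxid = id, rank = r, taxpath = list(tp),
        taxpath_names = list(tp), percentage = unname(v[id])
      )
    }
  }
  sample_profile(sample_id, tool_label, dplyr::bind_rows(rows))
}

rv <- function(..., rank = "species", normalized = FALSE) {
  vals <- c(...)
  rank_vector(vals, rank, normalized = normalized)
}

# Random gold/prediction pair on a small shared taxonomy; returns the tree.
random_small_tree <- function(seed, n_strains = 2, dropout = 0.3,
                              spurious = 0.2, noise = 0.5) {
  gold <- make_gold(1, n_strains, seed = seed)[[1]]
  pred <- perturb(gold,
                  perturbation_spec(dropout_rate = dropout,
                                    spurious_rate = spurious,
                                    abundance_noise = noise,
                                    seed = seed + 10000L),
                  "sim")
  build_tree(normalize_profile(gold), normalize_profile(pred))
}

cami_lines_one_sample <- c(
  "@SampleID:S1",
  "@Version:0.9.1",
  paste0("@Ranks:", paste(MAJOR_RANKS, collapse = "|")),
  "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE",
  "2\tsuperkingdom\t2\tBacteria\t100.0"
)
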