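# Greengenes-style lineage prefixes mapped onto the major ranks.
GG_PREFIXES <- c(k = "superkingdom", d = "superkingdom", p = "phylum",
                 c = "class", o = "order", f = "family", g = "genus",
                 s = "species", t = "strain")

#' Read profiles from a BIOM table
#'
#' Reads a BIOM 1.0 (JSON) or 2.x (HDF5) table whose observation metadata
#' carries taxonomy lineages (greengenes-style `k__...;p__...` prefixes or
#' plain positional levels) and converts it into one [sample_profile] per
#' BIOM sample. Counts are aggregated per rank along the lineages and turned
#' into relative abundances at each rank.
#'
#' @param path Path to a BIOM file.
#' @param tool_label Label to attach to the parsed profiles.
#' @return Named list of [sample_profile] objects.
#' @export
parse_biom <- function(path, tool_label = "unknown") {
  b <- biomformat::read_biom(path)
  obs <- biomformat::rownames(b)
  samp <- biomformat::colnames(b)
  d <- biomformat::biom_data(b)
  # biom_data drops to a plain vector when either dimension is 1
  counts <- if (is.null(dim(d)) && length(obs) == 1) {
    matrix(as.numeric(d[samp]), nrow = 1, dimnames = list(obs, samp))
  } else if (is.null(dim(d))) {
    matrix(as.numeric(d[obs]), ncol = 1, dimnames = list(obs, samp))
  } else {
    as.matrix(d)[obs, samp, drop = FALSE]
  }
  om <- biomformat::observation_metadata(b)
  if (is.null(om)) {
    stop("BIOM observations lack taxonomy lineages in their metadata")
  }
  lineages <- biom_lineages(om, rownames(counts))
  out <- list()
  for (s in colnames(counts)) {
    cnt <- counts[, s]
    keep <- which(cnt > 0)
    rows <- list()
    for (d in seq_along(MAJOR_RANKS)) {
      # taxon at depth d for each retained observation, "" when absent
      at_d <- vapply(lineages[keep], function(l) {
        if (length(l) >= d) l[d] else ""
      }, "")
      has <- nzchar(at_d)
      if (!any(has)) next
      agg <- tapply(cnt[keep][has], at_d[has], sum)
      rel <- agg / sum(agg) * 100
      for (taxon in names(rel)) {
        # taxpath: the (first) full lineage of this taxon, truncated to depth d
        li <- lineages[keep][has][match(taxon, at_d[has])][[1]]
        tp <- character(d)
        tp[seq_len(min(d, length(li)))] <- li[seq_len(min(d, length(li)))]
        rows[[length(rows) + 1]] <- tibble(
          taxid = taxon, rank = MAJOR_RANKS[d],
          taxpath = list(tp), taxpath_names = list(tp),
          percentage = unname(rel[taxon])
        )
      }
    }
    out[[s]] <- sample_profile(
      s, tool_label,
      if (length(rows) > 0) dplyr::bind_rows(rows) else empty_entries()
    )
  }
  out
}

# Normalize observation metadata into a list of per-observation lineage
# vectors aligned with the major ranks (position d = rank depth d, "" = skip).
biom_lineages <- function(om, obs_ids) {
  raw <- if (is.data.frame(om)) {
    lapply(seq_len(nrow(om)), function(i) as.character(unlist(om[i, ])))
  } else if (is.list(om)) {
    lapply(om, function(x) as.character(unlist(x)))
  } else {
    as.list(as.character(om))
  }
  raw <- lapply(raw, function(x) {
    x <- unlist(strsplit(x, ";", fixed = TRUE))
    trimws(x)
  })
  lapply(raw, function(levels) {
    out <- character(length(MAJOR_RANKS))
    prefixes <- sub("^([a-z])__.*$", "\\1", levels)
    prefixed <- grepl("^[a-z]__", levels)
    if (any(prefixed)) {
      for (i in which(prefixed)) {
        rnk <- GG_PREFIXES[prefixes[i]]
        name <- sub("^[a-z]__", "", levels[i])
        if (!is.na(rnk) && nzchar(name)) out[rank_depth(rnk)] <- name
      }
    } else {
      n <- min(length(levels), length(out))
      out[seq_len(n)] <- levels[seq_len(n)]
    }
    # drop trailing empties so length(lineage) = deepest assigned rank
    last <- max(c(0, which(nzchar(out))))
    out[seq_len(last)]
  })
}
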