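#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

#' Construct a sample profile
#'
#' A sample profile holds one sample's taxonomic composition for one tool (or
#' the gold standard): the verbatim profile rows plus per-rank abundance
#' vectors on the 0-1 fraction scale.
#'
#' @param sample_id Sample identifier.
#' @param tool_label Label of the producing tool ("gold" for the gold
#'   standard).
#' @param entries Tibble with columns `taxid`, `rank`, `taxpath` (list of
#'   character vectors, root-to-taxon, "" for skipped ranks), `taxpath_names`
#'   (parallel list), `percentage` (0-100 scale).
#' @return An object of class `sample_profile`.
#' @export
sample_profile <- function(sample_id, tool_label, entries = empty_entries()) {
  stopifnot(is.character(sample_id), length(sample_id) == 1)
  entries <- as_tibble(entries)
  if (nrow(entries) > 0) {
    dup <- duplicated(paste(entries$rank, entries$taxid, sep = "\r"))
    if (any(dup)) {
      stop("duplicate (rank, taxid) pair in sample '", sample_id, "': ",
           entries$rank[dup][1], "/", entries$taxid[dup][1])
    }
    if (any(entries$percentage < 0)) {
      stop("negative percentage in sample '", sample_id, "'")
    }
    bad_len <- lengths(entries$taxpath) != lengths(entries$taxpath_names)
    if (any(bad_len)) {
      stop("taxpath and taxpath_names lengths differ for taxid ",
           entries$taxid[bad_len][1])
    }
  }
  structure(
    list(sample_id = sample_id, tool_label = tool_label,
         entries = entries, ranks = entries_to_rank_vectors(entries),
         normalized = FALSE),
    class = "sample_profile"
  )
}

empty_entries <- function() {
  tibble(taxid = character(), rank = character(),
         taxpath = list(), taxpath_names = list(),
         percentage = numeric())
}

#' @export
print.sample_profile <- function(x, ...) {
  cat("<sample_profile> sample:", x$sample_id, " tool:", x$tool_label,
      " entries:", nrow(x$entries),
      if (x$normalized) " (normalized)" else "", "\n", sep = "")
  invisible(x)
}

# Build the rank -> rank_vector mapping (fractions) from an entries tibble.
entries_to_rank_vectors <- function(entries) {
  out <- list()
  for (r in MAJOR_RANKS) {
    sel <- entries$rank == r & entries$percentage > 0
    if (any(sel)) {
      ab <- entries$percentage[sel] / 100
      names(ab) <- entries$taxid[sel]
      out[[r]] <- rank_vector(ab, r)
    }
  }
  out
}

#' Construct a rank vector
#'
#' Named numeric vector of relative abundances (fractions) of the taxa at one
#' rank, the per-rank unit all metrics operate on.
#'
#' @param abundances Named non-negative numeric vector (taxid -> fraction).
#' @param rank Rank name, one of [MAJOR_RANKS].
#' @param normalized Whether the abundances sum to 1.
#' @return Named numeric vector of class `rank_vector` with attributes
#'   `rank` and `normalized`.
#' @export
rank_vector <- function(abundances = numeric(), rank, normalized = FALSE) {
  if (!rank %in% MAJOR_RANKS) stop("unknown rank: ", rank)
  if (length(abundances) > 0 && any(abundances < 0)) {
    stop("negative abundance in rank vector at rank ", rank)
  }
  if (normalized && length(abundances) > 0 &&
      abs(sum(abundances) - 1) > 1e-9) {
    stop("rank vector flagged normalized but sums to ", sum(abundances))
  }
  structure(as.numeric(abundances), names = names(abundances),
            rank = rank, normalized = normalized, class = "rank_vector")
}

#' Extract one rank's abundance vector from a profile
#'
#' @param p A [sample_profile].
#' @param rank Rank name.
#' @return A [rank_vector] (empty if the profile has no taxa at that rank).
#' @export
get_rank_vector <- function(p, rank) {
  v <- p$ranks[[rank]]
  if (is.null(v)) rank_vector(numeric(), rank, normalized = FALSE) else v
}

#' Parse profiles in the CAMI Bioboxes profiling format
#'
#' Reads a (possibly multi-sample) taxonomic profile. Each sample section
#' starts with an `@SampleID:` header; data rows are tab-separated
#' `TAXID RANK TAXPATH TAXPATHSN PERCENTAGE` with pipe-separated taxpaths.
#' Percentages are stored verbatim (no normalization); rows with zero
#' percentage are dropped (presence is defined by abundance strictly greater
#' than zero). Rows at ranks outside the eight major ranks are skipped with a
#' warning (tolerant mode, the default) or rejected (strict mode).
#'
#' @param input Path to a profile file, or a character vector of lines.
#' @param tool_label Label to attach to the parsed profiles.
#' @param strict If TRUE, unknown-rank rows are an error instead of a warning.
#' @return Named list of [sample_profile] objects (names are sample ids).
#' @export
parse_cami_profile <- function(input, tool_label = "unknown", strict = FALSE) {
  lines <- if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    readLines(input, warn = FALSE)
  } else {
    unlist(strsplit(input, "\n", fixed = TRUE))
  }
  profiles <- list()
  cur_id <- NULL
  cur_rows <- list()
  flush <- function() {
    if (is.null(cur_id)) return()
    profiles[[cur_id]] <<- sample_profile(
      cur_id, tool_label,
      if (length(cur_rows) > 0) dplyr::bind_rows(cur_rows) else empty_entries()
    )
  }
  for (i in seq_along(lines)) {
    line <- sub("\r$", "", lines[i])
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "#")) next
    if (startsWith(line, "@@")) next # column header
    if (startsWith(line, "@")) {
      kv <- sub("^@", "", line)
      key <- sub(":.*$", "", kv)
      if (tolower(key) == "sampleid") {
        flush()
        cur_id <- sub("^[^:]*:", "", kv)
        cur_rows <- list()
        if (!nzchar(cur_id)) stop("empty @SampleID at line ", i)
      }
      next # other @-metadata (@Version, @Ranks, ...) carried by the format
    }
    if (is.null(cur_id)) {
      stop("data row before any @SampleID header at line ", i)
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 5) {
      stop("malformed data row (fewer than 5 tab-separated fields) at line ", i)
    }
    taxid <- trimws(fields[1])
    rank <- trimws(fields[2])
    if (!rank %in% MAJOR_RANKS) {
      if (strict) stop("unknown rank '", rank, "' at line ", i)
      warning("skipping row with unknown rank '", rank, "' at line ", i,
              call. = FALSE)
      next
    }
    pct <- suppressWarnings(as.numeric(fields[5]))
    if (is.na(pct)) stop("unparsable percentage '", fields[5], "' at line ", i)
    if (pct < 0) stop("negative percentage at line ", i)
    taxpath <- strsplit(fields[3], "|", fixed = TRUE)[[1]]
    if (length(taxpath) == 0) taxpath <- taxid
    taxpath_names <- strsplit(fields[4], "|", fixed = TRUE)[[1]]
    length(taxpath_names) <- length(taxpath)
    taxpath_names[is.na(taxpath_names)] <- ""
    nonempty <- which(nzchar(taxpath))
    if (length(nonempty) == 0 || taxpath[max(nonempty)] != taxid ||
        max(nonempty) != rank_depth(rank)) {
      if (strict) {
        stop("taxpath inconsistent with rank/taxid at line ", i)
      }
      warning("skipping row with taxpath inconsistent with its rank at line ",
              i, call. = FALSE)
      next
    }
    if (pct == 0) next # zero-abundance rows carry no support
    cur_rows[[length(cur_rows) + 1]] <- tibble(
      taxid = taxid, rank = rank,
      taxpath = list(taxpath), taxpath_names = list(taxpath_names),
      percentage = pct
    )
  }
  flush()
  profiles
}

#' Normalize a profile's abundances per rank
#'
#' Rescales every non-empty rank so its abundances sum to 1 (100 on the
#' percentage scale of the verbatim entries). Applied by default to the gold
#' standard and all predictions before any metric, so that tools reporting
#' only part of the sample are not favoured. Ranks whose percentages sum to
#' more than 100 are rescaled too, with a warning.
#'
#' @param p A [sample_profile].
#' @return The profile with `normalized = TRUE` and rank sums of 1.
#' @export
normalize_profile <- function(p) {
  stopifnot(inherits(p, "sample_profile"))
  entries <- p$entries
  overfull <- character()
  for (r in MAJOR_RANKS) {
    sel <- which(entries$rank == r)
    if (length(sel) == 0) next
    tot <- sum(entries$percentage[sel])
    if (tot <= 0) next
    if (tot > 100 + 0.5) overfull <- c(overfull, r)
    entries$percentage[sel] <- entries$percentage[sel] / tot * 100
  }
  if (length(overfull) > 0) {
    warning("sample '", p$sample_id, "': rank(s) ",
            paste(overfull, collapse = ", "),
            " sum to more than 100% before normalization", call. = FALSE)
  }
  out <- p
  out$entries <- entries
  out$ranks <- lapply(entries_to_rank_vectors(entries), function(v) {
    attr(v, "normalized") <- TRUE
    v
  })
  out$normalized <- TRUE
  out
}

#' Write profiles in the CAMI Bioboxes profiling format
#'
#' Inverse of [parse_cami_profile()]: the emitted file re-parses to an
#' equivalent profile set (taxids, ranks and taxpaths exactly; percentages
#' within 1e-6).
#'
#' @param profiles List of [sample_profile] objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cami_profile <- function(profiles, path) {
  lines <- character()
  for (p in profiles) {
    stopifnot(inherits(p, "sample_profile"))
    lines <- c(lines,
               paste0("@SampleID:", p$sample_id),
               "@Version:0.9.1",
               paste0("@Ranks:", paste(MAJOR_RANKS, collapse = "|")),
               "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE")
    e <- p$entries
    if (nrow(e) > 0) {
      ord <- order(rank_depth(e$rank), e$taxid)
      e <- e[ord, ]
      lines <- c(lines, sprintf(
        "%s\t%s\t%s\t%s\t%s",
        e$taxid, e$rank,
        vapply(e$taxpath, paste, "", collapse = "|"),
        vapply(e$taxpath_names, paste, "", collapse = "|"),
        sprintf("%.6f", e$percentage)
      ))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Bundle gold-standard and predicted profiles
#'
#' @param gold Named list of gold [sample_profile]s (names = sample ids).
#' @param predictions Named list (tool label -> named list of
#'   [sample_profile]s).
#' @return An object of class `profile_set`. Prediction samples absent from
#'   the gold standard are an error; gold samples absent from a prediction
#'   are later scored as empty predictions.
#' @export
profile_set <- function(gold, predictions = list()) {
  gold_ids <- vapply(gold, function(p) p$sample_id, "")
  names(gold) <- gold_ids
  for (tool in names(predictions)) {
    ids <- vapply(predictions[[tool]], function(p) p$sample_id, "")
    names(predictions[[tool]]) <- ids
    extra <- setdiff(ids, gold_ids)
    if (length(extra) > 0) {
      stop("prediction of tool '", tool, "' contains sample(s) absent from ",
           "the gold standard: ", paste(extra, collapse = ", "))
    }
  }
  structure(list(gold = gold, predictions = predictions),
            class = "profile_set")
}
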