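test_that("minimal CAMI files parse into the expected profiles", {
  ps <- parse_cami_profile(cami_lines_one_sample, "toolX")
  expect_length(ps, 1)
  expect_equal(names(ps), "S1")
  p <- ps$S1
  expect_s3_class(p, "sample_profile")
  expect_equal(p$tool_label, "toolX")
  expect_equal(nrow(p$entries), 1)
  expect_equal(p$entries$rank, "superkingdom")
  expect_equal(p$entries$percentage, 100)
  expect_equal(unname(get_rank_vector(p, "superkingdom")["2"]), 1)
})

test_that("multi-sample streams split on @SampleID and keep row order", {
  lines <- c(
    "@SampleID:S1", "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE",
    "2\tsuperkingdom\t2\tBacteria\t60.0",
    "2157\tsuperkingdom\t2157\tArchaea\t40.0",
    "@SampleID:S2", "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE",
    "2157\tsuperkingdom\t2157\tArchaea\t100.0"
  )
  ps <- parse_cami_profile(lines, "t")
  expect_equal(names(ps), c("S1", "S2"))
  expect_equal(ps$S1$entries$taxid, c("2", "2157"))
  expect_equal(ps$S2$entries$taxid, "2157")
})

test_that("pipe-separated taxpaths parse with the row taxid last", {
  lines <- c(
    "@SampleID:S1", "@@TAXID\tRANK\tTAXPATH\tTAXPATHSN\tPERCENTAGE",
    "91061\tclass\t2|1239|91061\tBacteria|Firmicutes|Bacilli\t100.0"
  )
  p <- parse_cami_profile(lines, "t")$S1
  expect_equal(p$entries$taxpath[[1]], c("2", "1239", "91061"))
  expect_equal(p$entries$taxpath_names[[1]],
               c("Bacteria", "Firmicutes", "Bacilli"))
  expect_equal(p$entries$taxpath[[1]][3], p$entries$taxid)
})

test_that("format errors are reported with context", {
  expect_error(
    parse_cami_profile(c("2\tsuperkingdom\t2\tBacteria\t100.0"), "t"),
    "before any @SampleID"
  )
  expect_error(
    parse_cami_profile(c("@SampleID:S1",
                         "2\tsuperkingdom\t2\tBacteria\t-5"), "t"),
    "negative percentage"
  )
  expect_error(
    parse_cami_profile(c("@SampleID:S1",
                         "2\tsuperkingdom\t2\tBacteria\tabc"), "t"),
    "unparsable percentage"
  )
  expect_error(
    parse_cami_profile(c("@SampleID:S1",
                         "2\tsuperkingdom\t2\tBacteria\t50",
                         "2\tsuperkingdom\t2\tBacteria\t50"), "t"),
    "duplicate"
  )
})

test_that("unknown ranks are skipped with a warning, or error in strict mode", {
  lines <- c("@SampleID:S1",
             "2\tsuperkingdom\t2\tBacteria\t100.0",
             "131567\tno rank\t131567\tcellular organisms\t100.0")
  expect_warning(ps <- parse_cami_profile(lines, "t"), "unknown rank")
  expect_equal(nrow(ps$S1$entries), 1)
  expect_error(parse_cami_profile(lines, "t", strict = TRUE), "unknown rank")
})

test_that("zero-percentage rows are dropped on load", {
  lines <- c("@SampleID:S1",
             "2\tsuperkingdom\t2\tBacteria\t100.0",
             "2157\tsuperkingdom\t2157\tArchaea\t0.0")
  p <- parse_cami_profile(lines, "t")$S1
  expect_equal(p$entries$taxid, "2")
})

test_that("normalization rescales each rank to 1 and is idempotent", {
  p <- profile_from_ranks(
    "S1",
    list(species = c(A = 30, B = 20)),
    list(A = c("K", "", "", "", "", "", "A"),
         B = c("K", "", "", "", "", "", "B"))
  )
  n <- normalize_profile(p)
  v <- get_rank_vector(n, "species")
  expect_equal(unname(v[c("A", "B")]), c(0.6, 0.4))
  expect_true(n$normalized)
  n2 <- normalize_profile(n)
  expect_equal(as.numeric(get_rank_vector(n2, "species")), as.numeric(v))
  # empty rank stays empty
  expect_length(get_rank_vector(n, "genus"), 0)
})

test_that("normalization warns when a rank sums to more than 100%", {
  p <- profile_from_ranks(
    "S1", list(species = c(A = 80, B = 70)),
    list(A = c("K", "", "", "", "", "", "A"),
         B = c("K", "", "", "", "", "", "B"))
  )
  expect_warning(n <- normalize_profile(p), "more than 100")
  expect_equal(sum(get_rank_vector(n, "species")), 1, tolerance = 1e-12)
})

test_that("every non-empty rank vector sums to 1 after normalization", {
  gold <- make_gold(3, 15, seed = 11)
  for (p in lapply(gold, normalize_profile)) {
    for (r in MAJOR_RANKS) {
      v <- get_rank_vector(p, r)
      if (length(v) > 0) expect_equal(sum(v), 1, tolerance = 1e-9)
    }
  }
})

test_that("write/parse round-trips generated fixtures exactly enough", {
  gold <- make_gold(2, 12, seed = 3)
  pred <- perturb(gold, perturbation_spec(dropout_rate = 0.2,
                                          spurious_rate = 0.3,
                                          abundance_noise = 0.4,
                                          seed = 9), "sim")
  for (profiles in list(gold, pred)) {
    f <- withr::local_tempfile(fileext = ".profile")
    write_cami_profile(profiles, f)
    back <- parse_cami_profile(f, "roundtrip")
    expect_equal(names(back), names(profiles))
    for (sid in names(profiles)) {
      a <- profiles[[sid]]$entries
      b <- back[[sid]]$entries
      key <- function(e) order(e$rank, e$taxid)
      a <- a[key(a), ]
      b <- b[key(b), ]
      expect_equal(b$taxid, a$taxid)
      expect_equal(b$rank, a$rank)
      expect_equal(b$taxpath, a$taxpath)
      expect_equal(b$percentage, a$percentage, tolerance = 1e-6)
    }
  }
})

test_that("written percentages keep at least 6 significant digits", {
  p <- profile_from_ranks("S1", list(species = c(A = 33.333333)),
                          list(A = c("K", "", "", "", "", "", "A")))
  f <- withr::local_tempfile(fileext = ".profile")
  write_cami_profile(list(S1 = p), f)
  back <- parse_cami_profile(f, "t")$S1
  expect_equal(back$entries$percentage, 33.333333, tolerance = 1e-6)
})

test_that("writing an empty profile list yields a file with no samples", {
  f <- withr::local_tempfile(fileext = ".profile")
  write_cami_profile(list(), f)
  expect_length(parse_cami_profile(readLines(f), "t"), 0)
})

test_that("profile_set rejects prediction samples missing from gold", {
  gold <- make_gold(2, 5, seed = 1)
  stray <- list(S9 = sample_profile("S9", "t"))
  expect_error(profile_set(gold, list(t = stray)), "absent from")
})

test_that("BIOM tables read into per-rank relative abundances", {
  m <- matrix(c(3, 1, 0, 5), nrow = 2,
              dimnames = list(c("o1", "o2"), c("S1", "S2")))
  om <- data.frame(
    t1 = c("k__Bacteria", "k__Bacteria"),
    t2 = c("p__Firmicutes", "p__Bacteroidetes"),
    row.names = c("o1", "o2")
  )
  f <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(biomformat::make_biom(m, observation_metadata = om),
                         f)
  ps <- parse_biom(f, "bt")
  expect_setequal(names(ps), c("S1", "S2"))
  v <- get_rank_vector(ps$S1, "phylum")
  expect_equal(unname(v[c("Firmicutes", "Bacteroidetes")]), c(0.75, 0.25))
  expect_equal(unname(get_rank_vector(ps$S1, "superkingdom")["Bacteria"]), 1)
  # S2 has only o2
  expect_equal(unname(get_rank_vector(ps$S2, "phylum")["Bacteroidetes"]), 1)
})

test_that("single-observation BIOM normalizes to 1 and empty samples stay empty", {
  m <- matrix(c(10, 0), nrow = 1, dimnames = list("o1", c("S1", "S0")))
  om <- data.frame(t1 = "k__Bacteria", row.names = "o1")
  f <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(biomformat::make_biom(m, observation_metadata = om),
                         f)
  ps <- parse_biom(f, "bt")
  expect_equal(unname(get_rank_vector(ps$S1, "superkingdom")["Bacteria"]), 1)
  expect_equal(nrow(ps$S0$entries), 0)
})
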