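test_that("community table parsing handles the canonical three-row layout", {
  dir <- withr::local_tempdir()
  path <- write_community_csv(
    dir,
    genomes = c("seq_1.fa", "seq_2.fa", "seq_3.fa"),
    seq_type = c("chromosome", "chromosome", "plasmid"),
    abundances = list(sample_1 = c(1, 1, 1), sample_2 = c(2, 1, 3))
  )
  spec <- parse_community_table(path)
  expect_s3_class(spec, "community_spec")
  expect_equal(nrow(spec$entries), 3)
  expect_equal(spec$sample_ids, c("sample_1", "sample_2"))
  expect_equal(spec$entries$seq_type[3], "plasmid")
  expect_equal(unname(spec$abundance[, "sample_2"]), c(2, 1, 3))
  # relative paths resolve against the table directory
  expect_true(all(startsWith(spec$entries$path, normalizePath(dir))))
})

test_that("community table validation rejects bad rows", {
  dir <- withr::local_tempdir()
  bad_type <- write_community_csv(dir, "a.fa", "genome",
                                  list(sample_1 = 1))
  expect_error(parse_community_table(bad_type), "row 1")

  neg <- write_community_csv(dir, c("a.fa", "b.fa"),
                             c("chromosome", "chromosome"),
                             list(sample_1 = c(1, -2)))
  expect_error(parse_community_table(neg), "negative")

  dup <- write_community_csv(dir, c("a.fa", "a.fa"),
                             c("chromosome", "chromosome"),
                             list(sample_1 = c(1, 1)))
  expect_error(parse_community_table(dup), "duplicate")

  allzero <- write_community_csv(dir, c("a.fa", "b.fa"),
                                 c("chromosome", "chromosome"),
                                 list(sample_1 = c(1, 1),
                                      sample_2 = c(0, 0)))
  expect_error(parse_community_table(allzero), "sample_2")
})

test_that("zero abundance is legal and yields zero reads in that sample", {
  dir <- withr::local_tempdir()
  path <- write_community_csv(dir, c("a.fa", "b.fa"),
                              c("chromosome", "chromosome"),
                              list(sample_1 = c(0, 1),
                                   sample_2 = c(2, 1)))
  spec <- parse_community_table(path)
  budget <- allocate_reads(spec, "sample_1", 1000, c(a = 50000, b = 50000))
  expect_equal(unname(budget$pairs_by_genome[["a"]]), 0)
  expect_equal(unname(budget$pairs_by_genome[["b"]]), 1000)
})

test_that("uniform abundance draws stay in range and are reproducible", {
  x <- draw_abundances(17, 1, 3.5, seed = 7)
  expect_length(x, 17)
  expect_true(all(x >= 1 & x <= 3.5))

  big <- draw_abundances(1e5, 1, 3.5, seed = 8)
  expect_true(all(big >= 1 & big <= 3.5))

  expect_equal(draw_abundances(5, 2, 2, seed = 1), rep(2, 5))
  expect_identical(draw_abundances(10, 1, 3.5, seed = 3),
                   draw_abundances(10, 1, 3.5, seed = 3))
  expect_error(draw_abundances(3, 4, 2, seed = 1), "low")
})

test_that("read allocation is proportional to abundance times length", {
  dir <- withr::local_tempdir()
  path <- write_community_csv(dir, c("a.fa", "b.fa"),
                              c("chromosome", "chromosome"),
                              list(sample_1 = c(1, 2)))
  spec <- parse_community_table(path)
  b <- allocate_reads(spec, "sample_1", 3000, c(a = 1e5, b = 1e5))
  expect_equal(unname(b$pairs_by_genome), c(1000, 2000))

  one <- write_community_csv(withr::local_tempdir(), "solo.fa", "chromosome",
                             list(sample_1 = 5))
  b1 <- allocate_reads(parse_community_table(one), "sample_1", 777,
                       c(solo = 2e5))
  expect_equal(unname(b1$pairs_by_genome[["solo"]]), 777)
})

test_that("largest-remainder rounding reproduces the worked allocation", {
  # lengths (100000, 100000, 10000), abundances (2, 1, 3), 10000 pairs:
  # weights (200000, 100000, 30000) -> (6061, 3030, 909)
  dir <- withr::local_tempdir()
  path <- write_community_csv(dir, c("a.fa", "b.fa", "c.fa"),
                              rep("chromosome", 3),
                              list(sample_2 = c(2, 1, 3)))
  spec <- parse_community_table(path)
  b <- allocate_reads(spec, "sample_2", 10000,
                      c(a = 1e5, b = 1e5, c = 1e4))
  expect_equal(unname(b$pairs_by_genome), c(6061, 3030, 909))
  expect_equal(sum(b$pairs_by_genome), 10000)
})

test_that("allocation conserves the total and respects proportionality", {
  dir <- withr::local_tempdir()
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(2:6, 1)
    path <- write_community_csv(dir, paste0("g", seq_len(n), ".fa"),
                                rep("chromosome", n),
                                list(s = round(runif(n, 0, 4), 2)))
    spec <- tryCatch(parse_community_table(path), error = function(e) NULL)
    if (is.null(spec)) next   # all-zero draw
    lens <- sample(1e4:3e5, n)
    names(lens) <- spec$entries$genome_id
    total <- sample(1e3:1e5, 1)
    b <- allocate_reads(spec, "s", total, lens)
    expect_equal(sum(b$pairs_by_genome), total)
    expect_true(all(b$pairs_by_genome[spec$abundance[, "s"] == 0] == 0))
    # proportionality within one pair of rounding
    w <- spec$abundance[, "s"] * lens
    exact <- total * w / sum(w)
    expect_true(all(abs(b$pairs_by_genome - exact) <= 1))
  }
})

test_that("expected depth follows pairs * 2 * read_length / genome length", {
  b <- structure(list(sample_id = "s", total_read_pairs = 1000L,
                      pairs_by_genome = c(g = 1000L, z = 0L)),
                 class = "read_budget")
  d <- expected_depth(b, c(g = 1e5, z = 5e4), read_length = 150)
  expect_equal(unname(d[["g"]]), 3.0)
  expect_equal(unname(d[["z"]]), 0.0)
})
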