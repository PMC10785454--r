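make_budget <- function(pairs) {
  structure(list(sample_id = "s1",
                 total_read_pairs = sum(unlist(pairs)),
                 pairs_by_genome = unlist(pairs)),
            class = "read_budget")
}

test_that("zero-error reads are exact substrings at their recorded coordinates", {
  g <- c(gA = rand_seq(20000, 1), gB = rand_seq(15000, 2))
  sim <- simulate_sample(g, make_budget(c(gA = 150, gB = 100)),
                         fragment_model(), error_profile(substitution_rate = 0),
                         seed = 11)
  rl <- sim$read_length
  pv <- sim$provenance
  for (i in seq_len(nrow(pv))) {
    src <- g[[pv$genome_id[i]]]
    fwd <- substr(src, pv$start[i] + 1, pv$start[i] + rl)
    rev <- magsim:::revcomp(substr(src, pv$end[i] - rl + 1, pv$end[i]))
    if (pv$strand[i] == "+") {
      expect_identical(sim$reads$mate1[i], fwd)
      expect_identical(sim$reads$mate2[i], rev)
    } else {
      expect_identical(sim$reads$mate1[i], rev)
      expect_identical(sim$reads$mate2[i], fwd)
    }
  }
  expect_false(any(duplicated(sim$reads$read_id)))
})

test_that("FASTQ output contains exactly the budgeted number of records", {
  g <- c(gA = rand_seq(30000, 3))
  sim <- simulate_sample(g, make_budget(c(gA = 500)), fragment_model(),
                         error_profile(), seed = 4)
  dir <- withr::local_tempdir()
  paths <- write_sample_fastq(sim, dir)
  r1 <- magsim:::read_fastq(paths[["R1"]])
  r2 <- magsim:::read_fastq(paths[["R2"]])
  expect_equal(nrow(r1), 500)
  expect_equal(nrow(r2), 500)
  expect_identical(r1$read_id, r2$read_id)
})

test_that("observed substitution rate matches the profile", {
  g <- c(gA = rand_seq(50000, 5))
  n_pairs <- 400  # 400 * 2 * 150 = 120000 simulated bases
  profile <- error_profile(substitution_rate = 0.01)
  sim <- simulate_sample(g, make_budget(c(gA = n_pairs)), fragment_model(),
                         profile, seed = 21)
  rl <- sim$read_length
  pv <- sim$provenance
  mism <- 0L
  for (i in seq_len(nrow(pv))) {
    src <- g[[pv$genome_id[i]]]
    fwd <- substr(src, pv$start[i] + 1, pv$start[i] + rl)
    rev <- magsim:::revcomp(substr(src, pv$end[i] - rl + 1, pv$end[i]))
    exp1 <- if (pv$strand[i] == "+") fwd else rev
    exp2 <- if (pv$strand[i] == "+") rev else fwd
    mism <- mism + sum(utf8ToInt(sim$reads$mate1[i]) != utf8ToInt(exp1)) +
      sum(utf8ToInt(sim$reads$mate2[i]) != utf8ToInt(exp2))
  }
  n <- 2 * rl * n_pairs
  p <- 0.01
  z <- qnorm(0.995)
  half <- z * sqrt(p * (1 - p) / n)
  expect_gt(mism / n, p - half)
  expect_lt(mism / n, p + half)
})

test_that("simulation is reproducible for a fixed seed and errors on short genomes", {
  g <- c(gA = rand_seq(20000, 6))
  b <- make_budget(c(gA = 50))
  s1 <- simulate_sample(g, b, fragment_model(), error_profile(), seed = 9)
  s2 <- simulate_sample(g, b, fragment_model(), error_profile(), seed = 9)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$provenance, s2$provenance)

  tiny <- c(gA = short_seq(100, 1))
  expect_error(
    simulate_sample(tiny, make_budget(c(gA = 5)), fragment_model(),
                    error_profile(), seed = 1),
    "min_insert")
})

test_that("true per-base coverage agrees with the expected depth", {
  g <- c(gA = rand_seq(50000, 7))
  b <- make_budget(c(gA = 5000))   # expected depth 30x
  sim <- simulate_sample(g, b, fragment_model(), error_profile(), seed = 13)
  cov <- place_reads(sim$provenance, c(gA = nchar(g[["gA"]])))
  expected <- expected_depth(b, c(gA = nchar(g[["gA"]])))[["gA"]]
  expect_lt(abs(mean(cov$gA) - expected) / expected, 0.05)
})

test_that("pooling concatenates mates in order and round-trips by provenance", {
  g <- c(gA = rand_seq(20000, 8), gB = rand_seq(20000, 9))
  simA <- simulate_sample(g, make_budget(c(gA = 100, gB = 0)),
                          fragment_model(), error_profile(), seed = 1)
  simB <- simulate_sample(g, make_budget(c(gA = 0, gB = 200)),
                          fragment_model(), error_profile(), seed = 2)
  dir <- withr::local_tempdir()
  pA <- write_sample_fastq(simA, dir, prefix = "a")
  pB <- write_sample_fastq(simB, dir, prefix = "b")
  out1 <- file.path(dir, "pool_R1.fastq")
  out2 <- file.path(dir, "pool_R2.fastq")
  n <- pool_reads(c(pA[["R1"]], pB[["R1"]]), c(pA[["R2"]], pB[["R2"]]),
                  out1, out2)
  expect_equal(n, 300)
  r1 <- magsim:::read_fastq(out1)
  r2 <- magsim:::read_fastq(out2)
  expect_identical(r1$read_id, r2$read_id)
  # split pooled records by provenance: recovers the per-genome sets
  prov <- rbind(simA$provenance, simB$provenance)
  byg <- split(r1$seq, prov$genome_id[match(r1$read_id, prov$read_id)])
  expect_identical(sort(byg$gA), sort(simA$reads$mate1))
  expect_identical(sort(byg$gB), sort(simB$reads$mate1))

  # single input: records pass through unchanged
  solo1 <- file.path(dir, "solo_R1.fastq")
  solo2 <- file.path(dir, "solo_R2.fastq")
  pool_reads(pA[["R1"]], pA[["R2"]], solo1, solo2)
  expect_identical(readLines(solo1), readLines(pA[["R1"]]))

  expect_error(pool_reads(c(pA[["R1"]]), c(pB[["R2"]]), out1, out2),
               "mismatched")
})

test_that("subsampling keeps pairs at the requested rate, deterministically", {
  n <- 1e5
  fake <- structure(
    list(sample_id = "s", read_length = 150L,
         reads = data.frame(read_id = sprintf("r%06d", 1:n),
                            mate1 = "A", mate2 = "A",
                            stringsAsFactors = FALSE),
         qual_string = "I",
         provenance = data.frame(read_id = sprintf("r%06d", 1:n),
                                 genome_id = "g", start = 0L, end = 300L,
                                 strand = "+", stringsAsFactors = FALSE)),
    class = "sim_sample")
  expect_identical(subsample_reads(fake, 1.0, seed = 1)$reads, fake$reads)
  expect_equal(nrow(subsample_reads(fake, 0.0, seed = 1)$reads), 0)
  s1 <- subsample_reads(fake, 0.99, seed = 5)
  s2 <- subsample_reads(fake, 0.99, seed = 5)
  expect_identical(s1$reads$read_id, s2$reads$read_id)
  # both mates and the provenance row travel together
  expect_identical(s1$reads$read_id, s1$provenance$read_id)
  k <- nrow(s1$reads)
  z <- qnorm(0.9995)
  half <- z * sqrt(0.99 * 0.01 * n)
  expect_gt(k, 0.99 * n - half)
  expect_lt(k, 0.99 * n + half)
  expect_error(subsample_reads(fake, 1.5, seed = 1), "rate")
})
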