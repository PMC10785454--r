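test_that("read placement covers both fragment ends and conserves bases", {
  pv <- data.frame(read_id = "r1", genome_id = "g", start = 10L, end = 460L,
                   strand = "+", stringsAsFactors = FALSE)
  cov <- place_reads(pv, c(g = 1000), read_length = 150)$g
  expect_equal(cov[11:160], rep(1L, 150))    # mate 1
  expect_equal(cov[311:460], rep(1L, 150))   # mate 2
  expect_equal(sum(cov), 300)

  empty <- place_reads(pv[0, ], c(g = 1000), read_length = 150)$g
  expect_equal(sum(empty), 0)

  expect_error(place_reads(data.frame(read_id = "x", genome_id = "nope",
                                      start = 0L, end = 300L, strand = "+"),
                           c(g = 1000)),
               "unknown genome")
})

test_that("placed bases are conserved over random fragment sets", {
  set.seed(77)
  for (i in 1:10) {
    L <- 5000L
    n <- sample(50:200, 1)
    insert <- sample(200:400, n, replace = TRUE)
    start <- vapply(insert, function(ins) sample.int(L - ins + 1L, 1L) - 1L, 0L)
    pv <- data.frame(read_id = sprintf("r%d", 1:n), genome_id = "g",
                     start = start, end = start + insert, strand = "+",
                     stringsAsFactors = FALSE)
    cov <- place_reads(pv, c(g = L), read_length = 100)$g
    expect_equal(sum(cov), n * 200)
  }
})

test_that("pseudo-assembly splits at zero-coverage runs and filters by size", {
  g <- c(g1 = short_seq(5000, 31))
  cov <- list(g1 = rep(1L, 5000))
  sc <- pseudo_assemble(g, cov, min_scaffold_len = 500)
  expect_length(sc, 1)
  expect_identical(sc[[1]]$sequence, g[["g1"]])
  expect_false(sc[[1]]$is_chimeric)

  cov2 <- list(g1 = rep(1L, 5000)); cov2$g1[1001:1200] <- 0L
  sc2 <- pseudo_assemble(g, cov2, min_scaffold_len = 500)
  expect_length(sc2, 2)
  spans <- t(vapply(sc2, function(s)
    c(s$origins$source_start, s$origins$source_end), c(0, 0)))
  expect_setequal(split(spans, row(spans)), list(c(0, 1000), c(1200, 5000)))

  # a 1499 bp piece is discarded at min_scaffold_len 1500
  cov3 <- list(g1 = c(rep(1L, 1499), rep(0L, 3501)))
  expect_length(pseudo_assemble(g, cov3, min_scaffold_len = 1500), 0)
  expect_length(pseudo_assemble(g, cov3, min_scaffold_len = 1499), 1)
})

test_that("near-identical pieces merge into a chimeric scaffold when enabled", {
  shared <- short_seq(3000, 41)
  gA <- paste0(short_seq(4000, 42), shared)
  gB <- paste0(shared, short_seq(4000, 43))
  g <- c(gA = gA, gB = gB)
  cov <- list(gA = rep(1L, nchar(gA)), gB = rep(1L, nchar(gB)))
  off <- pseudo_assemble(g, cov, min_scaffold_len = 1000,
                         enable_chimeras = FALSE)
  expect_length(off, 2)
  on <- pseudo_assemble(g, cov, min_scaffold_len = 1000,
                        enable_chimeras = TRUE, chimera_anchor_len = 2000)
  expect_length(on, 1)
  expect_true(on[[1]]$is_chimeric)
  expect_setequal(on[[1]]$origins$genome_id, c("gA", "gB"))
  # origin intervals tile the scaffold without overlap
  o <- on[[1]]$origins[order(on[[1]]$origins$scaffold_start), ]
  expect_equal(o$scaffold_start[1], 0)
  expect_equal(o$scaffold_end[nrow(o)], nchar(on[[1]]$sequence))
  if (nrow(o) > 1) {
    expect_equal(o$scaffold_start[-1], o$scaffold_end[-nrow(o)])
  }
  # each interval reproduces its source sequence
  for (r in seq_len(nrow(o))) {
    expect_identical(
      substr(on[[1]]$sequence, o$scaffold_start[r] + 1, o$scaffold_end[r]),
      substr(g[[o$genome_id[r]]], o$source_start[r] + 1, o$source_end[r]))
  }
})

test_that("depth table reports mean and population variance per scaffold", {
  g <- c(g1 = short_seq(2000, 51))
  sc <- as_scaffold_set(g)
  uniform <- list(sample_1 = list(g1 = rep(10L, 2000)))
  d <- compute_depth_table(sc, uniform)
  expect_equal(d$`sample_1.bam`, 10)
  expect_equal(d$`sample_1.bam-var`, 0)
  expect_equal(d$totalAvgDepth, 10)

  half <- list(sample_1 = list(g1 = c(rep(10L, 1000), rep(20L, 1000))))
  d2 <- compute_depth_table(sc, half)
  expect_equal(d2$`sample_1.bam`, 15)
  expect_equal(d2$`sample_1.bam-var`, 25)

  none <- list(sample_1 = list(g1 = rep(0L, 2000)))
  d3 <- compute_depth_table(sc, none)
  expect_equal(d3$`sample_1.bam`, 0)
  expect_equal(d3$`sample_1.bam-var`, 0)

  # round trip through the jgi-dialect TSV
  path <- withr::local_tempfile(fileext = ".tsv")
  write_depth_table(d2, path)
  back <- read_depth_table(path)
  expect_equal(back$`sample_1.bam`, d2$`sample_1.bam`)
  expect_true(all(c("contigName", "contigLen", "totalAvgDepth",
                    "sample_1.bam", "sample_1.bam-var") %in% names(back)))
})

test_that("tetranucleotide signatures use 136 canonical classes", {
  v <- tnf_vector(short_seq(5000, 61))
  expect_length(v, 136)
  expect_equal(sum(v), 1, tolerance = 1e-9)

  homo <- tnf_vector("AAAAA")
  expect_equal(unname(homo[["AAAA"]]), 1)
  expect_equal(sum(homo), 1)

  s <- short_seq(3000, 62)
  expect_equal(tnf_vector(s), tnf_vector(magsim:::revcomp(s)))
  expect_error(tnf_vector("ACG"), "4 bp")
})

test_that("binning separates genomes by composition and depth", {
  gA <- short_seq(40000, 71)
  gB <- mutate_genome(gA, 0.05, seed = 72)$sequence
  pieces <- function(g, tag) {
    starts <- seq(0, 36000, by = 4000)
    out <- lapply(seq_along(starts), function(i)
      substr(g, starts[i] + 1, starts[i] + 4000))
    names(out) <- sprintf("%s_%02d", tag, seq_along(out))
    unlist(out)
  }
  seqs <- c(pieces(gA, "sA"), pieces(gB, "sB"))
  sc <- as_scaffold_set(seqs)
  depths <- c(rep(10, 10), rep(30, 10))
  dt <- as_depth_table(sc, depths)
  bins <- bin_scaffolds(sc, dt, min_bin_size_bp = 20000, seed = 1)
  real <- setdiff(names(bins$bins), "unbinned")
  expect_length(real, 2)
  ids <- vapply(sc, `[[`, "", "scaffold_id")
  origin <- vapply(sc, function(s) substr(s$origins$genome_id[1], 1, 2), "")
  for (b in real) {
    members <- origin[match(bins$bins[[b]], ids)]
    # scaffold names here encode the source; each bin is pure
    first <- substr(names(seqs)[match(bins$bins[[b]], ids)], 1, 2)
    expect_length(unique(first), 1)
  }
})

test_that("undersized clusters dissolve into the unbinned pool", {
  seqs <- c(a = short_seq(3000, 81), b = short_seq(3000, 82))
  sc <- as_scaffold_set(seqs)
  dt <- as_depth_table(sc, c(10, 10))
  bins <- bin_scaffolds(sc, dt, min_bin_size_bp = 200000, seed = 1)
  expect_equal(setdiff(names(bins$bins), "unbinned"), character(0))
  expect_setequal(bins$bins$unbinned, c("scaffold_0001", "scaffold_0002"))
})

test_that("binning is deterministic and partitions every scaffold", {
  set.seed(91)
  seqs <- stats::setNames(
    vapply(1:8, function(i) short_seq(5000, 90 + i), ""),
    sprintf("s%02d", 1:8))
  sc <- as_scaffold_set(seqs)
  dt <- as_depth_table(sc, sample(c(10, 40), 8, replace = TRUE))
  b1 <- bin_scaffolds(sc, dt, min_bin_size_bp = 5000, seed = 7)
  b2 <- bin_scaffolds(sc, dt, min_bin_size_bp = 5000, seed = 7)
  expect_identical(b1$bins, b2$bins)
  all_ids <- sort(unlist(b1$bins, use.names = FALSE))
  expect_identical(all_ids,
                   sort(vapply(sc, `[[`, "", "scaffold_id")))
})
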