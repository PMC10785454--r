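# Substitution errors: for each read position j the number of affected reads
# is Binomial(n, rate_j); affected reads get a uniformly chosen different
# base. Exactly equivalent to independent per-read-per-position Bernoulli
# draws, but touches only the mutated positions.
apply_substitutions <- function(reads, rates) {
  n <- length(reads)
  if (!n) return(reads)
  alts <- matrix(c("C", "G", "T",
                   "A", "G", "T",
                   "A", "C", "T",
                   "A", "C", "G"),
                 nrow = 4, byrow = TRUE,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(rates)) {
    r <- rates[j]
    if (r <= 0) next
    k <- stats::rbinom(1L, n, r)
    if (!k) next
    idx <- sample.int(n, k)
    cur <- substr(reads[idx], j, j)
    row <- match(cur, rownames(alts))
    ok <- !is.na(row)  # leave non-ACGT untouched
    if (!any(ok)) next
    pick <- sample.int(3L, sum(ok), replace = TRUE)
    newb <- alts[cbind(row[ok], pick)]
    tmp <- reads[idx[ok]]
    substr(tmp, j, j) <- newb
    reads[idx[ok]] <- tmp
  }
  reads
}

#' Simulate a paired-end metagenomic sample
#'
#' Draws the budgeted number of read pairs from each source sequence.
#' Fragment starts are uniform over valid positions; insert lengths are
#' normal(insert_mean, insert_sd) truncated to \[min_insert, genome length\];
#' each fragment is sequenced from a random strand, the second mate being the
#' reverse complement of the far end of the fragment. Substitution errors
#' are applied per position at the profile rate. Every read records its
#' provenance (source, fragment interval, strand) so true depth and
#' placement are known exactly.
#'
#' @param genomes Named character vector of source sequences.
#' @param budget A [allocate_reads()] result.
#' @param frag A [fragment_model()].
#' @param profile An [error_profile()].
#' @param seed Integer seed; fixed seed reproduces the sample exactly.
#' @return A `sim_sample` object: list with `sample_id`, `read_length`,
#'   `reads` (data.frame `read_id`, `mate1`, `mate2`), `qual_string` and
#'   `provenance` (data.frame `read_id`, `genome_id`, `start`, `end`,
#'   `strand`; 0-based half-open fragment coordinates).
#' @export
simulate_sample <- function(genomes, budget, frag = fragment_model(),
                            profile = error_profile(), seed) {
  stopifnot(inherits(budget, "read_budget"), inherits(frag, "fragment_model"),
            inherits(profile, "error_profile"))
  rl <- profile$read_length
  if (frag$min_insert < rl) stop("min_insert must be >= read_length")
  pairs <- budget$pairs_by_genome
  active <- names(pairs)[pairs > 0]
  missing <- setdiff(active, names(genomes))
  if (length(missing)) stop("missing genome sequence for: ", missing[1])
  short <- active[nchar(genomes[active]) < frag$min_insert]
  if (length(short)) {
    stop("genome '", short[1], "' is shorter than min_insert (",
         frag$min_insert, " bp)")
  }

  with_seed(seed, {
    per <- lapply(active, function(g) {
      n <- pairs[[g]]
      gseq <- genomes[[g]]
      L <- nchar(gseq)
      insert <- as.integer(round(stats::rnorm(n, frag$insert_mean, frag$insert_sd)))
      insert <- pmin(pmax(insert, frag$min_insert), L)
      start <- as.integer(floor(stats::runif(n) * (L - insert + 1)))
      end <- start + insert
      fwd <- substring(gseq, start + 1L, start + rl)
      rev <- revcomp(substring(gseq, end - rl + 1L, end))
      strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
      mate1 <- ifelse(strand == "+", fwd, rev)
      mate2 <- ifelse(strand == "+", rev, fwd)
      list(genome_id = rep(g, n), start = start, end = end, strand = strand,
           mate1 = mate1, mate2 = mate2)
    })
    genome_id <- unlist(lapply(per, `[[`, "genome_id"), use.names = FALSE)
    n_total <- length(genome_id)
    read_id <- sprintf("%s_%07d_%s", budget$sample_id, seq_len(n_total),
                       genome_id)
    mate1 <- apply_substitutions(
      unlist(lapply(per, `[[`, "mate1"), use.names = FALSE), profile$rates)
    mate2 <- apply_substitutions(
      unlist(lapply(per, `[[`, "mate2"), use.names = FALSE), profile$rates)
    structure(
      list(
        sample_id = budget$sample_id,
        read_length = rl,
        reads = data.frame(read_id = read_id, mate1 = mate1, mate2 = mate2,
                           stringsAsFactors = FALSE),
        qual_string = profile$qual_string,
        provenance = data.frame(
          read_id = read_id,
          genome_id = genome_id,
          start = unlist(lapply(per, `[[`, "start"), use.names = FALSE),
          end = unlist(lapply(per, `[[`, "end"), use.names = FALSE),
          strand = unlist(lapply(per, `[[`, "strand"), use.names = FALSE),
          stringsAsFactors = FALSE
        )
      ),
      class = "sim_sample"
    )
  })
}

#' Write a simulated sample as paired FASTQ plus a provenance table
#'
#' @param sim A [simulate_sample()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File prefix; files are `<prefix>_R1.fastq`,
#'   `<prefix>_R2.fastq` and `<prefix>_provenance.tsv`.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_sample_fastq <- function(sim, dir, prefix = sim$sample_id) {
  stopifnot(inherits(sim, "sim_sample"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  r1 <- file.path(dir, paste0(prefix, "_R1.fastq"))
  r2 <- file.path(dir, paste0(prefix, "_R2.fastq"))
  pv <- file.path(dir, paste0(prefix, "_provenance.tsv"))
  q <- rep(sim$qual_string, nrow(sim$reads))
  write_fastq(sim$reads$read_id, sim$reads$mate1, q, r1)
  write_fastq(sim$reads$read_id, sim$reads$mate2, q, r2)
  utils::write.table(sim$provenance, pv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(R1 = r1, R2 = r2, provenance = pv))
}

#' Pool per-genome (or per-source) FASTQ pairs into one sample pair
#'
#' Concatenates the forward files and the reverse files in the given order,
#' preserving record order, so R1/R2 records stay index-paired.
#'
#' @param r1_paths,r2_paths Parallel vectors of input FASTQ paths.
#' @param out_r1,out_r2 Output paths.
#' @return Number of pooled pairs, invisibly.
#' @export
pool_reads <- function(r1_paths, r2_paths, out_r1, out_r2) {
  stopifnot(length(r1_paths) == length(r2_paths))
  l1 <- lapply(r1_paths, read_fastq)
  l2 <- lapply(r2_paths, read_fastq)
  if (!identical(vapply(l1, nrow, 0L), vapply(l2, nrow, 0L))) {
    stop("mismatched record counts between mate files")
  }
  r1 <- do.call(rbind, l1)
  r2 <- do.call(rbind, l2)
  write_fastq(r1$read_id, r1$seq, r1$qual, out_r1)
  write_fastq(r2$read_id, r2$seq, r2$qual, out_r2)
  invisible(nrow(r1))
}

#' Randomly subsample read pairs
#'
#' Each pair is kept independently with probability `rate` (one Bernoulli
#' draw per pair; both mates are kept or dropped together), emulating
#' paired-aware `samplerate=` subsampling. Deterministic for a fixed seed.
#'
#' @param sim A [simulate_sample()] result.
#' @param rate Retention probability in \[0, 1\].
#' @param seed Integer seed.
#' @return A `sim_sample` with the kept subset.
#' @export
subsample_reads <- function(sim, rate, seed) {
  stopifnot(inherits(sim, "sim_sample"))
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  n <- nrow(sim$reads)
  keep <- if (rate >= 1) rep(TRUE, n) else if (rate <= 0) rep(FALSE, n) else {
    with_seed(seed, stats::runif(n) < rate)
  }
  out <- sim
  out$reads <- sim$reads[keep, , drop = FALSE]
  out$provenance <- sim$provenance[keep, , drop = FALSE]
  rownames(out$reads) <- NULL
  rownames(out$provenance) <- NULL
  out
}
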