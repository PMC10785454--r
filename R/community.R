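#' Parse a community definition table
#'
#' Reads the CSV table describing a synthetic community: one row per source
#' sequence with its FASTA path, whether it is a chromosome or a plasmid, and
#' its relative genome-copy abundance in each sample. The header must be
#' `genomes,seq_type,<sample columns...>`. Relative paths are resolved
#' against the directory containing the table.
#'
#' @param path Path to the community CSV.
#' @return A `community_spec` object: a list with `entries` (data.frame with
#'   columns `genome_id`, `path`, `seq_type`) , `abundance` (numeric matrix,
#'   genomes x samples) and `sample_ids`.
#' @export
parse_community_table <- function(path) {
  if (!file.exists(path)) stop("community table not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L || !identical(tolower(names(tab)[1:2]), c("genomes", "seq_type"))) {
    stop("community table header must be 'genomes,seq_type,<sample...>'")
  }
  sample_ids <- names(tab)[-(1:2)]
  if (nrow(tab) < 1L) stop("community table has no entries")

  seq_type <- trimws(tab$seq_type)
  bad <- which(!seq_type %in% c("chromosome", "plasmid"))
  if (length(bad)) {
    stop("invalid seq_type '", seq_type[bad[1]], "' in row ", bad[1],
         " (must be 'chromosome' or 'plasmid')")
  }
  paths <- trimws(tab$genomes)
  if (anyDuplicated(paths)) {
    stop("duplicate genome path in community table: ",
         paths[duplicated(paths)][1])
  }
  base <- dirname(normalizePath(path, mustWork = FALSE))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", paths), paths, file.path(base, paths))

  ab <- as.matrix(tab[, -(1:2), drop = FALSE])
  if (!is.numeric(ab)) {
    stop("non-numeric abundance value in community table")
  }
  if (anyNA(ab)) stop("missing abundance value in community table")
  if (any(ab < 0)) {
    bad <- which(ab < 0, arr.ind = TRUE)[1, ]
    stop("negative abundance in row ", bad[1], ", sample '",
         sample_ids[bad[2]], "'")
  }
  genome_id <- sub("\\.(fa|fasta|fna|gbk)$", "", basename(paths))
  if (anyDuplicated(genome_id)) {
    genome_id <- make.unique(genome_id, sep = "_")
  }
  dimnames(ab) <- list(genome_id, sample_ids)
  zero_samples <- colnames(ab)[colSums(ab > 0) == 0L]
  if (length(zero_samples)) {
    stop("sample '", zero_samples[1], "' has no entry with abundance > 0")
  }
  structure(
    list(
      entries = data.frame(genome_id = genome_id, path = abs,
                           seq_type = seq_type, stringsAsFactors = FALSE),
      abundance = ab,
      sample_ids = sample_ids
    ),
    class = "community_spec"
  )
}

#' @export
print.community_spec <- function(x, ...) {
  cat("<community_spec> ", nrow(x$entries), " sequences (",
      sum(x$entries$seq_type == "plasmid"), " plasmid), ",
      length(x$sample_ids), " sample(s)\n", sep = "")
  invisible(x)
}

#' Draw relative abundances from a uniform distribution
#'
#' Relative genome-copy abundances for a community are drawn independently
#' from uniform(low, high); the conventional range for community design is
#' 1 to 3.5.
#'
#' @param n Number of draws (one per organism).
#' @param low,high Bounds of the uniform distribution.
#' @param seed Integer seed; the same seed reproduces the same draws.
#' @return Numeric vector of length `n`.
#' @export
draw_abundances <- function(n, low = 1, high = 3.5, seed) {
  if (n < 1L) stop("n must be >= 1")
  if (low > high) stop("low must be <= high")
  with_seed(seed, stats::runif(n, low, high))
}

#' Allocate a per-sample read budget across genomes
#'
#' Converts relative genome-copy abundances into integer read-pair counts.
#' A genome's share is proportional to abundance x sequence length (equal
#' abundance means equal depth, not equal read count). Integerisation uses
#' the largest-remainder method, ties broken by table order, so the
#' allocation always sums exactly to `total_read_pairs`.
#'
#' @param spec A [parse_community_table()] result.
#' @param sample_id Which sample column to allocate.
#' @param total_read_pairs Total read pairs for the sample.
#' @param genome_lengths Named vector of sequence lengths (bp); required for
#'   every genome with abundance > 0 in the sample.
#' @return A `read_budget` object: list with `sample_id`, `total_read_pairs`
#'   and `pairs_by_genome` (named integer vector over all genomes).
#' @export
allocate_reads <- function(spec, sample_id, total_read_pairs, genome_lengths) {
  stopifnot(inherits(spec, "community_spec"))
  if (!sample_id %in% spec$sample_ids) stop("unknown sample: ", sample_id)
  total_read_pairs <- as.integer(total_read_pairs)
  stopifnot(total_read_pairs >= 0L)
  a <- stats::setNames(spec$abundance[, sample_id],
                       rownames(spec$abundance))
  if (all(a == 0)) stop("all abundances are 0 in sample ", sample_id)
  active <- names(a)[a > 0]
  missing <- setdiff(active, names(genome_lengths))
  if (length(missing)) {
    stop("genome_lengths missing for: ", paste(missing, collapse = ", "))
  }
  w <- numeric(length(a)); names(w) <- names(a)
  w[active] <- a[active] * genome_lengths[active]
  shares <- total_read_pairs * w / sum(w)
  base <- floor(shares)
  rem <- shares - base
  k <- total_read_pairs - sum(base)
  if (k > 0) {
    take <- order(-rem, seq_along(rem))[seq_len(k)]
    base[take] <- base[take] + 1
  }
  pairs <- as.integer(round(base))
  names(pairs) <- names(a)
  structure(
    list(sample_id = sample_id, total_read_pairs = total_read_pairs,
         pairs_by_genome = pairs),
    class = "read_budget"
  )
}

#' Expected per-genome depth of coverage implied by a read budget
#'
#' @param budget A [allocate_reads()] result.
#' @param genome_lengths Named vector of sequence lengths (bp).
#' @param read_length Read length in bp.
#' @return Named numeric vector: `pairs * 2 * read_length / length` per genome.
#' @export
expected_depth <- function(budget, genome_lengths, read_length = 150) {
  stopifnot(inherits(budget, "read_budget"), read_length > 0)
  p <- budget$pairs_by_genome
  depth <- p * 2 * read_length / genome_lengths[names(p)]
  depth[p == 0L] <- 0
  names(depth) <- names(p)
  depth
}
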