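# The 136 reverse-complement-canonical tetramer classes, lexicographically
# keyed by the smaller representative.
tnf_classes <- local({
  classes <- NULL
  function() {
    if (is.null(classes)) {
      kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 4)
      rc <- revcomp(kmers)
      canon <- ifelse(kmers <= rc, kmers, rc)
      classes <<- list(kmers = kmers, canon = canon,
                       levels = sort(unique(canon)))
    }
    classes
  }
})

#' Tetranucleotide frequency signature
#'
#' Counts all 4-mers of a sequence (windows containing non-ACGT characters
#' are skipped), merges each 4-mer with its reverse complement into one of
#' 136 canonical classes, and normalises to sum 1.
#'
#' @param sequence A DNA string (>= 4 bp).
#' @return Named numeric vector of length 136 summing to 1 (all zero if no
#'   window was countable).
#' @export
tnf_vector <- function(sequence) {
  if (nchar(sequence) < 4L) stop("sequence must be at least 4 bp")
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(sequence), width = 4)
  cls <- tnf_classes()
  merged <- tapply(as.numeric(counts),
                   cls$canon[match(names(counts), cls$kmers)], sum)
  out <- merged[cls$levels]
  out[is.na(out)] <- 0
  names(out) <- cls$levels
  tot <- sum(out)
  if (tot > 0) out <- out / tot
  out
}

#' Bin scaffolds by tetranucleotide frequency and depth
#'
#' Pairwise scaffold distance is
#' `w * EuclideanTNF + (1 - w) * mean_s |log1p(depth_i,s) - log1p(depth_j,s)|`
#' (the depth term averaged over samples; with one sample this is the plain
#' log1p-depth difference). Scaffolds are clustered by average-linkage
#' agglomeration cut at `distance_threshold`; clusters whose summed length
#' falls below `min_bin_size_bp` are dissolved into the unbinned pool. The
#' seed only fixes the tie-breaking order in which scaffolds enter the
#' clustering; results are fully deterministic given the seed.
#'
#' @param scaffolds A [pseudo_assemble()] result.
#' @param depth A [compute_depth_table()] result covering every scaffold.
#' @param tnf_weight Weight `w` of the TNF term (default 0.7).
#' @param distance_threshold Agglomeration cut height (default 0.15).
#' @param min_bin_size_bp Minimum summed bin length in bp (default 200000;
#'   plasmid mode reduces this, conventionally to 10000).
#' @param seed Integer seed for tie-breaking order.
#' @return A `bin_set`: list with `bins` (named list, bin id ->
#'   scaffold ids, ordered by decreasing total length), `unbinned_id`
#'   (`"unbinned"`, always present in `bins`) and `params`.
#' @export
bin_scaffolds <- function(scaffolds, depth, tnf_weight = 0.7,
                          distance_threshold = 0.15,
                          min_bin_size_bp = 200000, seed = 1) {
  stopifnot(inherits(scaffolds, "scaffold_set"))
  n <- length(scaffolds)
  params <- list(tnf_weight = tnf_weight,
                 distance_threshold = distance_threshold,
                 min_bin_size_bp = min_bin_size_bp, seed = seed)
  empty <- structure(list(bins = list(unbinned = character(0)),
                          unbinned_id = "unbinned", params = params),
                     class = "bin_set")
  if (n == 0L) return(empty)

  ids <- vapply(scaffolds, `[[`, "", "scaffold_id")
  missing <- setdiff(ids, depth$contigName)
  if (length(missing)) stop("no depth record for scaffold ", missing[1])

  ord <- with_seed(seed, sample.int(n))   # tie-breaking order only
  sc <- scaffolds[ord]
  ids <- ids[ord]
  lens <- vapply(sc, function(s) nchar(s$sequence), 0L)

  tnf <- t(vapply(sc, function(s) tnf_vector(s$sequence), numeric(136)))
  depth_cols <- grep("\\.bam$", names(depth), value = TRUE)
  drow <- match(ids, depth$contigName)
  dmat <- log1p(as.matrix(depth[drow, depth_cols, drop = FALSE]))

  if (n == 1L) {
    cl <- 1L
  } else {
    d_tnf <- as.matrix(stats::dist(tnf))
    d_dep <- matrix(0, n, n)
    for (k in seq_len(ncol(dmat))) {
      d_dep <- d_dep + abs(outer(dmat[, k], dmat[, k], "-"))
    }
    d_dep <- d_dep / ncol(dmat)
    d <- tnf_weight * d_tnf + (1 - tnf_weight) * d_dep
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    cl <- stats::cutree(hc, h = distance_threshold)
  }

  groups <- split(seq_len(n), cl)
  binned <- list(); unbinned <- character(0)
  for (g in groups) {
    if (sum(lens[g]) < min_bin_size_bp) {
      unbinned <- c(unbinned, ids[g])
    } else {
      binned[[length(binned) + 1L]] <- ids[g]
    }
  }
  if (length(binned)) {
    tot <- vapply(binned, function(s) sum(as.numeric(lens[match(s, ids)])), 0)
    first <- vapply(binned, function(s) min(s), "")
    binned <- binned[order(-tot, first)]
    names(binned) <- sprintf("bin.%d", seq_along(binned))
  }
  bins <- c(binned, list(unbinned = sort(unbinned)))
  structure(list(bins = bins, unbinned_id = "unbinned", params = params),
            class = "bin_set")
}

# Named list: bin id -> named character vector of scaffold sequences.
bin_sequences <- function(bins, scaffolds) {
  stopifnot(inherits(bins, "bin_set"), inherits(scaffolds, "scaffold_set"))
  ids <- vapply(scaffolds, `[[`, "", "scaffold_id")
  seqs <- vapply(scaffolds, `[[`, "", "sequence")
  names(seqs) <- ids
  lapply(bins$bins, function(s) seqs[s])
}

#' Write bins as FASTA files
#'
#' One file per bin (`bin.<k>.fa`), the unbinned pool as `unbinned.fa`.
#'
#' @param bins A [bin_scaffolds()] result.
#' @param scaffolds The matching `scaffold_set`.
#' @param dir Output directory.
#' @return Named vector of written paths, invisibly.
#' @export
write_bins_fasta <- function(bins, scaffolds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- bin_sequences(bins, scaffolds)
  paths <- character(0)
  for (b in names(seqs)) {
    fn <- file.path(dir, if (b == bins$unbinned_id) "unbinned.fa"
                         else paste0(b, ".fa"))
    if (length(seqs[[b]])) write_fasta(seqs[[b]], fn) else file.create(fn)
    paths[b] <- fn
  }
  invisible(paths)
}
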