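# Per-base coverage of one scaffold in one sample, assembled from the
# genome-space coverage vectors through the scaffold's origin intervals.
scaffold_base_coverage <- function(scaffold, coverage) {
  cov <- integer(nchar(scaffold$sequence))
  for (r in seq_len(nrow(scaffold$origins))) {
    o <- scaffold$origins[r, ]
    src <- coverage[[o$genome_id]]
    if (is.null(src)) next
    idx <- (o$source_start + 1L):o$source_end
    cov[(o$scaffold_start + 1L):o$scaffold_end] <- src[idx]
  }
  cov
}

#' Compute a jgi-style scaffold depth table
#'
#' For every scaffold and sample, the average depth (placed bases / scaffold
#' length) and the population variance of per-base coverage, in the dialect
#' of `jgi_summarize_bam_contig_depths`.
#'
#' @param scaffolds A [pseudo_assemble()] result.
#' @param coverage_by_sample Named list (one element per sample) of
#'   [place_reads()] results.
#' @return A `depth_table` data.frame: `contigName`, `contigLen`,
#'   `totalAvgDepth`, then one `<sample>.bam` / `<sample>.bam-var` column
#'   pair per sample.
#' @export
compute_depth_table <- function(scaffolds, coverage_by_sample) {
  stopifnot(inherits(scaffolds, "scaffold_set"))
  samples <- names(coverage_by_sample)
  n <- length(scaffolds)
  out <- data.frame(
    contigName = vapply(scaffolds, `[[`, "", "scaffold_id"),
    contigLen = vapply(scaffolds, function(s) nchar(s$sequence), 0L),
    totalAvgDepth = numeric(n),
    stringsAsFactors = FALSE
  )
  for (s in samples) {
    avg <- numeric(n); va <- numeric(n)
    for (i in seq_len(n)) {
      cov <- scaffold_base_coverage(scaffolds[[i]], coverage_by_sample[[s]])
      avg[i] <- mean(cov)
      va[i] <- mean((cov - avg[i])^2)   # population variance
    }
    out[[paste0(s, ".bam")]] <- avg
    out[[paste0(s, ".bam-var")]] <- va
  }
  depth_cols <- paste0(samples, ".bam")
  out$totalAvgDepth <- rowMeans(out[, depth_cols, drop = FALSE])
  class(out) <- c("depth_table", "data.frame")
  out
}

#' Write / read the jgi-dialect depth TSV
#' @param depth A [compute_depth_table()] result.
#' @param path TSV path.
#' @export
write_depth_table <- function(depth, path) {
  utils::write.table(depth, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_depth_table
#' @export
read_depth_table <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("depth_table", "data.frame")
  out
}
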