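# 3'-end Phred-style trim point for one quality vector: cut the trailing
# segment maximising sum(threshold - q_i); returns the kept length.
trim_point <- function(q, threshold) {
  d <- rev(threshold - q)
  s <- cumsum(d)
  m <- max(s)
  if (m <= 0) return(length(q))
  length(q) - which.max(s)
}

#' Quality-trim paired reads
#'
#' Applies 3'-end Phred-style trimming to both mates of every pair: each
#' read is cut at the position that maximises the sum of
#' `(threshold - quality)` over the trailing segment (the BWA/BBDuk trimming
#' rule). Pairs where either trimmed mate falls below `min_length` are
#' dropped entirely.
#'
#' @param r1,r2 data.frames with columns `read_id`, `seq`, `qual`
#'   (Phred+33), as returned by [read_fastq()].
#' @param quality_threshold Phred threshold Q (default 20).
#' @param min_length Minimum surviving mate length in bp (default 50).
#' @return List with trimmed `r1`, `r2`, and `report` (list: `pairs_in`,
#'   `pairs_out`, `pairs_dropped`, `bases_in`, `bases_out`).
#' @export
trim_reads <- function(r1, r2, quality_threshold = 20, min_length = 50) {
  stopifnot(nrow(r1) == nrow(r2))
  bad <- which(nchar(r1$seq) != nchar(r1$qual) | nchar(r2$seq) != nchar(r2$qual))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1], ": sequence/quality length mismatch")
  }
  n <- nrow(r1)
  trim_one <- function(df) {
    if (n == 0L) return(integer(0))
    vapply(phred_to_int(df$qual), trim_point, 0L,
           threshold = quality_threshold)
  }
  k1 <- trim_one(r1)
  k2 <- trim_one(r2)
  keep <- k1 >= min_length & k2 >= min_length
  bases_in <- sum(nchar(r1$seq)) + sum(nchar(r2$seq))
  clip <- function(df, k, keep) {
    out <- df[keep, , drop = FALSE]
    kk <- k[keep]
    out$seq <- substr(out$seq, 1L, kk)
    out$qual <- substr(out$qual, 1L, kk)
    rownames(out) <- NULL
    out
  }
  r1o <- clip(r1, k1, keep)
  r2o <- clip(r2, k2, keep)
  list(
    r1 = r1o, r2 = r2o,
    report = list(
      pairs_in = n,
      pairs_out = sum(keep),
      pairs_dropped = n - sum(keep),
      bases_in = bases_in,
      bases_out = sum(nchar(r1o$seq)) + sum(nchar(r2o$seq))
    )
  )
}
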