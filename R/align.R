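# Maximal exact matches of length >= k between query and ref, found by
# joining k-mer position tables on a hash and collapsing runs of consecutive
# positions on each diagonal. Coordinates are 0-based.
find_mems <- function(query, ref, k) {
  nq <- nchar(query); nr <- nchar(ref)
  if (nq < k || nr < k) return(NULL)
  qk <- substring(query, 1:(nq - k + 1L), k:nq)
  rk <- substring(ref, 1:(nr - k + 1L), k:nr)
  dtq <- data.table::data.table(kmer = qk, qpos = 0:(nq - k))
  dtr <- data.table::data.table(kmer = rk, rpos = 0:(nr - k))
  m <- dtr[dtq, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(m)) return(NULL)
  m[, diag := qpos - rpos]
  data.table::setorder(m, diag, qpos)
  m[, grp := cumsum(c(TRUE, diff(qpos) != 1L | diff(diag) != 0L))]
  mems <- m[, list(qpos = qpos[1], rpos = rpos[1],
                   len = .N + k - 1L), by = "grp"]
  as.data.frame(mems[, c("qpos", "rpos", "len")])
}

empty_hits <- function() {
  structure(
    data.frame(ref_id = character(0), query_id = character(0),
               ref_start = integer(0), ref_end = integer(0),
               query_start = integer(0), query_end = integer(0),
               length = integer(0), identity = numeric(0),
               stringsAsFactors = FALSE),
    class = c("alignment_hits", "data.frame")
  )
}

# Chain MEMs lying on one diagonal with inter-anchor gaps <= max_gap into a
# single hit; identity is computed column-wise over the full chained span
# (substitution-only divergence keeps both sequences on the diagonal, so the
# span comparison is exact).
chain_diagonal <- function(mems, qseq, rseq, max_gap) {
  o <- order(mems$qpos - mems$rpos, mems$qpos)
  mems <- mems[o, , drop = FALSE]
  diag <- mems$qpos - mems$rpos
  gap_prev <- c(Inf, mems$qpos[-1] - (mems$qpos[-nrow(mems)] +
                                        mems$len[-nrow(mems)]))
  new_chain <- diag != c(NA, diag[-length(diag)])
  new_chain[1] <- TRUE
  new_chain <- new_chain | gap_prev > max_gap
  cid <- cumsum(new_chain)
  out <- lapply(split(seq_len(nrow(mems)), cid), function(ix) {
    q1 <- mems$qpos[ix[1]]
    r1 <- mems$rpos[ix[1]]
    last <- ix[length(ix)]
    q2 <- mems$qpos[last] + mems$len[last]
    r2 <- mems$rpos[last] + mems$len[last]
    a <- substr(rseq, r1 + 1L, r2)
    b <- substr(qseq, q1 + 1L, q2)
    mm <- sum(utf8ToInt(a) != utf8ToInt(b))
    span <- r2 - r1
    data.frame(ref_start = r1, ref_end = r2, query_start = q1,
               query_end = q2, length = span,
               identity = 100 * (span - mm) / span,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Anchor-chain alignment between two sequence sets
#'
#' A deterministic stand-in for whole-genome alignment: maximal exact
#' anchors of length at least `anchor_k` are found between every
#' query/reference sequence pair, collinear anchors on the same diagonal
#' separated by at most `max_gap` bp are chained, and each chain reports its
#' span on both sequences plus the column-wise identity over the span.
#' Forward strand only; coordinates 0-based half-open internally (reports
#' use the 1-based inclusive convention, see [write_hits_tsv()]).
#'
#' @param query,ref Named character vectors of sequences, or paths to FASTA
#'   files.
#' @param anchor_k Minimum exact anchor length (default 20).
#' @param max_gap Maximum gap between chained anchors in bp (default 500).
#' @return An `alignment_hits` data.frame: `ref_id`, `query_id`,
#'   `ref_start`, `ref_end`, `query_start`, `query_end`, `length`,
#'   `identity` (percent).
#' @export
align_sequences <- function(query, ref, anchor_k = 20, max_gap = 500) {
  as_set <- function(x, what) {
    if (length(x) == 1L && is.null(names(x)) && file.exists(x)) {
      x <- read_fasta(x)
    }
    if (!length(x)) stop("empty ", what, " sequence set")
    if (is.null(names(x))) names(x) <- paste0(what, seq_along(x))
    x
  }
  query <- as_set(query, "query")
  ref <- as_set(ref, "ref")
  hits <- list()
  for (r in names(ref)) {
    for (q in names(query)) {
      mems <- find_mems(query[[q]], ref[[r]], anchor_k)
      if (is.null(mems) || !nrow(mems)) next
      h <- chain_diagonal(mems, query[[q]], ref[[r]], max_gap)
      h$ref_id <- r
      h$query_id <- q
      hits[[length(hits) + 1L]] <- h
    }
  }
  if (!length(hits)) return(empty_hits())
  out <- do.call(rbind, hits)
  out <- out[, c("ref_id", "query_id", "ref_start", "ref_end",
                 "query_start", "query_end", "length", "identity")]
  rownames(out) <- NULL
  class(out) <- c("alignment_hits", "data.frame")
  out
}

#' Filter alignment hits by length and identity
#'
#' Keeps hits with `length >= min_len` and `identity >= min_identity`
#' (both inclusive); the conventional contamination-analysis thresholds are
#' 2000 bp and 70 percent.
#'
#' @param hits An `alignment_hits` data.frame.
#' @param min_len Minimum hit length in bp.
#' @param min_identity Minimum percent identity.
#' @return Filtered `alignment_hits`.
#' @export
filter_hits <- function(hits, min_len = 2000, min_identity = 70) {
  out <- hits[hits$length >= min_len & hits$identity >= min_identity, ,
              drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("alignment_hits", "data.frame")
  out
}

#' Keep only hits at exactly 100 percent identity
#' @param hits An `alignment_hits` data.frame.
#' @return Filtered `alignment_hits`.
#' @export
perfect_hits <- function(hits) {
  out <- hits[hits$identity == 100, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("alignment_hits", "data.frame")
  out
}

#' Write hits in the show-coords column order
#'
#' TSV columns: ref_start, ref_end, query_start, query_end,
#' ref_len_aligned, query_len_aligned, identity, ref_id, query_id.
#' Coordinates are converted to the 1-based inclusive report convention.
#'
#' @param hits An `alignment_hits` data.frame.
#' @param path Output TSV.
#' @export
write_hits_tsv <- function(hits, path) {
  rep <- data.frame(
    ref_start = hits$ref_start + 1L, ref_end = hits$ref_end,
    query_start = hits$query_start + 1L, query_end = hits$query_end,
    ref_len_aligned = hits$ref_end - hits$ref_start,
    query_len_aligned = hits$query_end - hits$query_start,
    identity = hits$identity, ref_id = hits$ref_id, query_id = hits$query_id,
    stringsAsFactors = FALSE
  )
  utils::write.table(rep, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
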