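# Greedy selection of the longest mutually consistent subset of hits:
# hits are taken in decreasing length order and kept only if they overlap no
# already-kept hit on either their reference or their query sequence.
select_consistent_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  o <- order(-hits$length, hits$ref_id, hits$query_id, hits$ref_start)
  hits <- hits[o, , drop = FALSE]
  kept <- logical(nrow(hits))
  ref_iv <- list(); qry_iv <- list()
  overlaps <- function(ivs, s, e) {
    any(vapply(ivs, function(iv) s < iv[2] && iv[1] < e, TRUE))
  }
  for (i in seq_len(nrow(hits))) {
    rk <- hits$ref_id[i]; qk <- hits$query_id[i]
    if (overlaps(ref_iv[[rk]] %||% list(), hits$ref_start[i], hits$ref_end[i]))
      next
    if (overlaps(qry_iv[[qk]] %||% list(), hits$query_start[i], hits$query_end[i]))
      next
    kept[i] <- TRUE
    ref_iv[[rk]] <- c(ref_iv[[rk]], list(c(hits$ref_start[i], hits$ref_end[i])))
    qry_iv[[qk]] <- c(qry_iv[[qk]], list(c(hits$query_start[i], hits$query_end[i])))
  }
  out <- hits[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average nucleotide identity between two sequence sets
#'
#' Aligns set B (query) against set A (reference), applies the standard hit
#' filter, keeps per reference and per query the longest mutually consistent
#' (non-overlapping) hits, and reports the length-weighted mean identity of
#' that subset as ANI, together with the aligned fraction of each set
#' (union of covered bases / total bases).
#'
#' @param seq_set_a,seq_set_b Named character vectors of sequences (A is the
#'   reference side, B the query side).
#' @param anchor_k,max_gap Aligner parameters, see [align_sequences()].
#' @param min_len,min_identity Hit filter, see [filter_hits()].
#' @return List with `ani` (in \[0, 1\], `NA` when no qualifying hit),
#'   `aligned_fraction_a`, `aligned_fraction_b`, and the selected `hits`.
#' @export
compute_ani <- function(seq_set_a, seq_set_b, anchor_k = 20, max_gap = 500,
                        min_len = 2000, min_identity = 70) {
  if (!length(seq_set_a) || !length(seq_set_b)) {
    stop("both sequence sets must be non-empty")
  }
  hits <- align_sequences(query = seq_set_b, ref = seq_set_a,
                          anchor_k = anchor_k, max_gap = max_gap)
  hits <- filter_hits(hits, min_len = min_len, min_identity = min_identity)
  sel <- select_consistent_hits(hits)
  if (!nrow(sel)) {
    return(list(ani = NA_real_, aligned_fraction_a = 0,
                aligned_fraction_b = 0, hits = sel))
  }
  ani <- sum(sel$length * sel$identity) / sum(sel$length) / 100
  cov_a <- sum(vapply(split(sel, sel$ref_id), function(h)
    interval_union_length(h$ref_start, h$ref_end), 0))
  cov_b <- sum(vapply(split(sel, sel$query_id), function(h)
    interval_union_length(h$query_start, h$query_end), 0))
  list(
    ani = ani,
    aligned_fraction_a = cov_a / sum(nchar(seq_set_a)),
    aligned_fraction_b = cov_b / sum(nchar(seq_set_b)),
    hits = sel
  )
}

#' Pairwise source-by-bin ANI matrix
#'
#' Computes [compute_ani()] for every source sequence against every bin
#' (including the unbinned pool). Filtered full hit sets are retained per
#' pair for downstream completeness/contamination calculation.
#'
#' @param sources Named character vector, one sequence per source.
#' @param bin_seqs Named list (bin id -> named character vector of scaffold
#'   sequences), e.g. from `bin_sequences()`; empty bins yield absent ANI.
#' @param ... Passed to [compute_ani()].
#' @return An `ani_matrix` object: list with `ani`, `cov_source`, `cov_bin`
#'   (numeric matrices sources x bins, `NA`/0 when absent) and `hits`
#'   (named list `"<source>|<bin>"` of filtered hits).
#' @export
ani_matrix <- function(sources, bin_seqs, ...) {
  src <- names(sources)
  bns <- names(bin_seqs)
  ani <- matrix(NA_real_, length(src), length(bns),
                dimnames = list(src, bns))
  cov_s <- matrix(0, length(src), length(bns), dimnames = dimnames(ani))
  cov_b <- cov_s
  hits <- list()
  for (s in src) {
    for (b in bns) {
      if (!length(bin_seqs[[b]])) next
      res <- compute_ani(sources[s], bin_seqs[[b]], ...)
      ani[s, b] <- res$ani
      cov_s[s, b] <- res$aligned_fraction_a
      cov_b[s, b] <- res$aligned_fraction_b
      hits[[paste(s, b, sep = "|")]] <- res$hits
    }
  }
  structure(list(ani = ani, cov_source = cov_s, cov_bin = cov_b,
                 hits = hits),
            class = "ani_matrix")
}

#' Match bins to source sequences by mutual-best ANI
#'
#' A bin `b` is assigned to source `s` iff (a) `b` has the highest ANI to
#' `s` among all bins, (b) `s` has the highest ANI to `b` among all sources,
#' and (c) `b` is not the pool of unbinned scaffolds. Sources or bins
#' failing any criterion stay unmatched; the assignment is injective. Ties
#' are broken by higher aligned fraction, then lexicographic id.
#'
#' @param ani An [ani_matrix()] object, or a plain numeric matrix
#'   (rows = sources, columns = bins, `NA` = no qualifying alignment).
#' @param unbinned_bin_id Column excluded by criterion (c)
#'   (default `"unbinned"`).
#' @return A `match_assignment`: list with `pairs` (named character vector,
#'   source -> bin), `unmatched_sources`, `unmatched_bins` (the unbinned
#'   pool itself is not listed among bins).
#' @export
match_bins_to_sources <- function(ani, unbinned_bin_id = "unbinned") {
  if (inherits(ani, "ani_matrix")) {
    m <- ani$ani; cov_s <- ani$cov_source; cov_b <- ani$cov_bin
  } else {
    m <- ani
    cov_s <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
    cov_b <- cov_s
  }
  src <- rownames(m); bns <- colnames(m)
  argbest <- function(vals, covs, ids) {
    ok <- which(!is.na(vals))
    if (!length(ok)) return(NA_character_)
    o <- ok[order(-vals[ok], -covs[ok], ids[ok])]
    ids[o[1]]
  }
  best_bin <- vapply(src, function(s) argbest(m[s, ], cov_s[s, ], bns), "")
  best_src <- vapply(bns, function(b) argbest(m[, b], cov_b[, b], src), "")
  pairs <- character(0)
  for (s in src) {
    b <- best_bin[[s]]
    if (is.na(b) || identical(b, unbinned_bin_id)) next
    if (identical(best_src[[b]], s)) pairs[s] <- b
  }
  structure(
    list(pairs = pairs,
         unmatched_sources = setdiff(src, names(pairs)),
         unmatched_bins = setdiff(setdiff(bns, unbinned_bin_id),
                                  unname(pairs))),
    class = "match_assignment"
  )
}
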