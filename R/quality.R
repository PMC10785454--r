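#' Alignment-based true completeness and contamination
#'
#' With known sources, completeness and contamination are calculated rather
#' than estimated: completeness is the percentage of the source covered by
#' filtered hits to its matched bin; contamination is the percentage of the
#' bin covered by filtered hits from any *other* source. Interval unions
#' merge overlapping hits before measuring.
#'
#' @param source_id Matched source id.
#' @param bin_id Matched bin id.
#' @param anim An [ani_matrix()] carrying the filtered hits for every
#'   source/bin pair.
#' @param source_lengths Named vector of source lengths (bp).
#' @param bin_lengths Named vector of total bin lengths (bp).
#' @return A `quality_report` list: `source_id`, `bin_id`, `completeness`,
#'   `contamination` (percent), `quality_class` (see [classify_quality()]).
#' @export
completeness_contamination <- function(source_id, bin_id, anim,
                                       source_lengths, bin_lengths) {
  stopifnot(inherits(anim, "ani_matrix"))
  own <- anim$hits[[paste(source_id, bin_id, sep = "|")]]
  compl <- if (is.null(own) || !nrow(own)) 0 else {
    100 * interval_union_length(own$ref_start, own$ref_end) /
      source_lengths[[source_id]]
  }
  other <- setdiff(rownames(anim$ani), source_id)
  starts <- integer(0); ends <- integer(0); qids <- character(0)
  for (s in other) {
    h <- anim$hits[[paste(s, bin_id, sep = "|")]]
    if (is.null(h) || !nrow(h)) next
    starts <- c(starts, h$query_start); ends <- c(ends, h$query_end)
    qids <- c(qids, h$query_id)
  }
  contam <- if (!length(starts)) 0 else {
    covered <- sum(vapply(split(seq_along(starts), qids), function(ix)
      interval_union_length(starts[ix], ends[ix]), 0))
    100 * covered / bin_lengths[[bin_id]]
  }
  list(source_id = source_id, bin_id = bin_id,
       completeness = unname(compl), contamination = unname(contam),
       quality_class = classify_quality(compl, contam))
}

#' Classify bin quality against the high-quality draft cutoffs
#'
#' `"high"` requires completeness strictly over 90 percent and contamination
#' strictly under 5 percent; everything else is `"other"`.
#'
#' @param completeness,contamination Percentages.
#' @return `"high"` or `"other"`.
#' @export
classify_quality <- function(completeness, contamination) {
  if (completeness > 90 && contamination < 5) "high" else "other"
}

#' Assembly statistics for a set of scaffolds
#'
#' N50 is the length of the scaffold at which the cumulative length (in
#' descending length order) first reaches half the total; L50 is that
#' scaffold's rank. GC is computed over A/C/G/T bases only.
#'
#' @param sequences Character vector of scaffold sequences (>= 1).
#' @return List: `n_scaffolds`, `total_length`, `max_length`, `N50`, `L50`,
#'   `gc_percent`.
#' @export
scaffold_stats <- function(sequences) {
  if (!length(sequences)) stop("scaffold_stats requires at least one sequence")
  lens <- sort(nchar(sequences), decreasing = TRUE)
  total <- sum(as.numeric(lens))
  cum <- cumsum(as.numeric(lens))
  l50 <- which(cum >= total / 2)[1]
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(sequences))[, c("A", "C", "G", "T"), drop = FALSE])
  acgt <- sum(counts)
  list(
    n_scaffolds = length(sequences),
    total_length = total,
    max_length = lens[1],
    N50 = lens[l50],
    L50 = l50,
    gc_percent = if (acgt > 0) 100 * (counts[["G"]] + counts[["C"]]) / acgt
                 else NA_real_
  )
}
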