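#' Depth-subsampling sensitivity experiment
#'
#' Starting from a completed sample run, read pairs are randomly
#' subsampled (default retaining 99 percent), depth is recalculated over
#' the *same* scaffolds, binning is repeated with the *same* binning seed
#' and settings, and bins are re-matched to the sources. The point of the
#' experiment is that tiny depth fluctuations can flip whether a source's
#' scaffolds are binned at all.
#'
#' @param run A `sample_run` from [run_pipeline()].
#' @param rate Retention probability (default 0.99).
#' @param n_replicates Number of independent subsampling replicates
#'   (default 3).
#' @param seeds Optional integer vector of subsampling seeds (one per
#'   replicate); derived from the run's binning seed when omitted.
#' @return List with `report` (data.frame `source`, `replicate`,
#'   `matched_before`, `matched_after`) and `runs` (per-replicate list with
#'   the re-binned `bins` and `assignment`).
#' @export
run_subsample_experiment <- function(run, rate = 0.99, n_replicates = 3,
                                     seeds = NULL) {
  stopifnot(inherits(run, "sample_run"))
  if (is.null(run$sim$provenance)) stop("run carries no stored placements")
  if (is.null(seeds)) {
    seeds <- vapply(seq_len(n_replicates), function(i)
      derive_seed(run$bin_seed, 9000L, i), 0L)
  }
  stopifnot(length(seeds) == n_replicates)
  cfg <- run$config
  glen <- nchar(run$sources)
  before <- names(run$eval$assignment$pairs)
  all_sources <- names(run$sources)

  runs <- list()
  rows <- list()
  for (i in seq_len(n_replicates)) {
    sub <- subsample_reads(run$sim, rate, seed = seeds[i])
    coverage <- place_reads(sub$provenance, glen, cfg$read_length)
    cov_by_sample <- stats::setNames(list(coverage), run$sample_id)
    depth <- compute_depth_table(run$scaffolds, cov_by_sample)
    bins <- bin_scaffolds(run$scaffolds, depth, tnf_weight = cfg$tnf_weight,
                          distance_threshold = cfg$distance_threshold,
                          min_bin_size_bp = cfg$min_bin_size_bp,
                          seed = run$bin_seed)
    ev <- evaluate_bins(run$sources, run$scaffolds, bins,
                        anchor_k = cfg$anchor_k, max_gap = cfg$max_gap)
    after <- names(ev$assignment$pairs)
    rows[[i]] <- data.frame(
      source = all_sources,
      replicate = i,
      matched_before = all_sources %in% before,
      matched_after = all_sources %in% after,
      stringsAsFactors = FALSE
    )
    runs[[i]] <- list(seed = seeds[i], kept_pairs = nrow(sub$reads),
                      depth = depth, bins = bins,
                      assignment = ev$assignment)
  }
  list(report = do.call(rbind, rows), runs = runs)
}
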