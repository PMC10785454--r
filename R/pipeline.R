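# Deterministic child-seed derivation; keeps results inside 32-bit range.
derive_seed <- function(base, a = 0L, b = 0L) {
  as.integer((as.numeric(base) * 1009 + as.numeric(a) * 101 +
                as.numeric(b)) %% 2147483647)
}

#' Assemble a pipeline run configuration
#'
#' Defaults follow the package's module defaults; `plasmid_mode` reduces
#' the minimum bin size so plasmid-scale bins are not dissolved outright.
#' A YAML config file with any of these keys can be loaded with
#' [read_run_config()].
#'
#' @param community_table Path to the community CSV.
#' @param out_dir Output directory.
#' @param seed Integer seed; replicate `r` uses child seed `seed + r`.
#' @param replicates Number of replicates (default 3).
#' @param total_read_pairs Read pairs per sample (default 250000).
#' @param read_length Read length bp (default 150).
#' @param substitution_rate Flat substitution rate when no profile file is
#'   given (default 0.002).
#' @param error_profile Optional path to a 2-column error-profile TSV.
#' @param insert_mean,insert_sd,min_insert Fragment model (bp).
#' @param trim_quality,trim_min_length Trimming parameters.
#' @param min_scaffold_len Assembly size filter (bp).
#' @param plasmid_mode Reduce the minimum bin size (default FALSE).
#' @param min_bin_size_bp Minimum bin size; defaults to 200000, or 10000 in
#'   plasmid mode.
#' @param tnf_weight,distance_threshold Binning distance parameters.
#' @param anchor_k,max_gap Aligner parameters.
#' @param enable_chimeras,chimera_anchor_len Pseudo-assembly chimera merge.
#' @return A `run_config` list.
#' @export
run_config <- function(community_table, out_dir, seed, replicates = 3,
                       total_read_pairs = 250000, read_length = 150,
                       substitution_rate = 0.002, error_profile = NULL,
                       insert_mean = 400, insert_sd = 40, min_insert = 200,
                       trim_quality = 20, trim_min_length = 50,
                       min_scaffold_len = 1500, plasmid_mode = FALSE,
                       min_bin_size_bp = NULL, tnf_weight = 0.7,
                       distance_threshold = 0.15, anchor_k = 20,
                       max_gap = 500, enable_chimeras = FALSE,
                       chimera_anchor_len = 2000) {
  stopifnot(replicates >= 1)
  if (is.null(min_bin_size_bp)) {
    min_bin_size_bp <- if (plasmid_mode) 10000 else 200000
  }
  as.list(environment())
}

#' Read a YAML run configuration
#'
#' Recognised keys are the arguments of [run_config()] (the spec'd core
#' keys being `total_read_pairs`, `read_length`, `seed`, `replicates`,
#' `plasmid_mode`).
#'
#' @param path YAML file.
#' @param ... Overrides applied after the file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, utils::modifyList(vals, list(...)))
}

run_one_sample <- function(spec, genomes, sample_id, cfg, child_seed,
                           sidx, dir, log) {
  profile <- if (!is.null(cfg$error_profile)) {
    read_error_profile(cfg$error_profile)
  } else {
    error_profile(cfg$read_length, cfg$substitution_rate)
  }
  frag <- fragment_model(cfg$insert_mean, cfg$insert_sd, cfg$min_insert)
  glen <- nchar(genomes)

  budget <- allocate_reads(spec, sample_id, cfg$total_read_pairs, glen)
  sim_seed <- derive_seed(child_seed, sidx, 1L)
  sim <- simulate_sample(genomes, budget, frag, profile, seed = sim_seed)
  log("sample=%s sim_seed=%d pairs=%d", sample_id, sim_seed,
      nrow(sim$reads))
  write_sample_fastq(sim, dir, prefix = sample_id)

  # trimming is the identity when every profile quality is already at or
  # above the threshold; run the full rule only when it can change reads
  if (min(profile$quality) < cfg$trim_quality) {
    q <- rep(sim$qual_string, nrow(sim$reads))
    r1 <- data.frame(read_id = sim$reads$read_id, seq = sim$reads$mate1,
                     qual = q, stringsAsFactors = FALSE)
    r2 <- data.frame(read_id = sim$reads$read_id, seq = sim$reads$mate2,
                     qual = q, stringsAsFactors = FALSE)
    tr <- trim_reads(r1, r2, cfg$trim_quality, cfg$trim_min_length)
    keep <- sim$reads$read_id %in% tr$r1$read_id
    sim$reads <- sim$reads[keep, , drop = FALSE]
    sim$provenance <- sim$provenance[keep, , drop = FALSE]
    log("sample=%s trimmed: %d -> %d pairs", sample_id, tr$report$pairs_in,
        tr$report$pairs_out)
  }

  present <- names(glen)[budget$pairs_by_genome[names(glen)] > 0]
  coverage <- place_reads(sim$provenance, glen[present], cfg$read_length)
  scaffolds <- pseudo_assemble(genomes[present], coverage,
                               min_scaffold_len = cfg$min_scaffold_len,
                               enable_chimeras = cfg$enable_chimeras,
                               chimera_anchor_len = cfg$chimera_anchor_len)
  cov_by_sample <- stats::setNames(list(coverage), sample_id)
  depth <- compute_depth_table(scaffolds, cov_by_sample)
  write_depth_table(depth, file.path(dir, "depth.tsv"))

  bin_seed <- derive_seed(child_seed, sidx, 2L)
  bins <- bin_scaffolds(scaffolds, depth, tnf_weight = cfg$tnf_weight,
                        distance_threshold = cfg$distance_threshold,
                        min_bin_size_bp = cfg$min_bin_size_bp,
                        seed = bin_seed)
  log("sample=%s bin_seed=%d min_bin_size_bp=%d tnf_weight=%g threshold=%g bins=%d",
      sample_id, bin_seed, cfg$min_bin_size_bp, cfg$tnf_weight,
      cfg$distance_threshold, length(bins$bins) - 1L)
  write_bins_fasta(bins, scaffolds, file.path(dir, "bins"))

  eval <- evaluate_bins(genomes[present], scaffolds, bins,
                        anchor_k = cfg$anchor_k, max_gap = cfg$max_gap)
  run <- list(sample_id = sample_id, dir = dir, budget = budget, sim = sim,
              coverage = coverage, scaffolds = scaffolds, depth = depth,
              bins = bins, bin_seed = bin_seed, eval = eval,
              sources = genomes[present], config = cfg)
  class(run) <- "sample_run"
  write_general_summary(run, dir)
  write_bin_summary(run, dir)
  run
}

#' Evaluate bins against their known source sequences
#'
#' Computes the source-by-bin ANI matrix, the mutual-best match assignment,
#' and alignment-based completeness/contamination with quality class for
#' every matched pair.
#'
#' @param sources Named character vector of source sequences.
#' @param scaffolds The `scaffold_set` that was binned.
#' @param bins A [bin_scaffolds()] result.
#' @param anchor_k,max_gap Aligner parameters.
#' @return List with `anim` ([ani_matrix()]), `assignment`
#'   ([match_bins_to_sources()]) and `quality` (data.frame per matched
#'   pair).
#' @export
evaluate_bins <- function(sources, scaffolds, bins, anchor_k = 20,
                          max_gap = 500) {
  bseqs <- bin_sequences(bins, scaffolds)
  anim <- ani_matrix(sources, bseqs, anchor_k = anchor_k, max_gap = max_gap)
  assignment <- match_bins_to_sources(anim, bins$unbinned_id)
  src_len <- nchar(sources)
  bin_len <- vapply(bseqs, function(s) sum(nchar(s)), 0)
  qual <- lapply(names(assignment$pairs), function(s) {
    q <- completeness_contamination(s, assignment$pairs[[s]], anim,
                                    src_len, bin_len)
    data.frame(source = s, bin = q$bin_id, completeness = q$completeness,
               contamination = q$contamination,
               quality_class = q$quality_class, stringsAsFactors = FALSE)
  })
  qual <- if (length(qual)) do.call(rbind, qual) else {
    data.frame(source = character(0), bin = character(0),
               completeness = numeric(0), contamination = numeric(0),
               quality_class = character(0), stringsAsFactors = FALSE)
  }
  list(anim = anim, assignment = assignment, quality = qual,
       bin_seqs = bseqs, source_lengths = src_len, bin_lengths = bin_len)
}

#' Run the full simulation-to-evaluation pipeline
#'
#' For every replicate (child seed `seed + r`) and every sample column of
#' the community table: allocate reads, simulate and pool paired reads,
#' quality-trim, place reads, pseudo-assemble, compute the depth table, bin,
#' and evaluate bins against the sources. Every stage's parameters and
#' seeds are appended to `run_log.txt`; identical configurations produce
#' identical output trees.
#'
#' @param cfg A [run_config()].
#' @return A `pipeline_run`: list with `config` and `replicates` (list of
#'   lists of `sample_run` objects).
#' @export
run_pipeline <- function(cfg) {
  spec <- parse_community_table(cfg$community_table)
  genomes <- character(0)
  for (i in seq_len(nrow(spec$entries))) {
    fa <- read_fasta(spec$entries$path[i])
    genomes[spec$entries$genome_id[i]] <- unname(fa[1])
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  cat(sprintf("seed=%d replicates=%d total_read_pairs=%d read_length=%d\n",
              cfg$seed, cfg$replicates, cfg$total_read_pairs,
              cfg$read_length),
      file = log_path)
  log <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  reps <- list()
  for (r in seq_len(cfg$replicates)) {
    child <- cfg$seed + r
    log("replicate=%d child_seed=%d", r, child)
    rep_out <- list()
    for (sidx in seq_along(spec$sample_ids)) {
      s <- spec$sample_ids[sidx]
      dir <- file.path(cfg$out_dir, sprintf("replicate_%d", r), s)
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      res <- tryCatch(
        run_one_sample(spec, genomes, s, cfg, child, sidx, dir, log),
        error = function(e) {
          log("replicate=%d sample=%s FAILED: %s", r, s, conditionMessage(e))
          structure(list(sample_id = s, error = conditionMessage(e)),
                    class = "sample_run_error")
        }
      )
      rep_out[[s]] <- res
    }
    reps[[r]] <- rep_out
  }
  structure(list(config = cfg, spec = spec, genomes = genomes,
                 replicates = reps),
            class = "pipeline_run")
}

#' Write the general summary tables
#'
#' Three CSV files mirroring the usual summary sheets: `summary_stats.csv`
#' (scaffold statistics per bin and per source), `summary_quality.csv`
#' (completeness/contamination/quality class per matched pair) and
#' `summary_ani.csv` (`source,bin,ani,cov_source,cov_bin` for every pair
#' with a qualifying alignment).
#'
#' @param run A `sample_run`.
#' @param dir Output directory.
#' @return Paths of the three files, invisibly.
#' @export
write_general_summary <- function(run, dir = run$dir) {
  ev <- run$eval
  stat_row <- function(id, kind, seqs) {
    st <- scaffold_stats(seqs)
    data.frame(id = id, kind = kind, n_scaffolds = st$n_scaffolds,
               total_length = st$total_length, max_length = st$max_length,
               N50 = st$N50, L50 = st$L50,
               gc_percent = round(st$gc_percent, 4),
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (b in names(ev$bin_seqs)) {
    if (length(ev$bin_seqs[[b]])) {
      rows[[length(rows) + 1L]] <- stat_row(b, "bin", ev$bin_seqs[[b]])
    }
  }
  for (s in names(run$sources)) {
    rows[[length(rows) + 1L]] <- stat_row(s, "source", run$sources[s])
  }
  stats_path <- file.path(dir, "summary_stats.csv")
  utils::write.csv(do.call(rbind, rows), stats_path, row.names = FALSE)

  qual_path <- file.path(dir, "summary_quality.csv")
  utils::write.csv(ev$quality, qual_path, row.names = FALSE)

  m <- ev$anim
  idx <- which(!is.na(m$ani), arr.ind = TRUE)
  ani_df <- data.frame(
    source = rownames(m$ani)[idx[, 1]],
    bin = colnames(m$ani)[idx[, 2]],
    ani = m$ani[idx],
    cov_source = m$cov_source[idx],
    cov_bin = m$cov_bin[idx],
    stringsAsFactors = FALSE
  )
  ani_df <- ani_df[order(ani_df$source, ani_df$bin), , drop = FALSE]
  ani_path <- file.path(dir, "summary_ani.csv")
  utils::write.csv(ani_df, ani_path, row.names = FALSE)
  invisible(c(stats = stats_path, quality = qual_path, ani = ani_path))
}

#' Write the bin summary table
#'
#' One row per bin (the unbinned pool included, never marked matched):
#' the closest source by ANI (the bin-side criterion (b) view), the ANI and
#' aligned fractions, length and GC differences, and whether the full
#' mutual-best criteria held for the pair.
#'
#' @param run A `sample_run`.
#' @param dir Output directory.
#' @return Path of `bin_summary.csv`, invisibly.
#' @export
write_bin_summary <- function(run, dir = run$dir) {
  ev <- run$eval
  m <- ev$anim
  rows <- list()
  for (b in colnames(m$ani)) {
    vals <- m$ani[, b]
    ok <- which(!is.na(vals))
    if (length(ok)) {
      o <- ok[order(-vals[ok], -m$cov_bin[ok, b], rownames(m$ani)[ok])]
      s <- rownames(m$ani)[o[1]]
      bl <- ev$bin_lengths[[b]]
      sl <- ev$source_lengths[[s]]
      bin_gc <- scaffold_stats(ev$bin_seqs[[b]])$gc_percent
      src_gc <- scaffold_stats(run$sources[s])$gc_percent
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, closest_source = s, ani = m$ani[s, b],
        cov_source = m$cov_source[s, b], cov_bin = m$cov_bin[s, b],
        length_diff = bl - sl, gc_diff = round(bin_gc - src_gc, 4),
        matched = b != run$bins$unbinned_id &&
          s %in% names(ev$assignment$pairs) &&
          identical(unname(ev$assignment$pairs[[s]]), b),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, closest_source = NA_character_, ani = NA_real_,
        cov_source = NA_real_, cov_bin = NA_real_, length_diff = NA_real_,
        gc_diff = NA_real_, matched = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  path <- file.path(dir, "bin_summary.csv")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
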