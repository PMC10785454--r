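# Shared in-code fixtures for the suite. Everything is generated
# programmatically under fixed seeds; nothing is read from disk.

rand_seq <- function(n, seed, gc = 0.5) magsim::random_genome(max(n, 1000), gc, seed)

# A short random sequence below random_genome's length floor, for unit-scale
# alignment tests.
short_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Write a community CSV with given rows; returns the path.
write_community_csv <- function(dir, genomes, seq_type, abundances) {
  df <- data.frame(genomes = genomes, seq_type = seq_type,
                   stringsAsFactors = FALSE)
  for (s in names(abundances)) df[[s]] <- abundances[[s]]
  path <- file.path(dir, "community.csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Minimal hand-built scaffold_set over given named sequences, one scaffold
# per sequence spanning it fully.
as_scaffold_set <- function(seqs) {
  out <- lapply(seq_along(seqs), function(i) {
    list(scaffold_id = sprintf("scaffold_%04d", i),
         sequence = unname(seqs[[i]]),
         origins = data.frame(genome_id = names(seqs)[i], source_start = 0L,
                              source_end = nchar(seqs[[i]]),
                              scaffold_start = 0L,
                              scaffold_end = nchar(seqs[[i]]),
                              stringsAsFactors = FALSE),
         is_chimeric = FALSE)
  })
  structure(out, class = "scaffold_set")
}

# Hand-built depth table for a scaffold_set.
as_depth_table <- function(scaffolds, depths, sample = "sample_1") {
  ids <- vapply(scaffolds, `[[`, "", "scaffold_id")
  out <- data.frame(contigName = ids,
                    contigLen = vapply(scaffolds, function(s)
                      nchar(s$sequence), 0L),
                    totalAvgDepth = depths, stringsAsFactors = FALSE)
  out[[paste0(sample, ".bam")]] <- depths
  out[[paste0(sample, ".bam-var")]] <- 0
  class(out) <- c("depth_table", "data.frame")
  out
}

# Minimal ani_matrix carrying explicit hits, for quality-metric tests.
as_ani_matrix <- function(sources, bins, hits) {
  ani <- matrix(NA_real_, length(sources), length(bins),
                dimnames = list(sources, bins))
  structure(list(ani = ani, cov_source = ani, cov_bin = ani, hits = hits),
            class = "ani_matrix")
}

make_hits <- function(ref_id, query_id, ref_start, ref_end, query_start,
                      query_end, identity = 100) {
  data.frame(ref_id = ref_id, query_id = query_id, ref_start = ref_start,
             ref_end = ref_end, query_start = query_start,
             query_end = query_end, length = ref_end - ref_start,
             identity = identity, stringsAsFactors = FALSE)
}

# Exhaustive checker of the mutual-best criteria (a)(b)(c); the independent
# oracle for match_bins_to_sources on small matrices. Ties resolve to the
# lexicographically smallest id, matching the documented tie rule.
brute_force_match <- function(ani, unbinned = "unbinned") {
  src <- rownames(ani); bns <- colnames(ani)
  argmax_lex <- function(v) {
    ok <- which(!is.na(v))
    if (!length(ok)) return(NA_character_)
    top <- ok[v[ok] == max(v[ok])]
    sort(names(v)[top])[1]
  }
  best_bin <- vapply(src, function(s)
    argmax_lex(stats::setNames(ani[s, ], bns)), "")
  best_src <- vapply(bns, function(b)
    argmax_lex(stats::setNames(ani[, b], src)), "")
  pairs <- character(0)
  for (s in src) {
    b <- best_bin[[s]]
    if (!is.na(b) && b != unbinned && identical(best_src[[b]], s)) {
      pairs[s] <- b
    }
  }
  pairs
}

# Per-base boolean-array coverage oracle for interval unions.
per_base_union <- function(starts, ends, len) {
  covered <- logical(len)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) covered[(starts[i] + 1):ends[i]] <- TRUE
  }
  sum(covered)
}

# Tiny synthetic resistance-gene catalogue.
toy_catalogue <- function(seed = 99, n_genes = 3, gene_len = 1200,
                          panel = magsim::default_panel()) {
  genes <- vapply(seq_len(n_genes), function(i)
    short_seq(gene_len, seed + i), "")
  names(genes) <- sprintf("gene_%02d", seq_len(n_genes))
  pm <- lapply(seq_len(n_genes), function(i) panel[c(i, i + 10)])
  names(pm) <- names(genes)
  magsim::gene_catalogue(genes, pm, panel)
}
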