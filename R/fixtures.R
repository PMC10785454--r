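#' Generate a random genome sequence
#'
#' Bases are drawn i.i.d. with `P(G) + P(C) = gc_fraction` (split equally
#' between G and C, and between A and T).
#'
#' @param length Sequence length in bp (>= 1000).
#' @param gc_fraction GC content in (0, 1).
#' @param seed Integer seed.
#' @return A DNA string.
#' @export
random_genome <- function(length, gc_fraction = 0.5, seed) {
  if (length < 1000) stop("genome length must be >= 1000 bp")
  if (gc_fraction <= 0 || gc_fraction >= 1) stop("gc_fraction must be in (0, 1)")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  with_seed(seed, {
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  })
}

#' Mutate a genome by random substitutions
#'
#' Each position is substituted independently with probability `rate` to a
#' uniformly chosen different base — the divergence mechanism used to plant
#' close relatives at a known ANI (approximately `1 - rate`).
#'
#' @param sequence DNA string.
#' @param rate Per-base substitution probability in \[0, 1).
#' @param seed Integer seed.
#' @return List with `sequence` (mutated) and `n_substitutions`.
#' @export
mutate_genome <- function(sequence, rate, seed) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(list(sequence = sequence, n_substitutions = 0L))
  with_seed(seed, {
    L <- nchar(sequence)
    pos <- which(stats::runif(L) < rate)
    if (!length(pos)) {
      return(list(sequence = sequence, n_substitutions = 0L))
    }
    bases <- c("A", "C", "G", "T")
    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    cur <- chars[pos]
    pick <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), "",
                   USE.NAMES = FALSE)
    chars[pos] <- pick
    list(sequence = paste(chars, collapse = ""),
         n_substitutions = length(pos))
  })
}

#' Plant catalogue genes into a genome
#'
#' Inserts each gene verbatim at the requested position (positions refer to
#' the original, pre-insertion coordinates and must not overlap after
#' insertion); a manifest records the ground-truth location of every gene.
#'
#' @param genome DNA string.
#' @param genes Named character vector of gene sequences.
#' @param positions Integer vector of 0-based insertion points in the
#'   original genome, parallel to `genes`.
#' @return List with `sequence` and `manifest` (data.frame `gene_id`,
#'   `start`, `end` — 0-based half-open coordinates in the new genome).
#' @export
plant_genes <- function(genome, genes, positions) {
  stopifnot(length(genes) == length(positions))
  if (!length(genes)) {
    return(list(sequence = genome,
                manifest = data.frame(gene_id = character(0),
                                      start = integer(0), end = integer(0))))
  }
  if (any(positions < 0) || any(positions > nchar(genome))) {
    stop("insertion position outside genome bounds")
  }
  o <- order(positions)
  genes <- genes[o]; positions <- positions[o]
  if (anyDuplicated(positions)) stop("overlapping gene insertions")
  out <- character(0)
  manifest <- data.frame(gene_id = names(genes), start = NA_integer_,
                         end = NA_integer_)
  prev <- 0L; offset <- 0L
  for (i in seq_along(genes)) {
    out <- c(out, substr(genome, prev + 1L, positions[i]), genes[[i]])
    manifest$start[i] <- positions[i] + offset
    manifest$end[i] <- positions[i] + offset + nchar(genes[[i]])
    offset <- offset + nchar(genes[[i]])
    prev <- positions[i]
  }
  out <- c(out, substr(genome, prev + 1L, nchar(genome)))
  list(sequence = paste(out, collapse = ""), manifest = manifest)
}

#' Fixture recipe for a synthetic test community
#'
#' Describes a fully synthetic community with known ground truth: core
#' genomes (length and GC per genome), close relatives at fixed divergence,
#' plasmids tied to host genomes, and catalogue genes planted at known
#' positions. Abundances are drawn uniform(`abundance_low`,
#' `abundance_high`) and then spread so that, within each sample, the
#' depth ratio between abundance-adjacent genomes is at least
#' `min_depth_ratio` — the analogue of manually adjusting drawn abundances
#' to avoid near-identical depths.
#'
#' @param n_core_genomes Number of unrelated core genomes.
#' @param lengths,gc Per-genome lengths (bp) and GC fractions (recycled).
#' @param relatives List of `list(base = <index>, rate = <substitution
#'   rate>)` entries; rates must lie in (0, 0.3).
#' @param plasmids List of `list(host = <index>, length = <bp>,
#'   copy_factor = <x>)` entries.
#' @param planted_genes List of `list(genome = <index>, gene_id, position)`.
#' @param n_samples Number of community samples.
#' @param abundance_low,abundance_high Uniform draw bounds (default 1, 3.5).
#' @param min_depth_ratio Minimum abundance ratio between adjacent genomes
#'   after adjustment (default 1.8).
#' @param seed Integer seed (mandatory).
#' @return A `fixture_recipe` object.
#' @export
fixture_recipe <- function(n_core_genomes, lengths, gc = 0.5,
                           relatives = list(), plasmids = list(),
                           planted_genes = list(), n_samples = 1,
                           abundance_low = 1, abundance_high = 3.5,
                           min_depth_ratio = 1.8, seed) {
  stopifnot(n_core_genomes >= 1)
  if (missing(seed)) stop("a seed is mandatory for fixture recipes")
  lengths <- rep_len(lengths, n_core_genomes)
  gc <- rep_len(gc, n_core_genomes)
  for (r in relatives) {
    if (r$rate <= 0 || r$rate >= 0.3) stop("relative rates must be in (0, 0.3)")
    if (r$base < 1 || r$base > n_core_genomes) stop("relative base out of range")
  }
  structure(
    list(n_core_genomes = n_core_genomes, lengths = lengths, gc = gc,
         relatives = relatives, plasmids = plasmids,
         planted_genes = planted_genes, n_samples = n_samples,
         abundance_low = abundance_low, abundance_high = abundance_high,
         min_depth_ratio = min_depth_ratio, seed = as.integer(seed)),
    class = "fixture_recipe"
  )
}

#' Preset fixture recipes
#'
#' Four presets mirror the canonical community designs for exercising a
#' MAG pipeline: `baseline` (four unrelated genomes), `community_1a`
#' (multiple related organisms at 3-5 percent divergence), `community_1b`
#' (a single related pair at 1 percent), and `community_2` (the baseline
#' plus a low-copy and a high-copy plasmid).
#'
#' @param preset One of `"baseline"`, `"community_1a"`, `"community_1b"`,
#'   `"community_2"`.
#' @param seed Integer seed.
#' @return A [fixture_recipe()].
#' @export
fixture_preset <- function(preset = c("baseline", "community_1a",
                                      "community_1b", "community_2"),
                           seed) {
  preset <- match.arg(preset)
  base <- list(n_core_genomes = 4,
               lengths = c(300000, 280000, 250000, 220000),
               gc = c(0.35, 0.45, 0.55, 0.65))
  extra <- switch(preset,
    baseline = list(),
    community_1a = list(relatives = list(list(base = 1, rate = 0.03),
                                         list(base = 2, rate = 0.05))),
    community_1b = list(relatives = list(list(base = 1, rate = 0.01))),
    community_2 = list(plasmids = list(
      list(host = 1, length = 10000, copy_factor = 1),
      list(host = 2, length = 10000, copy_factor = 5)))
  )
  do.call(fixture_recipe, c(base, extra, list(seed = seed)))
}

# Spread abundances so consecutive (sorted) values differ by at least
# `ratio`; preserves the drawn order ranking.
spread_abundances <- function(a, ratio) {
  o <- order(a)
  out <- a
  for (i in seq_along(o)[-1]) {
    lo <- out[o[i - 1]] * ratio
    if (out[o[i]] < lo) out[o[i]] <- lo
  }
  out
}

#' Build a synthetic test community on disk
#'
#' Writes one FASTA per source sequence, a community table in the standard
#' `genomes,seq_type,<sample...>` CSV dialect (plasmids receive
#' `copy_factor` times their host's abundance), and a JSON manifest of all
#' ground truth: genome ids, lengths, GC, relative pairs with divergence
#' rates, plasmid hosts, and planted gene coordinates.
#'
#' @param recipe A [fixture_recipe()].
#' @param dir Output directory.
#' @param catalogue Optional [gene_catalogue()] supplying sequences for
#'   `planted_genes`.
#' @return List with `community_table` (path), `manifest` (path),
#'   `genomes` (named character vector of the sequences) and
#'   `manifest_data`.
#' @export
build_test_community <- function(recipe, dir, catalogue = NULL) {
  stopifnot(inherits(recipe, "fixture_recipe"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- recipe$n_core_genomes
  genomes <- character(0)
  seq_type <- character(0)
  info <- list()

  for (i in seq_len(n)) {
    id <- sprintf("genome_%02d", i)
    genomes[id] <- random_genome(recipe$lengths[i], recipe$gc[i],
                                 seed = recipe$seed + i)
    seq_type[id] <- "chromosome"
    info[[id]] <- list(id = id, role = "core", length = recipe$lengths[i],
                       gc = recipe$gc[i])
  }
  planted <- list()
  if (length(recipe$planted_genes)) {
    if (is.null(catalogue)) stop("planted_genes requires a catalogue")
    by_genome <- split(recipe$planted_genes,
                       vapply(recipe$planted_genes, `[[`, 0, "genome"))
    for (gi in names(by_genome)) {
      idx <- as.integer(gi)
      id <- sprintf("genome_%02d", idx)
      entries <- by_genome[[gi]]
      gene_ids <- vapply(entries, `[[`, "", "gene_id")
      pos <- vapply(entries, `[[`, 0, "position")
      res <- plant_genes(genomes[[id]], catalogue$genes[gene_ids], pos)
      genomes[id] <- res$sequence
      info[[id]]$length <- nchar(res$sequence)
      res$manifest$genome_id <- id
      planted[[length(planted) + 1L]] <- res$manifest
    }
  }
  rel_info <- list()
  for (k in seq_along(recipe$relatives)) {
    r <- recipe$relatives[[k]]
    base_id <- sprintf("genome_%02d", r$base)
    id <- sprintf("%s_rel%d", base_id, k)
    mut <- mutate_genome(genomes[[base_id]], r$rate,
                         seed = recipe$seed + 1000L + k)
    genomes[id] <- mut$sequence
    seq_type[id] <- "chromosome"
    info[[id]] <- list(id = id, role = "relative", base = base_id,
                       rate = r$rate, n_substitutions = mut$n_substitutions,
                       length = nchar(mut$sequence))
    rel_info[[length(rel_info) + 1L]] <- list(base = base_id, relative = id,
                                              rate = r$rate)
  }
  plasmid_host <- character(0)
  plasmid_copy <- numeric(0)
  for (k in seq_along(recipe$plasmids)) {
    p <- recipe$plasmids[[k]]
    host_id <- sprintf("genome_%02d", p$host)
    id <- sprintf("plasmid_%02d", k)
    gc <- info[[host_id]]$gc %||% 0.5
    genomes[id] <- random_genome(p$length, gc, seed = recipe$seed + 2000L + k)
    seq_type[id] <- "plasmid"
    info[[id]] <- list(id = id, role = "plasmid", host = host_id,
                       length = p$length, copy_factor = p$copy_factor)
    plasmid_host[id] <- host_id
    plasmid_copy[id] <- p$copy_factor
  }

  # abundances: uniform draws spread to enforce the depth-ratio floor;
  # plasmids inherit copy_factor x host abundance
  chrom <- names(genomes)[seq_type[names(genomes)] == "chromosome"]
  ab <- matrix(0, length(genomes), recipe$n_samples,
               dimnames = list(names(genomes),
                               paste0("sample_", seq_len(recipe$n_samples))))
  for (s in seq_len(recipe$n_samples)) {
    draws <- draw_abundances(length(chrom), recipe$abundance_low,
                             recipe$abundance_high,
                             seed = recipe$seed + 3000L + s)
    ab[chrom, s] <- spread_abundances(draws, recipe$min_depth_ratio)
    for (id in names(plasmid_host)) {
      ab[id, s] <- plasmid_copy[id] * ab[plasmid_host[id], s]
    }
  }

  paths <- character(0)
  for (id in names(genomes)) {
    fn <- file.path(dir, paste0(id, ".fa"))
    write_fasta(stats::setNames(genomes[id], id), fn)
    paths[id] <- paste0(id, ".fa")
  }
  tab <- data.frame(genomes = unname(paths),
                    seq_type = unname(seq_type[names(genomes)]),
                    stringsAsFactors = FALSE)
  for (s in colnames(ab)) tab[[s]] <- unname(ab[, s])
  table_path <- file.path(dir, "community.csv")
  utils::write.csv(tab, table_path, row.names = FALSE, quote = FALSE)

  manifest <- list(
    seed = recipe$seed,
    genomes = unname(lapply(info, function(x) x)),
    relatives = rel_info,
    planted_genes = if (length(planted)) do.call(rbind, planted) else NULL,
    abundance = as.data.frame(ab)
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  list(community_table = table_path, manifest = manifest_path,
       genomes = genomes, manifest_data = manifest)
}
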