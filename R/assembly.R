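#' Place reads on their source genomes from provenance
#'
#' Exact placement from the simulator's provenance table replaces read
#' mapping: each mate covers its end of the recorded fragment, so per-base
#' coverage is known without alignment. Mate 1 covers
#' `[start, start + read_length)`, mate 2 covers `[end - read_length, end)`.
#'
#' @param provenance data.frame with `genome_id`, `start`, `end` (0-based
#'   half-open fragment coordinates).
#' @param genome_lengths Named vector of source lengths (bp).
#' @param read_length Mate length in bp.
#' @return Named list of integer coverage vectors, one per genome in
#'   `genome_lengths` (all-zero when the genome received no reads).
#' @export
place_reads <- function(provenance, genome_lengths, read_length = 150) {
  unknown <- setdiff(unique(provenance$genome_id), names(genome_lengths))
  if (length(unknown)) {
    stop("provenance references unknown genome: ", unknown[1])
  }
  out <- lapply(names(genome_lengths), function(g) {
    L <- as.integer(genome_lengths[[g]])
    sel <- provenance$genome_id == g
    cov <- integer(L)
    if (any(sel)) {
      s <- provenance$start[sel]
      e <- provenance$end[sel]
      if (any(s < 0) || any(e > L)) {
        stop("provenance interval outside genome bounds for ", g)
      }
      # difference-array accumulation over both mates
      starts <- c(s, pmax(e - read_length, s))
      ends <- c(pmin(s + read_length, e), e)
      d <- integer(L + 1L)
      tab_s <- tabulate(starts + 1L, nbins = L)
      tab_e <- tabulate(ends, nbins = L)   # ends are exclusive, 1-based bin = end
      d[seq_len(L)] <- tab_s
      d[seq_len(L) + 1L] <- d[seq_len(L) + 1L] - tab_e
      cov <- cumsum(d)[seq_len(L)]
    }
    cov
  })
  names(out) <- names(genome_lengths)
  out
}

#' Coverage-aware pseudo-assembly
#'
#' A deterministic desk-scale stand-in for metagenomic assembly: each source
#' sequence is split at maximal runs of zero coverage; pieces shorter than
#' `min_scaffold_len` are discarded (the size filter applied to real
#' assemblies). Optionally, two pieces from different sources sharing an
#' exact substring of at least `chimera_anchor_len` bp are merged into one
#' chimeric scaffold (consensus taken from the first source across the
#' shared region), reproducing the "consensus assembly" failure mode of
#' closely related strains.
#'
#' @param genomes Named character vector of source sequences.
#' @param coverage Named list of per-base coverage vectors
#'   (see [place_reads()]).
#' @param min_scaffold_len Minimum scaffold length in bp (default 1500).
#' @param enable_chimeras Whether to merge near-identical pieces.
#' @param chimera_anchor_len Minimum exact shared substring for a merge (bp).
#' @return A `scaffold_set`: list of scaffolds, each a list with
#'   `scaffold_id`, `sequence`, `origins` (data.frame `genome_id`,
#'   `source_start`, `source_end`, `scaffold_start`, `scaffold_end`; 0-based
#'   half-open) and `is_chimeric`.
#' @export
pseudo_assemble <- function(genomes, coverage, min_scaffold_len = 1500,
                            enable_chimeras = FALSE,
                            chimera_anchor_len = 2000) {
  stopifnot(all(names(genomes) %in% names(coverage)))
  pieces <- list()
  for (g in names(genomes)) {
    cov <- coverage[[g]]
    if (length(cov) != nchar(genomes[[g]])) {
      stop("coverage length mismatch for ", g)
    }
    pos <- cov > 0L
    if (!any(pos)) next
    r <- rle(pos)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      s0 <- starts[k] - 1L      # 0-based
      e0 <- ends[k]             # exclusive
      if (e0 - s0 < min_scaffold_len) next
      pieces[[length(pieces) + 1L]] <- list(
        sequence = substr(genomes[[g]], s0 + 1L, e0),
        origins = data.frame(genome_id = g, source_start = s0,
                             source_end = e0, scaffold_start = 0L,
                             scaffold_end = e0 - s0,
                             stringsAsFactors = FALSE),
        is_chimeric = FALSE
      )
    }
  }

  if (enable_chimeras && length(pieces) > 1L) {
    pieces <- merge_chimeras(pieces, chimera_anchor_len)
  }

  # stable ids: order by decreasing length, then first origin
  if (length(pieces)) {
    lens <- vapply(pieces, function(p) nchar(p$sequence), 0L)
    keys <- vapply(pieces, function(p) p$origins$genome_id[1], "")
    o <- order(-lens, keys)
    pieces <- pieces[o]
    for (i in seq_along(pieces)) {
      pieces[[i]]$scaffold_id <- sprintf("scaffold_%04d", i)
    }
  }
  structure(pieces, class = "scaffold_set")
}

# Greedy single-pass chimera merging: the first pair of pieces from
# different sources sharing an exact run >= anchor_len is merged; each piece
# participates in at most one merge.
merge_chimeras <- function(pieces, anchor_len) {
  used <- rep(FALSE, length(pieces))
  out <- list()
  for (i in seq_along(pieces)) {
    if (used[i]) next
    merged <- pieces[[i]]
    for (j in seq_along(pieces)) {
      if (j == i || used[j]) next
      if (identical(pieces[[j]]$origins$genome_id[1],
                    merged$origins$genome_id[1])) next
      hit <- longest_shared_run(merged$sequence, pieces[[j]]$sequence,
                                anchor_len)
      if (is.null(hit)) next
      a_end <- hit$a_end        # exclusive, 0-based on piece i
      b_end <- hit$b_end        # exclusive, 0-based on piece j
      b <- pieces[[j]]
      tail_seq <- if (b_end < nchar(b$sequence)) {
        substr(b$sequence, b_end + 1L, nchar(b$sequence))
      } else ""
      off <- a_end
      b_orig <- b$origins
      b_orig$source_start <- b_orig$source_start + b_end
      b_orig$scaffold_start <- off
      b_orig$scaffold_end <- off + (b_orig$source_end - b_orig$source_start)
      new_orig <- merged$origins
      new_orig$source_end <- new_orig$source_start + a_end
      new_orig$scaffold_end <- a_end
      merged <- list(
        sequence = paste0(substr(merged$sequence, 1L, a_end), tail_seq),
        origins = rbind(new_orig, if (nchar(tail_seq)) b_orig),
        is_chimeric = TRUE
      )
      used[j] <- TRUE
      break
    }
    used[i] <- TRUE
    out[[length(out) + 1L]] <- merged
  }
  out
}

# Longest exact shared run between two sequences found by k-mer seeding on a
# single diagonal; returns NULL when shorter than min_len.
longest_shared_run <- function(a, b, min_len) {
  k <- 32L
  if (nchar(a) < k || nchar(b) < k || min_len < k) k <- min(32L, min_len)
  mems <- find_mems(a, b, k)
  if (is.null(mems) || !nrow(mems)) return(NULL)
  mems <- mems[mems$len >= min_len, , drop = FALSE]
  if (!nrow(mems)) return(NULL)
  best <- mems[which.max(mems$len), ]
  list(a_end = best$qpos + best$len, b_end = best$rpos + best$len)
}
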