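# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
# All exported operations that take a `seed` argument route through this, so
# library calls never disturb the user's random stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Union length of 0-based half-open intervals given as a 2-column matrix
# (start, end). Overlapping and abutting intervals are merged.
interval_union_length <- function(starts, ends) {
  stopifnot(length(starts) == length(ends))
  if (length(starts) == 0L) return(0)
  o <- order(starts, ends)
  s <- starts[o]; e <- ends[o]
  total <- 0
  cur_s <- s[1]; cur_e <- e[1]
  if (length(s) > 1L) {
    for (i in 2:length(s)) {
      if (s[i] <= cur_e) {
        if (e[i] > cur_e) cur_e <- e[i]
      } else {
        total <- total + (cur_e - cur_s)
        cur_s <- s[i]; cur_e <- e[i]
      }
    }
  }
  total + (cur_e - cur_s)
}

# Reverse complement for plain character vectors (ACGTN alphabet).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Named character vector <-> FASTA via Biostrings.
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

# FASTQ (Phred+33, 4-line records). Reading is gzip-transparent via file().
read_fastq <- function(path) {
  con <- file(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ (", path, "): record count not a multiple of 4")
  }
  n <- length(lines) %/% 4L
  ids <- sub("^@", "", lines[seq(1L, by = 4L, length.out = n)])
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop("malformed FASTQ (", path, "): sequence/quality length mismatch at record ",
         bad[1])
  }
  data.frame(read_id = ids, seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

write_fastq <- function(ids, seqs, quals, path) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  n <- length(ids)
  out <- character(4L * n)
  if (n) {
    out[seq(1L, by = 4L, length.out = n)] <- paste0("@", ids)
    out[seq(2L, by = 4L, length.out = n)] <- seqs
    out[seq(3L, by = 4L, length.out = n)] <- "+"
    out[seq(4L, by = 4L, length.out = n)] <- quals
  }
  writeLines(out, path)
  invisible(path)
}

phred_to_int <- function(qual_strings) {
  lapply(qual_strings, function(q) utf8ToInt(q) - 33L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
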