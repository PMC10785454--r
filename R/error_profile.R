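#' Construct an Illumina-like error profile
#'
#' A profile holds a per-position substitution rate and the matching Phred
#' quality track. Qualities are derived from the rates as
#' `Q(pos) = round(-10 * log10(max(rate, 10^-4.1)))`, clamped to \[2, 41\],
#' so a flat 0.2\% profile yields Q27 across the read.
#'
#' @param read_length Read length in bp.
#' @param substitution_rate Either a single rate applied at every position or
#'   a vector of length `read_length`.
#' @return An `error_profile` object (list with `read_length`, `rates`,
#'   `quality` integer vector and `qual_string`).
#' @export
error_profile <- function(read_length = 150, substitution_rate = 0.002) {
  read_length <- as.integer(read_length)
  stopifnot(read_length > 0)
  rates <- if (length(substitution_rate) == 1L) {
    rep(substitution_rate, read_length)
  } else {
    substitution_rate
  }
  if (length(rates) != read_length) {
    stop("substitution_rate must have length 1 or read_length")
  }
  if (any(rates < 0 | rates > 1)) stop("substitution rates must be in [0, 1]")
  q <- as.integer(round(-10 * log10(pmax(rates, 10^-4.1))))
  q <- pmin(pmax(q, 2L), 41L)
  structure(
    list(read_length = read_length, rates = rates, quality = q,
         qual_string = intToUtf8(q + 33L)),
    class = "error_profile"
  )
}

#' Read an error profile from a two-column TSV
#'
#' The dialect is `position<TAB>substitution_rate` with positions 1..L in
#' order; a header line is permitted.
#'
#' @param path TSV file.
#' @return An [error_profile()] object.
#' @export
read_error_profile <- function(path) {
  if (!file.exists(path)) stop("error profile not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!is.numeric(tab[[1]])) tab <- tab[-1, , drop = FALSE]  # header line
  pos <- as.integer(tab[[1]])
  rate <- as.numeric(tab[[2]])
  if (!identical(pos, seq_along(pos))) {
    stop("error profile positions must be 1..read_length in order")
  }
  error_profile(read_length = length(pos), substitution_rate = rate)
}

#' Write an error profile to the two-column TSV dialect
#' @param profile An [error_profile()] object.
#' @param path Output path.
#' @export
write_error_profile <- function(profile, path) {
  stopifnot(inherits(profile, "error_profile"))
  utils::write.table(
    data.frame(position = seq_len(profile$read_length), rate = profile$rates),
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Fragment (insert) size model for paired-end simulation
#'
#' Insert lengths are drawn normal(insert_mean, insert_sd) and truncated to
#' \[min_insert, genome length\]. `min_insert` must be at least the read
#' length (mates may overlap but never run off the fragment).
#'
#' @param insert_mean,insert_sd Mean and sd of the insert length (bp).
#' @param min_insert Minimum insert length (bp).
#' @return A `fragment_model` object.
#' @export
fragment_model <- function(insert_mean = 400, insert_sd = 40, min_insert = 200) {
  stopifnot(insert_mean > 0, insert_sd >= 0, min_insert > 0)
  structure(list(insert_mean = insert_mean, insert_sd = insert_sd,
                 min_insert = as.integer(min_insert)),
            class = "fragment_model")
}
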