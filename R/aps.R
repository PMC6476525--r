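#' AU fraction of a sequence
#'
#' The fraction of `A` plus `T` bases (`T` is the DNA representation of `U`,
#' so this is the AU content of the corresponding mRNA). `N` never counts as
#' AU but stays in the denominator: `"ATNNG"` has AU fraction 2/5.
#'
#' @param seq a nucleotide string, a [region()] or a [transcript()].
#' @return a fraction in `[0, 1]`.
#' @export
au_fraction <- function(seq) {
  s <- as_seq_string(seq)
  if (nchar(s) == 0L) stop("au_fraction: empty sequence")
  chars <- strsplit(s, "")[[1]]
  sum(chars == "A" | chars == "T") / length(chars)
}

as_seq_string <- function(x) {
  if (inherits(x, "region")) x$seq
  else if (inherits(x, "transcript")) x$seq
  else normalize_seq(x)
}

#' Sliding-window AU-content profile
#'
#' One point per window fully inside the region (a trailing partial window
#' is dropped), plus the fixed proximal statistic `first100_au`: the AU
#' fraction of positions `1..min(100, length)`. When the region is shorter
#' than 100 nt the statistic is still computed over the available length and
#' `short_region_flag` is set.
#'
#' @param region a [region()] (or a plain sequence).
#' @param window window width in nt (default 100, the width the proximal
#'   statistic uses).
#' @param step distance between window starts in nt (default 10).
#' @return an object of class `"au_profile"`: list with `region_id`,
#'   `window`, `step`, `points` (data frame `window_start`, `au_fraction`),
#'   `first100_au`, `short_region_flag`.
#' @export
au_profile <- function(region, window = 100, step = 10) {
  window <- as.integer(window); step <- as.integer(step)
  if (is.na(window) || window < 1L || is.na(step) || step < 1L)
    stop("au_profile: window and step must be positive integers")
  s <- as_seq_string(region)
  n <- nchar(s)
  if (n < 1L) stop("au_profile: empty region")
  id <- if (inherits(region, "region")) region$parent_id else "<sequence>"

  starts <- integer(0)
  if (n >= window) starts <- seq.int(1L, n - window + 1L, by = step)
  points <- data.frame(
    window_start = starts,
    au_fraction = vapply(starts, function(i)
      au_fraction(substr(s, i, i + window - 1L)), 0))

  head_len <- min(100L, n)
  structure(
    list(region_id = id, window = window, step = step, points = points,
         first100_au = au_fraction(substr(s, 1L, head_len)),
         short_region_flag = n < 100L),
    class = "au_profile")
}

#' @export
print.au_profile <- function(x, ...) {
  cat("AU profile of ", x$region_id, ": ", nrow(x$points), " windows (w=",
      x$window, ", step=", x$step, "), first-100 AU = ",
      round(100 * x$first100_au, 1), "%",
      if (x$short_region_flag) " [region < 100 nt]", "\n", sep = "")
  invisible(x)
}

#' Classify a 3' UTR for an AU-rich proximal sequence (APS)
#'
#' A 3' UTR is APS-positive when (1) its length is at least `min_len`
#' (inclusive, default 300 nt) and (2) the AU content of its first
#' `proximal_len` bases strictly exceeds `threshold` percent (default 50%).
#' Exactly 50% AU is negative; exactly 300 nt is long enough. The input must
#' be the region immediately after the stop codon, as produced by
#' [extract_utrs()].
#'
#' @param utr3 a [region()] (or plain sequence): the 3' UTR.
#' @param proximal_len length of the proximal window in nt (default 100).
#' @param threshold AU percentage that must be strictly exceeded (default 50).
#' @param min_len minimum 3' UTR length in nt, inclusive (default 300).
#' @return an object of class `"aps_call"`: list with `region_id`,
#'   `utr3_length`, `first100_au_percent`, `length_ok`, `au_ok`,
#'   `is_aps_positive`, `short_region_flag` and `params`.
#' @export
classify_aps <- function(utr3, proximal_len = 100, threshold = 50,
                         min_len = 300) {
  s <- as_seq_string(utr3)
  n <- nchar(s)
  if (n == 0L) stop("classify_aps: empty region")
  id <- if (inherits(utr3, "region")) utr3$parent_id else "<sequence>"
  head_len <- min(as.integer(proximal_len), n)
  au_pct <- 100 * au_fraction(substr(s, 1L, head_len))
  length_ok <- n >= min_len
  au_ok <- au_pct > threshold
  structure(
    list(region_id = id, utr3_length = n, first100_au_percent = au_pct,
         length_ok = length_ok, au_ok = au_ok,
         is_aps_positive = length_ok && au_ok,
         short_region_flag = n < proximal_len,
         params = list(proximal_len = as.integer(proximal_len),
                       threshold = threshold, min_len = as.integer(min_len))),
    class = "aps_call")
}

#' @export
print.aps_call <- function(x, ...) {
  cat("APS call for ", x$region_id, ": ",
      if (x$is_aps_positive) "POSITIVE" else "negative",
      " (3'UTR ", x$utr3_length, " nt [>= ", x$params$min_len, ": ",
      x$length_ok, "], first-", x$params$proximal_len, " AU ",
      round(x$first100_au_percent, 1), "% [> ", x$params$threshold, ": ",
      x$au_ok, "])\n", sep = "")
  invisible(x)
}

#' Scan a region for AU-rich element (ARE) pentamers
#'
#' Finds all, possibly overlapping, occurrences of the core ARE pentamer
#' (`AUUUA`, DNA representation `ATTTA`). Hits separated by a gap of at most
#' 5 nt (including overlapping hits) share a `cluster_id`, so tandem AREs
#' such as `ATTTATTTA` form one cluster. Externally predicted ARE intervals
#' can be used instead wherever a hit table is accepted; this scan replaces
#' no classifier, it is a documented pentamer search.
#'
#' @param region a [region()] or plain sequence.
#' @param pattern the motif to scan for (default `"ATTTA"`).
#' @param cluster_gap maximum gap in nt between hits of one cluster.
#' @return a data frame of hits sorted by start: `region_id`, `start`, `end`,
#'   `motif`, `cluster_id`. Zero rows when there is no hit.
#' @export
scan_are <- function(region, pattern = "ATTTA", cluster_gap = 5) {
  s <- as_seq_string(region)
  id <- if (inherits(region, "region")) region$parent_id else "<sequence>"
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(s))
  starts <- Biostrings::start(m)
  empty <- data.frame(region_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      cluster_id = integer())
  if (length(starts) == 0L) return(empty)
  starts <- sort(starts)
  ends <- starts + nchar(pattern) - 1L
  cluster <- cumsum(c(1L, (starts[-1] - ends[-length(ends)] - 1L) > cluster_gap))
  data.frame(region_id = id, start = starts, end = ends, motif = pattern,
             cluster_id = cluster)
}
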