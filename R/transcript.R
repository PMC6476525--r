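#' Construct a transcript record
#'
#' A transcript is an mRNA-space nucleotide sequence with 1-based inclusive
#' CDS coordinates. All coordinates in this package are 1-based inclusive:
#' a fragment written `(79, 153)` has length `153 - 79 + 1 = 75`. Getting
#' this convention wrong corrupts every downstream statistic, so it is
#' enforced here and never reinterpreted elsewhere.
#'
#' Input sequence is normalized on construction: lowercase is raised to
#' uppercase and RNA `U` is stored as DNA `T` (AU-content statistics treat
#' `A` and `T` as the AU class). Only `A`, `C`, `G`, `T`, `N` survive
#' normalization; any other character is an error. Sequences with more than
#' 10% `N` are rejected because composition statistics on mostly-ambiguous
#' sequence are meaningless.
#'
#' @param id record identifier (e.g. a RefSeq accession).
#' @param seq nucleotide sequence, DNA or RNA alphabet, any case.
#' @param cds_start,cds_end 1-based inclusive CDS coordinates with
#'   `1 <= cds_start < cds_end <= nchar(seq)`.
#' @param gene,species optional annotation strings.
#' @param validate_cds if `TRUE`, additionally require the CDS length to be a
#'   multiple of 3, to begin with `ATG` and to end with a stop codon. Off by
#'   default: vector-derived reporter cassettes need not satisfy it.
#' @return an object of class `"transcript"`.
#' @examples
#' tx <- transcript("x", "AAAUGGGCTAAAA", cds_start = 3, cds_end = 11)
#' tx$seq  # "AAATGGGCTAAAA" -- U stored as T
#' @export
transcript <- function(id, seq, cds_start, cds_end, gene = "", species = "",
                       validate_cds = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- normalize_seq(seq, id = id, max_n_fraction = 0.10)
  n <- nchar(seq)
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if (is.na(cds_start) || is.na(cds_end))
    stop("transcript '", id, "': CDS coordinates must be integers")
  if (cds_start < 1L || cds_end > n || cds_start >= cds_end)
    stop("transcript '", id, "': invalid CDS [", cds_start, ", ", cds_end,
         "] on sequence of length ", n)
  if (validate_cds) {
    cds_len <- cds_end - cds_start + 1L
    if (cds_len %% 3L != 0L)
      stop("transcript '", id, "': CDS length ", cds_len,
           " is not a multiple of 3")
    cds <- substr(seq, cds_start, cds_end)
    if (substr(cds, 1L, 3L) != "ATG")
      stop("transcript '", id, "': CDS does not begin with ATG")
    last <- substr(cds, cds_len - 2L, cds_len)
    if (!last %in% c("TAA", "TAG", "TGA"))
      stop("transcript '", id, "': CDS does not end with a stop codon")
  }
  structure(
    list(id = id, gene = gene, species = species, seq = seq,
         cds_start = cds_start, cds_end = cds_end),
    class = "transcript"
  )
}

#' @export
print.transcript <- function(x, ...) {
  n <- nchar(x$seq)
  cat("transcript ", x$id,
      if (nzchar(x$gene)) paste0(" (", x$gene, ")"),
      ": ", n, " nt, CDS ", x$cds_start, "-", x$cds_end,
      " (5'UTR ", x$cds_start - 1L, " nt, 3'UTR ", n - x$cds_end, " nt)\n",
      sep = "")
  invisible(x)
}

# Uppercase, U->T and alphabet check shared by all constructors. The >10% N
# rejection applies only where records enter the pipeline (transcript(),
# region()): ad-hoc sequence arithmetic on short strings must not trip it.
normalize_seq <- function(seq, id = "<sequence>", max_n_fraction = 1) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- chartr("u", "t", toupper(seq))
  seq <- chartr("U", "T", seq)
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad))
    stop("'", id, "': non-nucleotide characters after normalization: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  n <- nchar(seq)
  if (n == 0L) stop("'", id, "': empty sequence")
  n_count <- n - nchar(gsub("N", "", seq, fixed = TRUE))
  if (n_count / n > max_n_fraction)
    stop("'", id, "': ", n_count, "/", n, " bases are N (> ",
         round(100 * max_n_fraction), "%); ",
         "composition statistics would be meaningless")
  seq
}

#' Construct a sequence region
#'
#' A region is a subsequence of a parent sequence, addressed by 1-based
#' inclusive coordinates on that parent. `length(seq) == end - start + 1`
#' always holds.
#'
#' @param parent_id identifier of the parent sequence.
#' @param kind one of `"five_prime_utr"`, `"three_prime_utr"`, `"cds"`,
#'   `"custom"`.
#' @param start,end 1-based inclusive coordinates on the parent.
#' @param seq the region's own sequence (normalized like [transcript()]).
#' @return an object of class `"region"`.
#' @export
region <- function(parent_id, kind = "custom", start, end, seq) {
  kind <- match.arg(kind, c("five_prime_utr", "three_prime_utr", "cds", "custom"))
  seq <- normalize_seq(seq, id = parent_id, max_n_fraction = 0.10)
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || start > end)
    stop("region on '", parent_id, "': invalid coordinates [", start, ", ",
         end, "]")
  if (nchar(seq) != end - start + 1L)
    stop("region on '", parent_id, "': sequence length ", nchar(seq),
         " does not match [", start, ", ", end, "]")
  structure(list(parent_id = parent_id, kind = kind, start = start,
                 end = end, seq = seq),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat("region [", x$start, "-", x$end, "] (", x$kind, ") of ", x$parent_id,
      ": ", nchar(x$seq), " nt\n", sep = "")
  invisible(x)
}

region_length <- function(r) nchar(r$seq)

#' Extract the 5' and 3' UTRs of a transcript
#'
#' The 5' UTR spans positions `1 .. cds_start - 1`; the 3' UTR is the region
#' immediately after the stop codon, `cds_end + 1 .. length(seq)`. A UTR that
#' does not exist (CDS abutting the transcript end) is returned as `NULL`,
#' an explicit empty marker, so downstream operations fail loudly rather
#' than silently analysing a zero-length region.
#'
#' @param t a [transcript()].
#' @return an object of class `"utr_set"`: a list with elements
#'   `transcript_id`, `utr5` (region or `NULL`) and `utr3` (region or `NULL`).
#' @export
extract_utrs <- function(t) {
  stopifnot(inherits(t, "transcript"))
  n <- nchar(t$seq)
  utr5 <- if (t$cds_start > 1L)
    region(t$id, "five_prime_utr", 1L, t$cds_start - 1L,
           substr(t$seq, 1L, t$cds_start - 1L))
  utr3 <- if (t$cds_end < n)
    region(t$id, "three_prime_utr", t$cds_end + 1L, n,
           substr(t$seq, t$cds_end + 1L, n))
  structure(list(transcript_id = t$id, utr5 = utr5, utr3 = utr3),
            class = "utr_set")
}

#' @export
print.utr_set <- function(x, ...) {
  fmt <- function(r) if (is.null(r)) "absent" else paste0(nchar(r$seq), " nt")
  cat("UTRs of ", x$transcript_id, ": 5' ", fmt(x$utr5), ", 3' ", fmt(x$utr3),
      "\n", sep = "")
  invisible(x)
}

#' Take a subregion by 1-based inclusive coordinates
#'
#' Coordinates are relative to the input's own 5' end, so
#' `subregion(r, 79, 153)` returns a 75-nt fragment whatever `r$start` is on
#' the original parent. Composition holds:
#' `subregion(subregion(s, a, b), c, d) == subregion(s, a + c - 1, a + d - 1)`.
#'
#' @param x a [region()], [transcript()] (its full sequence) or a plain
#'   character sequence.
#' @param start,end 1-based inclusive coordinates, `1 <= start <= end <= length`.
#' @return a [region()] whose `parent_id` names the input and whose
#'   coordinates are the requested ones.
#' @export
subregion <- function(x, start, end) {
  if (inherits(x, "region")) {
    id <- x$parent_id; s <- x$seq
  } else if (inherits(x, "transcript")) {
    id <- x$id; s <- x$seq
  } else {
    id <- "<sequence>"; s <- normalize_seq(x)
  }
  start <- as.integer(start); end <- as.integer(end)
  n <- nchar(s)
  if (start < 1L || end > n || start > end)
    stop("subregion: coordinates [", start, ", ", end,
         "] out of bounds for length ", n)
  region(id, "custom", start, end, substr(s, start, end))
}

#' Reverse complement of a DNA sequence
#'
#' `A<->T`, `C<->G`, `N->N`; an involution (`revcomp(revcomp(s)) == s`).
#' Characters outside `ACGTN` (after case/U normalization) are an error.
#'
#' @param seq a nucleotide string.
#' @return the reverse complement string.
#' @export
revcomp <- function(seq) {
  seq <- normalize_seq(seq)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]), collapse = "")
}
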