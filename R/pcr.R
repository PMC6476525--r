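#' Declare a qPCR primer pair
#'
#' Both primers are written 5' to 3': the forward primer matches the sense
#' strand directly, the reverse primer matches the antisense strand (i.e.
#' its reverse complement is sought on the sense strand downstream of the
#' forward site). Matching is exact — qPCR primers are designed for perfect
#' complementarity, and the predicted amplicon size is the verifiable
#' contract.
#'
#' @param name primer set name (usually the target gene).
#' @param forward,reverse primer sequences, 5'->3', `A/C/G/T` only, at least
#'   10 nt each.
#' @return an object of class `"primer_pair"`.
#' @export
primer_pair <- function(name, forward, reverse) {
  stopifnot(is.character(name), length(name) == 1L)
  check <- function(p, which) {
    p <- toupper(p)
    if (nchar(p) < 10L)
      stop("primer set '", name, "': ", which, " primer shorter than 10 nt")
    if (grepl("[^ACGT]", p))
      stop("primer set '", name, "': ", which,
           " primer contains non-ACGT characters")
    p
  }
  structure(list(name = name, forward = check(forward, "forward"),
                 reverse = check(reverse, "reverse")),
            class = "primer_pair")
}

match_starts <- function(pattern, subject) {
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject))
  sort(Biostrings::start(m))
}

#' Predict the amplicon of a primer pair on a template
#'
#' Finds exact sense-strand matches of the forward primer and exact matches
#' of the reverse complement of the reverse primer downstream of (not
#' overlapping) a forward site. The amplicon spans both primer footprints:
#' `length = end - start + 1` where `start` is the first base of the forward
#' site and `end` the last base of the reverse site on the sense strand.
#'
#' A template with no product yields a result with `status = "none"` rather
#' than an error, so batch screens continue. Multiple possible products are
#' fatal under `require_unique` (all sites are listed); otherwise the
#' shortest product is reported with `status = "multiple"` — in a qPCR the
#' shortest product dominates amplification.
#'
#' @param template a [transcript()], [region()] or plain sequence.
#' @param primers a [primer_pair()].
#' @param require_unique if `TRUE` (default), more than one possible product
#'   is an error.
#' @return an object of class `"amplicon"`: list with `template_id`,
#'   `primer_set`, `status` (`"unique"`, `"none"` or `"multiple"`), and when
#'   a product exists `start`, `end`, `length` (all `NA` otherwise).
#' @export
find_amplicon <- function(template, primers, require_unique = TRUE) {
  stopifnot(inherits(primers, "primer_pair"))
  s <- as_seq_string(template)
  id <- if (inherits(template, "transcript")) template$id
        else if (inherits(template, "region")) template$parent_id
        else "<template>"
  f_starts <- match_starts(primers$forward, s)
  r_site <- revcomp(primers$reverse)
  r_starts <- match_starts(r_site, s)
  r_ends <- r_starts + nchar(r_site) - 1L

  products <- data.frame(start = integer(), end = integer())
  for (f in f_starts) {
    f_end <- f + nchar(primers$forward) - 1L
    hit <- r_ends[r_starts > f_end]
    for (e in hit)
      products[nrow(products) + 1L, ] <- list(f, e)
  }
  make <- function(status, start = NA_integer_, end = NA_integer_) {
    structure(list(template_id = id, primer_set = primers$name,
                   status = status, start = start, end = end,
                   length = if (is.na(start)) NA_integer_
                            else end - start + 1L),
              class = "amplicon")
  }
  if (nrow(products) == 0L) return(make("none"))
  if (nrow(products) == 1L)
    return(make("unique", products$start, products$end))
  if (require_unique)
    stop("primer set '", primers$name, "' on '", id, "': ",
         nrow(products), " possible products at (start, end): ",
         paste0("(", products$start, ", ", products$end, ")", collapse = " "))
  len <- products$end - products$start + 1L
  k <- which.min(len)
  make("multiple", products$start[k], products$end[k])
}

#' @export
print.amplicon <- function(x, ...) {
  if (x$status == "none")
    cat("no amplicon for ", x$primer_set, " on ", x$template_id, "\n",
        sep = "")
  else
    cat("amplicon for ", x$primer_set, " on ", x$template_id, ": ",
        x$length, " bp [", x$start, "-", x$end, "] (", x$status, ")\n",
        sep = "")
  invisible(x)
}

#' Screen primer sets against templates
#'
#' Every (template, primer set) combination is screened with
#' [find_amplicon()] with `require_unique` off, so multi-product pairs are
#' reported (shortest product, `status = "multiple"`) instead of aborting
#' the batch.
#'
#' @param templates a list of templates ([transcript()]s or sequences).
#' @param primer_sets a list of [primer_pair()]s.
#' @return a data frame with one row per combination: `template`,
#'   `primer_set`, `status`, `start`, `end`, `length`. Zero rows (with
#'   header) when either list is empty.
#' @export
batch_screen <- function(templates, primer_sets) {
  rows <- list()
  for (t in templates) for (p in primer_sets) {
    a <- find_amplicon(t, p, require_unique = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      template = a$template_id, primer_set = a$primer_set, status = a$status,
      start = a$start, end = a$end, length = a$length)
  }
  if (length(rows) == 0L)
    return(data.frame(template = character(), primer_set = character(),
                      status = character(), start = integer(),
                      end = integer(), length = integer()))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' The study's printed qPCR primer sets
#'
#' The primer pairs used for reference standardization and polysome-fraction
#' quantification, as printed in the source protocols: RPL27 (123 bp
#' amplicon on NM_000988), NeoR (84 bp on the pcDNA3.1 marker), CXCL8
#' (132 bp), Nluc (117 bp on the secNluc CDS), TNFAIP6 (212 bp on
#' NM_007115.3) and ACTB (121 bp on NM_001101.5). The CXCL8 pair's printed
#' template accession is internally inconsistent in the protocol and is
#' flagged when screened; its printed size is not treated as verifiable.
#'
#' @return a named list of [primer_pair()] objects with attribute
#'   `"expected_bp"` (named integer vector of printed amplicon sizes).
#' @export
study_primer_sets <- function() {
  sets <- list(
    RPL27 = primer_pair("RPL27", "ATCGCCAAGAGATCAAAGATAA",
                        "TCTGAAGACATCCTTATTGACG"),
    NeoR = primer_pair("NeoR", "CAAGATGGATTGCACGCAGG",
                       "GCAGCCGATTGTCTGTTGTG"),
    CXCL8 = primer_pair("CXCL8", "TGTGAAGGTGCAGTTTTGCCAAGG",
                        "GTTGGCGCAGTGTGGTCCACTC"),
    Nluc = primer_pair("Nluc", "GTGTCCGTAACTCCGATCCA",
                       "TTCGATCTGGCCCATTTGGT"),
    TNFAIP6 = primer_pair("TNFAIP6", "TGCTGGATGGATGGCTAAGG",
                          "ACTCATTTGGGAAGCCTGGAG"),
    ACTB = primer_pair("ACTB", "GTCATTCCAAATATGAGATGCGT",
                       "GCTATCACCTCCCCTGTGTG"))
  attr(sets, "expected_bp") <- c(RPL27 = 123L, NeoR = 84L, CXCL8 = 132L,
                                 Nluc = 117L, TNFAIP6 = 212L, ACTB = 121L)
  sets
}
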