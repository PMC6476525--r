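#' Normalize polysome-gradient fraction abundances to percentages
#'
#' Sucrose-gradient polysome profiling distributes an mRNA over ordered
#' fractions (14 in the protocol this package follows: fraction 1 is the
#' lightest, free-mRNA end; fraction 14 the heaviest polysomes). Per-mRNA
#' qPCR abundances are presented as a percentage of the sum of all
#' fractions, which makes profiles comparable across mRNAs and conditions
#' with different absolute yields.
#'
#' @param raw numeric vector of non-negative per-fraction abundances with a
#'   positive sum.
#' @param mrna,condition labels carried into summaries.
#' @param n_fractions required fraction count (default 14); a different
#'   count is fatal unless this parameter says so.
#' @return an object of class `"fraction_profile"`: list with `mrna`,
#'   `condition`, `fractions` (the raw values) and `percentages` (summing
#'   to 100).
#' @export
normalize_fractions <- function(raw, mrna = "", condition = "",
                                n_fractions = 14L) {
  if (length(raw) != n_fractions)
    stop("normalize_fractions: expected ", n_fractions, " fractions, got ",
         length(raw))
  if (any(!is.finite(raw)) || any(raw < 0))
    stop("normalize_fractions: abundances must be finite and non-negative")
  total <- sum(raw)
  if (total <= 0) stop("normalize_fractions: total abundance is zero")
  structure(list(mrna = mrna, condition = condition, fractions = raw,
                 percentages = 100 * raw / total),
            class = "fraction_profile")
}

#' @export
print.fraction_profile <- function(x, ...) {
  cat("polysome profile", if (nzchar(x$mrna)) paste0(" of ", x$mrna),
      if (nzchar(x$condition)) paste0(" (", x$condition, ")"),
      ": ", length(x$fractions), " fractions, heavy share (>=8) ",
      round(sum(x$percentages[8:length(x$percentages)]), 1), "%\n", sep = "")
  invisible(x)
}

#' Summarize how far a profile sits toward the heavy polysomes
#'
#' Two descriptive statistics of a normalized profile: `heavy_share`, the
#' percentage found in fractions `heavy_start` and beyond (default 8, the
#' second half of a 14-fraction gradient — the protocol defines no
#' monosome/polysome boundary, so this is a parameter, always reported with
#' its value), and `mean_fraction_index`, the percentage-weighted mean
#' fraction position. Both increase when an mRNA shifts toward larger
#' polysomes, i.e. toward more active translation.
#'
#' @param profile a [normalize_fractions()] profile.
#' @param heavy_start first fraction index counted as heavy, in
#'   `[1, n_fractions]`.
#' @return an object of class `"polysome_summary"`: list with `mrna`,
#'   `condition`, `heavy_share` (percent), `mean_fraction_index`,
#'   `heavy_start`.
#' @export
shift_summary <- function(profile, heavy_start = 8L) {
  stopifnot(inherits(profile, "fraction_profile"))
  n <- length(profile$percentages)
  heavy_start <- as.integer(heavy_start)
  if (is.na(heavy_start) || heavy_start < 1L || heavy_start > n)
    stop("shift_summary: heavy_start must be in [1, ", n, "]")
  p <- profile$percentages
  structure(list(mrna = profile$mrna, condition = profile$condition,
                 heavy_share = sum(p[heavy_start:n]),
                 mean_fraction_index = sum(seq_len(n) * p) / 100,
                 heavy_start = heavy_start),
            class = "polysome_summary")
}

#' @export
print.polysome_summary <- function(x, ...) {
  cat("polysome summary", if (nzchar(x$mrna)) paste0(" of ", x$mrna),
      if (nzchar(x$condition)) paste0(" (", x$condition, ")"),
      ": heavy share (fractions >= ", x$heavy_start, ") = ",
      round(x$heavy_share, 2), "%, mean fraction index = ",
      round(x$mean_fraction_index, 3), "\n", sep = "")
  invisible(x)
}

#' Compare polysome association between two conditions
#'
#' Differences of the [shift_summary()] statistics for the same mRNA under
#' two conditions, computed as `a - b`: positive values mean condition `a`
#' sits heavier on the gradient (more polysome-associated) than `b`.
#'
#' @param a,b [normalize_fractions()] profiles of the same mRNA.
#' @param heavy_start passed to [shift_summary()].
#' @return a list: `mrna`, `delta_heavy_share`, `delta_mean_index`,
#'   `heavy_start`.
#' @export
compare_conditions <- function(a, b, heavy_start = 8L) {
  stopifnot(inherits(a, "fraction_profile"), inherits(b, "fraction_profile"))
  if (!identical(a$mrna, b$mrna))
    stop("compare_conditions: profiles are for different mRNAs ('", a$mrna,
         "' vs '", b$mrna, "')")
  if (length(a$percentages) != length(b$percentages))
    stop("compare_conditions: fraction counts differ")
  sa <- shift_summary(a, heavy_start)
  sb <- shift_summary(b, heavy_start)
  list(mrna = a$mrna,
       delta_heavy_share = sa$heavy_share - sb$heavy_share,
       delta_mean_index = sa$mean_fraction_index - sb$mean_fraction_index,
       heavy_start = as.integer(heavy_start))
}

#' Read a long-format polysome fraction table
#'
#' Input TSV columns: `mrna`, `condition`, `fraction_index`, `abundance`.
#' Each (mrna, condition) group must contain every fraction index exactly
#' once; groups are normalized with [normalize_fractions()].
#'
#' @param path path to the TSV.
#' @param n_fractions expected fraction count (default 14).
#' @return a named list of [normalize_fractions()] profiles, names
#'   `"<mrna>:<condition>"`.
#' @export
read_fraction_table <- function(path, n_fractions = 14L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mrna", "condition", "fraction_index", "abundance")
  stopifnot(all(need %in% names(tab)))
  out <- list()
  for (key in unique(paste(tab$mrna, tab$condition, sep = ":"))) {
    g <- tab[paste(tab$mrna, tab$condition, sep = ":") == key, ]
    g <- g[order(g$fraction_index), ]
    if (!identical(as.integer(g$fraction_index), seq_len(n_fractions)))
      stop("fraction table group '", key, "' does not contain fractions 1..",
           n_fractions, " exactly once")
    out[[key]] <- normalize_fractions(g$abundance, mrna = g$mrna[1],
                                      condition = g$condition[1],
                                      n_fractions = n_fractions)
  }
  out
}
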