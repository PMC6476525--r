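# Seeded generators for every input the pipeline consumes. Each generator is
# a pure function of (parameters, seed): the global RNG state is saved and
# restored, and each generator draws from its own named substream of the
# global seed so adding a generator never perturbs existing fixtures.

#' Derive a named substream seed from a global seed
#'
#' Hashes a generator name into the global seed so each generator has an
#' independent, reproducible stream. The result is a non-negative integer
#' below 2^31.
#'
#' @param seed global integer seed.
#' @param name substream name.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

sample_bases <- function(n, au) {
  if (n == 0L) return("")
  p <- c(au / 2, au / 2, (1 - au) / 2, (1 - au) / 2)
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE, prob = p),
        collapse = "")
}

#' Generate a synthetic transcript with controlled per-region AU content
#'
#' Bases are drawn i.i.d. within each region with `P(A) = P(T) = au/2` and
#' `P(C) = P(G) = (1-au)/2`, so a region's realized AU fraction concentrates
#' around its target binomially. The CDS always begins `ATG` and ends `TAA`.
#' Two optional features shape the 3' UTR: `proximal_au` redraws its first
#' `len` bases at a separate AU target (so APS positives and negatives can
#' be built to order), and `conserved_block` records coordinates of a block
#' that [gen_homolog_set()] will keep substitution-free.
#'
#' @param utr5_len,cds_len,utr3_len region lengths in nt; `cds_len` must be
#'   a multiple of 3 and at least 6.
#' @param au_utr5,au_cds,au_utr3 target AU fractions in `[0, 1]`.
#' @param proximal_au optional `list(len =, au =)` override for the head of
#'   the 3' UTR; `len` must not exceed `utr3_len`.
#' @param conserved_block optional `c(start, length)` in 3'-UTR coordinates,
#'   stored as the `"conserved_block"` attribute.
#' @param id,gene,species annotation for the [transcript()].
#' @param seed integer seed; identical calls give identical transcripts.
#' @return a [transcript()].
#' @export
gen_transcript <- function(utr5_len = 150, cds_len = 300, utr3_len = 400,
                           au_utr5 = 0.5, au_cds = 0.5, au_utr3 = 0.5,
                           proximal_au = NULL, conserved_block = NULL,
                           id = "synthetic", gene = "", species = "synthetic",
                           seed = 1) {
  stopifnot(cds_len >= 6, cds_len %% 3 == 0,
            all(c(au_utr5, au_cds, au_utr3) >= 0),
            all(c(au_utr5, au_cds, au_utr3) <= 1))
  if (!is.null(proximal_au)) {
    stopifnot(is.list(proximal_au), all(c("len", "au") %in% names(proximal_au)),
              proximal_au$len <= utr3_len, proximal_au$au >= 0,
              proximal_au$au <= 1)
  }
  if (!is.null(conserved_block)) {
    stopifnot(length(conserved_block) == 2L,
              conserved_block[1] >= 1,
              conserved_block[1] + conserved_block[2] - 1 <= utr3_len)
  }
  with_local_seed(substream_seed(seed, "transcript"), {
    utr5 <- sample_bases(utr5_len, au_utr5)
    cds <- sample_bases(cds_len, au_cds)
    cds <- paste0("ATG", substr(cds, 4L, cds_len - 3L), "TAA")
    utr3 <- sample_bases(utr3_len, au_utr3)
    if (!is.null(proximal_au)) {
      head <- sample_bases(proximal_au$len, proximal_au$au)
      utr3 <- paste0(head, substr(utr3, proximal_au$len + 1L, utr3_len))
    }
    tx <- transcript(id, paste0(utr5, cds, utr3),
                     cds_start = utr5_len + 1L,
                     cds_end = utr5_len + cds_len,
                     gene = gene, species = species, validate_cds = TRUE)
    attr(tx, "conserved_block") <- conserved_block
    tx
  })
}

#' Generate homolog sequences around a conserved block
#'
#' Each homolog is the reference with i.i.d. substitutions (to a uniformly
#' chosen different base) at `substitution_rate` everywhere outside the
#' conserved block, and no substitutions inside it — a fixture for testing
#' conserved-block recovery, not a phylogenetic model.
#'
#' @param reference a [region()], [transcript()] (full sequence) or plain
#'   sequence.
#' @param n_species number of homologs.
#' @param substitution_rate per-site substitution probability in `[0, 0.5]`.
#' @param conserved_block optional `c(start, length)` on the reference kept
#'   substitution-free.
#' @param seed integer seed.
#' @return a list of [region()] objects named `homolog1..n`.
#' @export
gen_homolog_set <- function(reference, n_species = 4, substitution_rate = 0.2,
                            conserved_block = NULL, seed = 1) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 0.5, n_species >= 1)
  ref <- strsplit(as_seq_string(reference), "")[[1]]
  n <- length(ref)
  protected <- rep(FALSE, n)
  if (!is.null(conserved_block)) {
    s <- conserved_block[1]; l <- conserved_block[2]
    if (s < 1 || s + l - 1 > n)
      stop("gen_homolog_set: conserved block [", s, ", ", s + l - 1,
           "] outside reference of length ", n)
    protected[s:(s + l - 1)] <- TRUE
  }
  bases <- c("A", "C", "G", "T")
  with_local_seed(substream_seed(seed, "homologs"), {
    out <- lapply(seq_len(n_species), function(k) {
      hit <- stats::runif(n) < substitution_rate & !protected
      seq <- ref
      if (any(hit)) {
        seq[hit] <- vapply(seq[hit], function(b)
          sample(setdiff(bases, b), 1L), "")
      }
      region(paste0("homolog", k), "custom", 1L, n,
             paste(seq, collapse = ""))
    })
    names(out) <- paste0("homolog", seq_len(n_species))
    out
  })
}

#' Generate a replicate-level Ct table under a log2 expression model
#'
#' Each sample's target-gene Ct is `baseline - log2(fold)` plus Gaussian
#' noise of `ct_sigma` cycles; the reference gene sits at its own baseline
#' in every sample (stably expressed). A `control` sample with fold 1 is
#' always included, so [ddct_table()] on the output recovers the true folds
#' (exactly when `ct_sigma = 0`).
#'
#' @param true_folds named numeric vector of true fold changes per sample
#'   (relative to the control).
#' @param ct_sigma Gaussian noise SD on the Ct scale, in cycles.
#' @param n_replicates replicates per (sample, gene).
#' @param baseline,ref_baseline noiseless target/reference Ct at fold 1.
#' @param target,reference gene names used in the table.
#' @param seed integer seed.
#' @return a data frame: `sample`, `condition`, `gene`, `replicate`, `ct`.
#' @export
gen_ct_table <- function(true_folds, ct_sigma = 0.2, n_replicates = 3,
                         baseline = 24, ref_baseline = 18,
                         target = "target", reference = "ref", seed = 1) {
  stopifnot(!is.null(names(true_folds)), all(true_folds > 0), ct_sigma >= 0)
  folds <- c(true_folds, control = 1)
  with_local_seed(substream_seed(seed, "ct"), {
    rows <- lapply(names(folds), function(s) {
      rbind(
        data.frame(sample = s, condition = s, gene = target,
                   replicate = seq_len(n_replicates),
                   ct = baseline - log2(folds[[s]]) +
                     stats::rnorm(n_replicates, 0, ct_sigma)),
        data.frame(sample = s, condition = s, gene = reference,
                   replicate = seq_len(n_replicates),
                   ct = ref_baseline + stats::rnorm(n_replicates, 0, ct_sigma)))
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Generate paired reporter luminescence measurements
#'
#' Control-reporter signals are log-normal around `base_signal` with
#' coefficient of variation `cv`; UTR-reporter signals are log-normal around
#' `base_signal * true_ratio`. The log-normal is parameterized so that the
#' mean of the multiplicative noise is 1, making the per-replicate ratio an
#' (asymptotically) unbiased estimate of `true_ratio`.
#'
#' @param true_ratio true UTR/control expression ratio.
#' @param cv coefficient of variation of the multiplicative noise.
#' @param n number of paired replicates.
#' @param base_signal control-reporter mean signal (arbitrary units).
#' @param seed integer seed.
#' @return a data frame: `replicate`, `utr`, `control`.
#' @export
gen_luminescence <- function(true_ratio, cv = 0.1, n = 6,
                             base_signal = 1e4, seed = 1) {
  stopifnot(true_ratio > 0, cv >= 0, n >= 1)
  sdlog <- sqrt(log(1 + cv^2))
  with_local_seed(substream_seed(seed, "luminescence"), {
    noise <- function() stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    data.frame(replicate = seq_len(n),
               utr = base_signal * true_ratio * noise(),
               control = base_signal * noise())
  })
}

#' Generate a polysome fraction profile with a tunable heavy shift
#'
#' Fraction counts are multinomial at the given sequencing/qPCR depth around
#' a mean profile tilted toward heavier fractions by a per-fraction logit
#' offset growing with fraction index: `p'_i` is proportional to
#' `p_i * exp(shift * (i - 1))`, renormalized. `shift = 0` reproduces the
#' mean profile in expectation; positive shifts move mass rightwards (toward
#' larger polysomes), emulating translational activation.
#'
#' @param mean_profile probabilities over the fractions, summing to 1.
#' @param shift logit offset per fraction-index step (default 0).
#' @param depth total multinomial count.
#' @param mrna,condition labels for the profile.
#' @param seed integer seed.
#' @return a [normalize_fractions()] profile built from the sampled counts.
#' @export
gen_polysome <- function(mean_profile, shift = 0, depth = 1e4,
                         mrna = "synthetic", condition = "synthetic",
                         seed = 1) {
  if (abs(sum(mean_profile) - 1) > 1e-8)
    stop("gen_polysome: mean_profile must sum to 1")
  stopifnot(all(mean_profile >= 0), depth >= 1)
  n <- length(mean_profile)
  p <- mean_profile * exp(shift * (seq_len(n) - 1))
  p <- p / sum(p)
  with_local_seed(substream_seed(seed, "polysome"), {
    counts <- as.numeric(stats::rmultinom(1, size = depth, prob = p))
    normalize_fractions(counts, mrna = mrna, condition = condition,
                        n_fractions = n)
  })
}

#' Expected percentage profile of [gen_polysome()]
#'
#' The closed-form expectation of the sampled percentages under a given
#' shift, for checking Monte-Carlo estimates against truth.
#'
#' @inheritParams gen_polysome
#' @return a numeric vector of percentages summing to 100.
#' @export
polysome_expected_percent <- function(mean_profile, shift = 0) {
  n <- length(mean_profile)
  p <- mean_profile * exp(shift * (seq_len(n) - 1))
  100 * p / sum(p)
}

#' Generate western-blot band intensities with known phospho/total ratios
#'
#' Each lane gets a total band around `total_intensity` and a phospho band
#' around `total_intensity * ratio`, both with mean-1 log-normal
#' multiplicative noise at `band_cv`, plus a constant per-lane background
#' already included in the raw values (so the minimum-profile subtraction in
#' [western_ratio()] has something to remove). With `band_cv = 0` the
#' phospho/total ratios are recovered exactly.
#'
#' @param true_ratios named numeric vector: phospho/total ratio per lane.
#' @param band_cv coefficient of variation of the multiplicative noise.
#' @param total_intensity mean total-band intensity (arbitrary units).
#' @param background per-lane background added to both bands.
#' @param seed integer seed.
#' @return a data frame: `lane`, `protein` (`"phospho"`/`"total"`), `raw`,
#'   `background`.
#' @export
gen_bands <- function(true_ratios, band_cv = 0.05, total_intensity = 1e4,
                      background = 100, seed = 1) {
  stopifnot(!is.null(names(true_ratios)), all(true_ratios > 0), band_cv >= 0)
  n <- length(true_ratios)
  sdlog <- sqrt(log(1 + band_cv^2))
  with_local_seed(substream_seed(seed, "bands"), {
    noise <- function() stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    total <- total_intensity * noise()
    phospho <- total_intensity * true_ratios * noise()
    rbind(
      data.frame(lane = names(true_ratios), protein = "phospho",
                 raw = phospho + background, background = background),
      data.frame(lane = names(true_ratios), protein = "total",
                 raw = total + background, background = background))
  })
}
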