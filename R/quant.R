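#' Relative expression by the 2^-ddCt method
#'
#' Classic relative qPCR quantification: the target gene's Ct is referenced
#' to a stably expressed gene within each sample (`dCt = Ct_target -
#' Ct_reference`), the sample's dCt is referenced to the control condition
#' (`ddCt = dCt_sample - dCt_control`), and the fold change is
#' `efficiency^-ddCt`. Replicate Ct values are averaged on the Ct scale
#' before differencing (geometric-mean behaviour on the expression scale).
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_control,ct_ref_control
#'   numeric vectors of replicate Ct values (averaged internally).
#' @param efficiency amplification factor per cycle, in `(1, 2.2]`;
#'   default 2 (perfect doubling, the 2^-ddCt method as usually written).
#' @return a list of class `"relative_expression"`: `delta_ct_sample`,
#'   `delta_ct_control`, `delta_delta_ct`, `fold_change`, `efficiency`.
#' @examples
#' ddct(20, 18, 22, 18)$fold_change  # 4: the target gained 2 cycles
#' @export
ddct <- function(ct_target_sample, ct_ref_sample, ct_target_control,
                 ct_ref_control, efficiency = 2.0) {
  vals <- c(ct_target_sample, ct_ref_sample, ct_target_control,
            ct_ref_control)
  if (!all(is.finite(vals))) stop("ddct: all Ct values must be finite")
  if (efficiency <= 1 || efficiency > 2.2)
    stop("ddct: efficiency must be in (1, 2.2]")
  d_s <- mean(ct_target_sample) - mean(ct_ref_sample)
  d_c <- mean(ct_target_control) - mean(ct_ref_control)
  dd <- d_s - d_c
  structure(list(delta_ct_sample = d_s, delta_ct_control = d_c,
                 delta_delta_ct = dd, fold_change = efficiency^(-dd),
                 efficiency = efficiency),
            class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  cat("ddCt = ", round(x$delta_delta_ct, 3), ", fold change = ",
      signif(x$fold_change, 4), " (efficiency ", x$efficiency, ")\n",
      sep = "")
  invisible(x)
}

#' 2^-ddCt over a tidy Ct table
#'
#' Applies [ddct()] per sample to a replicate-level Ct table (columns
#' `sample`, `condition`, `gene`, `replicate`, `ct`), referencing every
#' sample's target dCt to the control sample's. A sample missing the
#' reference gene is a fatal error naming the sample.
#'
#' @param ct_table a data frame as above.
#' @param target,reference gene names in the `gene` column.
#' @param control sample name used as the ddCt baseline.
#' @param efficiency passed to [ddct()].
#' @return a data frame with one row per sample: `sample`, `gene`,
#'   `delta_ct`, `delta_delta_ct`, `fold_change`.
#' @export
ddct_table <- function(ct_table, target, reference, control,
                       efficiency = 2.0) {
  need <- c("sample", "gene", "ct")
  stopifnot(all(need %in% names(ct_table)))
  get_ct <- function(sample, gene) {
    v <- ct_table$ct[ct_table$sample == sample & ct_table$gene == gene]
    if (length(v) == 0L)
      stop("ddct_table: sample '", sample, "' has no Ct values for gene '",
           gene, "'")
    v
  }
  samples <- unique(ct_table$sample)
  if (!control %in% samples)
    stop("ddct_table: control sample '", control, "' not in table")
  res <- lapply(samples, function(s) {
    r <- ddct(get_ct(s, target), get_ct(s, reference),
              get_ct(control, target), get_ct(control, reference),
              efficiency = efficiency)
    data.frame(sample = s, gene = target, delta_ct = r$delta_ct_sample,
               delta_delta_ct = r$delta_delta_ct,
               fold_change = r$fold_change)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' UTR-reporter fold change over a UTR-less control
#'
#' The effect of fused UTRs on reporter expression: the ratio of the
#' UTR-reporter signal over the control-reporter signal, presented on the
#' log2 scale by default. Measurements are paired by position (replicate
#' batches measured on the same day); with `average = "after_ratio"`
#' (default) each pair yields a ratio and the summary is the mean of the
#' per-replicate log2 folds; with `"before_ratio"` signals are averaged
#' first and one ratio is computed. The same arithmetic serves protein
#' (luminescence) and mRNA levels — mRNA values should already be
#' reference-standardized (e.g. to NeoR via [ddct()]) upstream.
#'
#' @param utr,control numeric vectors of paired signals; `control` must be
#'   strictly positive.
#' @param scale `"log2"` (default) or `"linear"`.
#' @param average `"after_ratio"` (default) or `"before_ratio"`.
#' @return a list of class `"fold_change"`: `per_replicate` (folds on the
#'   requested scale; length 1 for `"before_ratio"`), `summary` (their
#'   mean), `scale`.
#' @export
reporter_fold_change <- function(utr, control, scale = c("log2", "linear"),
                                 average = c("after_ratio", "before_ratio")) {
  scale <- match.arg(scale)
  average <- match.arg(average)
  stopifnot(length(utr) == length(control), length(utr) >= 1L)
  if (any(control <= 0)) stop("reporter_fold_change: control signal <= 0")
  ratios <- if (average == "after_ratio") utr / control
            else mean(utr) / mean(control)
  folds <- if (scale == "log2") log2(ratios) else ratios
  structure(list(per_replicate = folds, summary = mean(folds),
                 scale = scale, average = average),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat("fold change (", x$scale, ", averaged ", x$average, "): ",
      signif(x$summary, 4), " over ", length(x$per_replicate),
      " replicate(s)\n", sep = "")
  invisible(x)
}

#' Plasmid-derived expression fold change with endogenous background
#'
#' Cells transfected with an empty plasmid express only endogenous message;
#' that background is subtracted from the full-transcript and CDS-only
#' transfections before their ratio is taken:
#' `fold = (full - control) / (cds - control)`, per replicate, separately
#' applicable to protein and mRNA measurements. A replicate whose
#' denominator is not positive, or whose numerator is negative, is flagged
#' non-computable (`NA` fold) rather than silently clipped; a numerator of
#' exactly zero is a genuine fold of 0.
#'
#' @param full,cds,control numeric vectors of paired replicate measurements
#'   in the same units.
#' @return a data frame with one row per replicate: `replicate`, `full`,
#'   `cds`, `control`, `fold_change`, `computable`.
#' @export
plasmid_fold_change <- function(full, cds, control) {
  stopifnot(length(full) == length(cds), length(cds) == length(control),
            length(full) >= 1L)
  num <- full - control
  den <- cds - control
  computable <- den > 0 & num >= 0
  fold <- ifelse(computable, num / den, NA_real_)
  data.frame(replicate = seq_along(full), full = full, cds = cds,
             control = control, fold_change = fold, computable = computable)
}

#' Western-blot band ratios normalized to a control lane
#'
#' Band intensities are background-subtracted per lane (the densitometry
#' software's "minimum profile" background is an input here), the
#' phospho/total ratio is formed per lane, and ratios are normalized to a
#' designated control lane so the control reads 1.0. A lane whose total band
#' is not positive after subtraction is fatal — the ratio is undefined.
#'
#' @param phospho,total numeric vectors of raw band intensities per lane.
#' @param background per-lane background, a scalar or a vector per lane
#'   (default 0: inputs already subtracted).
#' @param lanes optional lane names.
#' @param control_lane lane (name or index) whose normalized ratio is 1.0;
#'   default the first lane.
#' @return a data frame: `lane`, `phospho_net`, `total_net`, `ratio`,
#'   `norm_ratio`.
#' @export
western_ratio <- function(phospho, total, background = 0, lanes = NULL,
                          control_lane = 1L) {
  stopifnot(length(phospho) == length(total), length(phospho) >= 1L)
  n <- length(phospho)
  background <- rep_len(background, n)
  if (is.null(lanes)) lanes <- paste0("lane", seq_len(n))
  p <- phospho - background
  t <- total - background
  if (any(p < 0))
    stop("western_ratio: background exceeds phospho signal in lane(s) ",
         paste(lanes[p < 0], collapse = ", "))
  if (any(t <= 0))
    stop("western_ratio: total band not positive after background ",
         "subtraction in lane(s) ", paste(lanes[t <= 0], collapse = ", "))
  ratio <- p / t
  ctrl <- if (is.character(control_lane)) match(control_lane, lanes)
          else as.integer(control_lane)
  if (is.na(ctrl) || ctrl < 1L || ctrl > n)
    stop("western_ratio: control lane not found")
  data.frame(lane = lanes, phospho_net = p, total_net = t, ratio = ratio,
             norm_ratio = ratio / ratio[ctrl])
}

#' Phosphorylation fold change between control and inhibitor lanes
#'
#' The fold reduction in a phospho/total ratio caused by a treatment:
#' `fold = control_ratio / inhibitor_ratio`, so an inhibitor that drops the
#' ratio from 0.8 to 0.1 reads as an 8-fold reduction.
#'
#' @param control_ratio,inhibitor_ratio phospho/total ratios (e.g. from
#'   [western_ratio()]).
#' @return the fold change, a positive number.
#' @export
phospho_fold_change <- function(control_ratio, inhibitor_ratio) {
  if (any(inhibitor_ratio <= 0))
    stop("phospho_fold_change: inhibitor ratio must be positive")
  control_ratio / inhibitor_ratio
}
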