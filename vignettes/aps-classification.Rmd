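---
title: "Classifying AU-rich proximal UTR sequences and quantifying their reporters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying AU-rich proximal UTR sequences and quantifying their reporters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apsutr)
```

## The feature and the rule

Some mRNAs are translated far more efficiently in macrophages than in other
cell types, and the signal for that behaviour sits in the 3' UTR. The
feature this package classifies — the AU-rich proximal sequence, APS — is
defined by two conditions on the 3' UTR, the region immediately after the
stop codon:

1. the UTR is at least 300 bases long (inclusive: 300 passes, 299 fails);
2. the AU content of its first 100 bases strictly exceeds 50% (exactly 50%
   fails).

AU content is the fraction of `A` plus `U` bases; sequences are stored as
DNA, so `T` stands for `U` and the AU class is `{A, T}`. `N` never counts
as AU but stays in the denominator, and records with more than 10% `N` are
rejected outright — a composition statistic over mostly-ambiguous sequence
is noise.

Both cut-offs are parameters of `classify_aps()` (`min_len`, `threshold`,
`proximal_len`). The defaults are the operative definition; they are
exposed because the definition's own source hedges the window as "the first
hundred or so bases", and because one studied fragment of 283 nt behaves
like an APS carrier, so a user may legitimately probe the sensitivity of a
call to both knobs. The strict/inclusive reading of the two inequalities is
a deliberate literal interpretation, fixed here once so every downstream
number is reproducible.

```{r rule}
u <- paste0(strrep("AT", 30), strrep("GC", 170))  # 60% AU head, 400 nt
classify_aps(u)
```

## Coordinates

Every coordinate in the package is 1-based and inclusive, in mRNA space:
the fragment written `(79, 153)` has `153 - 79 + 1 = 75` bases. This is the
convention reporter constructs are named in, and an off-by-one here would
corrupt every AU window and amplicon length downstream, so it is enforced
in one place (`region()`) and never reinterpreted. Multi-exon genomic
coordinates are out of scope; inputs are transcript-space FASTA plus a CDS
coordinate table, or single-interval GenBank-style flat records.

## AU profiles

`au_profile()` slides a window (default 100 nt, step 10 nt) across a region
and reports one AU fraction per fully contained window; a trailing partial
window is dropped rather than padded. The windowing is cosmetic — it feeds
the line charts — while the APS call itself always uses the fixed
first-100-base statistic, so window and step can be changed freely without
touching any classification. UTRs shorter than 100 nt get their proximal
statistic over the available length plus a `short_region_flag`; such UTRs
can never be APS-positive anyway, since they fail `min_len` first.

## Reporter construct algebra

Mutant reporter UTRs are assembled by `apply_edits()` from an ordered edit
program (`take`, `insert_at`, `fuse`, `delete`) over named parts.
Coordinates are re-evaluated against the sequence as it stands when each
edit applies, matching how constructs are described ("inserted in between
positions 285 and 286"); a provenance log records each step with before and
after lengths so a construct is auditable and replayable byte-for-byte.
The mutagenesis logic the package reproduces is purely positional: a 91-nt
AU-poor donor inserted before base 1 *becomes* most of the new proximal
window and can flip a positive call negative, while the same donor placed
distally leaves the first 100 bases — and the call — untouched.

```{r construct}
utr <- paste0(strrep("AT", 35), strrep("GC", 165))   # 70% AU head
donor <- substr(strrep("GGC", 31), 1, 91)            # AU-poor donor
head_ins <- apply_edits(construct_spec("head", list(u = utr, d = donor),
                                       list(edit_insert_at(0, "d"))))
c(original = classify_aps(utr)$is_aps_positive,
  head_insert = classify_aps(head_ins)$is_aps_positive)
```

ARE motifs — the distinct, destabilizing `AUUUA` elements — are located by
`scan_are()` as a plain overlapping pentamer search with hits clustered
when their gap is at most 5 nt. This deliberately replaces no trained
classifier: externally predicted ARE intervals can be supplied as a table
and deleted with `delete_intervals()` instead.

## Alignment and conserved blocks

Cross-species conservation is assessed with an internally implemented
Needleman–Wunsch global aligner (match +1, mismatch −1, linear gap −2).
Tie-breaking in the traceback is fixed — diagonal, then up, then left — so
alignments are deterministic. The score recursion is vectorized row-wise
with a running-maximum identity, which keeps a few-hundred-nt alignment in
milliseconds without compiled code.

`find_conserved_blocks()` aligns each homolog to a designated reference and
scores each *reference column* by the fraction of homologs whose aligned
base matches (a gap counts as a mismatch); maximal runs of columns at or
above the identity threshold (default 1.0 — perfect columns, since the
source protocol states no threshold) are reported longest-first. Two
consequences of this design are worth knowing. First, it is pairwise-to-
reference, not a true multiple alignment; insertions private to one homolog
do not break a run because they create no reference column. Second, block
lengths are biased slightly upward: a flank column adjacent to a genuinely
conserved block extends it whenever every homolog happens to match there.
With 4 homologs at a 20% substitution rate that probability is
$0.8^4 \approx 0.41$ per column, so recovered lengths for an embedded 37-nt
block concentrate on 37–39 with an occasional longer run — the recovery
experiments in the test-suite measure exactly this behaviour.

## In-silico PCR

`find_amplicon()` matches the forward primer exactly on the sense strand
and the reverse complement of the reverse primer exactly downstream of it;
the amplicon spans both footprints. Exact matching is intentional: qPCR
primers are designed for perfect complementarity and the printed amplicon
size is the only verifiable contract. A missing product is a `"none"`
status, not an error, so batch screens continue; multiple products are
fatal under `require_unique`, otherwise the shortest (the species that
dominates qPCR amplification) is reported. The printed study primer sets
ship in `study_primer_sets()`; the CXCL8 pair is flagged because its
printed template accession is internally inconsistent in the source
protocol, so its printed 132-bp size is not treated as a verifiable target.

## Quantification arithmetic

* **2^−ΔΔCt** (`ddct()`, `ddct_table()`): replicate Ct values are averaged
  on the Ct scale before differencing — geometric-mean behaviour on the
  expression scale; the source protocol does not state its aggregation, so
  this choice is fixed and documented. Amplification efficiency defaults
  to 2.0 exactly (the method as usually written) with a per-primer
  override accepted in `(1, 2.2]`.
* **Reporter folds** (`reporter_fold_change()`): UTR-reporter over control
  ratios, log2 by default, replicates paired by batch. Whether replicates
  are averaged before or after the ratio is unstated in the source; both
  orders are supported, with after-the-ratio (mean of per-replicate log2
  folds) the default.
* **Plasmid-derived folds** (`plasmid_fold_change()`): endogenous
  background is subtracted from both transfections before the ratio,
  `(full − control)/(cds − control)`. A non-positive denominator or a
  negative numerator is flagged non-computable per replicate rather than
  clipped — with noisy data the subtraction can legitimately go negative,
  and silent clipping would bias folds; a numerator of exactly zero is a
  genuine fold of 0.
* **Western ratios** (`western_ratio()`, `phospho_fold_change()`): per-lane
  background (the densitometry "minimum profile") is subtracted, the
  phospho/total ratio formed, ratios normalized to a designated control
  lane, and treatment effects reported as control/inhibitor fold changes.
  A lane whose total band is non-positive after subtraction is fatal.

No hypothesis testing is attached to any of these: the measurements being
reproduced are reported as replicate-level values, and inventing a test
would add analysis their source never defined.

## Polysome profiles

Per-fraction qPCR abundances over a 14-fraction sucrose gradient are
normalized to percentages of their sum (`normalize_fractions()`), which is
idempotent and scale-invariant. `shift_summary()` reports the heavy-
fraction share — the percentage at or beyond `heavy_start` — and the
percentage-weighted mean fraction index. No fraction is canonically "the"
monosome/polysome boundary on these gradients, so `heavy_start` defaults
to 8 (the second half of the gradient) and is always carried in the
output: the summary is a parameterized descriptive statistic, not a
ribosome count. `compare_conditions()` takes simple differences, sign
convention positive = first profile heavier.

## What the synthetic generators emulate

All generators are pure functions of (parameters, seed), each drawing from
a named substream of the global seed so adding a generator never perturbs
existing fixtures.

* `gen_transcript()` draws bases i.i.d. per region at target AU
  composition — no dinucleotide structure, no codon usage; sufficient for
  testing composition statistics, and knowingly unrealistic about real UTR
  sequence. The realized head AU of a 100-nt window has binomial sd
  ≈ 5 percentage points around its target.
* `gen_homolog_set()` applies i.i.d. substitutions outside a protected
  block — a fixture for block recovery, not a phylogenetic model
  (no indels, no rate heterogeneity, no tree structure).
* `gen_ct_table()` places the target at `baseline − log2(fold)` with
  Gaussian noise on the Ct scale (the standard qPCR error model), the
  reference flat.
* `gen_luminescence()` and `gen_bands()` use mean-one log-normal
  multiplicative noise at a stated CV.
* `gen_polysome()` samples multinomial counts around a mean profile tilted
  by a per-fraction logit offset growing linearly with fraction index —
  the simplest mechanism that produces a rightward (heavy) shift;
  `polysome_expected_percent()` gives its closed-form expectation.

Passing tests therefore demonstrate that the arithmetic and the classifiers
are correct and that estimators recover known truth under these idealized
noise models. They do not demonstrate anything about real sequence
composition, real qPCR efficiency drift, gradient-to-gradient variation, or
antibody nonlinearity in densitometry.

## Problem sizes and numerical choices

The recovery experiments in the test-suite and acceptance script use: 1,000
random UTRs (50–2,000 nt) for the classifier/oracle agreement; 100
alignment self-score checks; 100 simulated Ct tables per true fold in
{0.25, 1, 4, 16} at σ_Ct = 0.2; 50 paired luminescence replicates at 10%
CV; 200 simulated condition pairs at multinomial depth 10⁴ for shift-sign
recovery; and 20 seeds of 4 homologs over a 300-nt reference for block
recovery. These sizes put Monte-Carlo error comfortably inside the
tolerances being checked while keeping a full run under a minute.

Degenerate inputs fail loudly by policy: empty sequences, absent UTRs
(`NULL`, never a zero-length region), zero-total fraction vectors,
non-positive control signals and out-of-bounds edits are all fatal errors
naming the offending record, because every one of them silently corrupts a
ratio or a percentage if allowed through.

## Limitations

Secondary structure, miRNA targeting, 5'-motif classes, true multiple
alignment and any trained ARE classifier are out of scope. The in-silico
PCR is exact-match only (no mismatch tolerance, no efficiency or melting
prediction). Conservation block lengths carry the upward flank-extension
bias described above. The accession-dependent checks (classifying the real
CXCL8 3' UTR, reproducing printed amplicon sizes on RefSeq records) require
network access via `fetch_refseq()` and are the only parts of the package
that cannot run offline.
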