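#!/usr/bin/env Rscript
# Conserved-block recovery experiment: a 37-nt block embedded in a 300-nt
# reference UTR, homologs substituted at 20% outside the block, recovery
# measured as the longest perfectly conserved run across 20 seeds.

library(apsutr)

seed <- 20260104
ref <- extract_utrs(gen_transcript(utr3_len = 300, seed = seed))$utr3

rows <- lapply(1:20, function(s) {
  hom <- gen_homolog_set(ref, n_species = 4, substitution_rate = 0.2,
                         conserved_block = c(120, 37), seed = seed + s)
  top <- find_conserved_blocks(ref, hom)[1, ]
  data.frame(seed = s, start = top$start, end = top$end, length = top$length)
})
tab <- do.call(rbind, rows)
write.table(tab, "results/conserved_blocks.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("embedded block: positions 120-156 (37 nt)\n")
cat("recovered lengths:", paste(tab$length, collapse = " "), "\n")
cat("median recovered length:", median(tab$length),
    "| within +/-2 nt:", sum(abs(tab$length - 37) <= 2), "/20\n")
cat("note: chance matches in the 20%-substituted flanks can extend a block;",
    "recovered lengths are biased slightly upward of 37.\n")
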