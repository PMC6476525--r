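#!/usr/bin/env Rscript
# Builds the synthetic transcript panel every later stage consumes: a set of
# mRNAs whose 3'-UTR head AU content and UTR lengths bracket the APS
# definition (AU > 50% in the first 100 nt, UTR >= 300 nt), written as
# FASTA + CDS coordinate table under results/.

library(apsutr)

dir.create("results", showWarnings = FALSE)
seed <- 20260101

recipes <- list(
  # id            utr3_len  head AU target (drawn binomially per base)
  aps_strong  = list(len = 1252, au = 0.70),  # long UTR, AU-rich head
  aps_weak    = list(len = 400,  au = 0.55),  # near the threshold
  gc_head     = list(len = 400,  au = 0.30),  # AU-poor head
  short_utr   = list(len = 299,  au = 0.90))  # AU-rich but < 300 nt

panel <- mapply(function(name, r) {
  gen_transcript(utr3_len = r$len,
                 proximal_au = list(len = min(100, r$len), au = r$au),
                 id = name, gene = toupper(name),
                 seed = seed + which(names(recipes) == name))
}, names(recipes), recipes, SIMPLIFY = FALSE)

# boundary case built exactly, not drawn: a head of precisely 50 A/T in
# 100 nt (strictly-greater rule makes it negative) spliced onto a
# generated tail via the construct machinery
base <- gen_transcript(utr3_len = 400, id = "at_boundary",
                       gene = "AT_BOUNDARY", seed = seed + 99)
head50 <- paste0(strrep("AT", 25), strrep("GC", 25))
utr3_50 <- apply_edits(construct_spec(
  "at_boundary_utr3", list(tail = extract_utrs(base)$utr3, head = head50),
  list(edit_take(101, 400), edit_insert_at(0, "head"))))
panel$at_boundary <- transcript(
  "at_boundary",
  paste0(substr(base$seq, 1, base$cds_end), utr3_50$seq),
  base$cds_start, base$cds_end, gene = "AT_BOUNDARY", species = "synthetic")

write_transcripts(panel, "results/panel.fa", "results/panel_cds.tsv")
rep <- region_report(panel)
write.table(rep, "results/panel_regions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("wrote", length(panel), "transcripts; region table:\n")
print(rep)
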