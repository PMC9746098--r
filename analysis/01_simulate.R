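#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Builds a 3 x 20 Mb toy genome with a 2% mappability blacklist, implants
# a somatic truth set (70 DEL / 25 DUP / 55 INS / 15 INV / 15 TRA, about
# one tenth the composition of a real breast-cancer consensus set) plus a
# shared germline set, and emulates the full multi-platform study design:
# 4 Illumina tools x 11 replicates, 2 linked-read tools x 11 replicates,
# and single-replicate PacBio / ONT / Hi-C tools, each with its own
# sensitivity profile, breakpoint jitter and false-positive rate, for
# tumor and normal samples (142 call sets in all).
#
# Outputs (results/):
#   truth_somatic.vcf, truth_germline.vcf  - the implanted truth sets
#   blacklist.bed                          - the simulated blacklist
#   callsets/<platform>_<tool>_r<k>_<sample>.vcf - emulated caller output
#   manifest.tsv                           - provenance of every call set

library(svconsensus)

seed <- 20260924
out <- "results"
dir.create(file.path(out, "callsets"), recursive = TRUE, showWarnings = FALSE)

genome <- genome_model(seed = seed + 1)
truth <- simulate_truth(genome, seed = seed + 2)
message(sprintf("truth: %d somatic + %d germline SVs",
                nrow(truth$somatic), nrow(truth$germline)))

write_sv_vcf(sv_callset(truth$somatic, "PacBio", "truth", "1", "tumor"),
             file.path(out, "truth_somatic.vcf"))
write_sv_vcf(sv_callset(truth$germline, "PacBio", "truth", "1", "normal"),
             file.path(out, "truth_germline.vcf"))
bl <- genome$blacklist$regions
write.table(bl, file.path(out, "blacklist.bed"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)

callsets <- emulate_callsets(truth, seed = seed + 3)
manifest <- do.call(rbind, lapply(names(callsets), function(nm) {
  cs <- callsets[[nm]]
  path <- file.path(out, "callsets", paste0(nm, ".vcf"))
  write_sv_vcf(cs, path)
  data.frame(file = path, platform = cs$platform, tool = cs$tool,
             replicate = cs$replicate, sample = cs$sample,
             n_records = nrow(cs$records))
}))
write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("wrote %d call sets (%d records total); manifest at %s",
                nrow(manifest), sum(manifest$n_records),
                file.path(out, "manifest.tsv")))
# no binary artifacts on purpose: stage 2 re-reads everything from the VCFs
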