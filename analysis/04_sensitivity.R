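#!/usr/bin/env Rscript
# Stage 4: sensitivity analyses.
#
# (a) Tumor purity x sequencing depth titration: somatic SV detection is
#     modelled as a Poisson supporting-read draw with mean
#     depth x purity x het_fraction x capture_eff against a 3-read
#     minimum, at the titration points 5/10/20/50/75/100% purity and
#     10-300X depth; recall curves are tabulated per SV type.
# (b) Cross-platform relative sensitivity: the proportion of each
#     platform's initial-call-set contribution reproduced by every other
#     platform, overall and stratified by SV size.
# (c) Orthogonal validation: a Bionano-style validation set (3 emulated
#     replicates, 2-of-3 replicate consensus, tumor-not-normal filter)
#     matched against the high-confidence set under the 500 bp /
#     >50% similarity / 10 kb (50 kb TRA) rules.
#
# Outputs (results/): purity_depth_recall.tsv, relative_sensitivity.tsv,
# bionano_validation.tsv

library(svconsensus)

seed <- 20260924
out <- "results"
truth_rec <- read_sv_vcf(file.path(out, "truth_somatic.vcf"),
                         "PacBio", "truth", "1", "tumor")$records
truth <- structure(list(somatic = truth_rec, germline = truth_rec[0, ],
                        genome = genome_model(seed = seed + 1)),
                   class = "truth_set")

## (a) purity / depth titration
ser <- simulate_purity_series(truth, seed = seed + 20)
tab <- purity_depth_curves(ser, truth)
write.table(tab, file.path(out, "purity_depth_recall.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
wide <- reshape(tab[tab$svtype == "ALL", c("purity", "depth", "recall")],
                idvar = "purity", timevar = "depth", direction = "wide")
message("overall recall by purity (rows) and depth (cols):")
print(round(wide, 3), row.names = FALSE)

## (b) relative sensitivity from the per-platform initial call set
memb <- read.table(file.path(out, "initial_members.tsv"), header = TRUE,
                   sep = "\t", stringsAsFactors = FALSE)
initial <- read_sv_vcf(file.path(out, "initial.vcf"),
                       "Illumina", "consensus", "1", "tumor")$records
# cluster ids in initial.vcf are "cluster<k>"; members carry the same ids
platform_calls <- lapply(split(memb$cluster_id, memb$platform),
                         function(ids) {
  keep <- initial$id %in% paste0("cluster", unique(ids))
  initial[keep, , drop = FALSE]
})
platform_calls <- platform_calls[vapply(platform_calls, nrow, 1L) > 0]
sm <- relative_sensitivity(platform_calls)
sm_long <- as.data.frame(as.table(sm))
names(sm_long) <- c("reference", "other", "fraction_reproduced")
write.table(sm_long, file.path(out, "relative_sensitivity.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("relative sensitivity (reference platform in rows):")
print(round(sm, 3))

## (c) Bionano-style orthogonal validation of the high-confidence set
bn_prof <- list(platform_profile(
  "Bionano", tools = c(Saphyr = 3),
  sensitivity = function(svtype, size) {
    p <- ifelse(svtype == "TRA", 0.8, ifelse(size >= 500, 0.75, 0))
    p[svtype == "INS" & size < 1000] <- 0.3
    p
  },
  jitter_sd = 1500, size_jitter_frac = 0.05, fp_rate = 0.1,
  fp_types = c("DEL", "DUP", "INS", "TRA")))
bn_sets <- emulate_callsets(truth, bn_prof, seed = seed + 30,
                            samples = "tumor")
bn_consensus <- replicate_consensus(bn_sets, min_replicates = 2)
hc <- read_sv_vcf(file.path(out, "high_confidence.vcf"),
                  "Illumina", "consensus", "1", "tumor")$records
m <- match_calls(hc, bn_consensus)
rep_tab <- match_report(m, file.path(out, "bionano_validation.tsv"))
message(sprintf(
  "orthogonal validation: %d/%d eligible high-confidence calls matched (%d ineligible <500 bp)",
  sum(rep_tab$status == "matched"), sum(rep_tab$status != "ineligible"),
  sum(rep_tab$status == "ineligible")))
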