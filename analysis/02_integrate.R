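#!/usr/bin/env Rscript
# Stage 2: multi-platform integration and consensus selection.
#
# Reads every call set back from the stage-1 VCFs (exercising the BND and
# symbolic-ALT readers), then runs the integration chain: split by size
# class and TRA status, window-merge per bucket, subtract tumor clusters
# supported in the normal sample, cluster by >50% reciprocal size
# similarity, drop 10X Long Ranger deletions under 20 kb, score per-tool
# and per-platform frequencies against the replicate census, and select
# the initial (>= 2 replicates, outside blacklist) and high-confidence
# (>= 2 platforms AND >= 2 tools) call sets.
#
# Outputs (results/): merged_members.tsv, consensus_scored.tsv,
# initial.vcf, high_confidence.vcf, summary_by_type.tsv,
# integration_metrics.tsv

library(svconsensus)

out <- "results"
manifest <- read.table(file.path(out, "manifest.tsv"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
callsets <- lapply(seq_len(nrow(manifest)), function(k) {
  m <- manifest[k, ]
  read_sv_vcf(m$file, m$platform, m$tool, as.character(m$replicate),
              m$sample)
})
message(sprintf("read %d call sets back from VCF", length(callsets)))

blacklist <- read_bed_regions(file.path(out, "blacklist.bed"),
                              label = "blacklist")
census <- census_from_callsets(callsets)
merged <- run_merge(callsets)
invisible(members_table(merged, file.path(out, "merged_members.tsv")))

cons <- run_consensus(merged, census, blacklist = blacklist)
invisible(consensus_table(cons$scored, file.path(out, "consensus_scored.tsv")))
write_sv_vcf(sv_callset(clusters_to_records(cons$initial),
                        "Illumina", "consensus", "1", "tumor"),
             file.path(out, "initial.vcf"))
write_sv_vcf(sv_callset(clusters_to_records(cons$high_confidence),
                        "Illumina", "consensus", "1", "tumor"),
             file.path(out, "high_confidence.vcf"))
write.table(cons$summary, file.path(out, "summary_by_type.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
# members of the initial clusters, in the post-exclusion numbering that
# initial.vcf / high_confidence.vcf use (the platform-exclusion step
# renumbers clusters, so merged_members.tsv ids do not apply here)
write.table(cons$initial$members, file.path(out, "initial_members.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# how well did integration recover the implanted truth?
truth <- read_sv_vcf(file.path(out, "truth_somatic.vcf"),
                     "PacBio", "truth", "1", "tumor")$records
ev <- data.frame(
  set = c("initial", "high_confidence"),
  n = c(nrow(cons$initial$clusters), nrow(cons$high_confidence$clusters)),
  recall = c(recall_precision(cons$initial, truth)$recall,
             recall_precision(cons$high_confidence, truth)$recall),
  precision = c(recall_precision(cons$initial, truth)$precision,
                recall_precision(cons$high_confidence, truth)$precision))
write.table(ev, file.path(out, "integration_metrics.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("integration metrics:")
print(ev)
message("per-type summary (scored / initial / high-confidence):")
print(cons$summary)
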