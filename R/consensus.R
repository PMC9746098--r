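# Frequency and consensus-score computation, and the initial /
# high-confidence call-set selection rules.

#' Replicate census: how many replicate call sets each tool contributed
#'
#' Frequencies are always computed against a census, never against
#' hard-coded denominators, so synthetic designs with other replicate
#' counts work unchanged. A tool is identified by its (platform, tool)
#' pair: the same caller run on two platforms (e.g. Sniffles on PacBio and
#' ONT) counts as two tools, matching how the study tallies call sets.
#'
#' @param platform,tool,n_replicates parallel vectors, one row per
#'   (platform, tool).
#' @return data.frame of class `replicate_census`.
#' @export
replicate_census <- function(platform, tool, n_replicates) {
  df <- data.frame(platform = as.character(platform),
                   tool = as.character(tool),
                   n_replicates = as.integer(n_replicates),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(paste(df$platform, df$tool)))
    stop("duplicate (platform, tool) in census")
  if (any(df$n_replicates < 1)) stop("replicate counts must be >= 1")
  class(df) <- c("replicate_census", "data.frame")
  df
}

#' Build a census from a collection of call sets
#'
#' @param callsets list of [sv_callset()].
#' @param sample which sample's call sets to count (default "tumor").
#' @return a [replicate_census()].
#' @export
census_from_callsets <- function(callsets, sample = "tumor") {
  keep <- vapply(callsets, function(cs) cs$sample == sample, logical(1))
  tab <- unique(do.call(rbind, lapply(callsets[keep], function(cs)
    data.frame(platform = cs$platform, tool = cs$tool,
               replicate = cs$replicate, stringsAsFactors = FALSE))))
  agg <- stats::aggregate(replicate ~ platform + tool, tab,
                          function(x) length(unique(x)))
  replicate_census(agg$platform, agg$tool, agg$replicate)
}

#' The study-design census
#'
#' Four Illumina tools with 11 replicates each (44 call sets), two 10X
#' tools with 11 each, and single-replicate long-read / Hi-C tools.
#'
#' @return a [replicate_census()].
#' @export
default_census <- function() {
  replicate_census(
    platform = c("Illumina", "Illumina", "Illumina", "Illumina",
                 "TenX", "TenX", "PacBio", "PacBio", "ONT", "ONT", "HiC"),
    tool = c("TNscope", "Delly", "Novobreak", "Manta",
             "LongRanger", "GrocSVs", "Sniffles", "PBSV",
             "Sniffles", "NanoSV", "Selva"),
    n_replicates = c(11, 11, 11, 11, 11, 11, 1, 1, 1, 1, 1))
}

check_census <- function(members, census) {
  have <- unique(paste(members$platform, members$tool))
  known <- paste(census$platform, census$tool)
  miss <- setdiff(have, known)
  if (length(miss) > 0)
    stop("member provenance absent from census: ", paste(miss, collapse = ", "))
}

#' Per-tool detection frequency of one merged SV
#'
#' For each (platform, tool): the number of distinct replicates of that
#' tool containing the SV, divided by the number of replicates the tool
#' was run on. Single-replicate tools yield 0 or 1; tools with no members
#' are absent from the result (not 0 entries).
#'
#' @param members member rows of one cluster (from `merged$members`).
#' @param census a [replicate_census()].
#' @return named numeric vector, names "platform/tool".
#' @export
tool_frequency <- function(members, census) {
  check_census(members, census)
  if (nrow(members) == 0) return(setNames(numeric(0), character(0)))
  key <- paste(members$platform, members$tool)
  nrep <- vapply(split(members$replicate, key),
                 function(x) length(unique(x)), integer(1))
  denom <- census$n_replicates[match(names(nrep),
                                     paste(census$platform, census$tool))]
  setNames(as.numeric(nrep) / denom,
           sub(" ", "/", names(nrep)))
}

#' Per-platform detection frequency of one merged SV
#'
#' For each platform: the number of distinct (tool, replicate) call sets on
#' that platform containing the SV, divided by the platform's total
#' call-set count in the census (e.g. 44 for four Illumina tools with 11
#' replicates each).
#'
#' @inheritParams tool_frequency
#' @return named numeric vector, names are platforms.
#' @export
platform_frequency <- function(members, census) {
  check_census(members, census)
  if (nrow(members) == 0) return(setNames(numeric(0), character(0)))
  ncall <- vapply(split(paste(members$tool, members$replicate),
                        members$platform),
                  function(x) length(unique(x)), integer(1))
  totals <- vapply(split(census$n_replicates, census$platform), sum,
                   numeric(1))
  setNames(as.numeric(ncall) / totals[names(ncall)], names(ncall))
}

#' Consensus score: sum of per-tool frequencies
#'
#' @param tool_freqs result of [tool_frequency()].
#' @return non-negative real; 0 for an empty map.
#' @export
consensus_score <- function(tool_freqs) {
  if (length(tool_freqs) == 0) return(0)
  sum(tool_freqs)
}

#' Score merged SVs against a replicate census
#'
#' Computes per-tool frequencies, per-platform frequencies and the
#' consensus score for every cluster.
#'
#' @param merged a `merged_svs` object.
#' @param census a [replicate_census()].
#' @return object of class `consensus_set`: list with `clusters` (cluster
#'   table plus `consensus_score`, `initial`, `high_confidence` flags),
#'   `tool_freq` and `platform_freq` long tables, `members`, `census`.
#' @export
score_consensus <- function(merged, census = default_census()) {
  check_census(merged$members, census)
  cl <- merged$clusters
  tf_rows <- list(); pf_rows <- list()
  score <- numeric(nrow(cl))
  for (k in seq_len(nrow(cl))) {
    mb <- merged$members[merged$members$cluster_id == cl$cluster_id[k], ,
                         drop = FALSE]
    tf <- tool_frequency(mb, census)
    pf <- platform_frequency(mb, census)
    score[k] <- consensus_score(tf)
    if (length(tf))
      tf_rows[[length(tf_rows) + 1]] <- data.frame(
        cluster_id = cl$cluster_id[k], tool = names(tf), freq = as.numeric(tf),
        stringsAsFactors = FALSE)
    if (length(pf))
      pf_rows[[length(pf_rows) + 1]] <- data.frame(
        cluster_id = cl$cluster_id[k], platform = names(pf),
        freq = as.numeric(pf), stringsAsFactors = FALSE)
  }
  cl$consensus_score <- score
  cl$initial <- FALSE
  cl$high_confidence <- FALSE
  structure(list(
    clusters = cl,
    tool_freq = if (length(tf_rows)) do.call(rbind, tf_rows) else
      data.frame(cluster_id = integer(), tool = character(), freq = numeric()),
    platform_freq = if (length(pf_rows)) do.call(rbind, pf_rows) else
      data.frame(cluster_id = integer(), platform = character(),
                 freq = numeric()),
    members = merged$members, census = census), class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("<consensus_set> %d clusters (%d initial, %d high-confidence)\n",
              nrow(x$clusters), sum(x$clusters$initial),
              sum(x$clusters$high_confidence)))
  invisible(x)
}

subset_consensus <- function(cons, keep_ids) {
  cons$clusters <- cons$clusters[cons$clusters$cluster_id %in% keep_ids, ,
                                 drop = FALSE]
  cons$members <- cons$members[cons$members$cluster_id %in% keep_ids, ,
                               drop = FALSE]
  cons$tool_freq <- cons$tool_freq[cons$tool_freq$cluster_id %in% keep_ids, ,
                                   drop = FALSE]
  cons$platform_freq <- cons$platform_freq[
    cons$platform_freq$cluster_id %in% keep_ids, , drop = FALSE]
  rownames(cons$clusters) <- NULL
  cons
}

#' Select the initial call set
#'
#' Retains clusters present in at least `min_replicates` distinct
#' (platform, tool, replicate) call sets and outside the blacklist /
#' non-primary contigs. Sets the `initial` flag.
#'
#' @param cons a `consensus_set`.
#' @param blacklist optional [genomic_regions()] blacklist.
#' @param min_replicates minimum replicate support (default 2).
#' @return filtered `consensus_set`.
#' @export
select_initial <- function(cons, blacklist = NULL, min_replicates = 2) {
  cl <- cons$clusters
  keep <- cl$n_replicates >= min_replicates
  if (!is.null(blacklist)) {
    drop <- positions_in_regions(cl$chrom1, cl$pos1, blacklist) |
      positions_in_regions(cl$chrom2, cl$pos2, blacklist)
    keep <- keep & !drop
  }
  keep <- keep & is_primary_chrom(cl$chrom1) & is_primary_chrom(cl$chrom2)
  out <- subset_consensus(cons, cl$cluster_id[keep])
  out$clusters$initial <- rep(TRUE, nrow(out$clusters))
  out
}

#' Select the high-confidence call set
#'
#' From an initial set, retains clusters supported by at least two
#' platforms and at least two tools, then removes clusters in the supplied
#' LOH regions. Sets the `high_confidence` flag (implying `initial`).
#'
#' @param cons a `consensus_set` that passed [select_initial()].
#' @param loh optional [genomic_regions()] with LOH regions
#'   (chr6p/chr16q/chrX in the human analysis).
#' @param min_platforms,min_tools agreement thresholds (default 2 and 2).
#' @return filtered `consensus_set`.
#' @export
select_high_confidence <- function(cons, loh = NULL, min_platforms = 2,
                                   min_tools = 2) {
  cl <- cons$clusters
  keep <- cl$n_platforms >= min_platforms & cl$n_tools >= min_tools
  if (!is.null(loh)) {
    drop <- positions_in_regions(cl$chrom1, cl$pos1, loh) |
      positions_in_regions(cl$chrom2, cl$pos2, loh)
    keep <- keep & !drop
  }
  out <- subset_consensus(cons, cl$cluster_id[keep])
  out$clusters$initial <- rep(TRUE, nrow(out$clusters))
  out$clusters$high_confidence <- rep(TRUE, nrow(out$clusters))
  out
}

#' Remove member contributions matching a provenance/type predicate
#'
#' Applied before scoring to drop platform-specific call classes (the
#' packaged default removes 10X Long Ranger deletions under 20 kb, which
#' are unreliable at that scale). Clusters left without members are
#' dropped; all counts are recomputed and never increase.
#'
#' @param merged a `merged_svs` object.
#' @param predicate function taking the members data frame and returning a
#'   logical vector marking members to REMOVE.
#' @param cfg size-class config for rebuilt clusters.
#' @return a `merged_svs` object.
#' @export
exclude_platform_calls <- function(merged, predicate,
                                   cfg = size_class_config()) {
  mb <- merged$members
  if (nrow(mb) == 0) return(merged)
  drop <- predicate(mb)
  stopifnot(is.logical(drop), length(drop) == nrow(mb))
  mb <- mb[!drop, , drop = FALSE]
  build_merged(mb, mb$cluster_id, cfg)
}

#' Predicate for 10X Long Ranger deletions shorter than 20 kb
#'
#' @param members members data frame.
#' @return logical vector (TRUE = remove).
#' @export
longranger_short_del_predicate <- function(members) {
  members$platform == "TenX" & members$tool == "LongRanger" &
    members$svtype == "DEL" & members$size < 20000
}

#' Export the consensus table
#'
#' One row per cluster with coordinates, counts, per-tool and per-platform
#' frequency columns, consensus score and flags.
#'
#' @param cons a `consensus_set`.
#' @param path optional TSV output path.
#' @return data frame.
#' @export
consensus_table <- function(cons, path = NULL) {
  cl <- cons$clusters
  tab <- cl[, c("cluster_id", "svtype", "chrom1", "pos1", "chrom2", "pos2",
                "size", "n_replicates", "n_tools", "n_platforms",
                "consensus_score", "initial", "high_confidence")]
  for (tool in sort(unique(cons$tool_freq$tool))) {
    sub <- cons$tool_freq[cons$tool_freq$tool == tool, ]
    tab[[paste0("freq_", gsub("[^A-Za-z0-9]", "_", tool))]] <-
      sub$freq[match(tab$cluster_id, sub$cluster_id)]
  }
  for (pf in sort(unique(cons$platform_freq$platform))) {
    sub <- cons$platform_freq[cons$platform_freq$platform == pf, ]
    tab[[paste0("pfreq_", pf)]] <- sub$freq[match(tab$cluster_id,
                                                  sub$cluster_id)]
  }
  tab[is.na(tab)] <- 0
  if (!is.null(path))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}

#' Convert consensus clusters to an SV record table
#'
#' Useful for writing selected sets back to VCF via [write_sv_vcf()].
#'
#' @param cons a `consensus_set` (or `merged_svs`).
#' @return an `sv_records` data frame of cluster representatives.
#' @export
clusters_to_records <- function(cons) {
  cl <- cons$clusters
  if (nrow(cl) == 0) return(empty_records())
  sv_records(id = paste0("cluster", cl$cluster_id), svtype = cl$svtype,
             chrom1 = cl$chrom1, pos1 = cl$pos1, chrom2 = cl$chrom2,
             pos2 = cl$pos2, size = cl$size)
}
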