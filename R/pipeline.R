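# End-to-end orchestration: split -> merge -> subtract -> cluster,
# consensus scoring/selection, and the Hi-C detection chain, with
# per-stage record counts logged so conservation is auditable.

combine_merged <- function(merged_list, cfg = size_class_config()) {
  merged_list <- merged_list[vapply(merged_list, function(m)
    nrow(m$members) > 0, logical(1))]
  if (length(merged_list) == 0)
    return(build_merged(empty_members(), integer(0), cfg))
  offset <- 0
  parts <- list()
  for (m in merged_list) {
    mb <- m$members
    mb$cluster_id <- mb$cluster_id + offset
    offset <- offset + max(mb$cluster_id)
    parts[[length(parts) + 1]] <- mb
  }
  members <- do.call(rbind, parts)
  build_merged(members, members$cluster_id, cfg)
}

#' Run the merge stage: split, merge, subtract, cluster
#'
#' Splits every call set by size class and TRA status, merges tumor and
#' normal call sets per bucket at that bucket's window, removes tumor
#' clusters supported in the normal sample, pools the buckets and applies
#' the reciprocal size-similarity clustering.
#'
#' @param callsets list of [sv_callset()] (tumor and normal).
#' @param cfg a [size_class_config()].
#' @param subtract_window optional override of the somatic-subtraction
#'   window; by default each bucket's merge window is used.
#' @param verbose log per-stage counts (default TRUE).
#' @return a `merged_svs` object of somatic clusters.
#' @export
run_merge <- function(callsets, cfg = size_class_config(),
                      subtract_window = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  tumor <- Filter(function(cs) cs$sample == "tumor", callsets)
  normal <- Filter(function(cs) cs$sample == "normal", callsets)
  n_in <- sum(vapply(tumor, function(cs) nrow(cs$records), integer(1)))
  say("run_merge: %d tumor call sets (%d records), %d normal call sets",
      length(tumor), n_in, length(normal))
  buckets_t <- lapply(tumor, split_by_size_and_type, cfg = cfg)
  buckets_n <- lapply(normal, split_by_size_and_type, cfg = cfg)
  keys <- unique(unlist(lapply(c(buckets_t, buckets_n), names)))
  window_of <- function(key) {
    if (key == "TRA") return(cfg$classes$window[cfg$n_classes])
    cfg$classes$window[as.integer(sub("size", "", key))]
  }
  per_bucket <- list()
  for (key in sort(keys)) {
    w <- window_of(key)
    cs_t <- Filter(Negate(is.null), lapply(buckets_t, `[[`, key))
    cs_n <- Filter(Negate(is.null), lapply(buckets_n, `[[`, key))
    if (length(cs_t) == 0) next
    mt <- merge_calls(cs_t, window = w, cfg = cfg)
    if (length(cs_n) > 0) {
      mn <- merge_calls(cs_n, window = w, cfg = cfg)
      sw <- if (is.null(subtract_window)) w else subtract_window
      ms <- somatic_subtract(mt, mn, window = sw)
    } else ms <- mt
    say("  bucket %s (window %g): %d clusters merged, %d somatic",
        key, w, nrow(mt$clusters), nrow(ms$clusters))
    per_bucket[[key]] <- ms
  }
  merged <- combine_merged(per_bucket, cfg)
  clustered <- cluster_merged(merged, cfg)
  say("run_merge: %d somatic clusters -> %d after similarity clustering",
      nrow(merged$clusters), nrow(clustered$clusters))
  clustered
}

#' Run the consensus stage: exclusions, scoring, selection
#'
#' @param merged a `merged_svs` object from [run_merge()].
#' @param census a [replicate_census()].
#' @param blacklist,loh optional [genomic_regions()] used by
#'   [select_initial()] and [select_high_confidence()].
#' @param exclude optional member-removal predicate applied before scoring
#'   (see [exclude_platform_calls()]); default removes Long Ranger
#'   deletions under 20 kb.
#' @param cfg size-class config.
#' @param verbose log per-stage counts.
#' @return list with `scored`, `initial`, `high_confidence`
#'   (`consensus_set` objects) and `summary` (per-svtype counts of the
#'   three sets).
#' @export
run_consensus <- function(merged, census = default_census(),
                          blacklist = NULL, loh = NULL,
                          exclude = longranger_short_del_predicate,
                          cfg = size_class_config(), verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(exclude)) {
    n0 <- nrow(merged$members)
    merged <- exclude_platform_calls(merged, exclude, cfg)
    say("run_consensus: platform exclusions removed %d member records",
        n0 - nrow(merged$members))
  }
  scored <- score_consensus(merged, census)
  initial <- select_initial(scored, blacklist = blacklist)
  hc <- select_high_confidence(initial, loh = loh)
  say("run_consensus: %d scored, %d initial, %d high-confidence",
      nrow(scored$clusters), nrow(initial$clusters), nrow(hc$clusters))
  lev <- sort(unique(scored$clusters$svtype))
  summary <- data.frame(
    svtype = lev,
    scored = as.integer(table(factor(scored$clusters$svtype, lev))),
    initial = as.integer(table(factor(initial$clusters$svtype, lev))),
    high_confidence = as.integer(table(factor(hc$clusters$svtype, lev))))
  list(scored = scored, initial = initial, high_confidence = hc,
       summary = summary)
}

#' Run the Hi-C detection chain on a matrix or triplet file
#'
#' @param input a [contact_matrix()] or the path of a triplet file
#'   readable by [read_hic_triplets()].
#' @param ... parameters forwarded to [hic_detect()].
#' @param verbose log per-stage counts.
#' @return `hic_candidates` with refined breakpoints and event classes.
#' @export
run_hic <- function(input, ..., verbose = TRUE) {
  M <- if (inherits(input, "contact_matrix")) input else
    read_hic_triplets(input)
  res <- hic_detect(M, ...)
  if (verbose)
    message(sprintf("run_hic: %d bins, %d candidate junction(s)",
                    nrow(M$bins), nrow(res)))
  res
}

#' Run the full synthetic demonstration pipeline
#'
#' simulate -> merge -> consensus -> Hi-C detect -> evaluate, writing all
#' tables under `out_dir`. Deterministic given the seed: re-running with
#' the same seed reproduces every output byte for byte.
#'
#' @param seed integer seed driving every random stage.
#' @param out_dir output directory (created if missing); NULL writes
#'   nothing.
#' @param hic_z_min candidate threshold used for the demo's Hi-C stage.
#' @param verbose log progress.
#' @return list with `truth`, `merged`, `consensus`, `hic`, `evaluation`.
#' @export
run_demo <- function(seed = 1, out_dir = NULL, hic_z_min = 6,
                     verbose = TRUE) {
  genome <- genome_model(seed = sub_seed(seed, 101))
  truth <- simulate_truth(genome, seed = sub_seed(seed, 102))
  callsets <- emulate_callsets(truth, seed = sub_seed(seed, 103))
  census <- census_from_callsets(callsets)
  merged <- run_merge(callsets, verbose = verbose)
  cons <- run_consensus(merged, census, blacklist = genome$blacklist,
                        verbose = verbose)
  large_tra <- truth$somatic[truth$somatic$svtype == "TRA", , drop = FALSE]
  M <- simulate_hic(genome, truth_svs = head(large_tra, 5),
                    seed = sub_seed(seed, 104))
  hic <- run_hic(M, Z_min = hic_z_min, verbose = verbose)
  ev <- list(
    initial = recall_precision(cons$initial, truth),
    high_confidence = recall_precision(cons$high_confidence, truth))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    members_table(merged, file.path(out_dir, "merged_members.tsv"))
    consensus_table(cons$high_confidence,
                    file.path(out_dir, "high_confidence.tsv"))
    write_sv_vcf(sv_callset(clusters_to_records(cons$high_confidence),
                            "Illumina", "consensus", "1", "tumor"),
                 file.path(out_dir, "high_confidence.vcf"))
    write_bedpe(hic, file.path(out_dir, "hic_candidates.bedpe"))
    write.table(cons$summary, file.path(out_dir, "summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(truth = truth, merged = merged, consensus = cons, hic = hic,
       evaluation = ev)
}
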