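# Orthogonal-validation matching: pairing calls between a query set and a
# validation set under per-type distance / size-similarity rules.

#' A matching rule for orthogonal validation
#'
#' The default rules mirror optical-mapping validation criteria: sized
#' types (DEL/DUP/INS/INV) are compared only above 500 bp (the validation
#' platform's resolution), require reciprocal size similarity above 0.5
#' and both breakends within 10 kb; translocations are exempt from the
#' size tests and allow 50 kb, with orientation ignored.
#'
#' @param svtypes types the rule applies to.
#' @param min_size_bp minimum size for both calls (ignored for TRA/BND).
#' @param size_similarity_min reciprocal similarity threshold (exclusive).
#' @param max_distance_bp maximum breakend distance (both breakends).
#' @param ignore_orientation orientation flag (kept for the record; the
#'   matcher never compares orientation).
#' @return list of class `match_rule`.
#' @export
match_rule <- function(svtypes, min_size_bp = 500, size_similarity_min = 0.5,
                       max_distance_bp = 10000, ignore_orientation = TRUE) {
  stopifnot(size_similarity_min > 0, size_similarity_min <= 1,
            max_distance_bp > 0)
  structure(list(svtypes = svtypes, min_size_bp = min_size_bp,
                 size_similarity_min = size_similarity_min,
                 max_distance_bp = max_distance_bp,
                 ignore_orientation = ignore_orientation),
            class = "match_rule")
}

#' @rdname match_rule
#' @export
default_match_rules <- function() {
  list(match_rule(c("DEL", "DUP", "INS", "INV"), min_size_bp = 500,
                  size_similarity_min = 0.5, max_distance_bp = 10000),
       match_rule(c("TRA", "BND"), min_size_bp = 0,
                  size_similarity_min = 0.5, max_distance_bp = 50000))
}

#' Matching rules for truth-based evaluation
#'
#' Same shape as [default_match_rules()] but with the size floor dropped
#' to the 50 bp SV definition (the 500 bp floor is an optical-mapping
#' resolution limit, not a property of truth sets).
#'
#' @export
evaluation_match_rules <- function() {
  list(match_rule(c("DEL", "DUP", "INS", "INV"), min_size_bp = 50,
                  size_similarity_min = 0.5, max_distance_bp = 10000),
       match_rule(c("TRA", "BND"), min_size_bp = 0,
                  size_similarity_min = 0.5, max_distance_bp = 50000))
}

rule_for_type <- function(rules, svtype) {
  for (r in rules) if (svtype %in% r$svtypes) return(r)
  NULL
}

# All rule-eligible (query, validation) index pairs with their distance
# (max of the two breakend distances) and size similarity. TRA/BND pairs
# of any "direction" match as long as the breakend chromosome sets agree.
eligible_pairs <- function(query, validation, rules) {
  out <- list()
  for (qi in seq_len(nrow(query))) {
    q <- query[qi, ]
    rule <- rule_for_type(rules, q$svtype)
    if (is.null(rule)) next
    tra <- q$svtype %in% c("TRA", "BND")
    if (!tra && q$size < rule$min_size_bp) next
    cand <- which(validation$svtype == q$svtype |
                    (tra & validation$svtype %in% c("TRA", "BND")))
    for (vi in cand) {
      v <- validation[vi, ]
      if (!tra && v$size < rule$min_size_bp) next
      if (!tra) {
        if (size_similarity(q$size, v$size) <= rule$size_similarity_min) next
      }
      # records are breakend-canonicalized, so pairwise comparison suffices
      if (q$chrom1 != v$chrom1 || q$chrom2 != v$chrom2) next
      d1 <- abs(q$pos1 - v$pos1); d2 <- abs(q$pos2 - v$pos2)
      if (max(d1, d2) > rule$max_distance_bp) next
      out[[length(out) + 1]] <- data.frame(
        qi = qi, vi = vi, distance = max(d1, d2),
        similarity = size_similarity(q$size, v$size))
    }
  }
  if (length(out) == 0)
    return(data.frame(qi = integer(), vi = integer(), distance = numeric(),
                      similarity = numeric()))
  do.call(rbind, out)
}

#' Match query calls against a validation set
#'
#' Applies the per-type [match_rule()]s: same svtype (TRA/BND
#' interchangeable, orientation never compared), both sizes above the
#' rule's floor (TRA exempt), reciprocal size similarity above the
#' threshold (TRA exempt), and both breakend distances within the rule's
#' window. Pairs are assigned greedily one-to-one by ascending breakend
#' distance (ties by query order), and every query is reported as
#' matched, unmatched, or ineligible (below the size floor or no
#' applicable rule).
#'
#' @param query,validation `sv_records` data frames.
#' @param rules list of [match_rule()] (default [default_match_rules()]).
#' @return list with `pairs` (query_id, validation_id, distance,
#'   similarity) and `status` (query_id, svtype, status, matched_id).
#' @export
match_calls <- function(query, validation, rules = default_match_rules()) {
  query <- as.data.frame(query); validation <- as.data.frame(validation)
  ep <- eligible_pairs(query, validation, rules)
  ep <- ep[order(ep$distance, ep$qi, ep$vi), , drop = FALSE]
  q_used <- logical(nrow(query)); v_used <- logical(nrow(validation))
  pairs <- list()
  for (k in seq_len(nrow(ep))) {
    qi <- ep$qi[k]; vi <- ep$vi[k]
    if (q_used[qi] || v_used[vi]) next
    q_used[qi] <- TRUE; v_used[vi] <- TRUE
    pairs[[length(pairs) + 1]] <- data.frame(
      query_id = query$id[qi], validation_id = validation$id[vi],
      distance = ep$distance[k], similarity = ep$similarity[k],
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(query_id = character(), validation_id = character(),
               distance = numeric(), similarity = numeric())
  status <- character(nrow(query))
  for (qi in seq_len(nrow(query))) {
    q <- query[qi, ]
    rule <- rule_for_type(rules, q$svtype)
    tra <- q$svtype %in% c("TRA", "BND")
    status[qi] <- if (is.null(rule) || (!tra && q$size < rule$min_size_bp))
      "ineligible" else if (q_used[qi]) "matched" else "unmatched"
  }
  status_df <- data.frame(
    query_id = query$id, svtype = query$svtype, status = status,
    matched_id = pairs$validation_id[match(query$id, pairs$query_id)],
    stringsAsFactors = FALSE)
  list(pairs = pairs, status = status_df)
}

#' Replicate-consensus selection for an orthogonal platform
#'
#' Keeps calls that are reproduced (under [match_calls()] rules, against
#' the sibling replicates) in at least `min_replicates` of the supplied
#' replicate call sets, de-duplicated across replicates; when a normal
#' call set is supplied, retained calls matching any normal call are
#' removed (tumor-not-normal filtering).
#'
#' @param callsets list of >= `min_replicates` replicate [sv_callset()]s.
#' @param min_replicates required replicate support (default 2).
#' @param rules matching rules (default [default_match_rules()]).
#' @param normal optional normal-sample `sv_records` (or [sv_callset()]).
#' @return `sv_records` of the consensus calls.
#' @export
replicate_consensus <- function(callsets, min_replicates = 2,
                                rules = default_match_rules(),
                                normal = NULL) {
  if (length(callsets) < min_replicates)
    stop("need at least min_replicates call sets")
  recs <- lapply(callsets, function(cs)
    if (inherits(cs, "sv_callset")) cs$records else as.data.frame(cs))
  keep_rows <- list()
  for (a in seq_along(recs)) {
    A <- recs[[a]]
    if (nrow(A) == 0) next
    support <- rep(1L, nrow(A))  # a call supports itself in its own replicate
    for (b in seq_along(recs)) {
      if (b == a || nrow(recs[[b]]) == 0) next
      m <- match_calls(A, recs[[b]], rules)
      support <- support + as.integer(m$status$status == "matched")
    }
    kept <- A[support >= min_replicates, , drop = FALSE]
    if (nrow(kept) > 0) {
      kept$replicate_origin <- a
      keep_rows[[length(keep_rows) + 1]] <- kept
    }
  }
  if (length(keep_rows) == 0) return(empty_records())
  pooled <- do.call(rbind, keep_rows)
  # de-duplicate across replicates: earlier replicates win
  pooled <- pooled[order(pooled$replicate_origin), , drop = FALSE]
  dedup <- pooled[0, , drop = FALSE]
  for (k in seq_len(nrow(pooled))) {
    row <- pooled[k, , drop = FALSE]
    if (nrow(dedup) > 0) {
      m <- match_calls(row, dedup, rules)
      if (any(m$status$status == "matched")) next
    }
    dedup <- rbind(dedup, row)
  }
  dedup$replicate_origin <- NULL
  if (!is.null(normal)) {
    nrm <- if (inherits(normal, "sv_callset")) normal$records else
      as.data.frame(normal)
    if (nrow(nrm) > 0 && nrow(dedup) > 0) {
      m <- match_calls(dedup, nrm, rules)
      dedup <- dedup[m$status$status != "matched", , drop = FALSE]
    }
  }
  rownames(dedup) <- NULL
  class(dedup) <- c("sv_records", "data.frame")
  dedup
}

#' Export a validation report
#'
#' @param match_result result of [match_calls()].
#' @param path optional TSV output path.
#' @return the status data frame with distances and similarities joined.
#' @export
match_report <- function(match_result, path = NULL) {
  st <- match_result$status
  st$distance <- match_result$pairs$distance[
    match(st$query_id, match_result$pairs$query_id)]
  st$similarity <- match_result$pairs$similarity[
    match(st$query_id, match_result$pairs$query_id)]
  if (!is.null(path))
    write.table(st, path, sep = "\t", quote = FALSE, row.names = FALSE)
  st
}
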