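# Evaluation: recall/precision against truth, cross-platform relative
# sensitivity, and purity/depth sensitivity curves.

as_records <- function(x) {
  if (inherits(x, "sv_callset")) return(x$records)
  if (inherits(x, "merged_svs") || inherits(x, "consensus_set")) {
    cl <- clusters_to_records(x)
    # carry a truth id into each cluster when any member has one
    mb <- x$members
    tid <- vapply(x$clusters$cluster_id, function(cid) {
      t <- unique(stats::na.omit(mb$truth_id[mb$cluster_id == cid]))
      if (length(t) > 0) t[1] else NA_character_
    }, character(1))
    cl$truth_id <- tid
    return(cl)
  }
  as.data.frame(x)
}

#' Recall and precision against a truth set
#'
#' When the calls carry simulator truth ids the evaluation is exact:
#' recall is the fraction of truth SVs whose id appears among the calls
#' and precision the fraction of calls carrying a valid truth id.
#' Otherwise calls are matched to truth by [match_calls()] under the
#' supplied rules. With an empty truth set recall is NA (undefined); with
#' no calls recall is 0 and precision NA.
#'
#' @param calls `sv_records`, [sv_callset()], `merged_svs` or
#'   `consensus_set`.
#' @param truth a `truth_set` (its somatic records are used) or
#'   `sv_records`.
#' @param rules matching rules (default [evaluation_match_rules()]).
#' @param use_truth_ids "auto" (use ids when present), TRUE or FALSE.
#' @return list with `recall`, `precision`, `n_calls`, `n_truth`, and
#'   `by_type` (per-svtype recall table).
#' @export
recall_precision <- function(calls, truth, rules = evaluation_match_rules(),
                             use_truth_ids = "auto") {
  calls <- as_records(calls)
  truth_rec <- if (inherits(truth, "truth_set")) truth$somatic else
    as.data.frame(truth)
  if (nrow(truth_rec) == 0) {
    return(list(recall = NA_real_, precision = NA_real_,
                n_calls = nrow(calls), n_truth = 0,
                by_type = data.frame(svtype = character(), recall = numeric()),
                note = "empty truth set: recall undefined"))
  }
  ids_ok <- "truth_id" %in% names(calls) && any(!is.na(calls$truth_id))
  use_ids <- identical(use_truth_ids, TRUE) ||
    (identical(use_truth_ids, "auto") && ids_ok)
  if (nrow(calls) == 0)
    return(list(recall = 0, precision = NA_real_, n_calls = 0,
                n_truth = nrow(truth_rec),
                by_type = data.frame(svtype = unique(truth_rec$svtype),
                                     recall = 0)))
  if (use_ids) {
    hit <- truth_rec$id %in% calls$truth_id
    precision <- mean(!is.na(calls$truth_id) &
                        calls$truth_id %in% truth_rec$id)
  } else {
    m <- match_calls(truth_rec, calls, rules)
    hit <- m$status$status == "matched"
    m2 <- match_calls(calls, truth_rec, rules)
    precision <- mean(m2$status$status == "matched")
  }
  by_type <- stats::aggregate(hit ~ truth_rec$svtype, FUN = mean)
  names(by_type) <- c("svtype", "recall")
  list(recall = mean(hit), precision = precision, n_calls = nrow(calls),
       n_truth = nrow(truth_rec), by_type = by_type)
}

#' Cross-platform relative sensitivity matrix
#'
#' `cell[ref, other]` is the proportion of the reference platform's calls
#' reproduced by the other platform under the matching rules; the matrix
#' is asymmetric by construction and its diagonal is 1 by definition. A
#' platform with zero calls yields an NA row. With `size_bins` the matrix
#' is additionally computed per size stratum of the reference calls
#' (TRA/BND fall in the last, open-ended bin).
#'
#' @param callsets_by_platform named list: platform -> `sv_records` or
#'   [sv_callset()] (pool replicate call sets per platform beforehand).
#' @param rules matching rules (default [evaluation_match_rules()]).
#' @param size_bins optional numeric break points for stratification.
#' @return a matrix, or with `size_bins` a named list of matrices.
#' @export
relative_sensitivity <- function(callsets_by_platform,
                                 rules = evaluation_match_rules(),
                                 size_bins = NULL) {
  if (length(callsets_by_platform) < 2)
    stop("need at least two platforms")
  recs <- lapply(callsets_by_platform, as_records)
  platforms <- names(recs)
  build <- function(recs_local) {
    out <- matrix(NA_real_, length(platforms), length(platforms),
                  dimnames = list(reference = platforms, other = platforms))
    for (a in platforms) for (b in platforms) {
      out[a, b] <- if (nrow(recs_local[[a]]) == 0) NA_real_
      else if (a == b) 1
      else mean(match_calls(recs_local[[a]], recs_local[[b]],
                            rules)$status$status == "matched")
    }
    out
  }
  if (is.null(size_bins)) return(build(recs))
  brk <- c(size_bins, Inf)
  labels <- paste0("(", c(0, size_bins), ",", c(size_bins, Inf), "]")
  out <- list()
  for (k in seq_along(brk)) {
    lo <- if (k == 1) 0 else brk[k - 1]
    hi <- brk[k]
    recs_k <- lapply(recs, function(df) {
      tra <- df$svtype %in% c("TRA", "BND")
      df[(df$size > lo & df$size <= hi) | (tra & is.infinite(hi)), ,
         drop = FALSE]
    })
    out[[labels[k]]] <- build(recs_k)
  }
  out
}

#' Recall by tumor purity, depth and SV type
#'
#' @param series result of [simulate_purity_series()] (names encode the
#'   purity/depth cell) or any named list of call sets with names
#'   "p<purity>_d<depth>".
#' @param truth a `truth_set` or somatic `sv_records`.
#' @param rules matching rules, used only when truth ids are absent.
#' @return data.frame with columns purity, depth, svtype ("ALL" plus each
#'   type), recall.
#' @export
purity_depth_curves <- function(series, truth,
                                rules = evaluation_match_rules()) {
  rows <- list()
  for (nm in names(series)) {
    m <- regmatches(nm, regexec("^p([0-9.]+)_d([0-9.]+)$", nm))[[1]]
    if (length(m) != 3) stop("series name not of the form p<purity>_d<depth>: ", nm)
    rp <- recall_precision(series[[nm]], truth, rules)
    rows[[length(rows) + 1]] <- data.frame(
      purity = as.numeric(m[2]), depth = as.numeric(m[3]), svtype = "ALL",
      recall = rp$recall, stringsAsFactors = FALSE)
    if (nrow(rp$by_type) > 0)
      rows[[length(rows) + 1]] <- data.frame(
        purity = as.numeric(m[2]), depth = as.numeric(m[3]),
        svtype = rp$by_type$svtype, recall = rp$by_type$recall,
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$depth, out$purity, out$svtype), , drop = FALSE]
}
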