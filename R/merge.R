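# Windowed breakpoint merging of multi-caller call sets, tumor-normal
# subtraction, and reciprocal size-similarity clustering of merged SVs.

empty_members <- function() {
  df <- empty_records()
  df$platform <- character(0); df$tool <- character(0)
  df$replicate <- character(0); df$sample <- character(0)
  df
}

pool_callsets <- function(callsets) {
  if (inherits(callsets, "sv_callset")) callsets <- list(callsets)
  parts <- lapply(callsets, function(cs) {
    df <- cs$records
    if (nrow(df) == 0) return(NULL)
    df$platform <- cs$platform; df$tool <- cs$tool
    df$replicate <- cs$replicate; df$sample <- cs$sample
    df
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0) return(empty_members())
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# Candidate + exact pairwise linkage on a member table. Returns a 2-column
# matrix of row indices (i < j). `window` may be scalar or per-row; the
# effective per-pair window is the larger of the two rows' windows.
# mode "merge": positional windows only, INS additionally needs size
# similarity >= 0.5. mode "cluster": non-TRA/BND pairs additionally need
# size similarity > 0.5.
link_edges <- function(df, window, same_type = TRUE,
                       mode = c("merge", "cluster")) {
  mode <- match.arg(mode)
  n <- nrow(df)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  if (any(window <= 0)) stop("window must be positive")
  w <- rep_len(window, n)
  key <- paste(if (same_type) df$svtype else "", df$chrom1, df$chrom2)
  pair_parts <- lapply(split(seq_len(n), key), function(g) {
    if (length(g) < 2) return(NULL)
    g <- g[order(df$pos1[g])]
    p1 <- df$pos1[g]
    wmax <- max(w[g])
    # for each a, candidates are the run of b > a with pos1 within wmax
    hi <- findInterval(p1 + wmax, p1)
    m <- pmax(hi - seq_along(g), 0)
    if (sum(m) == 0) return(NULL)
    a <- rep.int(seq_along(g), m)
    b <- a + sequence(m)
    cbind(g[a], g[b])
  })
  pair_parts <- pair_parts[!vapply(pair_parts, is.null, logical(1))]
  if (length(pair_parts) == 0) return(matrix(integer(0), ncol = 2))
  pairs <- do.call(rbind, pair_parts)
  i <- pairs[, 1]; j <- pairs[, 2]
  wij <- pmax(w[i], w[j])
  ok <- abs(df$pos1[i] - df$pos1[j]) <= wij
  ti <- df$svtype[i]
  is_ins <- ti == "INS"
  is_tra <- ti %in% c("TRA", "BND")
  sim <- size_similarity(df$size[i], df$size[j])
  # second breakend distance applies to everything except INS (degenerate END)
  ok <- ok & (is_ins | abs(df$pos2[i] - df$pos2[j]) <= wij)
  if (mode == "merge") {
    ok <- ok & (!is_ins | sim >= 0.5)
  } else {
    ok <- ok & (is_tra | sim > 0.5)
  }
  if (!same_type) {
    # still never link TRA/BND to a sized type: size logic is undefined
    ok <- ok & (is_tra == (df$svtype[j] %in% c("TRA", "BND")))
  }
  cbind(i[ok], j[ok])
}

# Connected components of the linkable graph.
component_membership <- function(n, edges) {
  if (n == 0) return(integer(0))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

build_merged <- function(members, membership, cfg = size_class_config()) {
  if (nrow(members) == 0) {
    cl <- data.frame(cluster_id = integer(), svtype = character(),
                     chrom1 = character(), pos1 = integer(),
                     chrom2 = character(), pos2 = integer(), size = numeric(),
                     size_class = integer(), window = numeric(),
                     rep_id = character(), n_members = integer(),
                     n_replicates = integer(), n_tools = integer(),
                     n_platforms = integer(), stringsAsFactors = FALSE)
    members$cluster_id <- integer(0)
    return(structure(list(clusters = cl, members = members),
                     class = "merged_svs"))
  }
  n <- nrow(members)
  membership <- as.integer(factor(membership))
  # representative per component: highest replicate support of its
  # (platform, tool), ties by smallest pos1 then id -- fully vectorized
  pt_key <- paste(membership, members$platform, members$tool)
  support <- ave(rep(1L, n), pt_key, FUN = sum)
  ord <- order(membership, -support, members$pos1, members$id)
  rep_rows <- ord[!duplicated(membership[ord])]
  rep_comp <- membership[rep_rows]
  idx_by_comp <- split(seq_len(n), membership)
  uniq_count <- function(x) vapply(split(x, membership),
                                   function(v) length(unique(v)), integer(1))
  r <- members[rep_rows, , drop = FALSE]
  sc <- size_class_of(r, cfg, strict = FALSE)
  clusters <- data.frame(
    svtype = r$svtype, chrom1 = r$chrom1, pos1 = r$pos1, chrom2 = r$chrom2,
    pos2 = r$pos2, size = r$size, size_class = sc$class, window = sc$window,
    rep_id = r$id, n_members = lengths(idx_by_comp)[as.character(rep_comp)],
    n_replicates = uniq_count(paste(members$platform, members$tool,
                                    members$replicate))[as.character(rep_comp)],
    n_tools = uniq_count(paste(members$platform,
                               members$tool))[as.character(rep_comp)],
    n_platforms = uniq_count(members$platform)[as.character(rep_comp)],
    stringsAsFactors = FALSE)
  rownames(clusters) <- NULL
  names_comps <- as.character(rep_comp)
  ord <- order(clusters$chrom1, clusters$pos1, clusters$svtype, clusters$rep_id)
  clusters <- clusters[ord, , drop = FALSE]
  old_ids <- names_comps[ord]
  new_of_old <- setNames(seq_along(old_ids), old_ids)
  clusters$cluster_id <- seq_len(nrow(clusters))
  clusters <- clusters[, c("cluster_id", setdiff(names(clusters), "cluster_id"))]
  rownames(clusters) <- NULL
  members$cluster_id <- as.integer(new_of_old[as.character(membership)])
  members <- members[order(members$cluster_id, members$platform, members$tool,
                           members$replicate, members$id), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(clusters = clusters, members = members), class = "merged_svs")
}

#' @export
print.merged_svs <- function(x, ...) {
  cat(sprintf("<merged_svs> %d clusters from %d member records\n",
              nrow(x$clusters), nrow(x$members)))
  if (nrow(x$clusters) > 0) print(table(x$clusters$svtype))
  invisible(x)
}

#' Split a call set by size class and TRA status
#'
#' Mirrors the per-size-class VCF splitting that precedes merging: records
#' are bucketed into the five size classes, with TRA/BND records extracted
#' into a separate bucket (they always use the large-class window).
#'
#' @param callset an [sv_callset()].
#' @param cfg a [size_class_config()].
#' @return named list of call sets: `size1` ... `sizeK` (non-TRA records of
#'   each class) and `TRA`; empty buckets are omitted. Every input record
#'   appears in exactly one bucket.
#' @export
split_by_size_and_type <- function(callset, cfg = size_class_config()) {
  df <- callset$records
  if (nrow(df) == 0) return(list())
  sc <- size_class_of(df, cfg)
  bucket <- ifelse(df$svtype %in% c("TRA", "BND"), "TRA",
                   paste0("size", sc$class))
  out <- lapply(split(seq_len(nrow(df)), bucket), function(idx) {
    sv_callset(df[idx, , drop = FALSE], callset$platform, callset$tool,
               callset$replicate, callset$sample)
  })
  out[order(names(out))]
}

#' Merge call sets by breakpoint windows
#'
#' Two records are linkable iff (a) they share an SV type (when
#' `same_type_required`), (b) both breakend chromosomes match and both
#' breakend positions are within `window` bp (for TRA both breakend
#' chromosome pairs must match), and (c) insertions additionally require
#' size similarity >= 0.5 (their END is degenerate). Merged groups are the
#' connected components of the linkable graph, so two members of one group
#' may individually violate the pairwise rule (transitive merging, as in
#' Survivor).
#'
#' @param callsets list of [sv_callset()] (typically one size/TRA bucket
#'   from each tool/replicate).
#' @param window merge window in bp (the bucket's class window).
#' @param same_type_required require type agreement (default TRUE).
#' @param cfg size-class config used to annotate clusters.
#' @return object of class `merged_svs`: list with a `clusters` data frame
#'   (one row per merged SV, representative coordinates, member counts) and
#'   a `members` data frame (every input record with provenance and its
#'   `cluster_id`).
#' @export
merge_calls <- function(callsets, window, same_type_required = TRUE,
                        cfg = size_class_config()) {
  if (window <= 0) stop("window must be positive")
  members <- pool_callsets(callsets)
  edges <- link_edges(members, window, same_type = same_type_required,
                      mode = "merge")
  build_merged(members, component_membership(nrow(members), edges), cfg)
}

#' Remove tumor clusters supported in the normal sample
#'
#' A tumor merged SV is removed iff some normal merged SV is linkable to
#' its representative under the [merge_calls()] predicate at the given
#' window; surviving clusters keep their provenance untouched.
#'
#' @param tumor,normal `merged_svs` merged at the same size class/window.
#' @param window subtraction window in bp.
#' @return `merged_svs` containing the somatic (tumor-only) clusters.
#' @export
somatic_subtract <- function(tumor, normal, window) {
  if (nrow(tumor$clusters) == 0 || nrow(normal$clusters) == 0) return(tumor)
  tc <- tumor$clusters; nc <- normal$clusters
  both <- rbind(tc[, c("svtype", "chrom1", "pos1", "chrom2", "pos2", "size")],
                nc[, c("svtype", "chrom1", "pos1", "chrom2", "pos2", "size")])
  edges <- link_edges(both, window, same_type = TRUE, mode = "merge")
  nt <- nrow(tc)
  cross <- edges[(edges[, 1] <= nt) != (edges[, 2] <= nt), , drop = FALSE]
  hit <- unique(pmin(cross[, 1], cross[, 2]))
  keep_ids <- tc$cluster_id[!seq_len(nt) %in% hit]
  subset_merged(tumor, keep_ids)
}

subset_merged <- function(merged, keep_ids) {
  cl <- merged$clusters[merged$clusters$cluster_id %in% keep_ids, , drop = FALSE]
  mb <- merged$members[merged$members$cluster_id %in% keep_ids, , drop = FALSE]
  relabel <- setNames(seq_len(nrow(cl)), cl$cluster_id)
  cl$cluster_id <- as.integer(relabel[as.character(cl$cluster_id)])
  mb$cluster_id <- as.integer(relabel[as.character(mb$cluster_id)])
  rownames(cl) <- NULL; rownames(mb) <- NULL
  structure(list(clusters = cl, members = mb), class = "merged_svs")
}

#' Cluster merged SVs by type, size similarity and breakpoint distance
#'
#' Two merged SVs cluster iff they share an SV type, their reciprocal size
#' similarity min/max exceeds 0.5 (TRA/BND exempt), and both breakend
#' distances are within the size class's clustering window (TRA: 10 kb;
#' for a pair spanning two classes the larger window applies). Clusters are
#' connected components; members and provenance counts are unioned.
#'
#' @param merged a `merged_svs` object (from the cross-tool merge step).
#' @param cfg a [size_class_config()].
#' @return a `merged_svs` object with clustered groups.
#' @export
cluster_merged <- function(merged, cfg = size_class_config()) {
  cl <- merged$clusters
  if (nrow(cl) < 2) return(merged)
  edges <- link_edges(cl, cl$window, same_type = TRUE, mode = "cluster")
  memb_cl <- component_membership(nrow(cl), edges)
  membership <- memb_cl[match(merged$members$cluster_id, cl$cluster_id)]
  build_merged(merged$members, membership, cfg)
}

#' Remove merged SVs in excluded regions or on non-primary contigs
#'
#' A merged SV is removed iff either representative breakend falls inside
#' any supplied region, or either breakend chromosome is not a primary
#' assembly chromosome (the ALT-contig rule).
#'
#' @param merged a `merged_svs` object.
#' @param regions a [genomic_regions()] object or a list of them
#'   (e.g. blacklist plus LOH regions).
#' @param drop_alt_contigs apply the primary-chromosome rule (default TRUE).
#' @return filtered `merged_svs`.
#' @export
filter_regions <- function(merged, regions = list(), drop_alt_contigs = TRUE) {
  cl <- merged$clusters
  if (nrow(cl) == 0) return(merged)
  if (inherits(regions, "genomic_regions")) regions <- list(regions)
  drop <- rep(FALSE, nrow(cl))
  if (drop_alt_contigs)
    drop <- drop | !is_primary_chrom(cl$chrom1) | !is_primary_chrom(cl$chrom2)
  for (rs in regions) {
    drop <- drop | positions_in_regions(cl$chrom1, cl$pos1, rs) |
      positions_in_regions(cl$chrom2, cl$pos2, rs)
  }
  subset_merged(merged, cl$cluster_id[!drop])
}

#' Export cluster membership as a flat table
#'
#' @param merged a `merged_svs` object.
#' @param path optional TSV output path.
#' @return data frame with columns cluster_id, svtype, chrom1, pos1,
#'   chrom2, pos2, size, platform, tool, replicate.
#' @export
members_table <- function(merged, path = NULL) {
  tab <- merged$members[, c("cluster_id", "svtype", "chrom1", "pos1",
                            "chrom2", "pos2", "size", "platform", "tool",
                            "replicate")]
  if (!is.null(path))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}
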