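#' @importFrom stats median rbinom rnorm rpois runif setNames complete.cases
#' @importFrom utils read.table write.table head
NULL

SV_TYPES <- c("DEL", "DUP", "INS", "INV", "TRA", "BND")
PLATFORMS <- c("Illumina", "TenX", "PacBio", "ONT", "HiC", "Bionano")

RECORD_COLS <- c("id", "svtype", "chrom1", "pos1", "chrom2", "pos2",
                 "size", "filter", "truth_id")

empty_records <- function() {
  data.frame(id = character(), svtype = character(),
             chrom1 = character(), pos1 = integer(),
             chrom2 = character(), pos2 = integer(),
             size = numeric(), filter = character(),
             truth_id = character(), stringsAsFactors = FALSE)
}

#' Construct a table of structural-variant records
#'
#' The package represents SVs as plain data frames with one row per record
#' and two breakends (`chrom1`/`pos1`, `chrom2`/`pos2`, both 1-based).
#' `size` is the absolute SV length in bp; translocations (`TRA`) and
#' unresolved breakends (`BND`) carry size 0 and are exempt from all size
#' logic. For insertions the two breakends coincide and `size` is the
#' inserted length. Breakends of intra-chromosomal records are stored in
#' canonical order (`pos2 >= pos1`); inter-chromosomal records are ordered
#' by (chrom, pos) so that merging is orientation-free.
#'
#' @param id character vector of record ids (unique within a call set).
#' @param svtype one of DEL, DUP, INS, INV, TRA, BND per record.
#' @param chrom1,pos1,chrom2,pos2 breakend coordinates (1-based).
#' @param size absolute size in bp (ignored and forced to 0 for TRA/BND).
#' @param filter VCF FILTER string, default "PASS".
#' @param truth_id optional simulator truth label (NA for real data).
#' @return data.frame of class `sv_records`.
#' @export
sv_records <- function(id, svtype, chrom1, pos1, chrom2 = chrom1,
                       pos2 = pos1, size = 0, filter = "PASS",
                       truth_id = NA_character_) {
  n <- length(id)
  if (n == 0) {
    df <- empty_records()
    class(df) <- c("sv_records", "data.frame")
    return(df)
  }
  df <- data.frame(id = as.character(id), svtype = as.character(svtype),
                   chrom1 = as.character(chrom1), pos1 = as.integer(pos1),
                   chrom2 = as.character(chrom2), pos2 = as.integer(pos2),
                   size = as.numeric(size),
                   filter = rep_len(as.character(filter), n),
                   truth_id = rep_len(as.character(truth_id), n),
                   stringsAsFactors = FALSE)
  bad <- !df$svtype %in% SV_TYPES
  if (any(bad)) stop("unknown svtype: ", paste(unique(df$svtype[bad]), collapse = ", "))
  df$size[df$svtype %in% c("TRA", "BND")] <- 0
  df <- canonicalize_breakends(df)
  validate_sv_records(df)
  class(df) <- c("sv_records", "data.frame")
  df
}

# Put breakends in canonical order and enforce size consistency for
# intra-chromosomal non-INS records.
canonicalize_breakends <- function(df) {
  ins <- df$svtype == "INS"
  df$chrom2[ins] <- df$chrom1[ins]
  df$pos2[ins] <- df$pos1[ins]
  swap <- (df$chrom1 == df$chrom2 & df$pos2 < df$pos1) |
    (df$chrom1 != df$chrom2 & df$chrom2 < df$chrom1)
  if (any(swap)) {
    tmpc <- df$chrom1[swap]; tmpp <- df$pos1[swap]
    df$chrom1[swap] <- df$chrom2[swap]; df$pos1[swap] <- df$pos2[swap]
    df$chrom2[swap] <- tmpc; df$pos2[swap] <- tmpp
  }
  intra <- df$chrom1 == df$chrom2 & !df$svtype %in% c("INS", "TRA", "BND")
  df$size[intra] <- df$pos2[intra] - df$pos1[intra]
  df
}

validate_sv_records <- function(df) {
  stopifnot(all(RECORD_COLS %in% names(df)))
  if (any(df$pos1 < 1 | df$pos2 < 1)) stop("positions must be >= 1")
  if (any(!nzchar(df$chrom1) | !nzchar(df$chrom2))) stop("empty chromosome name")
  intra <- df$chrom1 == df$chrom2 & !df$svtype %in% c("INS", "TRA", "BND")
  if (any(df$size[intra] != df$pos2[intra] - df$pos1[intra]))
    stop("size inconsistent with breakend span")
  invisible(df)
}

#' Construct a call set: SV records plus provenance
#'
#' A call set is the output of one (platform, tool, replicate, sample)
#' combination. Records are sorted by (chrom1, pos1) and exact-coordinate
#' duplicates (same type, breakends and size) are removed, with the number
#' of duplicates recorded in the `n_duplicates` attribute.
#'
#' @param records `sv_records` data frame.
#' @param platform one of Illumina, TenX, PacBio, ONT, HiC, Bionano.
#' @param tool caller name.
#' @param replicate replicate identifier (coerced to character).
#' @param sample "tumor" or "normal".
#' @return object of class `sv_callset`: a list with elements `records`,
#'   `platform`, `tool`, `replicate`, `sample`.
#' @export
sv_callset <- function(records, platform, tool, replicate = "1",
                       sample = c("tumor", "normal")) {
  sample <- match.arg(sample)
  if (!platform %in% PLATFORMS)
    stop("unknown platform: ", platform)
  records <- as.data.frame(records)
  dupkey <- with(records, paste(svtype, chrom1, pos1, chrom2, pos2, size))
  ndup <- sum(duplicated(dupkey))
  records <- records[!duplicated(dupkey), , drop = FALSE]
  records <- records[order(records$chrom1, records$pos1, records$chrom2,
                           records$pos2, records$id), , drop = FALSE]
  rownames(records) <- NULL
  if (anyDuplicated(records$id)) stop("record ids must be unique within a call set")
  out <- list(records = records, platform = platform, tool = tool,
              replicate = as.character(replicate), sample = sample)
  attr(out, "n_duplicates") <- ndup
  class(out) <- "sv_callset"
  out
}

#' @export
print.sv_callset <- function(x, ...) {
  cat(sprintf("<sv_callset> %s/%s rep %s (%s): %d records\n",
              x$platform, x$tool, x$replicate, x$sample, nrow(x$records)))
  invisible(x)
}

provenance_key <- function(cs) {
  paste(cs$platform, cs$tool, cs$replicate, cs$sample, sep = "|")
}

#' Size-class configuration for windowed merging
#'
#' Five size classes with upper-inclusive boundaries and their merge
#' windows: \[50,100\] -> 50 bp, (100,500\] -> 100 bp, (500,1000\] -> 500 bp,
#' (1000,30000\] -> 1000 bp, and >30 kb together with all TRA/BND -> 10 kb.
#'
#' @param classes data.frame with columns `lower`, `upper`, `window` (bp);
#'   classes must be contiguous and non-overlapping.
#' @param large_window merge window for the large class (>30 kb and TRA).
#' @return object of class `size_class_config`.
#' @export
size_class_config <- function(classes = data.frame(
                                lower = c(50, 100, 500, 1000),
                                upper = c(100, 500, 1000, 30000),
                                window = c(50, 100, 500, 1000)),
                              large_window = 10000) {
  stopifnot(nrow(classes) >= 1, all(classes$lower < classes$upper),
            all(diff(classes$lower) > 0))
  if (nrow(classes) > 1 &&
      any(classes$upper[-nrow(classes)] != classes$lower[-1]))
    stop("size classes must be contiguous")
  cfg <- rbind(classes,
               data.frame(lower = classes$upper[nrow(classes)], upper = Inf,
                          window = large_window))
  structure(list(classes = cfg, n_classes = nrow(cfg)),
            class = "size_class_config")
}

#' Assign an SV to its size class and merge window
#'
#' TRA and BND records always map to the large class (10 kb window)
#' regardless of size. Boundaries are upper-inclusive: a 100 bp SV falls in
#' the \[50,100\] class. Non-TRA records smaller than the lowest bound are
#' sub-threshold and rejected.
#'
#' @param records `sv_records` data frame.
#' @param cfg a [size_class_config()].
#' @param strict reject sub-threshold records (default TRUE); with
#'   `strict = FALSE` they are annotated with the lowest class instead
#'   (used when annotating already-merged clusters).
#' @return data.frame with columns `class` (1-based index) and `window` (bp),
#'   one row per record.
#' @export
size_class_of <- function(records, cfg = size_class_config(),
                          strict = TRUE) {
  cl <- cfg$classes
  lower0 <- cl$lower[1]
  idx <- integer(nrow(records))
  tra <- records$svtype %in% c("TRA", "BND")
  idx[tra] <- cfg$n_classes
  if (any(!tra)) {
    s <- records$size[!tra]
    if (strict && any(s < lower0))
      stop(sprintf("%d record(s) below the %g bp size threshold",
                   sum(s < lower0), lower0))
    # upper-inclusive: class i holds sizes in (lower_i, upper_i], except
    # the first class which includes its lower bound
    k <- findInterval(s, c(cl$lower[1], cl$upper[-cfg$n_classes]),
                      left.open = TRUE, rightmost.closed = FALSE)
    k[s <= lower0] <- 1L
    k <- pmin(pmax(k, 1L), cfg$n_classes)
    idx[!tra] <- k
  }
  data.frame(class = idx, window = cl$window[idx])
}

#' Construct a genomic region set
#'
#' Regions are stored as 0-based half-open intervals (the BED convention)
#' and queried against 1-based breakend positions.
#'
#' @param chrom,start,end parallel vectors (start < end, 0-based half-open).
#' @param label free-text label (e.g. "blacklist", "LOH").
#' @return object of class `genomic_regions`.
#' @export
genomic_regions <- function(chrom = character(), start = integer(),
                            end = integer(), label = "regions") {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("regions require start < end")
  structure(list(regions = df, label = label), class = "genomic_regions")
}

#' @export
print.genomic_regions <- function(x, ...) {
  cat(sprintf("<genomic_regions> '%s': %d intervals\n",
              x$label, nrow(x$regions)))
  invisible(x)
}

regions_to_granges <- function(rs) {
  df <- rs$regions
  if (nrow(df) == 0)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

# TRUE for each (chrom, pos) that falls inside any region
positions_in_regions <- function(chrom, pos, rs) {
  if (length(chrom) == 0) return(logical(0))
  gr <- regions_to_granges(rs)
  if (length(gr) == 0) return(rep(FALSE, length(chrom)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  IRanges::overlapsAny(q, gr)
}

#' Test whether chromosome names are primary assembly chromosomes
#'
#' Primary chromosomes are chr1-chr22, chrX, chrY, chrM (with or without
#' the "chr" prefix). Anything else (ALT contigs, decoys, unplaced
#' scaffolds) is non-primary and removed by the ALT-contig rule.
#'
#' @param chrom character vector of chromosome names.
#' @return logical vector.
#' @export
is_primary_chrom <- function(chrom) {
  grepl("^(chr)?([0-9]{1,2}|X|Y|M|MT)$", chrom)
}

# reciprocal size similarity min/max, defined as 1 for two TRA/BND
size_similarity <- function(size_a, size_b) {
  lo <- pmin(size_a, size_b)
  hi <- pmax(size_a, size_b)
  out <- ifelse(hi == 0, 1, lo / hi)
  ifelse(lo == 0 & hi > 0, 0, out)
}
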