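# Readers and writers for the two SV VCF dialects (symbolic ALT and BND
# mate pairs) and for BED region files.

# Parse one BND ALT string, e.g. "N[chr17:198982[" or "]13:123[T".
# Returns list(chrom, pos, retain) where `retain` is which side of THIS
# breakend is retained at the junction ("L" if the base precedes the
# bracket, "R" if it follows), or NULL if malformed.
parse_bnd_alt <- function(alt) {
  m <- regexec("^([ACGTNacgtn]*)([\\[\\]])([^:\\[\\]]+):([0-9]+)([\\[\\]])([ACGTNacgtn]*)$",
               alt, perl = TRUE)
  g <- regmatches(alt, m)[[1]]
  if (length(g) == 0 || g[3] != g[6]) return(NULL)
  if (!xor(nzchar(g[2]), nzchar(g[7]))) return(NULL)
  list(chrom = g[4], pos = as.integer(g[5]),
       retain = if (nzchar(g[2])) "L" else "R")
}

# DEL joins (lower retains L, upper retains R); DUP the reverse; INV both
# same side. Used only when both mates agree and no explicit SVTYPE=BND.
bnd_pair_type <- function(retain_lower, retain_upper) {
  if (retain_lower == "L" && retain_upper == "R") return("DEL")
  if (retain_lower == "R" && retain_upper == "L") return("DUP")
  "INV"
}

#' Read an SV VCF into a call set
#'
#' Accepts VCF 4.x with SVs encoded either as symbolic ALT (`<DEL>`,
#' `<DUP>`, `<INS>`, `<INV>`, `<TRA>`) with END/SVLEN INFO keys, or as BND
#' mate-pair breakend lines. BND mates on different chromosomes collapse to
#' a single TRA record; intra-chromosomal mate pairs are normalized to
#' DEL/DUP/INV when the bracket orientations of both mates agree and no
#' explicit `SVTYPE=BND` annotation is present, otherwise kept as BND.
#' Records failing FILTER other than PASS/"." can be kept or dropped.
#'
#' Malformed records (bad ALT, missing END for a symbolic non-INS type) are
#' rejected individually: parsing continues and the rejection count and
#' messages are returned as attributes `n_rejected` / `reject_messages` on
#' the call set (`n_input_lines` gives the data-line count, so
#' parsed lines + rejected == input lines).
#'
#' @param path VCF file path.
#' @param platform,tool,replicate,sample provenance of this call set.
#' @param pass_only drop records whose FILTER is not PASS or "." (default
#'   TRUE; this realizes the low-quality filter).
#' @return an [sv_callset()].
#' @export
read_sv_vcf <- function(path, platform, tool, replicate = "1",
                        sample = "tumor", pass_only = TRUE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_input <- nrow(fix)
  rejects <- character(0)
  if (n_input == 0) {
    cs <- sv_callset(empty_records(), platform, tool, replicate, sample)
    attr(cs, "n_input_lines") <- 0L
    attr(cs, "n_rejected") <- 0L
    return(cs)
  }
  info_get <- function(key) {
    val <- sub(sprintf(".*(?:^|;)%s=([^;]*).*", key), "\\1", fix$INFO)
    val[!grepl(sprintf("(^|;)%s=", key), fix$INFO)] <- NA_character_
    val
  }
  svtype_info <- info_get("SVTYPE")
  end_info <- suppressWarnings(as.numeric(info_get("END")))
  svlen_info <- suppressWarnings(as.numeric(info_get("SVLEN")))
  chr2_info <- info_get("CHR2")
  truth_info <- info_get("TRUTH_ID")
  mateid_info <- info_get("MATEID")
  pos <- as.integer(fix$POS)
  filt <- ifelse(is.na(fix$FILTER), ".", fix$FILTER)

  recs <- list()
  bnd_rows <- list()
  for (k in seq_len(n_input)) {
    alt <- fix$ALT[k]
    sym <- regmatches(alt, regexec("^<([A-Z]+)>$", alt))[[1]]
    if (length(sym) == 2) {
      ty <- sym[2]
      if (!ty %in% c("DEL", "DUP", "INS", "INV", "TRA")) {
        rejects <- c(rejects, sprintf("line %d: unsupported symbolic ALT %s", k, alt))
        next
      }
      if (ty == "TRA") {
        ch2 <- chr2_info[k]
        if (is.na(ch2) || is.na(end_info[k])) {
          rejects <- c(rejects, sprintf("line %d: TRA without CHR2/END", k))
          next
        }
        recs[[length(recs) + 1]] <- data.frame(
          id = fix$ID[k], svtype = "TRA", chrom1 = fix$CHROM[k], pos1 = pos[k],
          chrom2 = ch2, pos2 = as.integer(end_info[k]), size = 0,
          filter = filt[k], truth_id = truth_info[k], stringsAsFactors = FALSE)
      } else if (ty == "INS") {
        sz <- abs(svlen_info[k])
        if (is.na(sz)) {
          rejects <- c(rejects, sprintf("line %d: INS without SVLEN", k))
          next
        }
        recs[[length(recs) + 1]] <- data.frame(
          id = fix$ID[k], svtype = "INS", chrom1 = fix$CHROM[k], pos1 = pos[k],
          chrom2 = fix$CHROM[k], pos2 = pos[k], size = sz,
          filter = filt[k], truth_id = truth_info[k], stringsAsFactors = FALSE)
      } else {
        if (is.na(end_info[k])) {
          rejects <- c(rejects, sprintf("line %d: %s without END", k, ty))
          next
        }
        recs[[length(recs) + 1]] <- data.frame(
          id = fix$ID[k], svtype = ty, chrom1 = fix$CHROM[k], pos1 = pos[k],
          chrom2 = fix$CHROM[k], pos2 = as.integer(end_info[k]),
          size = abs(as.integer(end_info[k]) - pos[k]),
          filter = filt[k], truth_id = truth_info[k], stringsAsFactors = FALSE)
      }
    } else if (grepl("[][]", alt)) {
      bp <- parse_bnd_alt(alt)
      if (is.null(bp)) {
        rejects <- c(rejects, sprintf("line %d: malformed BND ALT %s", k, alt))
        next
      }
      bnd_rows[[length(bnd_rows) + 1]] <- data.frame(
        line = k, id = fix$ID[k], chrom = fix$CHROM[k], pos = pos[k],
        mchrom = bp$chrom, mpos = bp$pos, retain = bp$retain,
        mateid = mateid_info[k], explicit_bnd = identical(svtype_info[k], "BND"),
        filter = filt[k], truth_id = truth_info[k], stringsAsFactors = FALSE)
    } else {
      rejects <- c(rejects, sprintf("line %d: unrecognized ALT %s", k, alt))
    }
  }

  # collapse BND mate pairs
  if (length(bnd_rows) > 0) {
    bdf <- do.call(rbind, bnd_rows)
    bdf$key <- apply(bdf[, c("chrom", "pos", "mchrom", "mpos")], 1, function(r) {
      a <- paste(r[1], r[2]); b <- paste(r[3], r[4])
      paste(sort(c(a, b)), collapse = "~")
    })
    for (key in unique(bdf$key)) {
      grp <- bdf[bdf$key == key, , drop = FALSE]
      a <- grp[1, ]
      if (a$chrom != a$mchrom) {
        ty <- "TRA"
      } else if (any(grp$explicit_bnd)) {
        ty <- "BND"
      } else if (nrow(grp) >= 2) {
        lower <- grp[order(grp$pos), ][1, ]
        upper <- grp[order(grp$pos), ][nrow(grp), ]
        ty <- bnd_pair_type(lower$retain, upper$retain)
        # both mates must describe the reciprocal junction consistently
        if (nrow(grp) != 2 || lower$mpos != upper$pos || upper$mpos != lower$pos)
          ty <- "BND"
      } else {
        ty <- "BND"
      }
      sz <- if (ty %in% c("DEL", "DUP", "INV")) abs(a$mpos - a$pos) else 0
      recs[[length(recs) + 1]] <- data.frame(
        id = sub("_[12]$", "", a$id), svtype = ty, chrom1 = a$chrom,
        pos1 = a$pos, chrom2 = a$mchrom, pos2 = a$mpos, size = sz,
        filter = a$filter, truth_id = a$truth_id, stringsAsFactors = FALSE)
    }
  }

  df <- if (length(recs)) do.call(rbind, recs) else empty_records()
  if (pass_only && nrow(df) > 0)
    df <- df[df$filter %in% c("PASS", "."), , drop = FALSE]
  if (nrow(df) > 0) {
    df$size[df$svtype %in% c("TRA", "BND")] <- 0
    df <- canonicalize_breakends(df)
    class(df) <- c("sv_records", "data.frame")
  }
  cs <- sv_callset(df, platform, tool, replicate, sample)
  attr(cs, "n_input_lines") <- n_input
  attr(cs, "n_rejected") <- length(rejects)
  attr(cs, "reject_messages") <- rejects
  cs
}

#' Write a call set as a symbolic-ALT VCF
#'
#' DEL/DUP/INS/INV are written with symbolic ALT and END/SVLEN/SVTYPE INFO
#' keys (SVLEN negative for DEL, positive otherwise; for INS, END equals
#' POS). TRA and BND records are written as BND mate-pair lines linked by
#' MATEID, with an explicit SVTYPE INFO annotation so the type survives a
#' round trip. Lines are sorted by (CHROM, POS).
#'
#' @param callset an [sv_callset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(callset, path) {
  df <- callset$records
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=svconsensus",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Mate chromosome\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Breakend mate id\">",
    "##INFO=<ID=TRUTH_ID,Number=1,Type=String,Description=\"Simulator truth label\">",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##ALT=<ID=INS,Description=\"Insertion\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- character(0)
  ord_chrom <- character(0); ord_pos <- integer(0)
  emit <- function(chrom, p, id, alt, filter, info) {
    lines <<- c(lines, paste(chrom, p, id, "N", alt, ".", filter, info,
                             sep = "\t"))
    ord_chrom <<- c(ord_chrom, chrom); ord_pos <<- c(ord_pos, p)
  }
  for (k in seq_len(nrow(df))) {
    r <- df[k, ]
    truth <- if (!is.na(r$truth_id)) paste0(";TRUTH_ID=", r$truth_id) else ""
    if (r$svtype %in% c("TRA", "BND")) {
      id1 <- paste0(r$id, "_1"); id2 <- paste0(r$id, "_2")
      emit(r$chrom1, r$pos1, id1,
           sprintf("N[%s:%d[", r$chrom2, r$pos2), r$filter,
           sprintf("SVTYPE=%s;MATEID=%s%s", r$svtype, id2, truth))
      emit(r$chrom2, r$pos2, id2,
           sprintf("]%s:%d]N", r$chrom1, r$pos1), r$filter,
           sprintf("SVTYPE=%s;MATEID=%s%s", r$svtype, id1, truth))
    } else if (r$svtype == "INS") {
      emit(r$chrom1, r$pos1, r$id, "<INS>", r$filter,
           sprintf("SVTYPE=INS;END=%d;SVLEN=%d%s", r$pos1, as.integer(r$size),
                   truth))
    } else {
      svlen <- if (r$svtype == "DEL") -as.integer(r$size) else as.integer(r$size)
      emit(r$chrom1, r$pos1, r$id, sprintf("<%s>", r$svtype), r$filter,
           sprintf("SVTYPE=%s;END=%d;SVLEN=%d%s", r$svtype, r$pos2, svlen,
                   truth))
    }
  }
  lines <- lines[order(ord_chrom, ord_pos)]
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a BED file into a genomic region set
#'
#' Expects 3+ whitespace-separated columns, 0-based half-open. Malformed
#' rows (fewer than 3 columns, non-numeric coordinates, start >= end) are
#' rejected with a warning; valid rows are kept. Overlapping rows are
#' permitted and not merged. The rejection count is available as attribute
#' `n_rejected`.
#'
#' @param path BED file path.
#' @param label label for the region set (e.g. "blacklist", "LOH").
#' @return a [genomic_regions()] object.
#' @export
read_bed_regions <- function(path, label = "regions") {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(ln, "#") & !startsWith(ln, "track")]
  chrom <- character(0); start <- numeric(0); end <- numeric(0)
  n_rejected <- 0L
  for (i in seq_along(ln)) {
    f <- strsplit(trimws(ln[i]), "[ \t]+")[[1]]
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (length(f) < 3 || is.na(s) || is.na(e) || s >= e) {
      warning(sprintf("rejecting malformed BED row %d: %s", i, ln[i]))
      n_rejected <- n_rejected + 1L
      next
    }
    chrom <- c(chrom, f[1]); start <- c(start, s); end <- c(end, e)
  }
  rs <- genomic_regions(chrom, start, end, label = label)
  attr(rs, "n_rejected") <- n_rejected
  rs
}
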