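# Hi-C contact-matrix rearrangement detection: binning, quadrant Poisson
# z-scores, candidate junctions, exponential-kernel breakpoint refinement
# and quadrant-coverage event classification.

#' Construct a binned Hi-C contact matrix
#'
#' @param counts symmetric square matrix of read-pair counts N_ij over the
#'   global bin layout (chromosomes concatenated, `ceiling(length/w)` bins
#'   each).
#' @param w bin width in bp (default 50,000).
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param mapq_min MAPQ threshold that was applied at binning.
#' @return object of class `contact_matrix` with elements `counts`, `w`,
#'   `chrom_sizes`, `bins` (per-bin chrom/start/end table), `mapq_min`.
#' @export
contact_matrix <- function(counts, w = 50000, chrom_sizes, mapq_min = 20) {
  bins <- bin_layout(chrom_sizes, w)
  stopifnot(nrow(counts) == nrow(bins), ncol(counts) == nrow(bins))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!isTRUE(all.equal(counts, t(counts))))
    stop("contact matrix must be symmetric")
  structure(list(counts = counts, w = w, chrom_sizes = chrom_sizes,
                 bins = bins, mapq_min = mapq_min),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d bins (w=%g bp, %d chromosomes), total mass %g\n",
              nrow(x$bins), x$w, length(x$chrom_sizes), sum(x$counts)))
  invisible(x)
}

bin_layout <- function(chrom_sizes, w) {
  stopifnot(!is.null(names(chrom_sizes)), all(chrom_sizes > 0), w > 0)
  parts <- lapply(names(chrom_sizes), function(ch) {
    nb <- ceiling(chrom_sizes[[ch]] / w)
    data.frame(chrom = ch, start = (seq_len(nb) - 1) * w + 1,
               end = pmin(seq_len(nb) * w, chrom_sizes[[ch]]),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, parts)
  bins$bin <- seq_len(nrow(bins))
  bins
}

#' Map genomic positions to global bin indices
#'
#' @param M a [contact_matrix()].
#' @param chrom,pos coordinate vectors (1-based).
#' @return integer bin indices (NA for unknown chromosomes or positions
#'   outside the chromosome).
#' @export
bin_of <- function(M, chrom, pos) {
  offs <- c(0, cumsum(ceiling(M$chrom_sizes / M$w)))
  names(offs) <- c(names(M$chrom_sizes), "_end")
  idx <- match(chrom, names(M$chrom_sizes))
  out <- ifelse(is.na(idx) | pos < 1 | pos > M$chrom_sizes[idx], NA_integer_,
                offs[idx] + (pos - 1) %/% M$w + 1)
  as.integer(out)
}

#' Bin centers in genomic coordinates
#'
#' @param M a [contact_matrix()].
#' @param bin global bin indices.
#' @return data.frame with columns `chrom`, `pos` (bin midpoints).
#' @export
bin_center <- function(M, bin) {
  b <- M$bins[bin, , drop = FALSE]
  data.frame(chrom = b$chrom, pos = as.integer((b$start + b$end) %/% 2),
             stringsAsFactors = FALSE)
}

#' Bin read pairs into a contact matrix
#'
#' A pair contributes one count to N_ij and one to N_ji iff both mates map
#' with MAPQ strictly greater than `mapq_min` (a pair whose mates land in
#' the same bin adds 2 to that diagonal cell, so the total matrix mass is
#' always twice the number of passing pairs). Pairs failing the MAPQ
#' filter, or mapping to unknown chromosomes / out-of-range positions, are
#' counted and reported via attributes `n_mapq_failed` and `n_skipped`.
#'
#' @param pairs data.frame with columns chromA, posA, mapqA, chromB, posB,
#'   mapqB.
#' @param w bin width in bp.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param mapq_min MAPQ threshold (default 20, strict inequality).
#' @return a [contact_matrix()].
#' @export
bin_pairs <- function(pairs, w = 50000, chrom_sizes, mapq_min = 20) {
  bins <- bin_layout(chrom_sizes, w)
  n <- nrow(bins)
  counts <- matrix(0, n, n)
  pass <- pairs$mapqA > mapq_min & pairs$mapqB > mapq_min
  n_mapq <- sum(!pass)
  p <- pairs[pass, , drop = FALSE]
  M0 <- list(chrom_sizes = chrom_sizes, w = w)
  bi <- bin_of(M0, p$chromA, p$posA)
  bj <- bin_of(M0, p$chromB, p$posB)
  keep <- !is.na(bi) & !is.na(bj)
  n_skip <- sum(!keep)
  if (n_skip > 0)
    warning(sprintf("%d pair(s) skipped (unknown chromosome or position)",
                    n_skip))
  bi <- bi[keep]; bj <- bj[keep]
  if (length(bi) > 0) {
    inc <- table(factor(paste(c(bi, bj), c(bj, bi)),
                        levels = unique(paste(c(bi, bj), c(bj, bi)))))
    ij <- do.call(rbind, strsplit(names(inc), " "))
    counts[cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))] <- as.numeric(inc)
  }
  M <- contact_matrix(counts, w, chrom_sizes, mapq_min)
  attr(M, "n_mapq_failed") <- n_mapq
  attr(M, "n_skipped") <- n_skip
  M
}

#' Read / write a contact matrix as a sparse triplet text file
#'
#' The file carries its own layout: header lines `#w=<bp>` and one
#' `#chrom=<name>:<length>` per chromosome, followed by whitespace-
#' separated `bin_i bin_j count` rows (1-based global bins, upper triangle
#' including the diagonal).
#'
#' @param M a [contact_matrix()] (for writing).
#' @param path file path.
#' @param mapq_min recorded MAPQ threshold (reading only).
#' @return `read_hic_triplets` returns a [contact_matrix()];
#'   `write_hic_triplets` returns `path` invisibly.
#' @export
write_hic_triplets <- function(M, path) {
  header <- c(sprintf("#w=%g", M$w),
              sprintf("#chrom=%s:%g", names(M$chrom_sizes), M$chrom_sizes))
  idx <- which(upper.tri(M$counts, diag = TRUE) & M$counts > 0, arr.ind = TRUE)
  body <- sprintf("%d %d %g", idx[, 1], idx[, 2], M$counts[idx])
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_hic_triplets
#' @export
read_hic_triplets <- function(path, mapq_min = 20) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "#")]
  body <- ln[!startsWith(ln, "#") & nzchar(trimws(ln))]
  wline <- sub("^#w=", "", hdr[startsWith(hdr, "#w=")])
  if (length(wline) != 1) stop("triplet file lacks a #w= header")
  w <- as.numeric(wline)
  chl <- sub("^#chrom=", "", hdr[startsWith(hdr, "#chrom=")])
  if (length(chl) == 0) stop("triplet file lacks #chrom= headers")
  parts <- strsplit(chl, ":")
  chrom_sizes <- setNames(as.numeric(vapply(parts, `[`, "", 2)),
                          vapply(parts, `[`, "", 1))
  n <- sum(ceiling(chrom_sizes / w))
  counts <- matrix(0, n, n)
  if (length(body) > 0) {
    tr <- do.call(rbind, lapply(strsplit(trimws(body), "[ \t]+"), as.numeric))
    if (ncol(tr) != 3 || any(is.na(tr)) || any(tr[, 1] > n) || any(tr[, 2] > n))
      stop("malformed triplet rows or bins outside the declared layout")
    counts[tr[, 1:2, drop = FALSE]] <- tr[, 3]
    low <- tr[, 1] != tr[, 2]
    counts[tr[low, 2:1, drop = FALSE]] <- tr[low, 3]
  }
  contact_matrix(counts, w, chrom_sizes, mapq_min)
}

# Truncated rectangle sum over counts[a1..a2, b1..b2] (empty if a1>a2).
rect_sum <- function(counts, a1, a2, b1, b2) {
  n <- nrow(counts)
  a1 <- max(1, a1); b1 <- max(1, b1); a2 <- min(n, a2); b2 <- min(n, b2)
  if (a1 > a2 || b1 > b2) return(0)
  sum(counts[a1:a2, b1:b2])
}

#' Quadrant sums of a contact matrix at a bin pair
#'
#' N+ is the sum over the north-east quadrant (rows i..i+R, cols j..j+R)
#' plus the south-west quadrant (rows i-R..i, cols j-R..j); N- sums the
#' north-west and south-east quadrants likewise. The two terms of each sum
#' both include the center row/column and the center cell, exactly as the
#' defining formulas state (so the center cell is counted twice within N+
#' and twice within N-). Sums truncate at matrix edges.
#'
#' @param M a [contact_matrix()] (or a plain square matrix).
#' @param i,j bin indices.
#' @param R quadrant range in bins (>= 1).
#' @return named numeric vector `c(N_plus=, N_minus=)`.
#' @export
quadrant_sums <- function(M, i, j, R) {
  if (R < 1) stop("R must be >= 1")
  counts <- if (inherits(M, "contact_matrix")) M$counts else M
  n_plus <- rect_sum(counts, i, i + R, j, j + R) +
    rect_sum(counts, i - R, i, j - R, j)
  n_minus <- rect_sum(counts, i - R, i, j, j + R) +
    rect_sum(counts, i, i + R, j - R, j)
  c(N_plus = n_plus, N_minus = n_minus)
}

#' Poisson quadrant z-scores
#'
#' Z+ = (N+ - N-) / sqrt(N-) and Z- = (N- - N+) / sqrt(N+), with each
#' denominator floored at 1 when the corresponding count is 0 so the
#' scores stay finite and monotone in the numerator.
#'
#' @param n_plus,n_minus quadrant sums (vectors allowed).
#' @return list with components `Z_plus` and `Z_minus`.
#' @export
z_scores <- function(n_plus, n_minus) {
  if (any(n_plus < 0 | n_minus < 0)) stop("counts must be >= 0")
  list(Z_plus = (n_plus - n_minus) / sqrt(pmax(n_minus, 1)),
       Z_minus = (n_minus - n_plus) / sqrt(pmax(n_plus, 1)))
}

# Zero-padded integral image: P[i+1, j+1] = sum(counts[1..i, 1..j]).
integral_image <- function(counts) {
  n <- nrow(counts)
  P <- matrix(0, n + 1, n + 1)
  P[-1, -1] <- t(apply(apply(counts, 2, cumsum), 1, cumsum))
  P
}

# All-position rectangle sums where row bounds depend only on i and column
# bounds only on j. rlo/rhi/clo/chi are length-n clamped bound vectors.
rect_all <- function(P, rlo, rhi, clo, chi) {
  P[rhi + 1, chi + 1] - P[rlo, chi + 1] - P[rhi + 1, clo] + P[rlo, clo]
}

# The four quadrant-sum matrices for every (i,j) simultaneously.
# interior=TRUE gives the strictly interior quadrants (center row/column
# excluded), used for the variance of N+ - N- (shared cross cells cancel).
# bound_lo/bound_hi clip each bin's quadrant extent (per-bin bounds, used
# to stop windows at chromosome-block boundaries); defaults are the
# matrix edges.
quadrant_sum_matrices <- function(counts, R, interior = FALSE,
                                  bound_lo = NULL, bound_hi = NULL,
                                  P = NULL) {
  n <- nrow(counts)
  if (is.null(P)) P <- integral_image(counts)
  v <- seq_len(n)
  if (is.null(bound_lo)) bound_lo <- rep(1L, n)
  if (is.null(bound_hi)) bound_hi <- rep(n, n)
  off <- if (interior) 1L else 0L
  clamp <- function(x) pmin(pmax(x, bound_lo), bound_hi)
  zero_if_empty <- function(mat, lo, hi, by_row) {
    empty <- lo > hi
    if (any(empty)) {
      if (by_row) mat[empty, ] <- 0 else mat[, empty] <- 0
    }
    mat
  }
  mk <- function(rlo, rhi, clo, chi) {
    m <- rect_all(P, clamp(rlo), clamp(rhi), clamp(clo), clamp(chi))
    m <- zero_if_empty(m, pmax(rlo, bound_lo), pmin(rhi, bound_hi), TRUE)
    zero_if_empty(m, pmax(clo, bound_lo), pmin(chi, bound_hi), FALSE)
  }
  list(NE = mk(v + off, v + R, v + off, v + R),
       SW = mk(v - R, v - off, v - R, v - off),
       NW = mk(v - R, v - off, v + off, v + R),
       SE = mk(v + off, v + R, v - R, v - off))
}

#' Expected contact counts under the null
#'
#' For intra-chromosomal cells the expectation at offset d = |i-j| is the
#' mean observed count at that offset pooled across chromosomes (the
#' standard observed/expected distance-decay estimate); inter-chromosomal
#' cells get the global mean inter-chromosomal count.
#'
#' @param M a [contact_matrix()].
#' @return dense matrix of expected counts, same layout as `M$counts`.
#' @export
expected_matrix <- function(M) {
  counts <- M$counts
  bins <- M$bins
  n <- nrow(counts)
  chroms <- unique(bins$chrom)
  maxnb <- max(table(bins$chrom))
  sums <- numeric(maxnb); cells <- numeric(maxnb)
  for (ch in chroms) {
    idx <- bins$bin[bins$chrom == ch]
    B <- counts[idx, idx, drop = FALSE]
    d <- abs(col(B) - row(B))
    s <- tapply(B, d, sum)
    k <- as.integer(names(s)) + 1
    sums[k] <- sums[k] + as.numeric(s)
    cells[k] <- cells[k] + as.numeric(table(d))
  }
  lambda <- ifelse(cells > 0, sums / cells, 0)
  E <- matrix(0, n, n)
  inter_mask_total <- n * n - sum(table(bins$chrom)^2)
  inter_sum <- sum(counts)
  for (ch in chroms) {
    idx <- bins$bin[bins$chrom == ch]
    inter_sum <- inter_sum - sum(counts[idx, idx])
  }
  lambda_inter <- if (inter_mask_total > 0) inter_sum / inter_mask_total else 0
  E[] <- lambda_inter
  for (ch in chroms) {
    idx <- bins$bin[bins$chrom == ch]
    nb <- length(idx)
    d <- abs(col(matrix(0, nb, nb)) - row(matrix(0, nb, nb)))
    E[idx, idx] <- lambda[d + 1]
  }
  E
}

#' Detect candidate rearrangement junctions
#'
#' Scores every bin pair with the quadrant statistic and emits pairs whose
#' score exceeds `Z_min` and is a local maximum (no higher score within a
#' Chebyshev range of `local_max_range` bins, i.e. 3w at default settings).
#' Quadrant windows stop at chromosome-block boundaries (a window crossing
#' into the neighboring block would sweep up that chromosome's
#' near-diagonal mass), and inter-chromosomal pairs use the raw Poisson
#' z-scores of [z_scores()].
#' Intra-chromosomal pairs sit on a steep distance-decay gradient that
#' biases the raw contrast, so they are scored with a decay-centred
#' standardized contrast: ((N+ - N-) - (E+ - E-)) / sqrt(V), where E is
#' the [expected_matrix()] decay estimate and V is the expected variance
#' contributed by the strictly interior quadrant cells (the shared center
#' cross cancels in the difference). Intra-chromosomal pairs closer than
#' `diag_exclude` bins to the diagonal are suppressed.
#'
#' @param M a [contact_matrix()].
#' @param R quadrant range in bins (default 10).
#' @param Z_min score threshold (default 1).
#' @param local_max_range local-maximum range in bins (default 3).
#' @param diag_exclude intra-chromosomal diagonal suppression range in
#'   bins (default `R`).
#' @return data.frame of class `hic_candidates`, one row per candidate
#'   (i <= j) with bin indices, genomic bin centers, quadrant sums,
#'   z-scores and `score`, sorted by descending score.
#' @export
find_candidates <- function(M, R = 10, Z_min = 1, local_max_range = 3,
                            diag_exclude = R) {
  counts <- M$counts
  n <- nrow(counts)
  chrom_of <- M$bins$chrom
  # quadrant windows stop at chromosome-block boundaries: a window that
  # crossed into the neighboring chromosome would sweep up that
  # chromosome's near-diagonal mass and swamp the contrast
  blk <- ave(seq_len(n), chrom_of, FUN = min)
  bound_lo <- as.integer(blk)
  bound_hi <- as.integer(ave(seq_len(n), chrom_of, FUN = max))
  Q <- quadrant_sum_matrices(counts, R, bound_lo = bound_lo,
                             bound_hi = bound_hi)
  Np <- Q$NE + Q$SW
  Nm <- Q$NW + Q$SE
  intra <- outer(chrom_of, chrom_of, "==")
  z <- z_scores(Np, Nm)
  Zp <- z$Z_plus; Zm <- z$Z_minus
  if (any(intra)) {
    E <- expected_matrix(M)
    PE <- integral_image(E)
    QE <- quadrant_sum_matrices(E, R, bound_lo = bound_lo,
                                bound_hi = bound_hi, P = PE)
    QV <- quadrant_sum_matrices(E, R, interior = TRUE,
                                bound_lo = bound_lo, bound_hi = bound_hi,
                                P = PE)
    D <- (Np - Nm) - ((QE$NE + QE$SW) - (QE$NW + QE$SE))
    V <- QV$NE + QV$SW + QV$NW + QV$SE
    Zt <- D / sqrt(pmax(V, 1))
    Zp[intra] <- Zt[intra]
    Zm[intra] <- -Zt[intra]
  }
  S <- pmax(Zp, Zm)
  doff <- abs(outer(seq_len(n), seq_len(n), "-"))
  S[intra & doff <= diag_exclude] <- -Inf
  # local-maximum rule over Chebyshev distance <= local_max_range:
  # check each above-threshold cell against its neighborhood (sparse
  # path), falling back to a vectorized shift-max sweep when many cells
  # pass the threshold
  lmr <- local_max_range
  above <- which(S > Z_min, arr.ind = TRUE)
  if (nrow(above) <= 5000) {
    keep <- logical(nrow(above))
    for (k in seq_len(nrow(above))) {
      r <- above[k, 1]; cc <- above[k, 2]
      nb <- S[max(1, r - lmr):min(n, r + lmr),
              max(1, cc - lmr):min(n, cc + lmr)]
      keep[k] <- S[r, cc] >= max(nb)
    }
    cand <- above[keep & above[, 1] < above[, 2], , drop = FALSE]
  } else {
    nmax <- matrix(-Inf, n, n)
    for (dx in -lmr:lmr) {
      for (dy in -lmr:lmr) {
        if (dx == 0 && dy == 0) next
        src_r <- seq_len(n) + dx; src_c <- seq_len(n) + dy
        ok_r <- src_r >= 1 & src_r <= n; ok_c <- src_c >= 1 & src_c <= n
        sh <- matrix(-Inf, n, n)
        sh[ok_r, ok_c] <- S[src_r[ok_r], src_c[ok_c]]
        nmax <- pmax(nmax, sh)
      }
    }
    cand <- which(S > Z_min & S >= nmax & upper.tri(S, diag = FALSE),
                  arr.ind = TRUE)
  }
  if (nrow(cand) == 0) {
    out <- data.frame(i = integer(), j = integer(), chrom1 = character(),
                      pos1 = integer(), chrom2 = character(),
                      pos2 = integer(), N_plus = numeric(),
                      N_minus = numeric(), Z_plus = numeric(),
                      Z_minus = numeric(), score = numeric())
    class(out) <- c("hic_candidates", "data.frame")
    return(out)
  }
  bc1 <- bin_center(M, cand[, 1]); bc2 <- bin_center(M, cand[, 2])
  out <- data.frame(i = cand[, 1], j = cand[, 2],
                    chrom1 = bc1$chrom, pos1 = bc1$pos,
                    chrom2 = bc2$chrom, pos2 = bc2$pos,
                    N_plus = Np[cand], N_minus = Nm[cand],
                    Z_plus = Zp[cand], Z_minus = Zm[cand],
                    score = S[cand], stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hic_candidates", "data.frame")
  out
}

#' Filter candidate junctions by score and quadrant mass
#'
#' Deterministic replacement for a learned post-classifier: a candidate is
#' kept iff its score is at least `min_score` and the larger of its two
#' quadrant sums reaches `min_quadrant_mass` supporting read pairs. Order
#' is preserved.
#'
#' @param cands a `hic_candidates` data frame.
#' @param min_score minimum score (default 0, no-op).
#' @param min_quadrant_mass minimum max(N+, N-) (default 0, no-op).
#' @return filtered `hic_candidates`.
#' @export
filter_candidates <- function(cands, min_score = 0, min_quadrant_mass = 0) {
  keep <- cands$score >= min_score &
    pmax(cands$N_plus, cands$N_minus) >= min_quadrant_mass
  out <- cands[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exponential quadrant kernel of half-width khw bins: value
# exp(-(|dx|+|dy|) * w / decay_bp) on the selected quadrant pair, 0
# elsewhere. sign "plus" = NE/SW, "minus" = NW/SE.
quadrant_kernel <- function(khw, w, decay_bp, sign = c("plus", "minus")) {
  sign <- match.arg(sign)
  dx <- outer(-khw:khw, rep(1, 2 * khw + 1))
  dy <- t(dx)
  K <- exp(-(abs(dx) + abs(dy)) * w / decay_bp)
  on <- if (sign == "plus") (dx >= 0 & dy >= 0) | (dx <= 0 & dy <= 0)
        else (dx <= 0 & dy >= 0) | (dx >= 0 & dy <= 0)
  K * on
}

# Truncated cross-correlation of kernel K with matrix A at every position.
cross_correlate <- function(A, K) {
  na <- nrow(A); ma <- ncol(A)
  khw <- (nrow(K) - 1) %/% 2
  out <- matrix(0, na, ma)
  for (a in seq_len(na)) {
    r1 <- max(1, a - khw); r2 <- min(na, a + khw)
    kr <- (r1 - a + khw + 1):(r2 - a + khw + 1)
    for (b in seq_len(ma)) {
      c1 <- max(1, b - khw); c2 <- min(ma, b + khw)
      kc <- (c1 - b + khw + 1):(c2 - b + khw + 1)
      out[a, b] <- sum(A[r1:r2, c1:c2] * K[kr, kc, drop = FALSE])
    }
  }
  out
}

first_argmax <- function(m) {
  idx <- which(m == max(m), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  idx[1, ]
}

#' Refine a candidate breakpoint with exponential quadrant kernels
#'
#' Extracts the contact submatrix extending `half_window_bp` on each side
#' of the candidate (truncated at chromosome ends), cross-correlates it
#' with two exponential-decay kernels -- one supported on the NE/SW
#' quadrants, one on the NW/SE quadrants -- and takes the global maximum
#' of the two correlation surfaces as the refined breakpoint at
#' bin-center resolution. Ties break toward the NE/SW kernel and then the
#' smallest coordinates. An all-zero submatrix falls back to the candidate
#' bin centers with `fallback = TRUE`.
#'
#' @param M a [contact_matrix()].
#' @param i,j candidate bin pair.
#' @param half_window_bp refinement half-window (default 2 Mb).
#' @param decay_bp kernel decay constant in bp (default 5 bins).
#' @return list with `chrom1`, `bp1`, `chrom2`, `bp2`, `bin1`, `bin2`,
#'   `kernel` ("plus"/"minus"), `fallback`.
#' @export
refine_breakpoint <- function(M, i, j, half_window_bp = 2e6,
                              decay_bp = 5 * M$w) {
  bins <- M$bins
  hw <- max(1L, as.integer(round(half_window_bp / M$w)))
  chrom_i <- bins$chrom[i]; chrom_j <- bins$chrom[j]
  ri <- bins$bin[bins$chrom == chrom_i]
  rj <- bins$bin[bins$chrom == chrom_j]
  rows <- intersect(ri, (i - hw):(i + hw))
  cols <- intersect(rj, (j - hw):(j + hw))
  A <- M$counts[rows, cols, drop = FALSE]
  ctr <- bin_center(M, c(i, j))
  if (sum(A) == 0)
    return(list(chrom1 = chrom_i, bp1 = ctr$pos[1], chrom2 = chrom_j,
                bp2 = ctr$pos[2], bin1 = i, bin2 = j, kernel = NA_character_,
                fallback = TRUE))
  khw <- min(hw, as.integer(ceiling(4 * decay_bp / M$w)))
  Kp <- quadrant_kernel(khw, M$w, decay_bp, "plus")
  Km <- quadrant_kernel(khw, M$w, decay_bp, "minus")
  Cp <- cross_correlate(A, Kp)
  Cm <- cross_correlate(A, Km)
  if (max(Cp) >= max(Cm)) {
    am <- first_argmax(Cp); kern <- "plus"
  } else {
    am <- first_argmax(Cm); kern <- "minus"
  }
  b1 <- rows[am[1]]; b2 <- cols[am[2]]
  bc <- bin_center(M, c(b1, b2))
  list(chrom1 = chrom_i, bp1 = bc$pos[1], chrom2 = chrom_j, bp2 = bc$pos[2],
       bin1 = b1, bin2 = b2, kernel = kern, fallback = FALSE)
}

#' Classify a rearrangement junction from quadrant coverage
#'
#' Sums the read pairs in the four R-bin quadrants around the refined
#' breakpoint pair and compares each against its expected sum under the
#' null contact model (the [expected_matrix()] distance-decay estimate,
#' which also absorbs the decay gradient across intra-chromosomal
#' quadrants). A quadrant is "elevated" if its observed sum exceeds
#' `theta` times its expected sum AND holds at least `min_pairs` read
#' pairs (the absolute evidence floor keeps a single stray pair in an
#' otherwise empty quadrant from counting).
#' Classification: inter-chromosomal with exactly
#' one elevated quadrant = non-reciprocal translocation; two diagonally
#' opposite quadrants = reciprocal translocation; intra-chromosomal with
#' one elevated quadrant = deletion; two diagonally opposite ("butterfly")
#' quadrants = inversion; all four elevated = segmental duplication; any
#' other pattern (including none) = unclassified.
#'
#' @param M a [contact_matrix()].
#' @param chrom1,bp1,chrom2,bp2 refined breakpoint coordinates.
#' @param R quadrant range in bins (default 10).
#' @param theta elevation factor over the expected sum (default 3).
#' @param min_pairs minimum read pairs in a quadrant for it to count as
#'   elevated (default 5).
#' @param E optional precomputed [expected_matrix()] (computed from `M`
#'   when NULL; pass it when classifying many candidates).
#' @return list with `event_class`, `quadrant_coverage` (named observed
#'   mean counts for NE/NW/SW/SE), `expected_coverage` (expected means),
#'   `background` (the global expected mean over the four quadrants).
#' @export
classify_event <- function(M, chrom1, bp1, chrom2, bp2, R = 10, theta = 3,
                           min_pairs = 5, E = NULL) {
  i <- bin_of(M, chrom1, bp1); j <- bin_of(M, chrom2, bp2)
  if (is.na(i) || is.na(j)) stop("breakpoint outside the matrix layout")
  counts <- M$counts
  if (is.null(E)) E <- expected_matrix(M)
  n <- nrow(counts)
  qstat <- function(A, a1, a2, b1, b2) {
    a1 <- max(1, a1); b1 <- max(1, b1); a2 <- min(n, a2); b2 <- min(n, b2)
    if (a1 > a2 || b1 > b2) return(c(NA_real_, NA_real_))
    block <- A[a1:a2, b1:b2]
    c(mean(block), sum(block))
  }
  quad <- function(A) cbind(NE = qstat(A, i + 1, i + R, j + 1, j + R),
                            NW = qstat(A, i - R, i - 1, j + 1, j + R),
                            SW = qstat(A, i - R, i - 1, j - R, j - 1),
                            SE = qstat(A, i + 1, i + R, j - R, j - 1))
  qo <- quad(counts)
  qe <- quad(E)
  cov <- qo[1, ]
  elevated <- !is.na(cov) & qo[2, ] > theta * qe[2, ] & qo[2, ] >= min_pairs
  ne <- elevated["NE"]; nw <- elevated["NW"]
  sw <- elevated["SW"]; se <- elevated["SE"]
  k <- sum(elevated)
  inter <- chrom1 != chrom2
  cls <- if (k == 4) {
    "segmental_duplication"
  } else if (inter && k == 1) {
    "nonreciprocal_translocation"
  } else if (inter && k == 2 && ((ne && sw) || (nw && se))) {
    "reciprocal_translocation"
  } else if (!inter && k == 1) {
    "deletion"
  } else if (!inter && k == 2 && ((ne && sw) || (nw && se))) {
    "inversion"
  } else {
    "unclassified"
  }
  list(event_class = cls, quadrant_coverage = cov,
       expected_coverage = qe[1, ], background = mean(qe[1, ], na.rm = TRUE))
}

#' Run the full Hi-C junction detection pipeline
#'
#' bin-level detection ([find_candidates()]), deterministic filtering
#' ([filter_candidates()]), breakpoint refinement
#' ([refine_breakpoint()]) and event classification ([classify_event()]).
#'
#' @param M a [contact_matrix()].
#' @param R,Z_min,local_max_range,diag_exclude see [find_candidates()].
#' @param min_score,min_quadrant_mass see [filter_candidates()].
#' @param half_window_bp,decay_bp see [refine_breakpoint()].
#' @param theta,min_pairs see [classify_event()].
#' @return `hic_candidates` data frame with added columns `refined_bp1`,
#'   `refined_bp2`, `event_class`.
#' @export
hic_detect <- function(M, R = 10, Z_min = 1, local_max_range = 3,
                       diag_exclude = R, min_score = 0,
                       min_quadrant_mass = 0, half_window_bp = 2e6,
                       decay_bp = 5 * M$w, theta = 3, min_pairs = 5) {
  cands <- find_candidates(M, R = R, Z_min = Z_min,
                           local_max_range = local_max_range,
                           diag_exclude = diag_exclude)
  cands <- filter_candidates(cands, min_score, min_quadrant_mass)
  if (nrow(cands) == 0) {
    cands$refined_bp1 <- integer(0)
    cands$refined_bp2 <- integer(0)
    cands$event_class <- character(0)
    return(cands)
  }
  ref1 <- integer(nrow(cands)); ref2 <- integer(nrow(cands))
  cls <- character(nrow(cands))
  E <- expected_matrix(M)
  for (k in seq_len(nrow(cands))) {
    rf <- refine_breakpoint(M, cands$i[k], cands$j[k],
                            half_window_bp = half_window_bp,
                            decay_bp = decay_bp)
    ref1[k] <- rf$bp1; ref2[k] <- rf$bp2
    cls[k] <- classify_event(M, rf$chrom1, rf$bp1, rf$chrom2, rf$bp2,
                             R = R, theta = theta, min_pairs = min_pairs,
                             E = E)$event_class
  }
  cands$refined_bp1 <- ref1
  cands$refined_bp2 <- ref2
  cands$event_class <- cls
  cands
}

#' Write candidate junctions as BEDPE
#'
#' @param cands a `hic_candidates` data frame (refined columns optional).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(cands, path) {
  p1 <- if ("refined_bp1" %in% names(cands)) cands$refined_bp1 else cands$pos1
  p2 <- if ("refined_bp2" %in% names(cands)) cands$refined_bp2 else cands$pos2
  df <- data.frame(chrom1 = cands$chrom1, start1 = pmax(0, p1 - 1), end1 = p1,
                   chrom2 = cands$chrom2, start2 = pmax(0, p2 - 1), end2 = p2,
                   name = if ("event_class" %in% names(cands))
                     cands$event_class else ".",
                   score = round(cands$score, 3))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
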