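toy_matrix <- function(counts, w = 50000,
                       chrom_sizes = c(chrA = nrow(counts) * 50000)) {
  contact_matrix(counts, w = w, chrom_sizes = chrom_sizes)
}

test_that("quadrant sums follow the printed formulas including the center double-count", {
  one <- matrix(1, 30, 30)
  qs <- quadrant_sums(one, 15, 15, 1)
  # each term covers (R+1)^2 = 4 cells; center counted in both terms
  expect_equal(unname(qs), c(8, 8))
  expect_equal(unname(quadrant_sums(matrix(0, 10, 10), 5, 5, 2)), c(0, 0))
  expect_error(quadrant_sums(one, 5, 5, 0), "R must be")
})

test_that("quadrant sums agree with a naive double loop on random matrices", {
  set.seed(42)
  for (rep_k in 1:10) {
    A <- matrix(rpois(900, 3), 30, 30)
    A <- A + t(A)
    for (pt in list(c(1, 1), c(30, 30), c(1, 30), c(15, 8), c(7, 22))) {
      expect_equal(quadrant_sums(A, pt[1], pt[2], 4),
                   naive_quadrant_sums(A, pt[1], pt[2], 4))
    }
    # symmetry of the quadrant definition on symmetric matrices
    expect_equal(quadrant_sums(A, 10, 20, 5)[["N_plus"]],
                 quadrant_sums(A, 20, 10, 5)[["N_plus"]])
  }
})

test_that("z-scores reproduce the printed formulas with floored denominators", {
  z <- z_scores(16, 9)
  expect_equal(z$Z_plus, 7 / 3)
  expect_equal(z$Z_minus, -7 / 4)
  expect_equal(z_scores(5, 5), list(Z_plus = 0, Z_minus = 0))
  expect_equal(z_scores(5, 0)$Z_plus, 5)   # denominator floored at 1
  # opposite signs unless equal
  set.seed(3)
  for (k in 1:20) {
    np <- rpois(1, 20); nm <- rpois(1, 20)
    z <- z_scores(np, nm)
    if (np != nm) expect_lt(z$Z_plus * z$Z_minus, 0)
  }
})

test_that("read-pair binning applies the strict MAPQ filter and conserves mass", {
  pairs <- data.frame(
    chromA = c("chr1", "chr1", "chr1", "chrZ"),
    posA = c(10, 10, 60010, 100), mapqA = c(30, 15, 30, 30),
    chromB = c("chr1", "chr1", "chr1", "chr1"),
    posB = c(60010, 60010, 60020, 200), mapqB = c(30, 30, 30, 30))
  expect_warning(M <- bin_pairs(pairs, w = 50000,
                                chrom_sizes = c(chr1 = 2e5)), "skipped")
  # pair 1 links bins 1-2; pair 2 fails MAPQ (not > 20 on both);
  # pair 3 is within bin 2 (adds 2 to the diagonal); pair 4 unknown chrom
  expect_equal(M$counts[1, 2], 1)
  expect_equal(M$counts[2, 1], 1)
  expect_equal(M$counts[2, 2], 2)
  expect_equal(sum(M$counts), 2 * 2)   # twice the passing pairs
  expect_equal(attr(M, "n_mapq_failed"), 1L)
  expect_equal(attr(M, "n_skipped"), 1L)
})

test_that("triplet files round-trip the matrix exactly", {
  set.seed(9)
  A <- matrix(rpois(16 * 16, 1), 16, 16); A <- A + t(A)
  M <- contact_matrix(A, w = 1e5, chrom_sizes = c(c1 = 8e5, c2 = 8e5))
  f <- withr::local_tempfile(fileext = ".txt")
  write_hic_triplets(M, f)
  back <- read_hic_triplets(f)
  expect_equal(back$counts, M$counts)
  expect_equal(back$w, M$w)
  expect_equal(back$chrom_sizes, M$chrom_sizes)
  # malformed triplet: bin outside declared layout
  writeLines(c("#w=100000", "#chrom=c1:800000", "99 1 5"), f)
  expect_error(read_hic_triplets(f), "layout")
})

test_that("a zero matrix yields no candidates", {
  M <- toy_matrix(matrix(0, 40, 40))
  expect_equal(nrow(find_candidates(M, Z_min = 1)), 0)
})

test_that("an implanted inter-chromosomal junction is found at the right bin pair", {
  # +5 blocks on the NE and SW quadrants of (i0, j0) over a homogeneous
  # Poisson(1) background: signal mean 5x background, live denominators
  set.seed(77)
  n <- 80
  counts <- matrix(0, n, n)
  counts[upper.tri(counts, diag = TRUE)] <-
    rpois(sum(upper.tri(counts, diag = TRUE)), 1)
  counts <- counts + t(counts) - diag(diag(counts))
  sizes <- c(cA = 40 * 5e4, cB = 40 * 5e4)
  i0 <- 20; j0 <- 60   # cA bin 20, cB bin 20
  for (a in 0:10) for (b in 0:10) {
    counts[i0 + a, j0 + b] <- counts[i0 + a, j0 + b] + 5
    counts[j0 + b, i0 + a] <- counts[i0 + a, j0 + b]
    counts[i0 - a, j0 - b] <- counts[i0 - a, j0 - b] + 5
    counts[j0 - b, i0 - a] <- counts[i0 - a, j0 - b]
  }
  M <- contact_matrix(counts, w = 5e4, chrom_sizes = sizes)
  cands <- find_candidates(M, Z_min = 1)
  expect_gt(nrow(cands), 0)
  expect_lte(max(abs(c(cands$i[1], cands$j[1]) - c(i0, j0))), 1)
  expect_equal(cands$chrom1[1], "cA")
  expect_equal(cands$chrom2[1], "cB")
})

test_that("candidate filtering is a subset operation preserving order", {
  n <- 50
  counts <- matrix(0, n, n)
  counts[5:9, 30:34] <- 12; counts[30:34, 5:9] <- 12
  counts[15:16, 40:41] <- 3; counts[40:41, 15:16] <- 3
  M <- contact_matrix(counts, w = 5e4,
                      chrom_sizes = c(cA = 25 * 5e4, cB = 25 * 5e4))
  cands <- find_candidates(M, Z_min = 1)
  kept <- filter_candidates(cands, min_quadrant_mass = 10)
  expect_true(all(kept$i %in% cands$i))
  expect_true(all(pmax(kept$N_plus, kept$N_minus) >= 10))
  expect_equal(filter_candidates(cands, 0, 0), cands)
})

test_that("refinement recovers a noiseless step corner exactly", {
  n <- 80
  sizes <- c(cA = 40 * 5e4, cB = 40 * 5e4)
  counts <- matrix(0, n, n)
  x0 <- 20; y0 <- 55  # reciprocal junction: NE + SW quadrant mass at (x0,y0)
  for (a in 0:12) for (b in 0:12) {
    counts[x0 + a, y0 + b] <- 10
    counts[y0 + b, x0 + a] <- 10
    counts[x0 - a, y0 - b] <- 10
    counts[y0 - b, x0 - a] <- 10
  }
  M <- contact_matrix(counts, w = 5e4, chrom_sizes = sizes)
  # start refinement from a deliberately offset candidate
  rf <- refine_breakpoint(M, x0 + 3, y0 - 2)
  expect_equal(c(rf$bin1, rf$bin2), c(x0, y0))
  expect_false(rf$fallback)
  # empty submatrix falls back to the candidate bin centers, flagged
  M0 <- toy_matrix(matrix(0, 40, 40))
  rf0 <- refine_breakpoint(M0, 10, 30)
  expect_true(rf0$fallback)
  expect_equal(c(rf0$bin1, rf0$bin2), c(10, 30))
})

test_that("refinement ties break toward the NE/SW kernel", {
  # uniform matrix: both kernel surfaces tie everywhere
  M <- toy_matrix(matrix(1, 30, 30), chrom_sizes = c(cA = 15 * 5e4,
                                                     cB = 15 * 5e4))
  rf <- refine_breakpoint(M, 8, 22)
  expect_equal(rf$kernel, "plus")
})

test_that("the five canonical quadrant patterns classify correctly", {
  n <- 100
  sizes_inter <- c(cA = 50 * 5e4, cB = 50 * 5e4)
  base <- function() matrix(0, n, n)
  put <- function(counts, i0, j0, quads, val = 10, R = 8) {
    for (q in quads) {
      sr <- if (q %in% c("NE", "SE")) 1 else -1
      sc <- if (q %in% c("NE", "NW")) 1 else -1
      for (a in 1:R) for (b in 1:R) {
        r <- i0 + sr * a; cc <- j0 + sc * b
        counts[r, cc] <- val; counts[cc, r] <- val
      }
    }
    counts
  }
  cls <- function(counts, i0, j0, sizes) {
    M <- contact_matrix(counts, w = 5e4, chrom_sizes = sizes)
    bc <- bin_center(M, c(i0, j0))
    classify_event(M, bc$chrom[1], bc$pos[1], bc$chrom[2],
                   bc$pos[2])$event_class
  }
  i0 <- 20; j0 <- 80
  expect_equal(cls(put(base(), i0, j0, c("NE", "SW")), i0, j0, sizes_inter),
               "reciprocal_translocation")
  expect_equal(cls(put(base(), i0, j0, "NE"), i0, j0, sizes_inter),
               "nonreciprocal_translocation")
  expect_equal(cls(put(base(), i0, j0, c("NE", "NW", "SW", "SE")), i0, j0,
                   sizes_inter), "segmental_duplication")
  # intra fixtures use a longer chromosome so the implant does not
  # dominate the self-estimated distance-decay expectation
  n2 <- 300
  base2 <- function() matrix(0, n2, n2)
  sizes_intra <- c(cA = n2 * 5e4)
  expect_equal(cls(put(base2(), i0, j0, "NW"), i0, j0, sizes_intra),
               "deletion")
  expect_equal(cls(put(base2(), i0, j0, c("NE", "SW")), i0, j0, sizes_intra),
               "inversion")
  # nothing elevated -> unclassified, reported distinctly
  expect_equal(cls(base() + 1, i0, j0, c(cA = 100 * 5e4)), "unclassified")
})

test_that("detection is translation-equivariant on a noiseless implant", {
  n <- 90
  sizes <- c(cA = 45 * 5e4, cB = 45 * 5e4)
  top_at <- function(shift) {
    counts <- matrix(0, n, n)
    i0 <- 12 + shift; j0 <- 60 + shift
    for (a in 0:8) for (b in 0:8) {
      counts[i0 + a, j0 + b] <- 15
      counts[j0 + b, i0 + a] <- 15
    }
    M <- contact_matrix(counts, w = 5e4, chrom_sizes = sizes)
    cands <- find_candidates(M, Z_min = 1)
    c(cands$i[1], cands$j[1])
  }
  expect_equal(top_at(4) - top_at(0), c(4, 4))
})
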