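# Independent oracles used by the property tests. These restate the
# linking rules directly and compute components by boolean transitive
# closure, independent of the package's sweep + graph implementation.

# pairwise linkage predicate, restated from first principles; for a pair
# spanning two per-record windows the larger one applies
oracle_linkable <- function(a, b, wa, wb, mode = "merge") {
  window <- max(wa, wb)
  if (a$svtype != b$svtype) return(FALSE)
  if (a$chrom1 != b$chrom1 || a$chrom2 != b$chrom2) return(FALSE)
  tra <- a$svtype %in% c("TRA", "BND")
  sim <- if (max(a$size, b$size) == 0) 1 else
    min(a$size, b$size) / max(a$size, b$size)
  if (abs(a$pos1 - b$pos1) > window) return(FALSE)
  if (a$svtype != "INS" && abs(a$pos2 - b$pos2) > window) return(FALSE)
  if (mode == "merge") {
    if (a$svtype == "INS" && sim < 0.5) return(FALSE)
  } else {
    if (!tra && sim <= 0.5) return(FALSE)
  }
  TRUE
}

# components as the transitive closure of the pairwise predicate
oracle_components <- function(df, window, mode = "merge") {
  n <- nrow(df)
  if (n == 0) return(integer(0))
  w <- rep_len(window, n)
  A <- diag(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && oracle_linkable(df[i, ], df[j, ], w[i], w[j], mode))
        A[i, j] <- A[j, i] <- TRUE
    }
  }
  repeat {
    A2 <- A | ((A %*% A) > 0)
    if (identical(A2, A)) break
    A <- A2
  }
  membership <- integer(n)
  comp <- 0
  for (i in seq_len(n)) {
    if (membership[i] == 0) {
      comp <- comp + 1
      membership[A[i, ]] <- comp
    }
  }
  membership
}

# two component labelings describe the same partition?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    identical(as.integer(factor(a, levels = unique(a))),
              as.integer(factor(b, levels = unique(b))))
}

# random SV instance with clumped positions so that clusters actually form
random_sv_instance <- function(n, seed) {
  set.seed(seed)
  types <- sample(c("DEL", "DUP", "INS", "INV", "TRA"), n, replace = TRUE)
  anchor <- sample(c(1e4, 2e4, 5e4, 1e5), n, replace = TRUE)
  pos1 <- pmax(1, anchor + sample(-300:300, n, replace = TRUE))
  size <- ifelse(types == "TRA", 0,
                 pmax(50, round(exp(runif(n, log(60), log(5000))))))
  chrom1 <- sample(c("chr1", "chr2"), n, replace = TRUE)
  chrom2 <- ifelse(types == "TRA", "chr3", chrom1)
  pos2 <- ifelse(types == "TRA", pmax(1, anchor * 2 + sample(-300:300, n, TRUE)),
                 ifelse(types == "INS", pos1, pos1 + size))
  sv_records(id = sprintf("sv%d", seq_len(n)), svtype = types,
             chrom1 = chrom1, pos1 = pos1, chrom2 = chrom2, pos2 = pos2,
             size = size)
}

# naive double-loop quadrant sums (edge-truncated), used against the
# integral-image implementation
naive_quadrant_sums <- function(M, i, j, R) {
  n <- nrow(M)
  s <- function(r1, r2, c1, c2) {
    tot <- 0
    for (k in r1:r2) for (l in c1:c2)
      if (k >= 1 && k <= n && l >= 1 && l <= n) tot <- tot + M[k, l]
    tot
  }
  c(N_plus = s(i, i + R, j, j + R) + s(i - R, i, j - R, j),
    N_minus = s(i - R, i, j, j + R) + s(i, i + R, j - R, j))
}

combine_two <- function(m1, m2) {
  svconsensus:::combine_merged(list(m1, m2))
}

toy_callset <- function(records, platform = "Illumina", tool = "Manta",
                        replicate = "1", sample = "tumor") {
  sv_callset(records, platform, tool, replicate, sample)
}
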