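# Synthetic-data generators: toy genome, truth SV sets, emulated
# multi-platform caller outputs, Hi-C contact matrices with implanted
# rearrangements, and purity/depth titration series.

# run expr under a private RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed %% 2147483647)
  expr
}

sub_seed <- function(seed, k) (as.numeric(seed) * 7919 + k) %% 2147483647

#' A toy genome model with a mappability blacklist
#'
#' @param chromosomes named numeric vector of chromosome lengths (default
#'   three 20 Mb chromosomes).
#' @param blacklist_fraction fraction of each chromosome covered by
#'   blacklist intervals.
#' @param n_intervals blacklist intervals per chromosome.
#' @param seed RNG seed for interval placement.
#' @return list of class `genome_model` with `chromosomes` and `blacklist`
#'   (a [genomic_regions()]).
#' @export
genome_model <- function(chromosomes = c(chr1 = 2e7, chr2 = 2e7, chr3 = 2e7),
                         blacklist_fraction = 0.02, n_intervals = 4,
                         seed = 1) {
  stopifnot(all(chromosomes > 0), blacklist_fraction >= 0,
            blacklist_fraction < 0.5)
  bl <- with_seed(seed, {
    rows <- list()
    for (ch in names(chromosomes)) {
      len <- chromosomes[[ch]]
      if (blacklist_fraction == 0 || n_intervals == 0) next
      ilen <- floor(len * blacklist_fraction / n_intervals)
      starts <- sort(sample.int(len - ilen, n_intervals))
      # push overlapping intervals apart
      for (k in seq_along(starts)[-1]) {
        if (starts[k] < starts[k - 1] + ilen)
          starts[k] <- min(starts[k - 1] + ilen, len - ilen)
      }
      rows[[ch]] <- data.frame(chrom = ch, start = starts,
                               end = starts + ilen)
    }
    if (length(rows) == 0) genomic_regions(label = "blacklist")
    else {
      df <- do.call(rbind, rows)
      genomic_regions(df$chrom, df$start, df$end, label = "blacklist")
    }
  })
  structure(list(chromosomes = chromosomes, blacklist = bl),
            class = "genome_model")
}

default_size_ranges <- function() {
  list(DEL = c(50, 1e5), DUP = c(500, 1e5), INS = c(50, 1e4),
       INV = c(100, 1e5))
}

# one log-uniform size draw per requested SV
draw_sizes <- function(n, range) {
  round(exp(runif(n, log(range[1]), log(range[2]))))
}

#' Simulate a diploid truth SV set
#'
#' Places non-overlapping somatic and germline SVs outside the blacklist,
#' with log-uniform sizes per type. The default counts follow the
#' composition of a breast-cancer consensus call set (deletions most
#' common, then insertions, duplications, translocations, inversions) at
#' roughly one tenth scale. Deterministic given the seed.
#'
#' @param genome a [genome_model()].
#' @param somatic_counts,germline_counts named integer vectors per svtype
#'   (DEL/DUP/INS/INV/TRA).
#' @param size_ranges named list of c(lo, hi) bp per sized type.
#' @param seed RNG seed.
#' @param margin_bp free space demanded around each breakend.
#' @param max_tries placement retries per SV before giving up.
#' @return list of class `truth_set` with `somatic` and `germline`
#'   `sv_records`, plus `genome` and `seed`.
#' @export
simulate_truth <- function(genome,
                           somatic_counts = c(DEL = 70, DUP = 25, INS = 55,
                                              INV = 15, TRA = 15),
                           germline_counts = c(DEL = 40, DUP = 12, INS = 30,
                                               INV = 8, TRA = 4),
                           size_ranges = default_size_ranges(), seed = 1,
                           margin_bp = 2000, max_tries = 1000) {
  stopifnot(all(somatic_counts >= 0), all(germline_counts >= 0))
  for (ty in names(size_ranges)) {
    rg <- size_ranges[[ty]]
    stopifnot(rg[1] >= 50, rg[2] <= 5e6, rg[1] <= rg[2])
  }
  chroms <- names(genome$chromosomes)
  occupied <- lapply(genome$chromosomes, function(...)
    data.frame(start = numeric(0), end = numeric(0)))
  bl <- split(genome$blacklist$regions, genome$blacklist$regions$chrom)

  free_interval <- function(ch, lo, hi) {
    occ <- occupied[[ch]]
    if (nrow(occ) > 0 && any(lo <= occ$end & hi >= occ$start)) return(FALSE)
    b <- bl[[ch]]
    if (!is.null(b) && any(lo <= b$end & hi >= b$start)) return(FALSE)
    TRUE
  }
  claim <- function(ch, lo, hi) {
    occupied[[ch]] <<- rbind(occupied[[ch]], data.frame(start = lo, end = hi))
  }

  place_set <- function(counts, prefix) {
    rows <- list()
    for (ty in names(counts)) {
      n <- counts[[ty]]
      if (n == 0) next
      sizes <- if (ty == "TRA") rep(0, n) else draw_sizes(n, size_ranges[[ty]])
      for (k in seq_len(n)) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          if (ty == "TRA") {
            cpair <- sample(chroms, 2)
            p1 <- sample.int(genome$chromosomes[[cpair[1]]] - 2 * margin_bp,
                             1) + margin_bp
            p2 <- sample.int(genome$chromosomes[[cpair[2]]] - 2 * margin_bp,
                             1) + margin_bp
            if (free_interval(cpair[1], p1 - margin_bp, p1 + margin_bp) &&
                free_interval(cpair[2], p2 - margin_bp, p2 + margin_bp)) {
              claim(cpair[1], p1 - margin_bp, p1 + margin_bp)
              claim(cpair[2], p2 - margin_bp, p2 + margin_bp)
              rows[[length(rows) + 1]] <- data.frame(
                id = sprintf("%s_TRA_%d", prefix, k), svtype = "TRA",
                chrom1 = cpair[1], pos1 = p1, chrom2 = cpair[2], pos2 = p2,
                size = 0, stringsAsFactors = FALSE)
              placed <- TRUE
            }
          } else {
            sz <- sizes[k]
            ch <- sample(chroms, 1)
            span <- if (ty == "INS") 0 else sz
            maxstart <- genome$chromosomes[[ch]] - span - 2 * margin_bp
            if (maxstart < 1) next
            p1 <- sample.int(maxstart, 1) + margin_bp
            lo <- p1 - margin_bp; hi <- p1 + span + margin_bp
            if (free_interval(ch, lo, hi)) {
              claim(ch, lo, hi)
              rows[[length(rows) + 1]] <- data.frame(
                id = sprintf("%s_%s_%d", prefix, ty, k), svtype = ty,
                chrom1 = ch, pos1 = p1, chrom2 = ch,
                pos2 = if (ty == "INS") p1 else p1 + sz, size = sz,
                stringsAsFactors = FALSE)
              placed <- TRUE
            }
          }
          if (placed) break
        }
        if (!placed)
          stop(sprintf("could not place %s #%d after %d tries: genome too full",
                       ty, k, max_tries))
      }
    }
    if (length(rows) == 0) return(empty_records())
    df <- do.call(rbind, rows)
    sv_records(df$id, df$svtype, df$chrom1, df$pos1, df$chrom2, df$pos2,
               df$size, truth_id = df$id)
  }

  with_seed(seed, {
    somatic <- place_set(somatic_counts, "som")
    germline <- place_set(germline_counts, "germ")
    structure(list(somatic = somatic, germline = germline, genome = genome,
                   seed = seed), class = "truth_set")
  })
}

#' Per-platform caller emulation profile
#'
#' `sensitivity` maps (svtype, size) to a detection probability;
#' breakpoints are jittered with Gaussian noise, sizes multiplicatively;
#' false positives arrive at `fp_rate` per Mb of genome.
#'
#' @param platform platform name.
#' @param tools named integer vector: tool name -> replicate count.
#' @param sensitivity function(svtype, size) -> probability in \[0,1\].
#' @param jitter_sd breakpoint jitter SD in bp.
#' @param size_jitter_frac multiplicative size jitter SD.
#' @param fp_rate false positives per Mb per call set.
#' @param fp_types svtypes used for false positives.
#' @return list of class `platform_profile`.
#' @export
platform_profile <- function(platform, tools, sensitivity, jitter_sd = 10,
                             size_jitter_frac = 0.05, fp_rate = 0.3,
                             fp_types = c("DEL", "DUP", "INS", "INV")) {
  stopifnot(platform %in% PLATFORMS, jitter_sd >= 0, fp_rate >= 0)
  structure(list(platform = platform, tools = tools,
                 sensitivity = sensitivity, jitter_sd = jitter_sd,
                 size_jitter_frac = size_jitter_frac, fp_rate = fp_rate,
                 fp_types = fp_types), class = "platform_profile")
}

#' Default platform profiles mirroring the study design
#'
#' Simulation defaults, not measured values: they encode the qualitative
#' platform behaviour the integration assumes -- long reads are most
#' sensitive for insertions and sub-kilobase SVs, short reads do well on
#' mid-size deletions but poorly on insertions, linked reads favour large
#' events, and Hi-C only sees megabase-scale rearrangements and
#' translocations. Replicate counts follow the study design (4 Illumina
#' tools and 2 linked-read tools with 11 replicates; single-replicate
#' long-read and Hi-C tools).
#'
#' @param illumina_reps,tenx_reps replicate counts (default 11).
#' @return named list of [platform_profile()] objects.
#' @export
default_platform_profiles <- function(illumina_reps = 11, tenx_reps = 11) {
  sens_table <- function(tab, large_only_bp = NULL) {
    force(tab); force(large_only_bp)
    function(svtype, size) {
      p <- tab[svtype]
      p[is.na(p)] <- 0
      if (!is.null(large_only_bp))
        p[svtype != "TRA" & size < large_only_bp] <- 0
      unname(p)
    }
  }
  list(
    Illumina = platform_profile(
      "Illumina",
      tools = c(TNscope = illumina_reps, Delly = illumina_reps,
                Novobreak = illumina_reps, Manta = illumina_reps),
      sensitivity = sens_table(c(DEL = 0.80, DUP = 0.70, INS = 0.25,
                                 INV = 0.70, TRA = 0.70)),
      jitter_sd = 10, size_jitter_frac = 0.03, fp_rate = 0.5),
    TenX = platform_profile(
      "TenX",
      tools = c(LongRanger = tenx_reps, GrocSVs = tenx_reps),
      sensitivity = sens_table(c(DEL = 0.55, DUP = 0.50, INS = 0.10,
                                 INV = 0.50, TRA = 0.65)),
      jitter_sd = 50, size_jitter_frac = 0.05, fp_rate = 0.3),
    PacBio = platform_profile(
      "PacBio",
      tools = c(Sniffles = 1, PBSV = 1),
      sensitivity = sens_table(c(DEL = 0.90, DUP = 0.80, INS = 0.90,
                                 INV = 0.80, TRA = 0.80)),
      jitter_sd = 20, size_jitter_frac = 0.05, fp_rate = 0.2),
    ONT = platform_profile(
      "ONT",
      tools = c(Sniffles = 1, NanoSV = 1),
      sensitivity = sens_table(c(DEL = 0.85, DUP = 0.75, INS = 0.90,
                                 INV = 0.75, TRA = 0.80)),
      jitter_sd = 30, size_jitter_frac = 0.06, fp_rate = 0.3),
    HiC = platform_profile(
      "HiC",
      tools = c(Selva = 1),
      sensitivity = sens_table(c(DEL = 0.60, DUP = 0.50, INS = 0, INV = 0.50,
                                 TRA = 0.90), large_only_bp = 1e6),
      jitter_sd = 25000, size_jitter_frac = 0.02, fp_rate = 0.05,
      fp_types = c("DEL", "TRA"))
  )
}

jitter_records <- function(df, jitter_sd, size_frac, chrom_sizes) {
  n <- nrow(df)
  if (n == 0) return(df)
  clamp <- function(pos, ch)
    pmin(pmax(pos, 1), chrom_sizes[ch])
  j1 <- round(rnorm(n, 0, jitter_sd))
  df$pos1 <- as.integer(clamp(df$pos1 + j1, df$chrom1))
  sized <- !df$svtype %in% c("TRA", "BND", "INS")
  szj <- pmax(50, round(df$size * (1 + rnorm(n, 0, size_frac))))
  df$size[sized] <- szj[sized]
  df$pos2[sized] <- as.integer(clamp(df$pos1[sized] + df$size[sized],
                                     df$chrom2[sized]))
  df$size[sized] <- df$pos2[sized] - df$pos1[sized]
  ins <- df$svtype == "INS"
  df$pos2[ins] <- df$pos1[ins]
  ins_sz <- pmax(50, round(df$size * (1 + rnorm(n, 0, size_frac))))
  df$size[ins] <- ins_sz[ins]
  tra <- df$svtype %in% c("TRA", "BND")
  if (any(tra)) {
    j2 <- round(rnorm(n, 0, jitter_sd))
    df$pos2[tra] <- as.integer(clamp(df$pos2[tra] + j2[tra], df$chrom2[tra]))
  }
  df
}

#' Emulate multi-platform caller outputs from a truth set
#'
#' For every (platform, tool, replicate) the generator draws each truth SV
#' with the profile's sensitivity, jitters breakpoints and sizes, and adds
#' uniform false positives at the profile's rate. Germline SVs appear in
#' both the tumor and normal call sets; somatic SVs only in the tumor.
#' Truth ids travel in the records so evaluation can compute exact recall.
#' Deterministic given the seed (sub-seeded per call set, so subsetting
#' the profiles does not change the remaining call sets).
#'
#' @param truth a [simulate_truth()] result.
#' @param profiles list of [platform_profile()] (default
#'   [default_platform_profiles()]).
#' @param seed RNG seed.
#' @param samples which samples to emit (default tumor and normal).
#' @return list of [sv_callset()] objects.
#' @export
emulate_callsets <- function(truth, profiles = default_platform_profiles(),
                             seed = 1, samples = c("tumor", "normal")) {
  genome <- truth$genome
  chrom_sizes <- genome$chromosomes
  genome_mb <- sum(chrom_sizes) / 1e6
  out <- list()
  cs_index <- 0
  for (prof in profiles) {
    for (tool in names(prof$tools)) {
      for (rep_k in seq_len(prof$tools[[tool]])) {
        for (smp in samples) {
          cs_index <- cs_index + 1
          pool <- if (smp == "tumor") rbind(truth$germline, truth$somatic)
                  else truth$germline
          cs <- with_seed(sub_seed(seed, cs_index), {
            detected <- if (nrow(pool) > 0) {
              p <- prof$sensitivity(pool$svtype, pool$size)
              pool[runif(nrow(pool)) < p, , drop = FALSE]
            } else pool
            detected <- jitter_records(detected, prof$jitter_sd,
                                       prof$size_jitter_frac, chrom_sizes)
            nfp <- rpois(1, prof$fp_rate * genome_mb)
            fps <- if (nfp > 0) {
              ty <- sample(prof$fp_types, nfp, replace = TRUE)
              sz <- ifelse(ty == "TRA", 0, draw_sizes(nfp, c(50, 1e5)))
              ch1 <- sample(names(chrom_sizes), nfp, replace = TRUE)
              p1 <- vapply(ch1, function(ch)
                sample.int(chrom_sizes[[ch]] - 2e5, 1), numeric(1))
              ch2 <- ifelse(ty == "TRA",
                            sample(names(chrom_sizes), nfp, replace = TRUE),
                            ch1)
              p2 <- ifelse(ty == "TRA",
                           vapply(ch2, function(ch)
                             sample.int(chrom_sizes[[ch]] - 2e5, 1),
                             numeric(1)),
                           ifelse(ty == "INS", p1, p1 + sz))
              data.frame(id = sprintf("fp_%d", seq_len(nfp)), svtype = ty,
                         chrom1 = ch1, pos1 = p1, chrom2 = ch2, pos2 = p2,
                         size = sz, filter = "PASS",
                         truth_id = NA_character_, stringsAsFactors = FALSE)
            } else NULL
            det <- detected[, RECORD_COLS]
            all_rec <- rbind(det, fps)
            if (nrow(all_rec) > 0) {
              all_rec$id <- sprintf("%s_%s_r%s_%d", prof$platform, tool,
                                    rep_k, seq_len(nrow(all_rec)))
              all_rec <- canonicalize_breakends(all_rec)
              class(all_rec) <- c("sv_records", "data.frame")
            } else all_rec <- empty_records()
            sv_callset(all_rec, prof$platform, tool, as.character(rep_k), smp)
          })
          out[[sprintf("%s_%s_r%s_%s", prof$platform, tool, rep_k, smp)]] <- cs
        }
      }
    }
  }
  out
}

# add `draw` to cells (rows, cols) and their mirrors, truncating to bounds
add_symmetric <- function(counts, rows, cols, draws) {
  for (k in seq_along(draws)) {
    if (draws[k] == 0) next
    r <- rows[k]; c <- cols[k]
    counts[r, c] <- counts[r, c] + draws[k]
    if (r != c) counts[c, r] <- counts[c, r] + draws[k]
  }
  counts
}

#' Simulate a Hi-C contact matrix with implanted rearrangements
#'
#' Background counts are Poisson with a distance-decay mean
#' `depth / (1 + d/w)` for intra-chromosomal distance d and a small
#' constant (`depth / inter_ratio`) for inter-chromosomal pairs. Each
#' truth TRA/DEL/INV/DUP adds its canonical quadrant signal: a fresh
#' distance-decay diagonal emanating from the junction at
#' `signal_factor * depth / (1 + s)` for taxicab bin offset s, placed on
#' the NE/SW quadrants for reciprocal translocations and inversions, one
#' quadrant for non-reciprocal translocations and deletions, and all four
#' for duplications. The matrix is exactly symmetric and deterministic
#' given the seed.
#'
#' @param genome a [genome_model()].
#' @param truth_svs `sv_records` to implant (TRA/DEL/INV/DUP; INS and
#'   events spanning fewer than 2 bins are ignored); NULL for pure
#'   background.
#' @param w bin width (default 50,000).
#' @param depth expected read pairs per near-diagonal bin pair (default 5).
#' @param signal_factor implant strength relative to depth (default 5;
#'   0 gives pure background).
#' @param seed RNG seed.
#' @param inter_ratio intra/inter background ratio (default 5000).
#' @param implant_range template extent in bins (default 15).
#' @param tra_mode "reciprocal" (NE+SW) or "nonreciprocal" (NE only)
#'   translocation template.
#' @return a [contact_matrix()].
#' @export
simulate_hic <- function(genome, truth_svs = NULL, w = 50000, depth = 5,
                         signal_factor = 5, seed = 1, inter_ratio = 5000,
                         implant_range = 15,
                         tra_mode = c("reciprocal", "nonreciprocal")) {
  stopifnot(signal_factor >= 0, depth > 0)
  tra_mode <- match.arg(tra_mode)
  chrom_sizes <- genome$chromosomes
  bins <- bin_layout(chrom_sizes, w)
  n <- nrow(bins)
  M0 <- list(chrom_sizes = chrom_sizes, w = w)
  with_seed(seed, {
    lambda_inter <- depth / inter_ratio
    counts <- matrix(0, n, n)
    # background: draw the upper triangle (incl. diagonal), mirror below
    lam <- matrix(lambda_inter, n, n)
    for (ch in unique(bins$chrom)) {
      idx <- bins$bin[bins$chrom == ch]
      nb <- length(idx)
      d <- abs(col(matrix(0, nb, nb)) - row(matrix(0, nb, nb)))
      lam[idx, idx] <- depth / (1 + d)
    }
    ut <- upper.tri(lam, diag = TRUE)
    draws <- rpois(sum(ut), lam[ut])
    counts[ut] <- draws
    counts <- counts + t(counts) - diag(diag(counts))

    if (!is.null(truth_svs) && nrow(truth_svs) > 0 && signal_factor > 0) {
      Rimp <- implant_range
      offs <- expand.grid(a = 0:Rimp, b = 0:Rimp)
      for (k in seq_len(nrow(truth_svs))) {
        sv <- truth_svs[k, ]
        if (sv$svtype %in% c("INS", "BND")) next
        i0 <- bin_of(M0, sv$chrom1, sv$pos1)
        j0 <- bin_of(M0, sv$chrom2, sv$pos2)
        if (is.na(i0) || is.na(j0)) next
        if (sv$svtype != "TRA" && (j0 - i0) < 2) next
        quads <- switch(sv$svtype,
          TRA = if (tra_mode == "reciprocal") c("NE", "SW") else "NE",
          DEL = "NW",
          INV = c("NE", "SW"),
          DUP = c("NE", "NW", "SW", "SE"))
        rows_i <- bins$bin[bins$chrom == bins$chrom[i0]]
        cols_j <- bins$bin[bins$chrom == bins$chrom[j0]]
        for (q in quads) {
          sr <- if (q %in% c("NE", "SE")) 1 else -1
          sc <- if (q %in% c("NE", "NW")) 1 else -1
          r <- i0 + sr * offs$a
          cc <- j0 + sc * offs$b
          ok <- r %in% rows_i & cc %in% cols_j
          if (bins$chrom[i0] == bins$chrom[j0]) ok <- ok & r < cc
          if (!any(ok)) next
          mean_sig <- signal_factor * depth / (1 + offs$a[ok] + offs$b[ok])
          draws <- rpois(sum(ok), mean_sig)
          counts <- add_symmetric(counts, r[ok], cc[ok], draws)
        }
      }
    }
    contact_matrix(counts, w, chrom_sizes, mapq_min = 20)
  })
}

#' Simulate a tumor purity / sequencing depth titration series
#'
#' A somatic SV is detected in a given (purity, depth) cell iff its
#' supporting-read draw, Poisson with mean
#' `depth * purity * het_fraction * capture_eff`, reaches `min_support`
#' reads. Germline SVs are present at purity 1 regardless of the tumor
#' fraction. The defaults model a heterozygous SV (allele fraction 0.5)
#' whose junction is captured by 40% of overlapping read pairs and a
#' caller requiring 3 supporting reads.
#'
#' @param truth a [simulate_truth()] result.
#' @param purities tumor fractions (default 0.05-1, the titration ratios).
#' @param depths sequencing depths (default 10-300X).
#' @param het_fraction,capture_eff,min_support detection-model parameters.
#' @param seed RNG seed.
#' @param platform,tool provenance stamped on the emitted call sets.
#' @return named list mapping "p<purity>_d<depth>" to a tumor
#'   [sv_callset()].
#' @export
simulate_purity_series <- function(truth,
                                   purities = c(0.05, 0.10, 0.20, 0.50,
                                                0.75, 1.0),
                                   depths = c(10, 30, 50, 100, 200, 300),
                                   het_fraction = 0.5, capture_eff = 0.4,
                                   min_support = 3, seed = 1,
                                   platform = "Illumina", tool = "TNscope") {
  stopifnot(all(purities > 0), all(purities <= 1), all(depths > 0))
  out <- list()
  k <- 0
  for (pu in purities) {
    for (dp in depths) {
      k <- k + 1
      cs <- with_seed(sub_seed(seed, k), {
        som <- truth$somatic
        som_reads <- rpois(nrow(som), dp * pu * het_fraction * capture_eff)
        som <- som[som_reads >= min_support, , drop = FALSE]
        germ <- truth$germline
        germ_reads <- rpois(nrow(germ), dp * het_fraction * capture_eff)
        germ <- germ[germ_reads >= min_support, , drop = FALSE]
        rec <- rbind(som, germ)
        if (nrow(rec) > 0) {
          rec$id <- sprintf("p%g_d%g_%d", pu, dp, seq_len(nrow(rec)))
          class(rec) <- c("sv_records", "data.frame")
        }
        sv_callset(rec, platform, tool,
                   replicate = sprintf("p%g_d%g", pu, dp), sample = "tumor")
      })
      out[[sprintf("p%g_d%g", pu, dp)]] <- cs
    }
  }
  out
}
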