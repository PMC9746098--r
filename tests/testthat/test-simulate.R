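test_that("truth simulation is reproducible and respects its contracts", {
  g <- genome_model(seed = 3)
  t1 <- simulate_truth(g, seed = 11)
  t2 <- simulate_truth(g, seed = 11)
  expect_identical(t1$somatic, t2$somatic)
  expect_identical(t1$germline, t2$germline)
  # requested sizes within bounds
  t3 <- simulate_truth(g, somatic_counts = c(DEL = 100),
                       germline_counts = c(DEL = 0),
                       size_ranges = list(DEL = c(50, 1000)), seed = 5)
  expect_equal(nrow(t3$somatic), 100)
  expect_true(all(t3$somatic$size >= 50 & t3$somatic$size <= 1000))
  # zero counts give an empty set
  t0 <- simulate_truth(g, somatic_counts = c(DEL = 0),
                       germline_counts = c(DEL = 0), seed = 1)
  expect_equal(nrow(t0$somatic), 0)
  # somatic and germline ids are disjoint
  expect_equal(length(intersect(t1$somatic$id, t1$germline$id)), 0)
  # no breakend inside the blacklist
  expect_false(any(positions_in_regions(t1$somatic$chrom1, t1$somatic$pos1,
                                        g$blacklist)))
})

test_that("caller emulation hits the identity and null limits", {
  g <- genome_model(seed = 3)
  truth <- simulate_truth(g, somatic_counts = c(DEL = 20, INS = 10),
                          germline_counts = c(DEL = 10), seed = 21)
  perfect <- list(platform_profile(
    "PacBio", tools = c(Perfect = 1),
    sensitivity = function(svtype, size) rep(1, length(svtype)),
    jitter_sd = 0, size_jitter_frac = 0, fp_rate = 0))
  cs <- emulate_callsets(truth, perfect, seed = 2)
  tum <- cs[[grep("tumor", names(cs))]]
  expect_equal(sort(tum$records$truth_id),
               sort(c(truth$somatic$id, truth$germline$id)))
  expect_equal(tum$records[order(tum$records$truth_id),
                           c("svtype", "chrom1", "pos1", "pos2", "size")],
               {
                 want <- rbind(truth$germline, truth$somatic)
                 want <- want[order(want$id),
                              c("svtype", "chrom1", "pos1", "pos2", "size")]
                 rownames(want) <- NULL
                 want
               },
               ignore_attr = TRUE)
  # normal call set carries germline only
  nrm <- cs[[grep("normal", names(cs))]]
  expect_true(all(nrm$records$truth_id %in% truth$germline$id))
  # zero sensitivity leaves only false positives
  blind <- list(platform_profile(
    "ONT", tools = c(Blind = 1),
    sensitivity = function(svtype, size) rep(0, length(svtype)),
    fp_rate = 0.5))
  cs0 <- emulate_callsets(truth, blind, seed = 2)
  expect_true(all(is.na(cs0[[1]]$records$truth_id)))
})

test_that("jittered calls merge back to their truth SV when jitter is well within the window", {
  g <- genome_model(seed = 3)
  truth <- simulate_truth(g, somatic_counts = c(DEL = 40),
                          germline_counts = c(DEL = 0),
                          size_ranges = list(DEL = c(2000, 20000)), seed = 31)
  prof <- list(platform_profile(
    "Illumina", tools = c(A = 1, B = 1),
    sensitivity = function(svtype, size) rep(1, length(svtype)),
    jitter_sd = 20, size_jitter_frac = 0.01, fp_rate = 0))
  cs <- emulate_callsets(truth, prof, seed = 7, samples = "tumor")
  m <- merge_calls(cs, window = 1000)
  # each truth SV should collapse to one cluster containing both tools
  ok <- vapply(split(m$members$cluster_id, m$members$truth_id),
               function(x) length(unique(x)) == 1, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("simulated Hi-C matrices are symmetric with depth-proportional mass", {
  g <- genome_model(chromosomes = c(c1 = 5e6, c2 = 5e6), seed = 5)
  M1 <- simulate_hic(g, depth = 5, seed = 9)
  expect_identical(M1$counts, t(M1$counts))
  masses <- vapply(1:5, function(s)
    sum(simulate_hic(g, depth = 5, seed = 20 + s)$counts), numeric(1))
  masses10 <- vapply(1:5, function(s)
    sum(simulate_hic(g, depth = 10, seed = 40 + s)$counts), numeric(1))
  expect_equal(mean(masses10) / mean(masses), 2, tolerance = 0.05)
})

test_that("purity series obeys the Poisson detection limits", {
  g <- genome_model(seed = 5)
  truth <- simulate_truth(g, seed = 51)
  ser <- simulate_purity_series(truth, purities = c(0.05, 1), depths = c(10, 300),
                                seed = 4)
  # purity 1, depth 300: Poisson mean 60 >> 3 -> essentially everything
  rp_hi <- recall_precision(ser[["p1_d300"]], truth)
  expect_gte(rp_hi$recall, 0.99)
  # purity 0.05, depth 10: mean 0.1 << 3 -> essentially nothing
  rp_lo <- recall_precision(ser[["p0.05_d10"]], truth)
  expect_lte(rp_lo$recall, 0.05)
  # determinism
  ser2 <- simulate_purity_series(truth, purities = c(0.05, 1),
                                 depths = c(10, 300), seed = 4)
  expect_identical(ser[["p1_d300"]]$records, ser2[["p1_d300"]]$records)
})
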