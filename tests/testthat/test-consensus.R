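# A hand-constructed 3-platform fixture: one SV seen by Delly in 5 of 11
# Illumina replicates, Manta in 6 of 11, and PacBio Sniffles in its single
# replicate. Expected by hand: tool freqs {5/11, 6/11, 1}, consensus
# score 5/11 + 6/11 + 1 = 2, Illumina platform freq 11/44, PacBio 1/2.
fixture_members <- function() {
  data.frame(
    id = sprintf("m%d", 1:12), svtype = "DEL", chrom1 = "chr1",
    pos1 = 1000L, chrom2 = "chr1", pos2 = 1500L, size = 500,
    filter = "PASS", truth_id = NA_character_,
    platform = c(rep("Illumina", 11), "PacBio"),
    tool = c(rep("Delly", 5), rep("Manta", 6), "Sniffles"),
    replicate = c(as.character(1:5), as.character(1:6), "1"),
    sample = "tumor", cluster_id = 1L, stringsAsFactors = FALSE)
}

fixture_census <- function() {
  replicate_census(
    platform = c("Illumina", "Illumina", "Illumina", "Illumina", "PacBio",
                 "PacBio"),
    tool = c("TNscope", "Delly", "Novobreak", "Manta", "Sniffles", "PBSV"),
    n_replicates = c(11, 11, 11, 11, 1, 1))
}

test_that("tool and platform frequencies match hand arithmetic to 1e-9", {
  mb <- fixture_members()
  census <- fixture_census()
  tf <- tool_frequency(mb, census)
  expect_equal(unname(tf[["Illumina/Delly"]]), 5 / 11, tolerance = 1e-9)
  expect_equal(unname(tf[["Illumina/Manta"]]), 6 / 11, tolerance = 1e-9)
  expect_equal(unname(tf[["PacBio/Sniffles"]]), 1, tolerance = 1e-9)
  expect_equal(consensus_score(tf), 2, tolerance = 1e-9)
  pf <- platform_frequency(mb, census)
  expect_equal(unname(pf[["Illumina"]]), 11 / 44, tolerance = 1e-9)
  expect_equal(unname(pf[["PacBio"]]), 1 / 2, tolerance = 1e-9)
  # tools with zero members are absent, not 0 entries
  expect_false("Illumina/TNscope" %in% names(tf))
  expect_equal(consensus_score(setNames(numeric(0), character(0))), 0)
})

test_that("frequencies are bounded and scores invariant under member order", {
  mb <- fixture_members()
  census <- fixture_census()
  tf1 <- tool_frequency(mb, census)
  tf2 <- tool_frequency(mb[sample(nrow(mb)), ], census)
  expect_equal(sort(tf1), sort(tf2))
  expect_true(all(tf1 >= 0 & tf1 <= 1))
  pf <- platform_frequency(mb, census)
  expect_true(all(pf >= 0 & pf <= 1))
  expect_lte(consensus_score(tf1), nrow(census))
})

test_that("provenance absent from the census is a configuration error", {
  mb <- fixture_members()
  mb$platform[12] <- "ONT"
  expect_error(tool_frequency(mb, fixture_census()), "census")
})

test_that("initial selection requires two replicates and respects the blacklist", {
  recs <- list(
    one_rep = sv_records("a", "DEL", "chr1", 1e5, pos2 = 1e5 + 500, size = 500),
    two_rep = sv_records("b", "DEL", "chr2", 2e5, pos2 = 2e5 + 500, size = 500),
    blk = sv_records("c", "DEL", "chr3", 100, pos2 = 600, size = 500))
  css <- c(
    list(toy_callset(rbind(recs$one_rep, recs$two_rep, recs$blk),
                     tool = "Delly", replicate = "1")),
    list(toy_callset(rbind(recs$two_rep, recs$blk), tool = "Delly",
                     replicate = "2")))
  m <- run_merge(css, verbose = FALSE)
  census <- replicate_census("Illumina", "Delly", 2)
  scored <- score_consensus(m, census)
  blk <- genomic_regions("chr3", 0, 1000, label = "blacklist")
  init <- select_initial(scored, blacklist = blk)
  expect_equal(sort(unique(init$members$id)), "b")
  expect_true(all(init$clusters$initial))
})

test_that("high-confidence selection needs two platforms AND two tools", {
  mk <- function(platform, tool) toy_callset(
    sv_records(paste0(platform, tool), "DEL", "chr1", 5e4,
               pos2 = 5e4 + 300, size = 300), platform = platform,
    tool = tool)
  census <- replicate_census(
    c("Illumina", "Illumina", "PacBio", "ONT"),
    c("Manta", "Delly", "Sniffles", "Sniffles"), c(1, 1, 1, 1))
  run_case <- function(css) {
    m <- run_merge(css, verbose = FALSE)
    sc <- score_consensus(m, census)
    sc$clusters$initial <- TRUE
    nrow(select_high_confidence(sc)$clusters)
  }
  # two platforms, two tools -> kept
  expect_equal(run_case(list(mk("Illumina", "Manta"), mk("PacBio", "Sniffles"))), 1)
  # one platform, two tools -> dropped
  expect_equal(run_case(list(mk("Illumina", "Manta"), mk("Illumina", "Delly"))), 0)
  # the same caller on two platforms counts as two tools (study convention)
  expect_equal(run_case(list(mk("PacBio", "Sniffles"), mk("ONT", "Sniffles"))), 1)
})

test_that("platform exclusions recompute counts monotonically and drop empty clusters", {
  css <- list(
    toy_callset(sv_records("lr", "DEL", "chr1", 1e6, pos2 = 1e6 + 5000,
                           size = 5000), platform = "TenX",
                tool = "LongRanger"),
    toy_callset(sv_records("mt", "DEL", "chr1", 1e6 + 10, pos2 = 1e6 + 5010,
                           size = 5000), tool = "Manta"),
    toy_callset(sv_records("lr2", "DEL", "chr2", 1e6, pos2 = 1e6 + 5000,
                           size = 5000), platform = "TenX",
                tool = "LongRanger"))
  m <- run_merge(css, verbose = FALSE)
  out <- exclude_platform_calls(m, longranger_short_del_predicate)
  expect_equal(sort(out$members$id), "mt")   # solo Long Ranger cluster gone
  expect_true(all(out$clusters$n_tools <= max(m$clusters$n_tools)))
  # a predicate matching nothing is the identity
  none <- exclude_platform_calls(m, function(mb) rep(FALSE, nrow(mb)))
  expect_equal(none$clusters, m$clusters)
})

test_that("the filtering chain is monotone: high-confidence within initial within scored", {
  g <- genome_model(seed = 7)
  truth <- simulate_truth(g, somatic_counts = c(DEL = 25, DUP = 8, INS = 15,
                                                INV = 5, TRA = 5),
                          germline_counts = c(DEL = 10, DUP = 4, INS = 8,
                                              INV = 2, TRA = 2), seed = 8)
  css <- emulate_callsets(truth, seed = 9)
  m <- run_merge(css, verbose = FALSE)
  cons <- run_consensus(m, census_from_callsets(css),
                        blacklist = g$blacklist, verbose = FALSE)
  key <- function(x) x$clusters$rep_id
  expect_true(all(key(cons$initial) %in% key(cons$scored)))
  expect_true(all(key(cons$high_confidence) %in% key(cons$initial)))
  expect_true(all(cons$high_confidence$clusters$n_platforms >= 2))
  expect_true(all(cons$high_confidence$clusters$n_tools >= 2))
  expect_true(all(cons$high_confidence$clusters$n_replicates >= 2))
})
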