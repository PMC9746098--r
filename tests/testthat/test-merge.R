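test_that("breakpoint-window linking merges concordant calls and separates types", {
  a <- toy_callset(sv_records("a", "DEL", "chr1", 10000, pos2 = 10400,
                              size = 400), tool = "Manta")
  b <- toy_callset(sv_records("b", "DEL", "chr1", 10050, pos2 = 10430,
                              size = 380), tool = "Delly")
  m <- merge_calls(list(a, b), window = 100)
  expect_equal(nrow(m$clusters), 1)
  expect_equal(m$clusters$n_members, 2)
  expect_equal(m$clusters$n_tools, 2)
  # same coordinates but different types never merge
  d <- toy_callset(sv_records("d", "DUP", "chr1", 10000, pos2 = 10400,
                              size = 400), tool = "Delly")
  m2 <- merge_calls(list(a, d), window = 100)
  expect_equal(nrow(m2$clusters), 2)
})

test_that("insertions merge on position distance plus size similarity", {
  a <- toy_callset(sv_records("a", "INS", "chr2", 5000, size = 100),
                   tool = "Sniffles", platform = "PacBio")
  b <- toy_callset(sv_records("b", "INS", "chr2", 5040, size = 60),
                   tool = "PBSV", platform = "PacBio")
  c_ <- toy_callset(sv_records("c", "INS", "chr2", 5040, size = 40),
                    tool = "NanoSV", platform = "ONT")
  m <- merge_calls(list(a, b), window = 100)
  expect_equal(nrow(m$clusters), 1)        # sim 0.6 >= 0.5
  m2 <- merge_calls(list(a, c_), window = 100)
  expect_equal(nrow(m2$clusters), 2)       # sim 0.4 < 0.5
})

test_that("merging conserves records and never increases counts", {
  set.seed(5)
  css <- lapply(1:4, function(k)
    toy_callset(random_sv_instance(15, seed = 300 + k), tool = paste0("T", k)))
  n_in <- sum(vapply(css, function(cs) nrow(cs$records), integer(1)))
  m <- merge_calls(css, window = 500)
  expect_equal(nrow(m$members), n_in)
  expect_lte(nrow(m$clusters), n_in)
  expect_equal(sum(m$clusters$n_members), n_in)
})

test_that("merge components equal the transitive-closure oracle", {
  for (case in 1:20) {
    rec <- random_sv_instance(sample(5:30, 1), seed = 400 + case)
    cs <- toy_callset(rec)
    m <- merge_calls(list(cs), window = 200)
    got <- m$members$cluster_id[match(rec$id, m$members$id)]
    want <- oracle_components(as.data.frame(rec), 200, "merge")
    expect_true(same_partition(got, want),
                info = sprintf("merge oracle mismatch, case %d", case))
  }
})

test_that("component structure is invariant under input permutation", {
  rec <- random_sv_instance(25, seed = 99)
  cs1 <- toy_callset(rec)
  perm <- sample(nrow(rec))
  cs2 <- toy_callset(rec[perm, ])
  m1 <- merge_calls(list(cs1), window = 300)
  m2 <- merge_calls(list(cs2), window = 300)
  g1 <- m1$members$cluster_id[match(rec$id, m1$members$id)]
  g2 <- m2$members$cluster_id[match(rec$id, m2$members$id)]
  expect_true(same_partition(g1, g2))
})

test_that("somatic subtraction removes normal-supported clusters only", {
  tum <- merge_calls(list(toy_callset(sv_records(
    c("t1", "t2"), c("DEL", "TRA"), c("chr2", "chr3"), c(5000, 1e6),
    c("chr2", "chr17"), c(5300, 2e6), size = c(300, 0)))), window = 1000)
  nrm <- merge_calls(list(toy_callset(sv_records(
    "n1", "DEL", "chr2", 5020, pos2 = 5330, size = 310),
    sample = "normal")), window = 1000)
  out <- somatic_subtract(tum, nrm, window = 1000)
  expect_equal(out$clusters$svtype, "TRA")   # DEL removed, TRA retained
  # identity on empty normal; empty on self
  expect_equal(nrow(somatic_subtract(tum, merge_calls(list(), 1000),
                                     1000)$clusters), 2)
  expect_equal(nrow(somatic_subtract(tum, tum, 1000)$clusters), 0)
})

test_that("similarity clustering requires >50% reciprocal size similarity", {
  mk <- function(id, size, pos1, tool) toy_callset(
    sv_records(id, "DEL", "chr1", pos1, pos2 = pos1 + size, size = size),
    tool = tool)
  # sizes 100 and 60: similarity 0.6 > 0.5 -> may cluster
  m <- merge_calls(list(mk("a", 100, 10000, "Manta")), window = 50)
  m2 <- merge_calls(list(mk("b", 60, 10020, "Delly")), window = 50)
  cl <- cluster_merged(combine_two(m, m2))
  expect_equal(nrow(cl$clusters), 1)
  # sizes 100 and 49: similarity 0.49 <= 0.5 -> never clustered
  m3 <- merge_calls(list(mk("c", 49, 10020, "Delly"))
                    , window = 50)
  cl2 <- cluster_merged(combine_two(m, m3))
  expect_equal(nrow(cl2$clusters), 2)
})

test_that("clustering components equal the transitive-closure oracle", {
  for (case in 1:10) {
    rec <- random_sv_instance(sample(5:25, 1), seed = 600 + case)
    cs <- toy_callset(rec)
    # one record per pre-merge cluster: merge at a tiny window
    m <- merge_calls(list(cs), window = 1)
    cl <- cluster_merged(m)
    got <- cl$members$cluster_id[match(rec$id, cl$members$id)]
    w <- size_class_of(rec)$window
    want <- oracle_components(as.data.frame(rec), w, "cluster")
    expect_true(same_partition(got, want),
                info = sprintf("cluster oracle mismatch, case %d", case))
  }
})

test_that("region and ALT-contig filtering removes SVs by breakend position", {
  rec <- sv_records(c("in_loh", "clean", "alt"),
                    c("DEL", "DEL", "TRA"),
                    c("chr6", "chr2", "chr1"), c(1e6, 1e6, 5e5),
                    c("chr6", "chr2", "chr1_KI270706v1_random"),
                    c(1e6 + 500, 1e6 + 500, 9e5),
                    size = c(500, 500, 0))
  m <- merge_calls(list(toy_callset(rec)), window = 100)
  loh <- genomic_regions("chr6", 0, 6e7, label = "LOH")
  out <- filter_regions(m, loh)
  expect_equal(sort(out$members$id), "clean")
  # empty regions + primary chroms = identity
  m2 <- merge_calls(list(toy_callset(rec[2, ])), window = 100)
  expect_equal(nrow(filter_regions(m2, list())$clusters), 1)
})
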