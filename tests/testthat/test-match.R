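test_that("translocations match within 50 kb on both breakends, orientation-free", {
  q <- sv_records("q1", "TRA", "chr3", 1e6, "chr17", 2e6)
  v_ok <- sv_records("v1", "TRA", "chr3", 1e6 + 30000, "chr17", 2e6 + 12000)
  v_far <- sv_records("v2", "TRA", "chr3", 1e6 + 60000, "chr17", 2e6)
  m1 <- match_calls(q, v_ok)
  expect_equal(m1$status$status, "matched")
  m2 <- match_calls(q, v_far)
  expect_equal(m2$status$status, "unmatched")
  # TRA and BND are interchangeable for matching
  vb <- sv_records("v3", "BND", "chr3", 1e6 + 100, "chr17", 2e6 + 100)
  expect_equal(match_calls(q, vb)$status$status, "matched")
})

test_that("sized calls below the 500 bp resolution floor are ineligible", {
  q <- sv_records(c("small", "big"), "DEL", "chr1", c(1e5, 2e5),
                  pos2 = c(1e5 + 400, 2e5 + 900), size = c(400, 900))
  v <- sv_records("v", "DEL", "chr1", 2e5 + 50, pos2 = 2e5 + 980, size = 930)
  m <- match_calls(q, v)
  st <- setNames(m$status$status, m$status$query_id)
  expect_equal(unname(st["small"]), "ineligible")
  expect_equal(unname(st["big"]), "matched")
})

test_that("size similarity above 0.5 is required for sized types", {
  q <- sv_records("q", "INV", "chr2", 1e6, pos2 = 1e6 + 2000, size = 2000)
  v_sim <- sv_records("v1", "INV", "chr2", 1e6 + 100, pos2 = 1e6 + 1300,
                      size = 1200)
  v_dissim <- sv_records("v2", "INV", "chr2", 1e6 + 100, pos2 = 1e6 + 1000,
                         size = 900)
  expect_equal(match_calls(q, v_sim)$status$status, "matched")
  expect_equal(match_calls(q, v_dissim)$status$status, "unmatched")
})

test_that("greedy assignment is one-to-one by ascending distance", {
  q <- sv_records(c("near", "far"), "DEL", "chr1", c(10000, 14000),
                  pos2 = c(11000, 15000), size = 1000)
  v <- sv_records("v", "DEL", "chr1", 10100, pos2 = 11100, size = 1000)
  m <- match_calls(q, v)
  st <- setNames(m$status$status, m$status$query_id)
  expect_equal(unname(st["near"]), "matched")
  expect_equal(unname(st["far"]), "unmatched")
  expect_lte(nrow(m$pairs), min(nrow(q), nrow(v)))
})

test_that("the match predicate is symmetric and monotone in max distance", {
  set.seed(12)
  q <- random_sv_instance(12, seed = 801)
  v <- random_sv_instance(12, seed = 802)
  n_ab <- nrow(match_calls(q, v)$pairs)
  n_ba <- nrow(match_calls(v, q)$pairs)
  expect_equal(n_ab, n_ba)
  wide <- list(match_rule(c("DEL", "DUP", "INS", "INV"), 500, 0.5, 50000),
               match_rule(c("TRA", "BND"), 0, 0.5, 250000))
  expect_gte(nrow(match_calls(q, v, wide)$pairs), n_ab)
})

test_that("replicate consensus keeps 2-of-3 calls and drops singletons", {
  shared <- sv_records("s", "DEL", "chr1", 1e6, pos2 = 1e6 + 2000, size = 2000)
  jitter <- sv_records("s_j", "DEL", "chr1", 1e6 + 200, pos2 = 1e6 + 2150,
                       size = 1950)
  solo <- sv_records("x", "DUP", "chr2", 5e6, pos2 = 5e6 + 3000, size = 3000)
  r1 <- toy_callset(rbind(shared, solo), platform = "Bionano",
                    tool = "Saphyr", replicate = "1")
  r2 <- toy_callset(jitter, platform = "Bionano", tool = "Saphyr",
                    replicate = "2")
  r3 <- toy_callset(sv_records("y", "INS", "chr3", 1e6, size = 800),
                    platform = "Bionano", tool = "Saphyr", replicate = "3")
  out <- replicate_consensus(list(r1, r2, r3))
  expect_equal(out$id, "s")      # in 2 of 3; solo and y in 1 of 3
  # identical triplicates: identity (after de-duplication)
  trip <- replicate_consensus(list(r1, r1, r1))
  expect_equal(sort(trip$id), sort(r1$records$id))
  expect_error(replicate_consensus(list(r1)), "min_replicates")
})

test_that("tumor-not-normal filtering removes validated germline calls", {
  call <- sv_records("s", "DEL", "chr1", 1e6, pos2 = 1e6 + 2000, size = 2000)
  r1 <- toy_callset(call, platform = "Bionano", tool = "Saphyr", replicate = "1")
  r2 <- toy_callset(call, platform = "Bionano", tool = "Saphyr", replicate = "2")
  nrm <- sv_records("n", "DEL", "chr1", 1e6 + 50, pos2 = 1e6 + 2050,
                    size = 2000)
  expect_equal(nrow(replicate_consensus(list(r1, r2), normal = nrm)), 0)
  expect_equal(nrow(replicate_consensus(list(r1, r2))), 1)
})
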