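test_that("size classes partition [50, Inf) with upper-inclusive boundaries", {
  cfg <- size_class_config()
  recs <- sv_records(
    id = sprintf("r%d", 1:8), svtype = c(rep("DEL", 7), "TRA"),
    chrom1 = "chr1", pos1 = 1000,
    pos2 = 1000 + c(50, 100, 250, 500, 1000, 30000, 31000, 0),
    size = c(50, 100, 250, 500, 1000, 30000, 31000, 0))
  sc <- size_class_of(recs, cfg)
  expect_equal(sc$class, c(1, 1, 2, 2, 3, 4, 5, 5))
  expect_equal(sc$window, c(50, 50, 100, 100, 500, 1000, 10000, 10000))
  # totality: any size >= 50 lands in exactly one class
  sizes <- round(exp(seq(log(50), log(5e6), length.out = 200)))
  probe <- sv_records(sprintf("p%d", seq_along(sizes)), "DEL", "chr1", 1,
                      pos2 = 1 + sizes, size = sizes)
  cls <- size_class_of(probe, cfg)$class
  expect_true(all(cls %in% 1:5))
  expect_true(all(diff(cls) >= 0))
})

test_that("TRA always maps to the large class and sub-threshold SVs are rejected", {
  tra <- sv_records("t", "TRA", "chr1", 100, "chr2", 200)
  expect_equal(size_class_of(tra)$window, 10000)
  small <- sv_records("s", "DEL", "chr1", 100, pos2 = 140, size = 40)
  expect_error(size_class_of(small), "threshold")
})

test_that("record invariants are enforced and breakends canonicalized", {
  expect_error(sv_records("a", "DEL", "chr1", 0, pos2 = 100, size = 100),
               ">= 1")
  expect_error(sv_records("a", "FOO", "chr1", 10), "svtype")
  # reversed breakends are swapped into canonical order
  r <- sv_records("a", "DEL", "chr1", 500, "chr1", 100)
  expect_equal(r$pos1, 100L)
  expect_equal(r$size, 400)
  tra <- sv_records("t", "TRA", "chr9", 10, "chr2", 20, size = 123)
  expect_equal(tra$chrom1, "chr2")   # chromosome-ordered
  expect_equal(tra$size, 0)          # TRA size forced to 0
})

test_that("call sets deduplicate exact coordinate duplicates and report counts", {
  r <- sv_records(c("a", "b"), "DEL", "chr1", c(100, 100),
                  pos2 = c(400, 400), size = 300)
  cs <- sv_callset(r, "Illumina", "Manta")
  expect_equal(nrow(cs$records), 1)
  expect_equal(attr(cs, "n_duplicates"), 1L)
})

test_that("primary chromosome detection implements the ALT-contig rule", {
  expect_true(all(is_primary_chrom(c("chr1", "chr22", "chrX", "chrY", "7",
                                     "X", "chrM"))))
  expect_false(any(is_primary_chrom(c("chr1_KI270706v1_random", "chrUn_GL000195v1",
                                      "HLA-A*01:01", "chr17_alt"))))
})
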