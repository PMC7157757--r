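test_that("extract_region returns the expected residue stretches", {
  prot <- paste(rep("ACDEFGHIKL", 25), collapse = "")  # 250 aa
  expect_equal(nchar(extract_region(prot, sid_region("AKR2", 136, 203))), 68L)
  expect_equal(nchar(extract_region(prot, sid_region("AKR1", 132, 192))), 61L)
  expect_equal(extract_region("MQSTAILKR", sid_region("p", 2, 4)), "QST")
  expect_error(sid_region("p", 5, 3), "start <= end")
  expect_error(extract_region("MQST", sid_region("p", 2, 9)), "out of bounds")
})

test_that("align_pair handles exact and near-exact pairs", {
  al <- align_pair("ACDEFGHIKL", "ACDEFGHIKL")
  expect_equal(percent_identity(al), 100)
  expect_false(grepl("-", paste0(al$a, al$b)))

  al <- align_pair("ACDE", "ACDF")
  expect_equal(percent_identity(al), 75)
  expect_equal(nchar(al$a), 4L)

  expect_error(align_pair("AC1E", "ACDE"), "non-amino-acid")
})

test_that("removing gaps from an alignment recovers the inputs", {
  set.seed(12)
  aa <- rownames(oracle_blosum62)[1:20]
  for (i in 1:10) {
    a <- paste(sample(aa, sample(5:25, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(5:25, 1), replace = TRUE), collapse = "")
    al <- align_pair(a, b)
    expect_equal(gsub("-", "", al$a), a)
    expect_equal(gsub("-", "", al$b), b)
    expect_equal(nchar(al$a), nchar(al$b))
  }
})

test_that("alignment scores agree with Biostrings pairwiseAlignment", {
  set.seed(13)
  aa <- rownames(oracle_blosum62)[1:20]
  for (i in 1:12) {
    a <- paste(sample(aa, sample(8:30, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(8:30, 1), replace = TRUE), collapse = "")
    ours <- align_pair(a, b)$score
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = oracle_blosum62,
      gapOpening = 10, gapExtension = 0.5, type = "global"))
    expect_equal(ours, ref, label = paste(a, b))
  }
})

test_that("percent identity is symmetric and bounded", {
  set.seed(14)
  aa <- rownames(oracle_blosum62)[1:20]
  for (i in 1:8) {
    a <- paste(sample(aa, 15, replace = TRUE), collapse = "")
    b <- paste(sample(aa, 18, replace = TRUE), collapse = "")
    pid_ab <- percent_identity(align_pair(a, b))
    pid_ba <- percent_identity(align_pair(b, a))
    expect_equal(pid_ab, pid_ba)
    expect_gte(pid_ab, 0)
    expect_lte(pid_ab, 100)
  }
  expect_equal(percent_identity(align_pair("WYWYW", "WYWYW")), 100)
})

test_that("project_region maps coordinates through a gapless homolog", {
  a <- "MKLVNQAGHTRWYPEDSACF"
  # b = a with 3 residues prepended: region shifts by +3
  b <- paste0("GGG", a)
  r <- project_region(a, b, sid_region("a", 5, 12))
  expect_equal(r$start, 8L)
  expect_equal(r$end, 15L)
  # identity projection
  r <- project_region(a, a, sid_region("a", 3, 9))
  expect_equal(c(r$start, r$end), c(3L, 9L))
})

test_that("sid_identity reports mean and min over all pairs", {
  res <- sid_identity(c(x = "ACDEFGHIKL", y = "ACDEFGHIKL", z = "ACDEFGHIKW"))
  expect_equal(nrow(res$pairwise), 3L)
  expect_equal(res$pairwise$identity, c(100, 90, 90))
  expect_equal(res$mean_identity, mean(c(100, 90, 90)))
  expect_equal(res$min_identity, 90)
})

test_that("epitope coverage merges, clips and ignores outside intervals", {
  r100 <- sid_region("p", 1, 100)
  expect_equal(epitope_coverage(data.frame(start = c(10, 15), end = c(20, 30)),
                                r100), 21)
  expect_equal(epitope_coverage(data.frame(start = integer(0), end = integer(0)),
                                r100), 0)
  expect_equal(epitope_coverage(NULL, r100), 0)
  # fully outside the region
  expect_equal(epitope_coverage(data.frame(start = 150, end = 160), r100), 0)
  # clipping at the region edge
  expect_equal(epitope_coverage(data.frame(start = 95, end = 130), r100), 6)
  # a 51/68 case
  r <- sid_region("p", 136, 203)
  expect_equal(epitope_coverage(data.frame(start = 140, end = 190), r),
               100 * 51 / 68)
})

test_that("coverage is invariant to interval order and splitting", {
  r <- sid_region("p", 1, 80)
  whole <- data.frame(start = c(5, 40), end = c(25, 60))
  split <- data.frame(start = c(40, 5, 13, 50), end = c(49, 12, 25, 60))
  expect_equal(epitope_coverage(whole, r), epitope_coverage(split, r))
})

test_that("read_epitopes converts BED coordinates to 1-based inclusive", {
  path <- system.file("extdata", "synthetic_sid_epitopes.tsv",
                      package = "musicodon")
  ep <- read_epitopes(path)
  expect_equal(ep$start[1], 136L)
  expect_equal(ep$end[1], 168L)
  ep1 <- read_epitopes(path, bed = FALSE)
  expect_equal(ep1$start[1], 135L)
})
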