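test_that("generators are bit-reproducible under fixed seeds", {
  expect_identical(random_cds(50, seed = 1), random_cds(50, seed = 1))
  expect_false(identical(random_cds(50, seed = 1), random_cds(50, seed = 2)))
  expect_identical(paralog_pair(40, 0.7, seed = 3),
                   paralog_pair(40, 0.7, seed = 3))
  expect_identical(canon_pair(20, 4, seed = 5), canon_pair(20, 4, seed = 5))
  t1 <- tempfile(); t2 <- tempfile()
  random_interaction_table(30, seed = 9, path = t1)
  random_interaction_table(30, seed = 9, path = t2)
  expect_identical(readBin(t1, "raw", file.size(t1)),
                   readBin(t2, "raw", file.size(t2)))
})

test_that("random_cds has the right length, alphabet and composition", {
  expect_equal(random_cds(0, seed = 1), "")
  s <- random_cds(25, seed = 2)
  expect_equal(nchar(s), 75L)
  expect_false(grepl("[^ACGT]", s))
  # law of large numbers: each base near 0.25 over 1e5 codons
  big <- random_cds(1e5, seed = 3)
  counts <- table(strsplit(big, "")[[1]])
  freqs <- counts / (3e5)
  sigma <- sqrt(0.25 * 0.75 / 3e5)
  expect_true(all(abs(freqs - 0.25) < 3 * sigma + 1e-12))
})

test_that("paralog pairs realize their target codon identity", {
  pp <- paralog_pair(100, 1.0, seed = 4)
  expect_identical(pp$a, pp$b)
  expect_equal(pp$identity, 1)

  pp <- paralog_pair(500, 0, seed = 5)
  expect_lte(pp$identity, 0.02)

  pp <- paralog_pair(500, 0.6, seed = 6)
  expect_gte(pp$identity, 0.58)
  expect_lte(pp$identity, 0.62)
})

test_that("canon pairs delay the leading voice and reject lag 0", {
  cp <- canon_pair(15, lag = 3, seed = 7)
  expect_equal(nchar(cp$b), nchar(cp$a) + 9L)
  expect_equal(substr(cp$b, 10, nchar(cp$b)), cp$a)
  expect_error(canon_pair(15, lag = 0, seed = 7), "lag")
})

test_that("random interaction tables parse and follow their category law", {
  tmp <- tempfile(fileext = ".tsv")
  random_interaction_table(100, c(D = 1), seed = 8, path = tmp)
  tab <- parse_interactions(tmp)
  expect_equal(nrow(tab), 100L)
  expect_true(all(tab$category == "D"))

  # calibration: multinomial goodness of fit rarely rejected at alpha = 0.01
  probs <- c(A = 0.1, B = 0.2, C = 0.3, D = 0.4)
  rejections <- 0L
  n_rep <- 100L
  for (s in seq_len(n_rep)) {
    tab <- random_interaction_table(200, probs, seed = s)
    counts <- vapply(names(probs), function(k) sum(tab$category == k), 0L)
    p <- suppressWarnings(stats::chisq.test(counts, p = probs)$p.value)
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, stats::qbinom(0.999, n_rep, 0.01) + 1L)
})

test_that("synthetic SEC standards respect geometry and fit requirements", {
  g <- sec_geometry()
  std <- synthetic_sec_standards(n = 7, noise_sd = 0.1, seed = 10, geometry = g)
  expect_true(all(std$ve_ml >= g$vo & std$ve_ml <= g$vc))
  expect_error(synthetic_sec_standards(n = 2), "at least 3")
})

test_that("derive_seed separates purposes deterministically", {
  expect_identical(derive_seed(1, "cds"), derive_seed(1, "cds"))
  expect_false(derive_seed(1, "cds") == derive_seed(1, "paralog"))
  expect_true(derive_seed(.Machine$integer.max, "x") < 2^31)
  expect_gte(derive_seed(12345, "y2h"), 0L)
})
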