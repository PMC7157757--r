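test_that("sample_grid expands notes onto the eighth-note grid", {
  expect_equal(sample_grid(sonify("TGC")), rep("T", 6))
  expect_equal(sample_grid(sonify("GGA")), c("S", "S", "S", "S", "L", "L"))
  expect_equal(sample_grid(sonify("GCC")), c("D", "D", "D", "R", "M", "R"))
  expect_length(sample_grid(sonify("")), 0L)
  v <- sonify(random_cds(17, seed = 5))
  expect_length(sample_grid(v), 6L * 17L)
})

test_that("interval classification is symmetric and transposition-invariant", {
  for (a in 0:11) {
    for (b in 0:11) {
      expect_equal(interval_class(a, b), interval_class(b, a))
      for (s in c(1, 5, 11)) {
        expect_equal(interval_class(a + s, b + s), interval_class(a, b))
      }
    }
  }
  expect_equal(interval_class(0, 0), "unison")
  expect_equal(interval_class(0, 5), "P4")
  expect_equal(interval_class(7, 0), "P5")
  expect_equal(interval_class(0, 6), "other")  # tritone is not consonant
})

test_that("consonance_profile matches hand-computable fixtures", {
  v <- sonify(random_cds(20, seed = 1))
  p <- consonance_profile(v, v, 0)
  expect_equal(p$f_unison, 1)
  expect_equal(p$f_cons, 1)
  expect_equal(p$overlap_bars, 20L)
  expect_equal(sum(p$bar_counts[, c("unison", "P4", "P5", "other")]),
               6L * p$overlap_bars)

  allS <- degrees_voice(rep("S", 10))
  allD <- degrees_voice(rep("D", 10))
  p <- consonance_profile(allS, allD, 0)
  expect_equal(p$f_p45, 1)  # S vs D is a perfect fifth everywhere
  expect_equal(p$f_unison, 0)

  expect_error(consonance_profile(v, v, 25), "overlap")
})

test_that("profile is symmetric under swapping voices and negating the offset", {
  vA <- sonify(random_cds(30, seed = 11))
  vB <- sonify(random_cds(24, seed = 12))
  for (off in c(-4, 0, 3)) {
    p1 <- consonance_profile(vA, vB, off)
    p2 <- consonance_profile(vB, vA, -off)
    expect_equal(p1$f_unison, p2$f_unison)
    expect_equal(p1$f_p45, p2$f_p45)
    expect_equal(p1$overlap_bars, p2$overlap_bars)
  }
})

test_that("random degree pairs hit the enumerated consonance rate", {
  # oracle: exhaustive enumeration over all 7 x 7 degree pairs
  degs <- names(ORACLE_SEMITONES)
  hits <- 0L
  for (a in degs) {
    for (b in degs) {
      d <- abs(ORACLE_SEMITONES[[a]] - ORACLE_SEMITONES[[b]]) %% 12
      if (d %in% c(0, 5, 7)) hits <- hits + 1L
    }
  }
  expected <- hits / 49
  n <- 4000
  set.seed(99)
  vA <- degrees_voice(sample(degs, n, replace = TRUE))
  vB <- degrees_voice(sample(degs, n, replace = TRUE))
  got <- consonance_profile(vA, vB, 0)$f_cons
  tol <- 4 * sqrt(expected * (1 - expected) / n)
  expect_lt(abs(got - expected), tol)
})

test_that("best_offset recovers a planted shift and prefers offset 0 on ties", {
  cds <- random_cds(40, seed = 21)
  vA <- sonify(cds)
  vB <- sonify(paste0(random_cds(5, seed = 22), cds))  # A delayed 5 bars in B
  bo <- best_offset(vA, vB, max_offset = 8)
  expect_equal(bo$offset, 5L)
  expect_equal(bo$profile$f_unison, 1)

  bo <- best_offset(vA, vA, max_offset = 8)
  expect_equal(bo$offset, 0L)
  expect_error(best_offset(vA, vB, max_offset = 45), "smaller")
})

test_that("permutation test is reproducible, extreme for self-comparison, and degenerate on constant voices", {
  v <- sonify(random_cds(40, seed = 31))
  r1 <- permutation_test(v, v, 0, n_perm = 999, seed = 5)
  r2 <- permutation_test(v, v, 0, n_perm = 999, seed = 5)
  expect_identical(r1$null_samples, r2$null_samples)
  expect_equal(r1$p_value, 0.001)

  const <- sonify(strrep("TGC", 10))
  r <- permutation_test(const, const, 0, n_perm = 99, seed = 1)
  expect_equal(r$p_value, 1)
  expect_true(all(r$null_samples == r$observed))

  expect_error(permutation_test(v, v, 0, n_perm = 5), "n_perm")
})

test_that("permutation test p-values respect their defined bounds", {
  vA <- sonify(random_cds(20, seed = 41))
  vB <- sonify(random_cds(20, seed = 42))
  r <- permutation_test(vA, vB, 0, n_perm = 49, seed = 3)
  expect_gte(r$p_value, 1 / 50)
  expect_lte(r$p_value, 1)
})

test_that("unison_runs finds exactly a planted identical block", {
  set.seed(7)
  n <- 30
  cdsA <- random_cds(n, seed = 51)
  codA <- substring(cdsA, 3 * seq_len(n) - 2, 3 * seq_len(n))
  vA <- sonify(cdsA)
  gridA <- matrix(sample_grid(vA), nrow = 6)
  # B: same as A in bars 11..14 (1-based), slot-distinct everywhere else
  codB <- codA
  m <- default_mapping()
  for (i in setdiff(seq_len(n), 11:14)) {
    repeat {
      cand <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                    collapse = "")
      g <- sample_grid(sonify(cand))
      if (any(g != gridA[, i])) {
        codB[i] <- cand
        break
      }
    }
  }
  vB <- sonify(paste(codB, collapse = ""))
  runs <- unison_runs(consonance_profile(vA, vB, 0), min_len = 4)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$start_bar, 10L)  # 0-based
  expect_equal(runs$end_bar, 13L)
  expect_equal(runs$length_bars, 4L)

  # identical voices: one full-length run
  runs <- unison_runs(consonance_profile(vA, vA, 0), min_len = 3)
  expect_equal(runs$start_bar, 0L)
  expect_equal(runs$end_bar, n - 1L)
})

test_that("imitation_lags detects canons at the planted lag", {
  cp <- canon_pair(25, lag = 3, seed = 61)
  vA <- sonify(cp$a)
  vB <- sonify(cp$b)
  hits <- imitation_lags(vA, vB, min_len = 6)
  expect_true(any(hits$lag_bars == 3 & hits$start_index == 0 &
                    hits$length_bars == 25))

  # unrelated voices: no long common run
  v1 <- sonify(random_cds(40, seed = 62))
  v2 <- sonify(random_cds(40, seed = 63))
  expect_equal(nrow(imitation_lags(v1, v2, min_len = 6)), 0L)
})

test_that("conservation_summary ranks an identical pair first and stays symmetric", {
  cds <- random_cds(30, seed = 71)
  voices <- list(a = sonify(cds, label = "a"),
                 b = sonify(cds, label = "b"),
                 c = sonify(random_cds(30, seed = 72), label = "c"))
  s <- conservation_summary(voices, max_offset = 5, min_run = 2)
  expect_equal(nrow(s), 3L)
  top <- s[which.max(s$f_unison), ]
  expect_setequal(c(top$voice_a, top$voice_b), c("a", "b"))
  expect_equal(top$f_unison, 1)

  m <- pairwise_matrix(s, "f_unison")
  expect_true(isSymmetric(m))
  expect_equal(m["a", "b"], 1)
})

test_that("paralog pairs at higher identity are more unison (seeded check)", {
  mean_unison <- function(identity, seeds) {
    mean(vapply(seeds, function(s) {
      pp <- paralog_pair(80, identity, seed = s)
      consonance_profile(sonify(pp$a), sonify(pp$b), 0)$f_unison
    }, 0))
  }
  lo <- mean_unison(0.4, 1:10)
  hi <- mean_unison(0.8, 1:10)
  expect_gt(hi, lo)
})
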