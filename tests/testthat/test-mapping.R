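test_that("default mapping carries the attested codon bars", {
  m <- default_mapping()
  expect_s3_class(m, "codon_mapping")
  expect_equal(nrow(m), 64L)
  attested <- list(
    UGC = list("T", 1L, 3),
    CAA = list("MF", 2L, c(2, 1)),
    UCG = list("SR", 1L, c(2, 1)),
    UCC = list("SMR", 1L, c(2, 0.5, 0.5)),
    GCG = list("DRR", 2L, c(1.5, 0.5, 1)),
    GCC = list("DRMR", 2L, c(1.5, 0.5, 0.5, 0.5)),
    GGA = list("SL", 2L, c(2, 1)),
    GGC = list("SLDR", 2L, c(1.5, 0.5, 0.5, 0.5)),
    UCA = list("S", 1L, 3),
    UCU = list("SL", 1L, c(1.5, 1.5))  # SL collides with GGA: dotted quarters
  )
  for (cd in names(attested)) {
    i <- match(cd, m$codon)
    expect_equal(m$formula[i], attested[[cd]][[1]], label = cd)
    expect_equal(m$base_size[i], attested[[cd]][[2]], label = cd)
    expect_equal(rhythm_for(cd, m)$durations, attested[[cd]][[3]], label = cd)
    expect_equal(m$provenance[i], "paper", label = cd)
  }
  expect_true("SL" %in% attr(m, "collision_set"))
})

test_that("every bar of every codon fills exactly three beats from the allowed durations", {
  m <- default_mapping()
  for (i in seq_len(nrow(m))) {
    d <- rhythm_for(m$codon[i], m)$durations
    expect_equal(sum(d), 3, label = m$codon[i])
    expect_true(all(d %in% c(3, 2, 1.5, 1, 0.5)), label = m$codon[i])
  }
})

test_that("the shipped mapping is injective over (pitches, durations)", {
  m <- default_mapping()
  key <- paste(m$formula, m$durations)
  expect_equal(anyDuplicated(key), 0L)
})

test_that("mapping validation rejects broken tables", {
  m <- default_mapping()
  tmp <- tempfile(fileext = ".tsv")
  write_tab <- function(df) {
    write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    tmp
  }
  df <- as.data.frame(m)[, c("codon", "formula", "base_size", "provenance")]

  expect_error(load_mapping(write_tab(df[df$codon != "AAA", ])), "AAA")

  bad <- df; bad$base_size[bad$codon == "GGA"] <- 1L
  expect_error(load_mapping(write_tab(bad)), "attested")

  bad <- df; bad$formula[bad$codon == "AAA"] <- "DRMRS"
  expect_error(load_mapping(write_tab(bad)), "length out of range")

  bad <- df; bad$base_size[bad$codon == "AAA"] <- 3L
  expect_error(load_mapping(write_tab(bad)), "base_size")

  bad <- df; bad$formula[bad$codon == "AAA"] <- "DQ"
  expect_error(load_mapping(write_tab(bad)), "non-solfege")
})

test_that("a user table resolving a collision by rhythm only warns", {
  m <- default_mapping()
  df <- as.data.frame(m)[, c("codon", "formula", "base_size", "provenance")]
  # make AAA a duplicate bar of AAG (same formula and base size)
  df$formula[df$codon == "AAA"] <- df$formula[df$codon == "AAG"]
  tmp <- tempfile(fileext = ".tsv")
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(load_mapping(tmp), "not injective")
})

test_that("solfege degrees form the fixed seven-member bijection", {
  d <- solfege_degrees()
  expect_equal(nrow(d), 7L)
  expect_equal(d$semitone_offset, c(0L, 2L, 4L, 5L, 7L, 9L, 11L))
  expect_equal(anyDuplicated(d$letter), 0L)
  expect_equal(formula_semitones("SMR")[[1]], c(7L, 4L, 2L))
  expect_error(formula_semitones("SQ"), "unknown solfege")
})
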