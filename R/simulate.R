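# Seeded generators for every input the analyses consume. They emulate the
# statistical structure the methods assume (random codons, codon-level
# divergence, canonic delays, categorical interaction tables, exponential
# calibration standards) -- not biological realism: no codon-usage bias, no
# dN/dS, no chromatographic peak shapes.

#' Random coding sequence
#'
#' @param n_codons number of codons.
#' @param seed integer seed (bit-reproducible output).
#' @param base_probs probabilities of `A`,`C`,`G`,`T` at each position.
#' @return DNA string of length `3 * n_codons`.
#' @examples
#' random_cds(4, seed = 1)
#' @export
random_cds <- function(n_codons, seed, base_probs = rep(0.25, 4)) {
  stopifnot(n_codons >= 0, length(base_probs) == 4, all(base_probs >= 0))
  if (n_codons == 0) return("")
  with_seed(derive_seed(seed, "cds"), {
    paste(sample(c("A", "C", "G", "T"), 3 * n_codons, replace = TRUE,
                 prob = base_probs), collapse = "")
  })
}

#' Paralog pair at a target codon identity
#'
#' Generates a random CDS and a derived copy in which a fixed number of
#' codons -- `round((1 - target_identity) * n_codons)` -- are substituted by
#' different random codons, so the realized codon-level identity matches the
#' target up to rounding. Substitution acts on whole codons because bars
#' (codons) are the comparison unit of the ensemble analyses.
#'
#' @param n_codons number of codons.
#' @param target_identity desired fraction of identical codons, in `[0, 1]`.
#' @param seed integer seed.
#' @return list with `a`, `b` (DNA strings) and `identity` (realized codon
#'   identity).
#' @export
paralog_pair <- function(n_codons, target_identity, seed) {
  stopifnot(n_codons >= 1, target_identity >= 0, target_identity <= 1)
  a <- random_cds(n_codons, seed)
  k <- round((1 - target_identity) * n_codons)
  codons <- substring(a, 3 * seq_len(n_codons) - 2, 3 * seq_len(n_codons))
  with_seed(derive_seed(seed, "paralog"), {
    pos <- if (k > 0) sample.int(n_codons, k) else integer(0)
    for (i in pos) {
      repeat {
        cand <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                      collapse = "")
        if (cand != codons[i]) break
      }
      codons[i] <- cand
    }
  })
  b <- paste(codons, collapse = "")
  ca <- substring(a, 3 * seq_len(n_codons) - 2, 3 * seq_len(n_codons))
  list(a = a, b = b, identity = mean(ca == codons))
}

#' Canon pair: a voice and its delayed restatement
#'
#' `b` consists of `lag` random filler codons followed by the full sequence
#' of `a`, so the second voice imitates the first at the given lag.
#'
#' @param n_codons codons in the leading voice.
#' @param lag delay in codons (> 0).
#' @param seed integer seed.
#' @return list with `a` and `b` (DNA strings; `b` has `n_codons + lag`
#'   codons).
#' @export
canon_pair <- function(n_codons, lag, seed) {
  stopifnot(n_codons >= 1)
  lag <- as.integer(lag)
  if (lag <= 0L) stop("lag must be > 0")
  a <- random_cds(n_codons, seed)
  fill <- with_seed(derive_seed(seed, "canonfill"), {
    paste(sample(c("A", "C", "G", "T"), 3 * lag, replace = TRUE), collapse = "")
  })
  list(a = a, b = paste0(fill, a))
}

#' Random two-hybrid interaction table
#'
#' Generates `n` synthetic records with categories drawn from
#' `category_probs`, in the TSV schema read by [parse_interactions()].
#'
#' @param n number of records.
#' @param category_probs named probabilities over categories
#'   `A`,`B`,`C`,`D`,`E`,`F`,`NA`.
#' @param seed integer seed.
#' @param path optional path; when given the table is also written as TSV
#'   (byte-stable for a fixed seed).
#' @return The table as a data.frame.
#' @export
random_interaction_table <- function(n,
                                     category_probs = c(A = 0.1, B = 0.1,
                                                        C = 0.2, D = 0.6),
                                     seed = 1L, path = NULL) {
  stopifnot(n >= 0, all(category_probs >= 0), sum(category_probs) > 0)
  cats <- names(category_probs)
  stopifnot(!is.null(cats), all(cats %in% c("A", "B", "C", "D", "E", "F", "NA")))
  tab <- with_seed(derive_seed(seed, "y2h"), {
    data.frame(
      name = sprintf("SYNP%04d", seq_len(n)),
      description = sprintf("synthetic prey protein %d", seq_len(n)),
      accession = sprintf("SYN%05d", seq_len(n)),
      category = if (n > 0) sample(cats, n, replace = TRUE,
                                   prob = category_probs) else character(0),
      nfkb_flag = FALSE, gene_match_flag = FALSE,
      stringsAsFactors = FALSE)
  })
  if (!is.null(path)) {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tab
}

#' Synthetic size-exclusion calibration standards
#'
#' Standards lying on the exponential model `MW = a * exp(-b * Kav)`, with
#' optional multiplicative lognormal noise; partition coefficients are evenly
#' spread in (0, 1) and elution volumes back-computed from the column
#' geometry, so every standard elutes between the void and geometric volumes.
#'
#' @param a model intercept in Da.
#' @param b decay rate per unit Kav.
#' @param n number of standards (>= 3, matching what a fit needs).
#' @param noise_sd standard deviation of the lognormal noise (0 = exact).
#' @param seed integer seed (ignored when `noise_sd` is 0).
#' @param geometry a [sec_geometry()].
#' @param path optional CSV output path (`name,mw_kda,ve_ml`).
#' @return data.frame with `name`, `mw_kda`, `ve_ml`.
#' @export
synthetic_sec_standards <- function(a = 166086, b = 3.377, n = 5,
                                    noise_sd = 0, seed = 1L,
                                    geometry = sec_geometry(), path = NULL) {
  stopifnot(a > 0, b > 0, noise_sd >= 0)
  if (n < 3) stop("at least 3 standards are required for a calibration fit")
  kav <- seq(0.1, 0.9, length.out = n)
  mw_da <- a * exp(-b * kav)
  if (noise_sd > 0) {
    mw_da <- with_seed(derive_seed(seed, "sec"), {
      mw_da * exp(stats::rnorm(n, 0, noise_sd))
    })
  }
  out <- data.frame(name = sprintf("STD%d", seq_len(n)),
                    mw_kda = mw_da / 1000,
                    ve_ml = geometry$vo + kav * (geometry$vc - geometry$vo))
  if (!is.null(path)) {
    write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  }
  out
}
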