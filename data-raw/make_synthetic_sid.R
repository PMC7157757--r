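# Builds inst/extdata/synthetic_akr_sid_proteins.fasta: a SYNTHETIC stand-in
# triplet of akirin-like proteins (no real UniProt sequences are shipped).
# One 210-residue base protein is sampled uniformly over the 20 amino acids;
# two paralogs derive from it by substituting 20% of positions each,
# independently, which puts pairwise identities of the SID stretches well
# above the 60% working range the SID analyses target.
# Run from the repository root: Rscript data-raw/make_synthetic_sid.R

set.seed(20260919)
aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
n <- 210
base <- sample(aa, n, replace = TRUE)

mutate <- function(x, rate) {
  pos <- which(runif(length(x)) < rate)
  for (i in pos) x[i] <- sample(setdiff(aa, x[i]), 1)
  x
}

p1 <- base                      # AKR2-like
p2 <- mutate(base, 0.20)        # AKR1-like paralog
p3 <- mutate(base, 0.20)        # SUB-like ortholog

lines <- c(
  ">SYN_AKR2 synthetic akirin2-like protein (not a UniProt sequence)",
  paste(p1, collapse = ""),
  ">SYN_AKR1 synthetic akirin1-like paralog (not a UniProt sequence)",
  paste(p2, collapse = ""),
  ">SYN_SUB synthetic subolesin-like ortholog (not a UniProt sequence)",
  paste(p3, collapse = ""))
writeLines(lines, "inst/extdata/synthetic_akr_sid_proteins.fasta")
cat("identities vs base:", mean(p1 == p2), mean(p1 == p3), mean(p2 == p3), "\n")
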