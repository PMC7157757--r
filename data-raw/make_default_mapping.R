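# Builds inst/extdata/codon_mapping.tsv: the shipped default 64-codon table.
#
# Ten assignments are attested by the source algorithm and fixed verbatim.
# The other 54 follow a deterministic convention documented in
# ?default_mapping and the methods vignette:
#   * base size: first base U -> 1 note, A/C/G -> 2 notes
#   * base formula: per dinucleotide prefix; prefixes not covered by an
#     attested entry take, in alphabetical prefix order, the first unused
#     formula in scale order (D < R < M < F < S < L < T)
#   * appendage: third base A -> none, G -> R, U -> L, C -> MR; falls back to
#     M if the conventional bar would duplicate an attested one (UGA only)
# Run from the repository root: Rscript data-raw/make_default_mapping.R

scale <- c("D", "R", "M", "F", "S", "L", "T")
bases <- c("A", "C", "G", "U")
prefixes <- as.vector(t(outer(bases, bases, paste0)))  # alphabetical

attested <- data.frame(
  codon = c("UGC", "CAA", "UCG", "UCC", "GCG", "GCC", "GGA", "GGC", "UCA", "UCU"),
  formula = c("T", "MF", "SR", "SMR", "DRR", "DRMR", "SL", "SLDR", "S", "SL"),
  base_size = c(1L, 2L, 1L, 1L, 2L, 2L, 2L, 2L, 1L, 1L),
  stringsAsFactors = FALSE
)

base_size_of <- function(prefix) if (substr(prefix, 1, 1) == "U") 1L else 2L

# base formulas implied by the attested entries
attested_base <- vapply(seq_len(nrow(attested)), function(i) {
  substr(attested$formula[i], 1, attested$base_size[i])
}, "")
names(attested_base) <- substr(attested$codon, 1, 2)
attested_base <- attested_base[!duplicated(names(attested_base))]

candidates1 <- scale
candidates2 <- as.vector(t(outer(scale, scale, paste0)))  # DD, DR, DM, ...

# attested bases are reserved before any extended prefix is assigned
base_formula <- attested_base
for (p in setdiff(sort(unique(prefixes)), names(base_formula))) {
  cands <- if (base_size_of(p) == 1L) candidates1 else candidates2
  base_formula[p] <- setdiff(cands, base_formula)[1]
}

appendage <- c(A = "", C = "MR", G = "R", U = "L")

codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
codons <- sort(codons)
rows <- lapply(codons, function(cd) {
  i <- match(cd, attested$codon)
  if (!is.na(i)) {
    return(data.frame(codon = cd, formula = attested$formula[i],
                      base_size = attested$base_size[i], provenance = "paper"))
  }
  p <- substr(cd, 1, 2)
  b3 <- substr(cd, 3, 3)
  f <- paste0(base_formula[[p]], appendage[[b3]])
  sz <- base_size_of(p)
  # repair: never duplicate an attested (formula, base_size) bar
  if (any(attested$formula == f & attested$base_size == sz)) {
    f <- paste0(base_formula[[p]], "M")
  }
  data.frame(codon = cd, formula = f, base_size = sz, provenance = "extended")
})
tab <- do.call(rbind, rows)

# injectivity check against the same rhythm rules the package applies
collision <- intersect(tab$formula[tab$base_size == 1], tab$formula[tab$base_size == 2])
dur <- mapply(function(sz, nf, col) {
  key <- paste0(sz, nf)
  switch(key,
         "10" = "3", "11" = if (col) "1.5,1.5" else "2,1", "12" = "2,0.5,0.5",
         "20" = "2,1", "21" = "1.5,0.5,1", "22" = "1.5,0.5,0.5,0.5")
}, tab$base_size, nchar(tab$formula) - tab$base_size,
   tab$base_size == 1 & tab$formula %in% collision)
stopifnot(!anyDuplicated(paste(tab$formula, dur)))

write.table(tab, "inst/extdata/codon_mapping.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", nrow(tab), "codons; collision set:", paste(collision, collapse = " "), "\n")
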