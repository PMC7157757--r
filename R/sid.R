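# Selected interacting domains (SIDs): extraction, global alignment,
# percent identity, and protective-epitope coverage. The aligner is an
# in-package Needleman-Wunsch with affine gaps; a gap of length L costs
# gap_open + L * gap_extend, matching the usual convention, with BLOSUM62
# (loaded from Biostrings) as the default substitution matrix.

.AA_LETTERS <- strsplit("ARNDCQEGHILKMFPSTWYVBZX*", "")[[1]]

.default_submat <- function() {
  if (is.null(.mapping_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .mapping_cache$blosum62 <- e$BLOSUM62
  }
  .mapping_cache$blosum62
}

#' Load a substitution matrix from a TSV file
#'
#' Square matrix with amino-acid letters as header and row names, tab
#' separated, as an override for the default BLOSUM62.
#'
#' @param path TSV file.
#' @return Numeric matrix with dimnames.
#' @export
read_submat <- function(path) {
  tab <- read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop("substitution matrix must be square with matching row/column names")
  }
  m
}

#' A SID region on a protein
#'
#' @param protein_id accession of the protein.
#' @param start,end 1-based inclusive residue coordinates.
#' @return A `sid_region` list.
#' @export
sid_region <- function(protein_id, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    stop("invalid region: need 1 <= start <= end")
  }
  structure(list(protein_id = protein_id, start = start, end = end),
            class = "sid_region")
}

#' Extract a region from a protein sequence
#'
#' @param sequence protein sequence string.
#' @param region a [sid_region()].
#' @return The subsequence, of length `end - start + 1`.
#' @examples
#' extract_region("MQSTAILKR", sid_region("p", 2, 4))  # "QST"
#' @export
extract_region <- function(sequence, region) {
  stopifnot(inherits(region, "sid_region"))
  if (region$end > nchar(sequence)) {
    stop("region ", region$start, "-", region$end,
         " out of bounds for sequence of length ", nchar(sequence))
  }
  substr(sequence, region$start, region$end)
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch over the full lengths of both sequences. A gap of length
#' L costs `gap_open + L * gap_extend`. Traceback ties are broken
#' deterministically: substitution first, then gap in the second sequence,
#' then gap in the first.
#'
#' @param a,b protein sequences (non-empty strings).
#' @param submat substitution matrix (default BLOSUM62 from Biostrings).
#' @param gap_open,gap_extend non-negative gap penalties.
#' @return An `aligned_pair`: list with gapped strings `a`, `b` (equal
#'   length) and the alignment `score`.
#' @examples
#' align_pair("ACDE", "ACDF")$score
#' @export
align_pair <- function(a, b, submat = .default_submat(),
                       gap_open = 10, gap_extend = 0.5) {
  stopifnot(nchar(a) > 0, nchar(b) > 0, gap_open >= 0, gap_extend >= 0)
  sa <- strsplit(toupper(a), "")[[1]]
  sb <- strsplit(toupper(b), "")[[1]]
  bad <- setdiff(c(sa, sb), rownames(submat))
  if (length(bad) > 0L) {
    stop("non-amino-acid character(s): ", paste(unique(bad), collapse = ", "))
  }
  n <- length(sa); m <- length(sb)
  NEG <- -1e9
  # three-state affine DP: M (aligned pair), X (gap in b), Y (gap in a)
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1, 1] <- 0
  for (i in 2L:(n + 1L)) X[i, 1] <- -gap_open - (i - 1) * gap_extend
  for (j in 2L:(m + 1L)) Y[1, j] <- -gap_open - (j - 1) * gap_extend
  sub <- submat[sa, sb, drop = FALSE]
  for (i in 2L:(n + 1L)) {
    Mi1 <- M[i - 1L, ]; Xi1 <- X[i - 1L, ]; Yi1 <- Y[i - 1L, ]
    Xrow <- X[i, ]; Mrow <- M[i, ]; Yrow <- Y[i, ]
    for (j in 2L:(m + 1L)) {
      best_prev <- max(Mi1[j - 1L], Xi1[j - 1L], Yi1[j - 1L])
      Mrow[j] <- best_prev + sub[i - 1L, j - 1L]
      Xrow[j] <- max(max(Mi1[j], Yi1[j]) - gap_open - gap_extend,
                     Xi1[j] - gap_extend)
      Yrow[j] <- max(max(Mrow[j - 1L], Xrow[j - 1L]) - gap_open - gap_extend,
                     Yrow[j - 1L] - gap_extend)
    }
    M[i, ] <- Mrow; X[i, ] <- Xrow; Y[i, ] <- Yrow
  }
  score <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  # traceback with deterministic tie-breaking: M, then X (gap in b), then Y
  eps <- 1e-9
  i <- n + 1L; j <- m + 1L
  state <- if (M[i, j] >= score - eps) "M" else
           if (X[i, j] >= score - eps) "X" else "Y"
  ra <- character(0); rb <- character(0)
  while (i > 1L || j > 1L) {
    if (state == "M") {
      ra <- c(sa[i - 1L], ra); rb <- c(sb[j - 1L], rb)
      val <- M[i, j] - sub[i - 1L, j - 1L]
      i <- i - 1L; j <- j - 1L
      state <- if (i == 1L && j == 1L) "M"
               else if (abs(M[i, j] - val) < eps) "M"
               else if (abs(X[i, j] - val) < eps) "X" else "Y"
    } else if (state == "X") {
      ra <- c(sa[i - 1L], ra); rb <- c("-", rb)
      val <- X[i, j]
      i <- i - 1L
      state <- if (abs(M[i, j] - gap_open - gap_extend - val) < eps) "M"
               else if (abs(X[i, j] - gap_extend - val) < eps) "X" else "Y"
    } else {
      ra <- c("-", ra); rb <- c(sb[j - 1L], rb)
      val <- Y[i, j]
      j <- j - 1L
      state <- if (abs(M[i, j] - gap_open - gap_extend - val) < eps) "M"
               else if (abs(X[i, j] - gap_open - gap_extend - val) < eps) "X"
               else "Y"
    }
  }
  structure(list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""),
                 score = score, gap_open = gap_open, gap_extend = gap_extend),
            class = "aligned_pair")
}

#' Percent identity of an aligned pair
#'
#' `100 * identical columns / mutually non-gap columns`.
#'
#' @param aligned an `aligned_pair` from [align_pair()].
#' @return Percentage in `[0, 100]`.
#' @export
percent_identity <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_pair"))
  ca <- strsplit(aligned$a, "")[[1]]
  cb <- strsplit(aligned$b, "")[[1]]
  both <- ca != "-" & cb != "-"
  if (!any(both)) return(0)
  100 * sum(ca[both] == cb[both]) / sum(both)
}

#' Project a region from one protein onto a homolog
#'
#' Aligns the two full-length sequences and maps the region's 1-based
#' coordinates through the alignment columns; useful when a SID is known on
#' one protein and the homologous stretch is wanted on another. Region
#' endpoints falling in gaps move inward to the nearest aligned residue.
#'
#' @param from_seq sequence carrying the known region.
#' @param to_seq homologous sequence to project onto.
#' @param region a [sid_region()] in `from_seq` coordinates.
#' @param ... passed to [align_pair()].
#' @return A [sid_region()] in `to_seq` coordinates.
#' @export
project_region <- function(from_seq, to_seq, region, ...) {
  stopifnot(inherits(region, "sid_region"))
  al <- align_pair(from_seq, to_seq, ...)
  ca <- strsplit(al$a, "")[[1]]
  cb <- strsplit(al$b, "")[[1]]
  pos_a <- cumsum(ca != "-")
  pos_b <- cumsum(cb != "-")
  cols <- which(pos_a >= region$start & pos_a <= region$end &
                  ca != "-" & cb != "-")
  if (length(cols) == 0L) {
    stop("region does not project onto any aligned residue")
  }
  sid_region(region$protein_id, pos_b[min(cols)], pos_b[max(cols)])
}

#' Mean and minimum pairwise identity of a set of SIDs
#'
#' Aligns every pair of SID sequences and reports both the mean and the
#' minimum pairwise identity (the field-standard summary is ambiguous between
#' the two, so both are returned).
#'
#' @param seqs named character vector of SID sequences (>= 2).
#' @param ... passed to [align_pair()].
#' @return List with `pairwise` (data.frame of pairs and identities),
#'   `mean_identity`, `min_identity`.
#' @export
sid_identity <- function(seqs, ...) {
  stopifnot(length(seqs) >= 2L)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  pairs <- utils::combn(length(seqs), 2)
  rows <- apply(pairs, 2, function(ij) {
    al <- align_pair(seqs[[ij[1]]], seqs[[ij[2]]], ...)
    data.frame(a = names(seqs)[ij[1]], b = names(seqs)[ij[2]],
               identity = percent_identity(al), stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, rows)
  list(pairwise = pw, mean_identity = mean(pw$identity),
       min_identity = min(pw$identity))
}

#' Read epitope intervals from a BED-like TSV
#'
#' Columns `protein_id`, `start`, `end`, `label`, `source`. Coordinates in
#' the file follow BED convention (0-based, half-open) and are converted to
#' the 1-based inclusive coordinates used throughout this package.
#'
#' @param path TSV file.
#' @param bed logical; set `FALSE` if the file is already 1-based inclusive.
#' @return data.frame with 1-based inclusive `start`, `end`.
#' @export
read_epitopes <- function(path, bed = TRUE) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "start", "end")
  if (!all(need %in% names(tab))) {
    stop("epitope table must have columns: ", paste(need, collapse = ", "))
  }
  if (bed) tab$start <- tab$start + 1L
  if (any(tab$start > tab$end)) stop("epitope interval with start > end")
  tab
}

#' Epitope coverage of a SID
#'
#' Fraction of the region's residues covered by the union of the epitope
#' intervals: overlapping intervals are merged, clipped to the region, and
#' the covered residue count is divided by the region length. Intervals
#' entirely outside the region contribute nothing.
#'
#' @param intervals data.frame with 1-based inclusive `start`, `end` (e.g.
#'   from [read_epitopes()]), in the region's coordinate system.
#' @param region a [sid_region()].
#' @return Percentage in `[0, 100]`.
#' @examples
#' epitope_coverage(data.frame(start = c(10, 15), end = c(20, 30)),
#'                  sid_region("p", 1, 100))  # 21
#' @export
epitope_coverage <- function(intervals, region) {
  stopifnot(inherits(region, "sid_region"))
  if (is.null(intervals) || nrow(intervals) == 0L) return(0)
  ir <- IRanges::IRanges(start = as.integer(intervals$start),
                         end = as.integer(intervals$end))
  merged <- IRanges::reduce(ir)
  clipped <- IRanges::restrict(merged, start = region$start, end = region$end)
  covered <- sum(IRanges::width(clipped))
  100 * covered / (region$end - region$start + 1L)
}
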