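#' @importFrom utils read.delim write.table head
NULL

# The ten codon assignments attested in the source algorithm description.
# These are immutable: any mapping table that contradicts them is rejected.
.ATTESTED_ENTRIES <- data.frame(
  codon = c("UGC", "CAA", "UCG", "UCC", "GCG", "GCC", "GGA", "GGC", "UCA", "UCU"),
  formula = c("T", "MF", "SR", "SMR", "DRR", "DRMR", "SL", "SLDR", "S", "SL"),
  base_size = c(1L, 2L, 1L, 1L, 2L, 2L, 2L, 2L, 1L, 1L),
  stringsAsFactors = FALSE
)

.RNA_BASES <- c("A", "C", "G", "U")
.ALL_CODONS <- as.vector(outer(
  outer(.RNA_BASES, .RNA_BASES, paste0), .RNA_BASES, paste0
))

#' Rhythm of a codon bar
#'
#' Every codon occupies one 3/4 bar (three quarter-note beats). The rhythm is
#' fully determined by the size of the melodic base (1 or 2 notes), the number
#' of following notes (0-2), and whether the formula is shared between a
#' one-note-base and a two-note-base codon (a "collision", disambiguated by a
#' distinct metric scheme):
#'
#' * base 1, 0 following: dotted half note, `3.0`
#' * base 1, 1 following: half + quarter `2.0, 1.0`; if the formula collides
#'   with a two-note base, two dotted quarters `1.5, 1.5`
#' * base 1, 2 following: half + two eighths `2.0, 0.5, 0.5`
#' * base 2, 0 following: half + quarter `2.0, 1.0`
#' * base 2, 1 following: dotted quarter + eighth + quarter `1.5, 0.5, 1.0`
#' * base 2, 2 following: dotted quarter + eighth + two eighths
#'   `1.5, 0.5, 0.5, 0.5`
#'
#' Durations always sum to exactly 3 beats.
#'
#' @param codon an RNA codon present in `mapping` (DNA `T` accepted).
#' @param mapping a [codon_mapping] object.
#' @return A list with `base_size`, `n_follow`, `durations` (beats, quarter
#'   note = 1) and `collision_variant`.
#' @examples
#' m <- default_mapping()
#' rhythm_for("UCC", m)$durations  # 2.0 0.5 0.5
#' rhythm_for("UCU", m)$durations  # 1.5 1.5 (formula SL collides with GGA)
#' @export
rhythm_for <- function(codon, mapping) {
  stopifnot(inherits(mapping, "codon_mapping"))
  codon <- .normalize_codons(codon)
  i <- match(codon, mapping$codon)
  if (is.na(i)) stop("codon not in mapping: ", codon)
  list(
    base_size = mapping$base_size[i],
    n_follow = mapping$n_follow[i],
    durations = .parse_durations(mapping$durations[i]),
    collision_variant = mapping$collision[i]
  )
}

.rhythm_durations <- function(base_size, n_follow, collision) {
  key <- paste0(base_size, n_follow)
  if (key == "10") return("3")
  if (key == "11") return(if (collision) "1.5,1.5" else "2,1")
  if (key == "12") return("2,0.5,0.5")
  if (key == "20") return("2,1")
  if (key == "21") return("1.5,0.5,1")
  if (key == "22") return("1.5,0.5,0.5,0.5")
  stop("invalid rhythm class: base_size ", base_size, ", n_follow ", n_follow)
}

.parse_durations <- function(x) as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])

.normalize_codons <- function(codons) {
  codons <- toupper(codons)
  chartr("T", "U", codons)
}

#' Load and validate a codon-to-melody mapping table
#'
#' Reads a TSV with columns `codon`, `formula`, `base_size` and (optionally)
#' `provenance`, covering all 64 codons, and turns it into a validated
#' `codon_mapping`. Validation enforces: completeness (64 RNA codons),
#' formula length 1-4 over the solfège letters, base size 1 or 2 with at most
#' two following notes, and agreement with the ten attested codon assignments,
#' which are immutable. Formulas that occur with both base sizes form the
#' *collision set*; their one-note-base rhythm switches to two dotted quarters
#' so that every codon keeps a distinct bar. If a user table still leaves two
#' codons with identical pitches and durations the loader warns (detokenize
#' will then refuse to invert those bars).
#'
#' @param path path to a mapping TSV. The package default lives at
#'   `system.file("extdata", "codon_mapping.tsv", package = "musicodon")`.
#' @return A `codon_mapping`: a data.frame with columns `codon`, `formula`,
#'   `base_size`, `n_follow`, `provenance`, `collision`, `durations`, plus a
#'   `collision_set` attribute.
#' @seealso [default_mapping()], [rhythm_for()], [sonify()]
#' @examples
#' m <- load_mapping(system.file("extdata", "codon_mapping.tsv",
#'                               package = "musicodon"))
#' subset(m, codon == "UGC")
#' @export
load_mapping <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("codon", "formula", "base_size")
  if (!all(need %in% names(tab))) {
    stop("mapping table must have columns: ", paste(need, collapse = ", "))
  }
  tab$codon <- .normalize_codons(tab$codon)
  tab$formula <- toupper(tab$formula)
  tab$base_size <- suppressWarnings(as.integer(tab$base_size))
  if (is.null(tab$provenance)) tab$provenance <- "extended"
  .build_mapping(tab[, c("codon", "formula", "base_size", "provenance")],
                 mapping_id = basename(path))
}

.build_mapping <- function(tab, mapping_id = "custom") {
  missing <- setdiff(.ALL_CODONS, tab$codon)
  if (length(missing) > 0L) {
    stop("mapping is missing codon(s): ", paste(missing, collapse = ", "))
  }
  dup <- tab$codon[duplicated(tab$codon)]
  if (length(dup) > 0L) {
    stop("duplicated codon(s) in mapping: ", paste(unique(dup), collapse = ", "))
  }
  extra <- setdiff(tab$codon, .ALL_CODONS)
  if (length(extra) > 0L) {
    stop("invalid codon(s) in mapping: ", paste(extra, collapse = ", "))
  }
  if (anyNA(tab$base_size) || !all(tab$base_size %in% c(1L, 2L))) {
    stop("base_size must be 1 or 2 for every codon")
  }
  flen <- nchar(tab$formula)
  if (any(flen < 1L | flen > 4L)) {
    stop("formula length out of range (1-4) for codon(s): ",
         paste(tab$codon[flen < 1L | flen > 4L], collapse = ", "))
  }
  bad <- grepl(paste0("[^", paste(.SOLFEGE_LETTERS, collapse = ""), "]"), tab$formula)
  if (any(bad)) {
    stop("formula contains non-solfege letters for codon(s): ",
         paste(tab$codon[bad], collapse = ", "))
  }
  tab$n_follow <- flen - tab$base_size
  if (any(tab$n_follow < 0L | tab$n_follow > 2L)) {
    stop("number of following notes must be 0-2 for codon(s): ",
         paste(tab$codon[tab$n_follow < 0L | tab$n_follow > 2L], collapse = ", "))
  }
  # attested entries are immutable
  at <- .ATTESTED_ENTRIES
  got <- tab[match(at$codon, tab$codon), ]
  conflict <- got$formula != at$formula | got$base_size != at$base_size
  if (any(conflict)) {
    stop("mapping contradicts attested codon assignment(s): ",
         paste(sprintf("%s (expected %s/%d, got %s/%d)",
                       at$codon[conflict], at$formula[conflict],
                       at$base_size[conflict], got$formula[conflict],
                       got$base_size[conflict]), collapse = "; "))
  }
  collision_set <- intersect(tab$formula[tab$base_size == 1L],
                             tab$formula[tab$base_size == 2L])
  tab$collision <- tab$formula %in% collision_set
  tab$durations <- mapply(.rhythm_durations, tab$base_size, tab$n_follow,
                          tab$collision & tab$base_size == 1L)
  key <- paste(tab$formula, tab$durations)
  if (anyDuplicated(key)) {
    warning("mapping is not injective; identical bars for codons: ",
            paste(tab$codon[key %in% key[duplicated(key)]], collapse = ", "))
  }
  tab <- tab[order(match(tab$codon, .ALL_CODONS)), ]
  rownames(tab) <- NULL
  structure(tab,
            collision_set = sort(collision_set),
            mapping_id = mapping_id,
            class = c("codon_mapping", "data.frame"))
}

#' The shipped default 64-codon mapping
#'
#' Ten codon assignments are fixed by the source algorithm (provenance
#' `"paper"`); the remaining 54 are filled by a deterministic convention
#' (provenance `"extended"`): the first base selects the base size (`U` gives
#' a one-note base, `A`/`C`/`G` a two-note base), the dinucleotide prefix
#' selects the base formula (unassigned prefixes take the first unused
#' formula in scale order), and the third base selects the appended notes
#' (`A` none, `G` appends R, `U` appends L, `C` appends MR; the appendage
#' falls back to M in the single case where the convention would duplicate an
#' attested bar). The resulting table is injective: no two codons share both
#' pitches and durations. Pass your own table through [load_mapping()] to
#' override the extension.
#'
#' @return A `codon_mapping` (see [load_mapping()]).
#' @examples
#' m <- default_mapping()
#' attr(m, "collision_set")
#' @export
default_mapping <- function() {
  if (is.null(.mapping_cache$default)) {
    path <- system.file("extdata", "codon_mapping.tsv", package = "musicodon")
    .mapping_cache$default <- load_mapping(path)
  }
  .mapping_cache$default
}

.mapping_cache <- new.env(parent = emptyenv())

#' @export
print.codon_mapping <- function(x, ...) {
  cat(sprintf("codon_mapping '%s': 64 codons, %d attested, collision set {%s}\n",
              attr(x, "mapping_id"), sum(x$provenance == "paper"),
              paste(attr(x, "collision_set"), collapse = ", ")))
  print.data.frame(head(as.data.frame(x), 8))
  cat("...\n")
  invisible(x)
}
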