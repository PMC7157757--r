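# Yeast two-hybrid interaction records and their PBS confidence categories.
# PBS (Predicted Biological Score) is an e-value-based confidence rank:
# categories A-D partition (0, 1) by decreasing confidence; E marks
# promiscuous prey, F proven technical artifacts, and NA records that could
# not be scored. E/F/NA are assigned from annotation, never from an e-value.

.PBS_BREAKS <- c(0, 1e-10, 1e-5, 10^-2.5, 1)
.PBS_CATEGORIES <- c("A", "B", "C", "D", "E", "F", "NA")

#' Classify a PBS e-value into a confidence category
#'
#' Categories partition (0, 1): A in (0, 1e-10), B in \[1e-10, 1e-5), C in
#' \[1e-5, 1e-2.5), D in \[1e-2.5, 1). A value equal to a threshold falls in
#' the weaker (higher-lettered) category, matching the strict inequality
#' chain A < 1e-10 < B < 1e-5 < C < 1e-2.5 < D < 1.
#'
#' @param e_value numeric vector of e-values in (0, 1).
#' @return Character vector of categories (`"A"`-`"D"`).
#' @examples
#' classify_pbs(c(1e-12, 1e-10, 1e-3))  # "A" "B" "C"
#' @export
classify_pbs <- function(e_value) {
  if (any(e_value <= 0 | e_value >= 1)) {
    stop("e-values must lie strictly between 0 and 1 ",
         "(E, F and NA are annotation-assigned, not e-value-derived)")
  }
  # right-open intervals: a boundary value goes to the weaker category
  c("A", "B", "C", "D")[findInterval(e_value, .PBS_BREAKS,
                                     rightmost.closed = FALSE)]
}

#' Parse a two-hybrid interaction table
#'
#' Reads a TSV with columns `name`, `description`, `accession`, `category`
#' and logical flags `nfkb_flag` (prior NF-kB involvement) and
#' `gene_match_flag` (prey matched a gene sequence rather than a protein).
#' Validates categories and uniqueness of (name, accession) pairs.
#'
#' @param path TSV file.
#' @return An `interaction_table` (data.frame subclass) in file order.
#' @examples
#' t1 <- parse_interactions(system.file("extdata", "akr2_y2h_table1.tsv",
#'                                      package = "musicodon"))
#' nrow(t1)  # 47
#' @export
parse_interactions <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = NULL)
  if (nrow(tab) == 0L) {
    warning("interaction table is empty: ", path)
    tab <- data.frame(name = character(0), description = character(0),
                      accession = character(0), category = character(0),
                      nfkb_flag = logical(0), gene_match_flag = logical(0))
    return(structure(tab, provenance = basename(path),
                     class = c("interaction_table", "data.frame")))
  }
  need <- c("name", "accession", "category")
  if (!all(need %in% names(tab))) {
    stop("interaction table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(tab$description)) tab$description <- ""
  tab$nfkb_flag <- if (is.null(tab$nfkb_flag)) FALSE else
    toupper(tab$nfkb_flag) %in% c("TRUE", "1", "YES")
  tab$gene_match_flag <- if (is.null(tab$gene_match_flag)) FALSE else
    toupper(tab$gene_match_flag) %in% c("TRUE", "1", "YES")
  tab$category <- toupper(tab$category)
  bad <- !tab$category %in% .PBS_CATEGORIES
  if (any(bad)) {
    stop("unknown PBS category letter(s): ",
         paste(unique(tab$category[bad]), collapse = ", "))
  }
  if (any(!nzchar(tab$accession))) stop("empty accession in interaction table")
  key <- paste(tab$name, tab$accession)
  if (anyDuplicated(key)) {
    stop("duplicate (name, accession) record(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  tab <- tab[, c("name", "description", "accession", "category",
                 "nfkb_flag", "gene_match_flag")]
  structure(tab, provenance = basename(path),
            class = c("interaction_table", "data.frame"))
}

#' Filter interaction records by PBS category
#'
#' The conventional candidate filter keeps A-D; E (promiscuous prey), F
#' (technical artifact) and NA records are not considered interactions.
#'
#' @param table an `interaction_table` from [parse_interactions()].
#' @param categories character set of categories to keep.
#' @return The subset, in original order, still an `interaction_table`.
#' @examples
#' t1 <- parse_interactions(system.file("extdata", "akr2_y2h_table1.tsv",
#'                                      package = "musicodon"))
#' nrow(filter_by_category(t1, c("A", "B")))  # 8
#' @export
filter_by_category <- function(table, categories = c("A", "B", "C", "D")) {
  stopifnot(inherits(table, "interaction_table"))
  bad <- setdiff(categories, .PBS_CATEGORIES)
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  out <- table[table$category %in% categories, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, provenance = attr(table, "provenance"),
            class = class(table))
}

#' Summarize an interaction table
#'
#' @param table an `interaction_table`.
#' @return List with `n`, `by_category` (named counts over A-F and NA),
#'   `pct_by_category`, `n_nfkb_flag`, `n_gene_match_flag`.
#' @export
summarize_interactions <- function(table) {
  stopifnot(inherits(table, "interaction_table"))
  counts <- vapply(.PBS_CATEGORIES,
                   function(k) sum(table$category == k), 0L)
  list(n = nrow(table),
       by_category = counts,
       pct_by_category = if (nrow(table)) 100 * counts / nrow(table)
                         else counts * 0,
       n_nfkb_flag = sum(table$nfkb_flag),
       n_gene_match_flag = sum(table$gene_match_flag))
}
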