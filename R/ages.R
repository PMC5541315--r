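# Gene age strata (phylostratigraphy) ----------------------------------------

# Internal canonical ordering of the eight consensus gene-age strata, oldest
# first. "euk_bac" (genes horizontally transferred from bacteria) carries no
# intrinsic rank; it is ancient in origin and is ordered between euk_archaea
# and eukaryota for the youngest-protein rule.
.AGE_CLASSES <- c(
  "cellular_organisms", "euk_archaea", "euk_bac", "eukaryota",
  "opisthokonta", "eumetazoa", "vertebrata", "mammalia"
)

#' Gene-age strata
#'
#' The eight consensus evolutionary strata used throughout the package, from
#' oldest (first cellular organisms) to youngest (mammalia). The
#' horizontally-transferred-from-bacteria stratum (`euk_bac`) has no intrinsic
#' position on the tree; it is treated as ancient and ordered between
#' `euk_archaea` and `eukaryota`.
#'
#' @return Character vector of the eight stratum names in evolutionary order.
#' @export
#' @examples
#' age_classes()
age_classes <- function() .AGE_CLASSES

#' Coerce stratum labels to an ordered factor
#'
#' @param x Character vector of stratum names (see [age_classes()]); `NA` is
#'   kept as `NA` (unknown age).
#' @return Ordered factor with the eight strata as levels, oldest first.
#' @export
as_age_class <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% .AGE_CLASSES)
  if (any(bad)) {
    stop("unknown age class(es): ", paste(unique(x[bad]), collapse = ", "),
         "; valid strata are: ", paste(.AGE_CLASSES, collapse = ", "))
  }
  factor(x, levels = .AGE_CLASSES, ordered = TRUE)
}

#' Read a gene-age table
#'
#' Reads a two-column TSV mapping gene symbols to one of the eight strata.
#'
#' @param path Path to a headered TSV with columns `gene` and `stratum`.
#' @return Named character vector: gene symbol -> stratum name.
#' @export
read_gene_ages <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "stratum") %in% names(tab))) {
    stop("gene-age table must have columns 'gene' and 'stratum'")
  }
  if (anyDuplicated(tab$gene)) {
    stop("duplicate gene symbols in age table: ",
         paste(unique(tab$gene[duplicated(tab$gene)]), collapse = ", "))
  }
  as_age_class(tab$stratum)  # validates labels
  stats::setNames(tab$stratum, tab$gene)
}

#' Write a gene-age table
#'
#' @param ages Named character vector (gene -> stratum).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_ages <- function(ages, path) {
  utils::write.table(
    data.frame(gene = names(ages), stratum = unname(ages)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
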