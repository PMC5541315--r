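# Gene-age enrichment of cancer driver genes -----------------------------------

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing at
#' least `k` genes from a stratum of size `K` when drawing `n` genes without
#' replacement from a universe of size `N`.
#'
#' @param k Observed overlap (drivers in the stratum).
#' @param K Stratum size in the universe.
#' @param n Number of draws (drivers in the universe).
#' @param N Universe size.
#' @return The upper-tail p-value.
#' @export
#' @examples
#' hypergeom_upper_tail(3, 5, 3, 10)  # choose(5,3)/choose(10,3) = 1/12
hypergeom_upper_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (is.na(k) || is.na(K) || is.na(n) || is.na(N) ||
      k < 0 || K < 0 || n < 0 || N < 0 || K > N || n > N || k > min(K, n)) {
    stop("inconsistent hypergeometric counts: need 0 <= k <= min(K, n) <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

.stars <- function(q) {
  ifelse(q < 0.001, "***", ifelse(q < 0.01, "**", ifelse(q < 0.05, "*", "")))
}

#' Gene-age enrichment of a driver gene set
#'
#' Tests each of the eight evolutionary strata for over-representation of
#' driver genes relative to the gene universe of the age map, using the
#' hypergeometric upper tail, with Benjamini-Hochberg correction across the
#' eight strata of this driver set (the correction family is the eight strata
#' within one driver dataset). Drivers absent from the universe are dropped
#' (the universe is the set of genes with consensus age information).
#'
#' @param drivers Character vector of driver gene symbols, or a list with
#'   elements `name` and `genes`.
#' @param ages Named character vector (gene -> stratum), as from
#'   [read_gene_ages()].
#' @param alpha FDR level for the `significant` flag.
#' @return Data frame with one row per stratum: `stratum`, `k` (drivers in
#'   stratum), `K` (universe genes in stratum), `n` (drivers in universe), `N`
#'   (universe size), `p_value`, `q_value`, `significant`, `stars`
#'   (`*` q < 0.05, `**` q < 0.01, `***` q < 0.001). The number of drivers
#'   dropped for lacking age information is attached as attribute
#'   `n_unmapped`.
#' @export
enrich_driver_ages <- function(drivers, ages, alpha = 0.05) {
  if (is.list(drivers)) drivers <- drivers$genes
  drivers <- unique(as.character(drivers))
  if (!length(drivers)) stop("empty driver gene set")
  universe <- names(ages)
  mapped <- intersect(drivers, universe)
  if (!length(mapped)) {
    stop("no driver gene present in the age-map universe")
  }
  N <- length(universe)
  n <- length(mapped)
  K <- table(factor(ages, levels = .AGE_CLASSES))
  k <- table(factor(ages[mapped], levels = .AGE_CLASSES))
  p <- vapply(.AGE_CLASSES, function(s) {
    hypergeom_upper_tail(as.integer(k[s]), as.integer(K[s]), n, N)
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    stratum = .AGE_CLASSES,
    k = as.integer(k),
    K = as.integer(K),
    n = n,
    N = N,
    p_value = unname(p),
    q_value = unname(q),
    significant = unname(q < alpha),
    stars = unname(.stars(q)),
    stringsAsFactors = FALSE
  )
  attr(out, "n_unmapped") <- length(drivers) - n
  out
}

#' Read a driver gene list
#'
#' @param path Text file with one gene symbol per line; blank lines and lines
#'   starting with `#` are ignored.
#' @return Character vector of gene symbols.
#' @export
read_driver_genes <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (!length(x)) stop("driver gene list is empty")
  unique(x)
}
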