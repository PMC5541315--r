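# Simulation accuracy against expression-change annotations --------------------

.DIRECTIONS <- c("up", "down", "unchanged")

#' Simulated expression-change direction of nodes
#'
#' Compares node activities between the cancer-like and the normal-like
#' attractor: `up` if cancer - normal > tol, `down` if normal - cancer > tol,
#' otherwise `unchanged`.
#'
#' @param cancer,normal Attractors (or named activity vectors). Both must
#'   contain every requested node.
#' @param nodes Node ids to compare; defaults to all nodes shared by both
#'   attractors.
#' @param tol Half-width of the "unchanged" band on the activity scale.
#' @return Named character vector of directions.
#' @export
#' @examples
#' simulated_direction(c(A = 0.9), c(A = 0.1))  # up
simulated_direction <- function(cancer, normal, nodes = NULL, tol = 0.1) {
  c_state <- .attractor_state(cancer)
  n_state <- .attractor_state(normal)
  if (is.null(nodes)) nodes <- intersect(names(c_state), names(n_state))
  missing <- setdiff(nodes, intersect(names(c_state), names(n_state)))
  if (length(missing)) {
    stop("node(s) missing from an attractor: ", paste(missing, collapse = ", "))
  }
  d <- c_state[nodes] - n_state[nodes]
  stats::setNames(ifelse(d > tol, "up", ifelse(d < -tol, "down", "unchanged")),
                  nodes)
}

#' Read an expression-change annotation table
#'
#' @param path Headered TSV with columns `node`, `dataset`, `direction`
#'   (`up`/`down`/`unchanged`).
#' @return Data frame with those three columns.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("node", "dataset", "direction") %in% names(tab))) {
    stop("annotation table must have columns node, dataset, direction")
  }
  tab$direction <- tolower(tab$direction)
  if (!all(tab$direction %in% .DIRECTIONS)) {
    stop("direction must be one of: ", paste(.DIRECTIONS, collapse = ", "))
  }
  tab[, c("node", "dataset", "direction")]
}

#' Simulation accuracy against annotated expression changes
#'
#' For each annotation dataset, the fraction of annotated nodes whose simulated
#' direction (cancer vs normal attractor, [simulated_direction()]) matches the
#' annotated direction. Nodes annotated but absent from both attractors are
#' skipped, not counted as errors, so accuracy is computed over the (sub)network
#' nodes only.
#'
#' @param cancer,normal Attractors (or named activity vectors).
#' @param annotations Data frame with columns `node`, `dataset`, `direction`
#'   (see [read_annotations()]); a named character vector is treated as a
#'   single dataset.
#' @param tol Unchanged band passed to [simulated_direction()].
#' @param count_unchanged If `FALSE`, node/dataset pairs where both the
#'   simulation and the annotation say `unchanged` are dropped from numerator
#'   and denominator.
#' @return List with `summary` (data frame: dataset, n_compared, n_consistent,
#'   accuracy) and `detail` (per node and dataset: simulated vs annotated
#'   direction and consistency flag).
#' @export
simulation_accuracy <- function(cancer, normal, annotations, tol = 0.1,
                                count_unchanged = TRUE) {
  if (is.character(annotations) && !is.null(names(annotations))) {
    annotations <- data.frame(node = names(annotations), dataset = "dataset1",
                              direction = unname(annotations),
                              stringsAsFactors = FALSE)
  }
  stopifnot(all(c("node", "dataset", "direction") %in% names(annotations)))
  if (!all(annotations$direction %in% .DIRECTIONS)) {
    stop("direction must be one of: ", paste(.DIRECTIONS, collapse = ", "))
  }
  shared <- intersect(names(.attractor_state(cancer)),
                      names(.attractor_state(normal)))
  detail <- annotations[annotations$node %in% shared, , drop = FALSE]
  if (!nrow(detail)) stop("no annotated node present in both attractors")
  sim <- simulated_direction(cancer, normal, unique(detail$node), tol = tol)
  detail$simulated <- unname(sim[detail$node])
  detail$consistent <- detail$simulated == detail$direction
  if (!count_unchanged) {
    detail <- detail[!(detail$simulated == "unchanged" &
                         detail$direction == "unchanged"), , drop = FALSE]
    if (!nrow(detail)) stop("no comparable node after dropping unchanged pairs")
  }
  summary <- do.call(rbind, lapply(split(detail, detail$dataset), function(d) {
    data.frame(dataset = d$dataset[1], n_compared = nrow(d),
               n_consistent = sum(d$consistent),
               accuracy = mean(d$consistent), stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  rownames(detail) <- NULL
  list(summary = summary, detail = detail)
}
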