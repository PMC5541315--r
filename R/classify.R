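# Cell-status assignment of attractors ----------------------------------------

.CELL_STATUSES <- c("proliferation", "cell_cycle_arrest", "apoptosis",
                    "stress_response", "unclassified")

#' Cell status labels
#' @return The five labels an attractor can receive: proliferation
#'   (cancer-like), cell_cycle_arrest (normal-like), apoptosis,
#'   stress_response, unclassified.
#' @export
cell_statuses <- function() .CELL_STATUSES

.attractor_state <- function(attractor) {
  if (inherits(attractor, "endo_attractor")) attractor$state
  else if (is.numeric(attractor) && !is.null(names(attractor))) attractor
  else stop("expected an endo_attractor or a named numeric state vector")
}

#' Functional-module activity states of an attractor
#'
#' A module is called active when its member nodes behave as they would under
#' full module function: promoting nodes above the activity threshold and
#' module-inhibiting nodes at or below it. Each node casts one vote
#' (a promoting node votes "active" if its activity exceeds the threshold; an
#' inhibiting node votes "active" if its activity is at or below it); the
#' module is active on a strict majority, with ties resolved to inactive.
#' Nodes assigned to module `"other"` are ignored; modules with no annotated
#' nodes are excluded with a warning.
#'
#' @param attractor An `endo_attractor` or named activity vector.
#' @param net An [network()] object whose nodes carry `module` and
#'   `module_role` annotations.
#' @param threshold Activity cutoff separating high from low (default 0.5 of
#'   the reportable range).
#' @return Named character vector: module -> `"active"`/`"inactive"`.
#' @export
module_states <- function(attractor, net, threshold = 0.5) {
  stopifnot(inherits(net, "endo_network"))
  state <- .attractor_state(attractor)
  nodes <- net$nodes[net$nodes$module != "other", , drop = FALSE]
  if (!nrow(nodes)) {
    warning("no node carries a functional-module annotation")
    return(stats::setNames(character(0), character(0)))
  }
  missing <- setdiff(nodes$id, names(state))
  if (length(missing)) {
    stop("attractor lacks values for annotated node(s): ",
         paste(missing, collapse = ", "))
  }
  mods <- unique(nodes$module)
  out <- vapply(mods, function(m) {
    sub <- nodes[nodes$module == m, , drop = FALSE]
    high <- state[sub$id] > threshold
    votes <- ifelse(sub$module_role == "promotes", high, !high)
    if (sum(votes) > length(votes) / 2) "active" else "inactive"
  }, character(1))
  stats::setNames(out, mods)
}

#' Cell status from module states
#'
#' Applies the verbal classification rules in fixed precedence order:
#' \enumerate{
#'   \item proliferation (cancer-like): cell_cycle, glycolysis,
#'     immune_response and angiogenesis active while apoptosis and
#'     cell_adhesion inactive;
#'   \item cell_cycle_arrest (normal-like): cell_adhesion active and all other
#'     modules inactive;
#'   \item apoptosis: apoptosis active and all other modules inactive;
#'   \item stress_response: immune_response active;
#'   \item otherwise unclassified.
#' }
#' Modules absent from `ms` are skipped in rule evaluation, so the function is
#' total over partial module maps. The precedence resolves the overlap between
#' the stress-response rule and the others.
#'
#' @param ms Named character (`"active"`/`"inactive"`) or logical vector as
#'   returned by [module_states()].
#' @return One label from [cell_statuses()].
#' @export
cell_status_from_modules <- function(ms) {
  if (is.character(ms)) {
    if (!all(ms %in% c("active", "inactive"))) {
      stop("module states must be 'active'/'inactive' (or logical)")
    }
    ms <- ms == "active"
  }
  stopifnot(is.logical(ms), !is.null(names(ms)))
  bad <- setdiff(names(ms), setdiff(.FUNCTIONAL_MODULES, "other"))
  if (length(bad)) stop("unknown module(s): ", paste(bad, collapse = ", "))

  on <- function(m) !is.na(ms[m]) & isTRUE(unname(ms[m]))
  present <- function(m) m %in% names(ms)
  active_set <- c("cell_cycle", "glycolysis", "immune_response", "angiogenesis")
  inactive_set <- c("apoptosis", "cell_adhesion")
  all_on <- function(set) all(vapply(set[vapply(set, present, logical(1))],
                                     on, logical(1)))
  all_off <- function(set) {
    set <- set[vapply(set, present, logical(1))]
    all(!vapply(set, on, logical(1)))
  }
  others_off <- function(except) all_off(setdiff(names(ms), except))

  if (all_on(active_set) && all_off(inactive_set)) return("proliferation")
  if (present("cell_adhesion") && on("cell_adhesion") &&
      others_off("cell_adhesion")) return("cell_cycle_arrest")
  if (present("apoptosis") && on("apoptosis") &&
      others_off("apoptosis")) return("apoptosis")
  if (present("immune_response") && on("immune_response")) return("stress_response")
  "unclassified"
}

#' Read a reference attractor table
#'
#' Reference attractors are published steady states of the complete networks,
#' supplied as a TSV with a `node` column, one numeric column per reference
#' attractor, and one row whose `node` field is `cell_status` giving each
#' reference's label.
#'
#' @param path TSV path.
#' @return A list of class `endo_reference_set`: `states` (named list of named
#'   activity vectors) and `labels` (named character, one label per reference).
#' @export
read_reference_attractors <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  if (!("node" %in% names(tab))) stop("reference table needs a 'node' column")
  lab_row <- tab$node == "cell_status"
  if (sum(lab_row) != 1) {
    stop("reference table must contain exactly one 'cell_status' row")
  }
  refs <- setdiff(names(tab), "node")
  labels <- stats::setNames(as.character(tab[lab_row, refs]), refs)
  if (!all(labels %in% .CELL_STATUSES)) {
    stop("unknown cell status label(s): ",
         paste(setdiff(labels, .CELL_STATUSES), collapse = ", "))
  }
  vals <- tab[!lab_row, , drop = FALSE]
  states <- lapply(refs, function(r) {
    stats::setNames(as.numeric(vals[[r]]), vals$node)
  })
  names(states) <- refs
  reference_attractors(states, labels)
}

#' Construct a reference attractor set
#'
#' @param states Named list of named activity vectors (one per reference).
#' @param labels Named character vector of cell statuses, names matching
#'   `states`.
#' @return An `endo_reference_set`.
#' @export
reference_attractors <- function(states, labels) {
  stopifnot(is.list(states), length(states) >= 1,
            setequal(names(states), names(labels)))
  if (!all(labels %in% .CELL_STATUSES)) {
    stop("labels must be drawn from cell_statuses()")
  }
  structure(list(states = states, labels = labels[names(states)]),
            class = "endo_reference_set")
}

#' Classify an attractor by nearest reference attractor
#'
#' Computes the mean absolute per-node activity difference between the
#' attractor and each reference over their shared nodes, and returns the label
#' of the nearest reference when that distance is at most `max_dist`. Ties and
#' distances beyond `max_dist` yield `"unclassified"` (tied candidates are
#' reported in the `candidates` attribute).
#'
#' @param attractor An `endo_attractor` or named activity vector.
#' @param refs An `endo_reference_set`.
#' @param max_dist Maximum mean absolute difference for a match.
#' @return A cell status label with attributes `distance` (named vector of
#'   distances to each reference) and, on a tie, `candidates`.
#' @export
match_to_reference <- function(attractor, refs, max_dist = 0.3) {
  stopifnot(inherits(refs, "endo_reference_set"))
  state <- .attractor_state(attractor)
  dists <- vapply(refs$states, function(ref) {
    shared <- intersect(names(ref), names(state))
    if (!length(shared)) {
      stop("no shared nodes between attractor and a reference attractor")
    }
    mean(abs(state[shared] - ref[shared]))
  }, numeric(1))
  best <- which(dists == min(dists))
  if (min(dists) > max_dist) {
    out <- "unclassified"
  } else if (length(best) > 1) {
    out <- "unclassified"
    attr(out, "candidates") <- names(dists)[best]
  } else {
    out <- unname(refs$labels[names(dists)[best]])
  }
  attr(out, "distance") <- dists
  out
}

#' Driver-gene direction check between two attractors
#'
#' For every node annotated as oncogene or tumour suppressor (TSG), reports
#' whether its activity in the proliferation (cancer-like) attractor exceeds
#' its activity in the cell-cycle-arrest (normal-like) attractor. Oncogene
#' nodes are expected higher in proliferation; TSG nodes lower.
#'
#' @param proliferation,arrest Attractors (or named activity vectors) over the
#'   same network.
#' @param net An [network()] object with `driver_type` annotations.
#' @return A list with `report` (per-driver-node data frame: id, driver_type,
#'   proliferation and arrest activities, higher_in_proliferation,
#'   follows_expectation) and `summary` (counts of expectation-consistent nodes
#'   by driver type).
#' @export
check_driver_directions <- function(proliferation, arrest, net) {
  stopifnot(inherits(net, "endo_network"))
  p <- .attractor_state(proliferation)
  a <- .attractor_state(arrest)
  drivers <- net$nodes[net$nodes$driver_type != "none", , drop = FALSE]
  missing <- setdiff(drivers$id, intersect(names(p), names(a)))
  if (length(missing)) {
    stop("driver node(s) missing from an attractor: ",
         paste(missing, collapse = ", "))
  }
  higher <- p[drivers$id] > a[drivers$id]
  follows <- ifelse(drivers$driver_type == "oncogene", higher, !higher)
  report <- data.frame(
    id = drivers$id,
    driver_type = drivers$driver_type,
    proliferation = unname(p[drivers$id]),
    arrest = unname(a[drivers$id]),
    higher_in_proliferation = unname(higher),
    follows_expectation = unname(follows),
    stringsAsFactors = FALSE
  )
  summary <- do.call(rbind, lapply(c("oncogene", "tsg"), function(ty) {
    sub <- report[report$driver_type == ty, , drop = FALSE]
    data.frame(driver_type = ty, n = nrow(sub),
               consistent = sum(sub$follows_expectation),
               stringsAsFactors = FALSE)
  }))
  list(report = report, summary = summary)
}
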