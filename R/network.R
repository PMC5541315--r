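# Signed regulatory networks --------------------------------------------------

.FUNCTIONAL_MODULES <- c("cell_cycle", "glycolysis", "apoptosis",
                         "cell_adhesion", "immune_response", "angiogenesis",
                         "other")
.DRIVER_TYPES <- c("oncogene", "tsg", "none")
.EDGE_SIGNS <- c("activation", "inhibition")

#' Functional modules recognised by the cell-status rules
#' @return Character vector of module names (six hallmark modules plus
#'   `"other"` for unassigned nodes).
#' @export
functional_modules <- function() .FUNCTIONAL_MODULES

.normalize_sign <- function(sign) {
  s <- tolower(trimws(as.character(sign)))
  s[s %in% c("+1", "1", "+", "activate", "activates", "activation")] <- "activation"
  s[s %in% c("-1", "-", "inhibit", "inhibits", "inhibition")] <- "inhibition"
  bad <- !(s %in% .EDGE_SIGNS)
  if (any(bad)) {
    stop("unknown edge sign(s): ", paste(unique(sign[bad]), collapse = ", "),
         " (expected 'activation'/'inhibition' or '+1'/'-1')")
  }
  s
}

.split_proteins <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  lapply(out, function(p) trimws(p[nzchar(trimws(p))]))
}

#' Construct a signed regulatory network
#'
#' A network is a pair of data frames: node annotations and signed directed
#' edges. Node ids must be unique; every edge endpoint must be a node; at most
#' one edge may exist per (source, target, sign) triple. A node's
#' `component_proteins` defaults to its own id (single-protein node).
#'
#' @param nodes Data frame with column `id` and optional columns `label`,
#'   `proteins` (semicolon-separated component gene symbols), `module`
#'   (see [functional_modules()]), `module_role` (`"promotes"`/`"inhibits"`:
#'   whether the node promotes or inhibits its module's function),
#'   `driver_type` (`"oncogene"`, `"tsg"`, `"none"`) and `age_class`.
#' @param edges Data frame with columns `source`, `target`, `sign`
#'   (`"activation"`/`"inhibition"`, `"+1"`/`"-1"` accepted).
#' @return An object of class `endo_network`: a list with elements `nodes`
#'   and `edges` (validated, normalised data frames).
#' @export
network <- function(nodes, edges = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!("id" %in% names(nodes)) || nrow(nodes) < 1) {
    stop("nodes must be a data frame with at least one row and an 'id' column")
  }
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  }
  if (is.null(nodes$label)) nodes$label <- nodes$id
  if (is.null(nodes$proteins) || all(is.na(nodes$proteins))) {
    nodes$proteins <- nodes$id
  }
  nodes$proteins <- as.character(nodes$proteins)
  empty <- !nzchar(trimws(nodes$proteins)) | is.na(nodes$proteins)
  nodes$proteins[empty] <- nodes$id[empty]
  if (is.null(nodes$module)) nodes$module <- "other"
  nodes$module[is.na(nodes$module) | !nzchar(nodes$module)] <- "other"
  bad_mod <- !(nodes$module %in% .FUNCTIONAL_MODULES)
  if (any(bad_mod)) {
    stop("unknown functional module(s): ",
         paste(unique(nodes$module[bad_mod]), collapse = ", "))
  }
  if (is.null(nodes$module_role)) nodes$module_role <- "promotes"
  nodes$module_role[is.na(nodes$module_role) | !nzchar(nodes$module_role)] <- "promotes"
  if (!all(nodes$module_role %in% c("promotes", "inhibits"))) {
    stop("module_role must be 'promotes' or 'inhibits'")
  }
  if (is.null(nodes$driver_type)) nodes$driver_type <- "none"
  nodes$driver_type[is.na(nodes$driver_type) | !nzchar(nodes$driver_type)] <- "none"
  if (!all(nodes$driver_type %in% .DRIVER_TYPES)) {
    stop("driver_type must be one of: ", paste(.DRIVER_TYPES, collapse = ", "))
  }
  if (is.null(nodes$age_class)) nodes$age_class <- NA_character_
  nodes$age_class <- as.character(as_age_class(nodes$age_class))

  if (nrow(edges)) {
    need <- c("source", "target", "sign")
    if (!all(need %in% names(edges))) {
      stop("edges must have columns source, target, sign")
    }
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    edges$sign <- .normalize_sign(edges$sign)
    dangling <- !(edges$source %in% nodes$id) | !(edges$target %in% nodes$id)
    if (any(dangling)) {
      i <- which(dangling)[1]
      stop(sprintf("edge %s -> %s (%s) references a node not in the node set",
                   edges$source[i], edges$target[i], edges$sign[i]))
    }
    key <- paste(edges$source, edges$target, edges$sign)
    if (anyDuplicated(key)) {
      stop("duplicate edges: ", paste(unique(key[duplicated(key)]), collapse = "; "))
    }
  }
  nodes <- nodes[, c("id", "label", "proteins", "module", "module_role",
                     "driver_type", "age_class")]
  rownames(nodes) <- NULL
  edges <- data.frame(source = edges$source, target = edges$target,
                      sign = edges$sign, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "endo_network")
}

#' @export
print.endo_network <- function(x, ...) {
  cat(sprintf("<endo_network> %d nodes, %d edges (%d activation, %d inhibition)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "activation"),
              sum(x$edges$sign == "inhibition")))
  known <- sum(!is.na(x$nodes$age_class))
  cat(sprintf("  node ages assigned: %d/%d\n", known, nrow(x$nodes)))
  invisible(x)
}

#' Read a network from edge and node tables
#'
#' Edge table: headered TSV with columns `source`, `target`, `sign` where sign
#' is spelled `activation`/`inhibition` (`+1`/`-1` also accepted). Node table:
#' headered TSV with columns `id`, `label`, `proteins` (semicolon-separated),
#' `module`, `driver_type`, and optionally `module_role` and `age_class`.
#' Nodes that appear only in the edge table are auto-created with empty
#' annotations, with a warning; this tolerates partially annotated inputs.
#'
#' @param edge_table Path to the edge TSV.
#' @param node_table Path to the node TSV, or `NULL` to derive all nodes from
#'   the edge table.
#' @return An [network()] object.
#' @export
read_network <- function(edge_table, node_table = NULL) {
  edges <- utils::read.delim(edge_table, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "sign") %in% names(edges))) {
    stop("edge table must have columns source, target, sign")
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (is.null(node_table)) {
    nodes <- data.frame(id = unique(c(edges$source, edges$target)),
                        stringsAsFactors = FALSE)
  } else {
    nodes <- utils::read.delim(node_table, stringsAsFactors = FALSE,
                               colClasses = "character")
    if (!("id" %in% names(nodes))) stop("node table must have an 'id' column")
    missing <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
    if (length(missing)) {
      warning("node(s) present only in the edge table, auto-created with ",
              "empty annotations: ", paste(missing, collapse = ", "))
      extra <- data.frame(id = missing, stringsAsFactors = FALSE)
      for (col in setdiff(names(nodes), "id")) extra[[col]] <- NA_character_
      nodes <- rbind(nodes, extra)
    }
  }
  network(nodes, edges)
}

#' Write a network to edge and node tables
#'
#' Inverse of [read_network()]: reproduces the TSV dialect it reads, so that a
#' read/write round trip preserves both tables up to row order.
#'
#' @param net An [network()] object.
#' @param edge_table,node_table Output TSV paths.
#' @return `net`, invisibly.
#' @export
write_network <- function(net, edge_table, node_table) {
  stopifnot(inherits(net, "endo_network"))
  utils::write.table(net$edges, edge_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$nodes, node_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(net)
}

#' Age of a (possibly multi-protein) node
#'
#' A node representing a protein complex takes the age of its youngest
#' component: the stratum appearing latest in the evolutionary ordering of
#' [age_classes()].
#'
#' @param proteins Character vector of component gene symbols.
#' @param age_map Named character vector (gene -> stratum), as from
#'   [read_gene_ages()].
#' @return A stratum name, or `NA_character_` if no component is mapped.
#' @export
#' @examples
#' node_age(c("CDK1", "CCNB1"),
#'          c(CDK1 = "eukaryota", CCNB1 = "vertebrata"))  # "vertebrata"
node_age <- function(proteins, age_map) {
  strata <- age_map[match(proteins, names(age_map))]
  strata <- strata[!is.na(strata)]
  if (!length(strata)) return(NA_character_)
  ranks <- match(strata, .AGE_CLASSES)
  .AGE_CLASSES[max(ranks)]
}

#' Assign ages to all nodes of a network
#'
#' Applies the youngest-component rule ([node_age()]) to every node. Nodes with
#' no mapped component keep an unknown (`NA`) age and are reported in a
#' message.
#'
#' @param net An [network()] object.
#' @param age_map Named character vector (gene -> stratum).
#' @return The network with the `age_class` node column filled in.
#' @export
assign_node_ages <- function(net, age_map) {
  stopifnot(inherits(net, "endo_network"))
  comps <- .split_proteins(net$nodes$proteins)
  ages <- vapply(comps, node_age, character(1), age_map = age_map)
  unknown <- net$nodes$id[is.na(ages)]
  if (length(unknown)) {
    message("no component protein mapped for node(s): ",
            paste(unknown, collapse = ", "), " (age left unknown)")
  }
  net$nodes$age_class <- ages
  net
}

#' Extract the subnetwork originating from given strata
#'
#' Induced subgraph on the nodes whose age class lies in `allowed` (plus any
#' explicitly forced nodes): exactly those nodes are kept, together with every
#' edge whose two endpoints are both kept; edge signs are unchanged.
#' `force_include` handles manually justified exceptions (e.g. retaining a
#' complex whose components have ancient homologs) without touching the age
#' assignment itself.
#'
#' @param net An [network()] object with node ages assigned.
#' @param allowed Character vector of stratum names (see [age_classes()]).
#' @param force_include Character vector of node ids kept regardless of age.
#' @return The induced `endo_network`.
#' @export
extract_age_subnetwork <- function(net, allowed, force_include = character()) {
  stopifnot(inherits(net, "endo_network"))
  allowed <- as.character(as_age_class(allowed))
  unknown_force <- setdiff(force_include, net$nodes$id)
  if (length(unknown_force)) {
    stop("force_include names absent node(s): ",
         paste(unknown_force, collapse = ", "))
  }
  keep <- (!is.na(net$nodes$age_class) & net$nodes$age_class %in% allowed) |
    net$nodes$id %in% force_include
  if (!any(keep)) {
    stop("no node falls in the requested strata; broaden 'allowed' or check ",
         "age assignment")
  }
  ids <- net$nodes$id[keep]
  edges <- net$edges[net$edges$source %in% ids & net$edges$target %in% ids, ,
                     drop = FALSE]
  network(net$nodes[keep, , drop = FALSE], edges)
}
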