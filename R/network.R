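#' Signed directed regulatory network
#'
#' Constructs a validated `regulatory_network`: an ordered node table plus a
#' signed directed edge list. This is the container every other function in
#' the package operates on. Nodes represent genes or signaling activities;
#' an edge `i -> n` means `i` is a regulator of `n`, i.e. `i` belongs to the
#' input set of `n`.
#'
#' Duplicate edges with the same (source, target) are collapsed to a single
#' edge. Collapsing is an error when the duplicates carry contradictory signs
#' (one activating, one repressing); an `unknown` sign merges silently with
#' either specific sign. Self-loops are legal and preserved — a self-loop is
#' a directed cycle of length one and is treated as such by all cycle and
#' FVS computations.
#'
#' @param nodes data.frame with columns `id` (unique character),
#'   `display_name` (character, defaults to `id`) and `kind`
#'   (`"gene"` or `"signaling"`, defaults to `"gene"`); or a character
#'   vector of ids.
#' @param edges data.frame with columns `source`, `target` and `sign`
#'   (`"activating"`, `"repressing"` or `"unknown"`; the file tokens
#'   `+`, `-`, `?` are also accepted). May have zero rows.
#' @param name character scalar naming the network.
#' @return An object of class `regulatory_network` with elements `nodes`,
#'   `edges` and `name`.
#' @examples
#' net <- regulatory_network(
#'   nodes = c("A", "B"),
#'   edges = data.frame(source = "A", target = "B", sign = "+")
#' )
#' net
#' @export
regulatory_network <- function(nodes, edges = NULL, name = "network") {
  if (is.character(nodes)) {
    nodes <- data.frame(id = nodes, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(nodes), "id" %in% names(nodes))
  nodes$id <- as.character(nodes$id)
  if (anyNA(nodes$id) || any(nodes$id == "")) {
    stop("node ids must be non-empty strings")
  }
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  }
  if (is.null(nodes$display_name)) nodes$display_name <- nodes$id
  nodes$display_name <- as.character(nodes$display_name)
  if (is.null(nodes$kind)) nodes$kind <- "gene"
  nodes$kind <- as.character(nodes$kind)
  bad_kind <- setdiff(unique(nodes$kind), c("gene", "signaling"))
  if (length(bad_kind)) stop("unknown node kind: ", paste(bad_kind, collapse = ", "))
  nodes <- nodes[, c("id", "display_name", "kind")]
  rownames(nodes) <- NULL

  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    stopifnot(all(c("source", "target") %in% names(edges)))
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    if (is.null(edges$sign)) edges$sign <- "unknown"
    edges$sign <- canonical_sign(as.character(edges$sign))
    dangling <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(dangling)) {
      stop("edge endpoint not declared as a node: ",
           paste(unique(dangling), collapse = ", "))
    }
    edges <- collapse_duplicate_edges(edges)
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges[, c("source", "target", "sign")],
                 name = as.character(name)[1]),
            class = "regulatory_network")
}

canonical_sign <- function(sign) {
  out <- rep("unknown", length(sign))
  out[sign %in% c("+", "activating", "activates", "1", "+1")] <- "activating"
  out[sign %in% c("-", "repressing", "represses", "-1")] <- "repressing"
  out
}

sign_token <- function(sign) c(activating = "+", repressing = "-", unknown = "?")[sign]

#' @keywords internal
collapse_duplicate_edges <- function(edges) {
  key <- paste(edges$source, edges$target, sep = "\r")
  if (!anyDuplicated(key)) return(edges)
  keep <- !duplicated(key)
  merged <- edges[keep, , drop = FALSE]
  mkey <- key[keep]
  for (k in unique(key[duplicated(key)])) {
    signs <- unique(edges$sign[key == k])
    specific <- setdiff(signs, "unknown")
    if (length(specific) > 1L) {
      pair <- strsplit(k, "\r", fixed = TRUE)[[1]]
      stop("conflicting signs on duplicate edge ", pair[1], " -> ", pair[2])
    }
    merged$sign[mkey == k] <- if (length(specific)) specific else "unknown"
  }
  merged
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %s: %d nodes, %d edges (%d activating, %d repressing, %d unknown)\n",
              x$name, nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "activating"),
              sum(x$edges$sign == "repressing"),
              sum(x$edges$sign == "unknown")))
  invisible(x)
}

#' Number of nodes / edges
#' @param net a `regulatory_network`
#' @return integer count
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Node ids in declaration order
#' @param net a `regulatory_network`
#' @return character vector
#' @export
node_ids <- function(net) net$nodes$id

#' Input sets (in-neighborhoods)
#'
#' For every node `n`, the set of its regulators
#' `I_n = { i : (i -> n) is an edge }`. These are the second-argument sets of
#' the node drift functions in the dynamics module, and they carry the entire
#' graph structure of the network.
#'
#' @param net a `regulatory_network`
#' @return named list of character vectors, one entry per node, in node order.
#' @export
in_neighborhoods <- function(net) {
  ids <- node_ids(net)
  out <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) out[[id]] <- net$edges$source[net$edges$target == id]
  out
}

#' Convert to an igraph object
#'
#' Directed igraph with vertex attributes `name` (the id), `display_name`,
#' `kind` and edge attribute `sign`.
#'
#' @param net a `regulatory_network`
#' @return an `igraph` graph
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    d = net$edges, directed = TRUE, vertices = net$nodes)
  g
}

#' Delete a set of nodes (and incident edges)
#'
#' @param net a `regulatory_network`
#' @param ids character vector of node ids to remove; all must exist.
#' @return the reduced `regulatory_network`
#' @export
delete_nodes <- function(net, ids) {
  unknown <- setdiff(ids, node_ids(net))
  if (length(unknown)) stop("unknown node id: ", paste(unknown, collapse = ", "))
  keep_n <- !(net$nodes$id %in% ids)
  keep_e <- !(net$edges$source %in% ids) & !(net$edges$target %in% ids)
  regulatory_network(net$nodes[keep_n, , drop = FALSE],
                     net$edges[keep_e, , drop = FALSE], name = net$name)
}

#' Integer adjacency representation
#'
#' Internal workhorse format for the cycle and FVS algorithms: successor
#' lists indexed by node position.
#' @keywords internal
adjacency_list <- function(net) {
  ids <- node_ids(net)
  idx <- stats::setNames(seq_along(ids), ids)
  adj <- vector("list", length(ids))
  for (i in seq_along(ids)) adj[[i]] <- integer(0)
  if (nrow(net$edges)) {
    s <- idx[net$edges$source]; t <- idx[net$edges$target]
    for (k in seq_along(s)) adj[[s[k]]] <- c(adj[[s[k]]], t[k])
    adj <- lapply(adj, function(v) sort(unique(v)))
  }
  list(adj = adj, ids = ids)
}

#' Sanitize a display name into a node id
#'
#' Gene-name punctuation (slashes, spaces) is kept in `display_name` but
#' replaced in ids so that ids are safe across all supported file dialects.
#' @param x character vector of display names
#' @return character vector of ids
#' @export
sanitize_id <- function(x) {
  gsub("[^A-Za-z0-9._-]+", ".", gsub("[[:space:]]+", "_", x))
}

#' Test two networks for equality up to node ordering
#' @param a,b `regulatory_network` objects
#' @return logical
#' @export
networks_equal <- function(a, b) {
  na <- a$nodes[order(a$nodes$id), ]; nb <- b$nodes[order(b$nodes$id), ]
  rownames(na) <- rownames(nb) <- NULL
  ea <- a$edges[order(a$edges$source, a$edges$target), ]
  eb <- b$edges[order(b$edges$source, b$edges$target), ]
  rownames(ea) <- rownames(eb) <- NULL
  identical(na, nb) && identical(ea, eb)
}
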