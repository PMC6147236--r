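#' Read a regulatory network from a file
#'
#' Supported dialects:
#' \describe{
#'   \item{`edgelist_tsv`}{UTF-8 tab-separated file with header
#'     `source<TAB>target<TAB>sign`, sign in `+`, `-`, `?`. Lines starting
#'     with `#` are comments; a directive comment `#!node<TAB>id[<TAB>display
#'     name[<TAB>kind]]` declares a node explicitly (needed only for isolated
#'     nodes or to attach display names / kinds).}
#'   \item{`sif`}{whitespace-separated `source relation target` with relation
#'     one of `activates`, `represses`, `regulates`; a line holding a single
#'     token declares an isolated node.}
#'   \item{`graphml`}{directed GraphML with edge attribute `sign` and optional
#'     vertex attributes `display_name`, `kind` (read via igraph).}
#' }
#' Unknown sign tokens are mapped to `unknown`. Node order is order of first
#' appearance. Duplicate edges collapse (conflicting signs are an error).
#'
#' @param path file path
#' @param format one of `"edgelist_tsv"`, `"sif"`, `"graphml"`
#' @param name network name; defaults to the file base name
#' @return a [regulatory_network]
#' @export
load_network <- function(path, format = c("edgelist_tsv", "sif", "graphml"),
                         name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  switch(format,
         edgelist_tsv = read_edgelist_tsv(path, name),
         sif = read_sif(path, name),
         graphml = read_graphml(path, name))
}

read_edgelist_tsv <- function(path, name) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  node_rec <- list()
  edge_rec <- list()
  header_seen <- FALSE
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (line == "" || grepl("^\\s*$", line)) next
    if (startsWith(line, "#")) {
      if (startsWith(line, "#!node\t")) {
        f <- strsplit(sub("^#!node\t", "", line), "\t", fixed = TRUE)[[1]]
        node_rec[[length(node_rec) + 1L]] <- list(
          id = f[1],
          display_name = if (length(f) >= 2) f[2] else f[1],
          kind = if (length(f) >= 3) f[3] else "gene")
      }
      next
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (!header_seen) {
      if (!identical(tolower(f[1:2]), c("source", "target"))) {
        stop("line ", ln, ": expected header 'source\\ttarget\\tsign'")
      }
      header_seen <- TRUE
      next
    }
    if (length(f) < 2L || f[1] == "" || f[2] == "") {
      stop("line ", ln, ": malformed edge row (need source<TAB>target[<TAB>sign])")
    }
    edge_rec[[length(edge_rec) + 1L]] <- list(
      source = f[1], target = f[2],
      sign = if (length(f) >= 3) f[3] else "?")
  }
  build_from_records(node_rec, edge_rec, name)
}

read_sif <- function(path, name) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  node_rec <- list(); edge_rec <- list()
  rel_sign <- c(activates = "+", represses = "-", regulates = "?")
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "#")) next
    f <- strsplit(line, "[ \t]+")[[1]]
    if (length(f) == 1L) {
      node_rec[[length(node_rec) + 1L]] <- list(id = f[1], display_name = f[1],
                                                kind = "gene")
    } else if (length(f) == 3L) {
      sgn <- rel_sign[f[2]]
      if (is.na(sgn)) sgn <- "?"
      edge_rec[[length(edge_rec) + 1L]] <- list(source = f[1], target = f[3],
                                                sign = unname(sgn))
    } else {
      stop("line ", ln, ": malformed SIF row (need 'source relation target')")
    }
  }
  build_from_records(node_rec, edge_rec, name)
}

read_graphml <- function(path, name) {
  g <- igraph::read_graph(path, format = "graphml")
  if (!igraph::is_directed(g)) stop("GraphML graph must be directed")
  va <- igraph::vertex_attr(g)
  ids <- as.character(va$name)
  nodes <- data.frame(
    id = ids,
    display_name = if (!is.null(va$display_name)) as.character(va$display_name) else ids,
    kind = if (!is.null(va$kind)) as.character(va$kind) else "gene",
    stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  sgn <- igraph::edge_attr(g, "sign")
  if (is.null(sgn)) sgn <- rep("?", nrow(el))
  edges <- data.frame(source = el[, 1], target = el[, 2],
                      sign = as.character(sgn), stringsAsFactors = FALSE)
  regulatory_network(nodes, edges, name = name)
}

build_from_records <- function(node_rec, edge_rec, name) {
  declared <- if (length(node_rec)) {
    do.call(rbind, lapply(node_rec, function(r) {
      data.frame(id = r$id, display_name = r$display_name, kind = r$kind,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(id = character(), display_name = character(),
               kind = character(), stringsAsFactors = FALSE)
  }
  edges <- if (length(edge_rec)) {
    do.call(rbind, lapply(edge_rec, function(r) {
      data.frame(source = r$source, target = r$target, sign = r$sign,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(source = character(), target = character(), sign = character(),
               stringsAsFactors = FALSE)
  }
  # node order: declared nodes first, then first appearance in the edge rows
  implied <- unique(as.vector(t(as.matrix(edges[, c("source", "target")]))))
  extra <- setdiff(implied, declared$id)
  nodes <- rbind(declared,
                 data.frame(id = extra, display_name = extra,
                            kind = rep("gene", length(extra)),
                            stringsAsFactors = FALSE))
  regulatory_network(nodes, edges, name = name)
}

#' Write a regulatory network to a file
#'
#' Round-trip stable: `load_network(write_network(net, ...))` equals `net`
#' up to node ordering. Unknown signs are written as the dialect's unknown
#' token (`?` / `regulates`).
#'
#' @param net a [regulatory_network]
#' @param path output path
#' @param format one of `"edgelist_tsv"`, `"sif"`, `"graphml"`
#' @return invisibly, `path`
#' @export
write_network <- function(net, path, format = c("edgelist_tsv", "sif", "graphml")) {
  format <- match.arg(format)
  switch(format,
    edgelist_tsv = {
      con <- file(path, open = "wt", encoding = "UTF-8")
      on.exit(close(con))
      writeLines(sprintf("# network: %s", net$name), con)
      for (i in seq_len(nrow(net$nodes))) {
        writeLines(paste("#!node", net$nodes$id[i], net$nodes$display_name[i],
                         net$nodes$kind[i], sep = "\t"), con)
      }
      writeLines("source\ttarget\tsign", con)
      if (nrow(net$edges)) {
        writeLines(paste(net$edges$source, net$edges$target,
                         sign_token(net$edges$sign), sep = "\t"), con)
      }
    },
    sif = {
      rel <- c(activating = "activates", repressing = "represses",
               unknown = "regulates")
      lines <- character(0)
      used <- unique(c(net$edges$source, net$edges$target))
      isolated <- setdiff(node_ids(net), used)
      if (length(isolated)) lines <- c(lines, isolated)
      if (nrow(net$edges)) {
        lines <- c(lines, paste(net$edges$source, rel[net$edges$sign],
                                net$edges$target))
      }
      writeLines(lines, path)
    },
    graphml = {
      g <- as_igraph(net)
      igraph::E(g)$sign <- sign_token(net$edges$sign)
      igraph::write_graph(g, path, format = "graphml")
    })
  invisible(path)
}
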