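#' Is the network free of directed cycles?
#'
#' Kahn topological elimination. A self-loop is a directed cycle of length
#' one, so any self-loop makes the answer `FALSE`.
#'
#' @param net a [regulatory_network]
#' @return logical scalar
#' @export
is_acyclic <- function(net) {
  al <- adjacency_list(net)
  kahn_acyclic(al$adj, rep(TRUE, length(al$ids)))
}

# Kahn's algorithm on the active subgraph; self-loop nodes never reach
# in-degree zero, so they (correctly) force a FALSE.
kahn_acyclic <- function(adj, active) {
  n <- length(adj)
  indeg <- integer(n)
  for (i in which(active)) {
    succ <- adj[[i]][active[adj[[i]]]]
    if (i %in% succ) return(FALSE)      # self-loop
    indeg[succ] <- indeg[succ] + 1L
  }
  queue <- which(active & indeg == 0L)
  removed <- 0L
  total <- sum(active)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    removed <- removed + 1L
    for (w in adj[[v]]) {
      if (!active[w]) next
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  removed == total
}

#' Count simple directed cycles
#'
#' Johnson's algorithm (blocked search per strongly connected component).
#' Self-loops count as length-1 cycles. Dense graphs can hold exponentially
#' many cycles, so counting stops at `cap`; the result then carries
#' `attr(, "capped") = TRUE` and equals `cap`.
#'
#' @param net a [regulatory_network]
#' @param cap maximum number of cycles to count (default `1e6`)
#' @return integer count with logical attribute `capped`
#' @export
count_simple_cycles <- function(net, cap = 1e6) {
  al <- adjacency_list(net)
  n <- length(al$ids)
  count <- 0L
  capped <- FALSE
  # self-loops first; Johnson below runs on the loop-free graph
  adj <- al$adj
  for (i in seq_len(n)) {
    if (i %in% adj[[i]]) {
      count <- count + 1L
      adj[[i]] <- setdiff(adj[[i]], i)
    }
  }
  if (count >= cap) {
    out <- as.integer(cap); attr(out, "capped") <- TRUE; return(out)
  }

  blocked <- logical(n)
  bsets <- vector("list", n)
  stack_ <- integer(0)
  env <- environment()

  unblock <- function(u) {
    blocked[u] <<- FALSE
    for (w in bsets[[u]]) {
      if (blocked[w]) unblock(w)
    }
    bsets[[u]] <<- integer(0)
  }

  circuit <- function(v, s, sub_adj) {
    found <- FALSE
    stack_ <<- c(stack_, v)
    blocked[v] <<- TRUE
    for (w in sub_adj[[v]]) {
      if (env$capped) break
      if (w == s) {
        env$count <- env$count + 1L
        if (env$count >= cap) env$capped <- TRUE
        found <- TRUE
      } else if (!blocked[w]) {
        if (circuit(w, s, sub_adj)) found <- TRUE
      }
    }
    if (found) {
      unblock(v)
    } else {
      for (w in sub_adj[[v]]) {
        if (!(v %in% bsets[[w]])) bsets[[w]] <<- c(bsets[[w]], v)
      }
    }
    stack_ <<- stack_[-length(stack_)]
    found
  }

  for (s in seq_len(n)) {
    if (capped) break
    # SCCs of the subgraph on vertices >= s; take the component containing
    # the least vertex with at least one internal edge
    active <- rep(FALSE, n); active[s:n] <- TRUE
    comp <- tarjan_scc(adj, active)
    # least-vertex nontrivial SCC
    start <- NA_integer_; members <- NULL
    for (cc in comp) {
      if (length(cc) < 2L) next
      m <- min(cc)
      if (is.na(start) || m < start) { start <- m; members <- cc }
    }
    if (is.na(start)) break
    sub_adj <- vector("list", n)
    memb <- logical(n); memb[members] <- TRUE
    for (v in members) sub_adj[[v]] <- adj[[v]][memb[adj[[v]]]]
    blocked[members] <- FALSE
    for (v in members) bsets[[v]] <- integer(0)
    circuit(start, start, sub_adj)
    adj[[start]] <- integer(0)          # exclude s from later searches
    for (v in seq_len(n)) adj[[v]] <- setdiff(adj[[v]], start)
    s_next <- start                      # loop variable only advances by for
  }
  out <- as.integer(count)
  attr(out, "capped") <- capped
  out
}

# Tarjan strongly connected components restricted to `active` vertices.
# Iterative (explicit stack) so deep graphs do not overflow R's C stack.
tarjan_scc <- function(adj, active) {
  n <- length(adj)
  index <- rep(NA_integer_, n)
  low <- integer(n)
  onstack <- logical(n)
  stk <- integer(0)
  next_index <- 0L
  comps <- list()

  for (root in which(active)) {
    if (!is.na(index[root])) next
    # work stack of (vertex, position in successor list)
    work <- list(list(v = root, i = 0L))
    while (length(work)) {
      fr <- work[[length(work)]]
      v <- fr$v
      if (fr$i == 0L) {
        index[v] <- low[v] <- next_index
        next_index <- next_index + 1L
        stk <- c(stk, v); onstack[v] <- TRUE
      }
      succ <- adj[[v]][active[adj[[v]]]]
      advanced <- FALSE
      while (fr$i < length(succ)) {
        fr$i <- fr$i + 1L
        w <- succ[[fr$i]]
        if (is.na(index[w])) {
          work[[length(work)]] <- fr
          work[[length(work) + 1L]] <- list(v = w, i = 0L)
          advanced <- TRUE
          break
        } else if (onstack[w]) {
          low[v] <- min(low[v], index[w])
        }
      }
      if (advanced) next
      work[[length(work)]] <- NULL
      if (low[v] == index[v]) {
        pos <- max(which(stk == v))
        members <- stk[pos:length(stk)]
        stk <- stk[seq_len(pos - 1L)]
        onstack[members] <- FALSE
        comps[[length(comps) + 1L]] <- members
      }
      if (length(work)) {
        parent <- work[[length(work)]]
        low[parent$v] <- min(low[parent$v], low[v])
        work[[length(work)]] <- parent
      }
    }
  }
  comps
}

#' Is a node set a feedback vertex set?
#'
#' `TRUE` iff deleting `candidate` (and incident edges) leaves an acyclic
#' graph.
#'
#' @param net a [regulatory_network]
#' @param candidate character vector of node ids (may be empty)
#' @return logical scalar
#' @export
is_fvs <- function(net, candidate) {
  unknown <- setdiff(candidate, node_ids(net))
  if (length(unknown)) stop("unknown node id: ", paste(unknown, collapse = ", "))
  al <- adjacency_list(net)
  active <- !(al$ids %in% candidate)
  kahn_acyclic(al$adj, active)
}

# -------------------------------------------------------------------------
# Exact minimum-FVS machinery.
#
# The problem decomposes over nontrivial strongly connected components:
# every directed cycle lives inside one SCC, so the global family of minimum
# FVSs is the Cartesian product of per-SCC families and the minimum size is
# the sum of per-SCC minima. Within an SCC we branch on the vertices of a
# shortest directed cycle (every FVS must contain at least one of them),
# with depth bounded by the current best; enumeration reruns the branching
# at the exact optimum and collects every co-optimal set. Dominance rules
# that could discard co-optimal solutions are deliberately not used.
# -------------------------------------------------------------------------

# shortest directed cycle in the active subgraph, as a vector of vertices;
# NULL if acyclic. BFS from every active vertex; self-loops win immediately.
shortest_cycle <- function(adj, active) {
  for (v in which(active)) {
    if (v %in% adj[[v]]) return(v)
  }
  best <- NULL
  for (s in which(active)) {
    # BFS tree from s; first arrival back at s closes a shortest cycle via s
    parent <- rep(NA_integer_, length(adj))
    dist <- rep(NA_integer_, length(adj))
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (!is.null(best) && dist[v] + 1L >= length(best)) break
      for (w in adj[[v]]) {
        if (!active[w]) next
        if (w == s) {
          cyc <- v
          while (cyc[[1L]] != s) cyc <- c(parent[cyc[[1L]]], cyc)
          if (is.null(best) || length(cyc) < length(best)) best <- cyc
          queue <- integer(0)
          break
        }
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          parent[w] <- v
          queue <- c(queue, w)
        }
      }
    }
    if (!is.null(best) && length(best) == 1L) return(best)
  }
  best
}

# minimum FVS size of the active subgraph (branch and bound)
fvs_min_size_rec <- function(adj, active, depth, best) {
  if (depth >= best) return(best)
  cyc <- shortest_cycle(adj, active)
  if (is.null(cyc)) return(depth)
  for (v in cyc) {
    active[v] <- FALSE
    best <- fvs_min_size_rec(adj, active, depth + 1L, best)
    active[v] <- TRUE
    if (best == depth + 1L && is.null(shortest_cycle(adj, active))) break
  }
  best
}

# all FVSs of exactly size k in the active subgraph (k = the minimum).
# `seen` (an environment) prunes repeated partial states.
fvs_enum_rec <- function(adj, active, chosen, k, acc, seen) {
  key <- paste(sort(chosen), collapse = ",")
  skey <- paste0(length(chosen), "|", key)
  if (!is.null(seen[[skey]])) return(invisible())
  seen[[skey]] <- TRUE
  cyc <- shortest_cycle(adj, active)
  if (is.null(cyc)) {
    # since k is the true minimum, an acyclic state implies |chosen| == k
    acc[[key]] <- sort(chosen)
    return(invisible())
  }
  if (length(chosen) >= k) return(invisible())
  for (v in cyc) {
    active[v] <- FALSE
    fvs_enum_rec(adj, active, c(chosen, v), k, acc, seen)
    active[v] <- TRUE
  }
  invisible()
}

#' Size of the minimum feedback vertex set
#'
#' @param net a [regulatory_network]
#' @return nonnegative integer; 0 for acyclic networks
#' @export
minimum_fvs_size <- function(net) {
  al <- adjacency_list(net)
  n <- length(al$ids)
  active <- rep(TRUE, n)
  total <- 0L
  for (comp in tarjan_scc(al$adj, active)) {
    if (length(comp) == 1L && !(comp %in% al$adj[[comp]])) next
    sub_active <- rep(FALSE, n); sub_active[comp] <- TRUE
    total <- total + fvs_min_size_rec(al$adj, sub_active, 0L, length(comp))
  }
  total
}

#' Enumerate all minimum feedback vertex sets
#'
#' Exact enumeration of every minimum-cardinality FVS, with an
#' alternative-choice factorization when the family is a Cartesian product
#' of interchangeable node groups (two nodes are exchangeable iff swapping
#' them everywhere maps the family onto itself; the factorization is
#' reported only after verifying that picking one node per group rebuilds
#' the family exactly).
#'
#' @param net a [regulatory_network]
#' @param max_sets resource budget: error if the family would exceed this
#'   many sets (default `1e5`); never a silent partial answer.
#' @return an object of class `fvs_family`: list with `minimum_size`
#'   (integer), `sets` (list of sorted character vectors, ordered
#'   lexicographically) and `groups` (list of character vectors, or `NULL`
#'   when the family does not factorize).
#' @export
enumerate_minimum_fvs <- function(net, max_sets = 1e5) {
  al <- adjacency_list(net)
  n <- length(al$ids)
  comps <- tarjan_scc(al$adj, rep(TRUE, n))
  per_scc <- list()
  for (comp in comps) {
    if (length(comp) == 1L && !(comp %in% al$adj[[comp]])) next
    sub_active <- rep(FALSE, n); sub_active[comp] <- TRUE
    k <- fvs_min_size_rec(al$adj, sub_active, 0L, length(comp))
    acc <- new.env(parent = emptyenv())
    seen <- new.env(parent = emptyenv())
    fvs_enum_rec(al$adj, sub_active, integer(0), k, acc, seen)
    sets <- lapply(ls(acc), function(nm) acc[[nm]])
    if (!length(sets)) stop("internal error: no FVS found for an SCC")
    per_scc[[length(per_scc) + 1L]] <- sets
    sz <- prod(vapply(per_scc, length, 1L))
    if (sz > max_sets) {
      stop("minimum-FVS family exceeds budget of ", max_sets, " sets")
    }
  }
  # Cartesian product across SCCs
  sets <- list(integer(0))
  for (fam in per_scc) {
    sets <- unlist(lapply(sets, function(s) lapply(fam, function(t) c(s, t))),
                   recursive = FALSE)
  }
  sets <- lapply(sets, function(s) sort(al$ids[s]))
  ord <- order(vapply(sets, paste, "", collapse = "\r"))
  sets <- sets[ord]
  fam <- structure(list(minimum_size = if (length(sets)) length(sets[[1L]]) else 0L,
                        sets = sets, groups = NULL),
                   class = "fvs_family")
  fam$groups <- factorize_family(fam$sets)
  fam
}

# exchangeability-class factorization; NULL unless product reconstruction
# reproduces the family exactly
factorize_family <- function(sets) {
  if (!length(sets)) return(NULL)
  k <- length(sets[[1L]])
  if (k == 0L) return(list())
  members <- sort(unique(unlist(sets)))
  keyset <- function(ss) sort(vapply(ss, paste, "", collapse = "\r"))
  orig_key <- keyset(sets)
  co_occur <- function(u, v) {
    any(vapply(sets, function(s) u %in% s && v %in% s, TRUE))
  }
  # alternative choices exclude each other, so two nodes of one group never
  # share a set; without this refinement every pair of always-present
  # (singleton-group) nodes would be declared exchangeable
  exchangeable <- function(u, v) {
    if (co_occur(u, v)) return(FALSE)
    swapped <- lapply(sets, function(s) {
      s[s == u] <- "\rU\r"; s[s == v] <- u; s[s == "\rU\r"] <- v
      sort(s)
    })
    identical(keyset(swapped), orig_key)
  }
  # union-find over members
  parent <- stats::setNames(members, members)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_along(members)) {
    for (j in seq_len(i - 1L)) {
      u <- members[i]; v <- members[j]
      if (find(u) != find(v) && exchangeable(u, v)) parent[[find(u)]] <- find(v)
    }
  }
  roots <- vapply(members, find, "")
  groups <- unname(split(members, roots))
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, "", 1L))]
  # verify: one choice per group rebuilds the family
  if (prod(vapply(groups, length, 1L)) != length(sets)) return(NULL)
  if (length(groups) != k) return(NULL)
  product <- list(character(0))
  for (g in groups) {
    product <- unlist(lapply(product, function(s) lapply(g, function(x) c(s, x))),
                      recursive = FALSE)
  }
  product <- lapply(product, sort)
  if (!identical(keyset(product), orig_key)) return(NULL)
  groups
}

#' @export
print.fvs_family <- function(x, ...) {
  cat(sprintf("<fvs_family> minimum size %d, %d minimum FVS(s)\n",
              x$minimum_size, length(x$sets)))
  if (!is.null(x$groups)) {
    cat("alternative-choice factorization: ",
        paste(vapply(x$groups, function(g) paste0("{", paste(g, collapse = "|"), "}"),
                     ""), collapse = " x "),
        sprintf("  (%s = %d)\n",
                paste(vapply(x$groups, length, 1L), collapse = " x "),
                length(x$sets)), sep = "")
  }
  for (s in utils::head(x$sets, 20L)) cat("  {", paste(s, collapse = ", "), "}\n")
  if (length(x$sets) > 20L) cat("  ...\n")
  invisible(x)
}

#' Brute-force minimum-FVS oracle
#'
#' Exhaustive subset search in increasing cardinality, using igraph's DAG
#' test as an independent acyclicity route. Reference semantics for
#' [enumerate_minimum_fvs]; refuses networks above `max_nodes`.
#'
#' @param net a [regulatory_network]
#' @param max_nodes refusal threshold (default 14)
#' @return an `fvs_family`
#' @export
brute_force_minimum_fvs <- function(net, max_nodes = 14) {
  n <- n_nodes(net)
  if (n > max_nodes) {
    stop("brute force refused: ", n, " nodes exceeds max_nodes = ", max_nodes)
  }
  g <- as_igraph(net)
  ids <- node_ids(net)
  for (k in 0:n) {
    hits <- list()
    for (comb in combn_list(n, k)) {
      h <- igraph::delete_vertices(g, ids[comb])
      if (igraph::is_dag(h)) hits[[length(hits) + 1L]] <- sort(ids[comb])
    }
    if (length(hits)) {
      ord <- order(vapply(hits, paste, "", collapse = "\r"))
      fam <- structure(list(minimum_size = k, sets = hits[ord], groups = NULL),
                       class = "fvs_family")
      fam$groups <- factorize_family(fam$sets)
      return(fam)
    }
  }
  stop("unreachable")
}

combn_list <- function(n, k) {
  if (k == 0L) return(list(integer(0)))
  if (k > n) return(list())
  m <- utils::combn(n, k)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

#' Serialize an FVS family to JSON
#'
#' `{minimum_size, sets: [[id,...]], groups: [[id,...]] | null}`.
#'
#' @param fam an `fvs_family`
#' @param path optional path; if `NULL` the JSON string is returned
#' @return JSON string (invisibly when written to a file)
#' @export
fvs_family_json <- function(fam, path = NULL) {
  obj <- list(minimum_size = fam$minimum_size,
              sets = lapply(fam$sets, as.list),
              groups = if (is.null(fam$groups)) NULL else lapply(fam$groups, as.list))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
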