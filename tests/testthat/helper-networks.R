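# Shared fixtures and independent oracles for the test suite.

# brute-force simple-cycle enumeration: DFS over simple paths, counting a
# cycle only when closed at its minimum vertex (so each cycle counts once).
# Independent of the Johnson implementation in the package.
oracle_count_cycles <- function(net) {
  al <- fvscontrol:::adjacency_list(net)
  adj <- al$adj
  n <- length(al$ids)
  count <- 0L
  path_on <- logical(n)
  dfs <- function(v, start) {
    for (w in adj[[v]]) {
      if (w == start) {
        count <<- count + 1L
      } else if (w > start && !path_on[w]) {
        path_on[w] <<- TRUE
        dfs(w, start)
        path_on[w] <<- FALSE
      }
    }
  }
  for (s in seq_len(n)) {
    path_on[s] <- TRUE
    dfs(s, s)
    path_on[s] <- FALSE
  }
  count
}

# random DAG on n nodes: edges only from lower to higher index
random_dag <- function(n, m, seed) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  stopifnot(m <= nrow(pairs))
  pick <- fvscontrol:::with_seed(seed, sample(nrow(pairs), m))
  ids <- sprintf("d%02d", seq_len(n))
  regulatory_network(ids, data.frame(
    source = ids[pairs[pick, 1]], target = ids[pairs[pick, 2]],
    sign = "activating", stringsAsFactors = FALSE),
    name = sprintf("dag_n%d_m%d_%d", n, m, seed))
}

# 4-node bidirectional ring
ring4 <- function() {
  ids <- c("r1", "r2", "r3", "r4")
  nxt <- c(2, 3, 4, 1)
  regulatory_network(ids, data.frame(
    source = c(ids, ids[nxt]), target = c(ids[nxt], ids),
    sign = "unknown", stringsAsFactors = FALSE), name = "ring4")
}

# two independent toggle switches (4 nodes, 4 repressing edges)
double_toggle <- function() {
  generate_network(synth_spec(4, 4, n_toggle_motifs = 2, seed = 1))
}

same_family <- function(a, b) {
  a$minimum_size == b$minimum_size && identical(a$sets, b$sets)
}
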