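test_that("acyclicity test treats self-loops as cycles", {
  expect_true(is_acyclic(get_fixture("fig1e")$network))
  expect_false(is_acyclic(get_fixture("fig1a")$network))
  loop <- regulatory_network("A", data.frame(source = "A", target = "A", sign = "+"))
  expect_false(is_acyclic(loop))
})

test_that("simple-cycle counts match the caption values and the DFS oracle", {
  expect_equal(as.integer(count_simple_cycles(get_fixture("fig1a")$network)), 3L)
  expect_equal(as.integer(count_simple_cycles(get_fixture("fig1e")$network)), 0L)
  expect_equal(as.integer(count_simple_cycles(ring4())), oracle_count_cycles(ring4()))
  # seeded random digraphs against the independent DFS enumeration
  withr::local_seed(11)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    net <- generate_network(synth_spec(n, sample(4:min(12, n * n), 1),
                                       seed = 500 + i))
    expect_equal(as.integer(count_simple_cycles(net)), oracle_count_cycles(net),
                 info = paste("graph", i))
  }
})

test_that("cycle counting caps instead of exploding", {
  cnt <- count_simple_cycles(ring4(), cap = 2)
  expect_equal(as.integer(cnt), 2L)
  expect_true(attr(cnt, "capped"))
  full <- count_simple_cycles(ring4())
  expect_false(attr(full, "capped"))
})

test_that("is_fvs matches the deletion definition", {
  f1a <- get_fixture("fig1a")$network
  expect_true(is_fvs(f1a, "A"))
  expect_false(is_fvs(f1a, "B"))        # self-loop A->A survives
  expect_true(is_fvs(f1a, node_ids(f1a)))
  expect_true(is_fvs(f1a, character(0)) == is_acyclic(f1a))
  expect_error(is_fvs(f1a, "Q"), "unknown node id")
})

test_that("minimum FVS size handles toy, acyclic and disjoint-union cases", {
  expect_equal(minimum_fvs_size(get_fixture("fig1a")$network), 1L)
  expect_equal(minimum_fvs_size(get_fixture("fig1e")$network), 0L)
  # disjoint union: size adds over components
  a <- get_fixture("fig1a")$network
  t2 <- double_toggle()
  ids <- c(paste0("L_", node_ids(a)), paste0("R_", node_ids(t2)))
  edges <- rbind(
    data.frame(source = paste0("L_", a$edges$source),
               target = paste0("L_", a$edges$target), sign = a$edges$sign),
    data.frame(source = paste0("R_", t2$edges$source),
               target = paste0("R_", t2$edges$target), sign = t2$edges$sign))
  un <- regulatory_network(ids, edges)
  expect_equal(minimum_fvs_size(un),
               minimum_fvs_size(a) + minimum_fvs_size(t2))
})

test_that("enumeration returns complete, minimal, verified families", {
  fam <- enumerate_minimum_fvs(get_fixture("fig1a")$network)
  expect_equal(fam$minimum_size, 1L)
  expect_equal(fam$sets, list("A"))
  expect_equal(fam$groups, list("A"))

  famf <- enumerate_minimum_fvs(get_fixture("fig1f")$network)
  expect_equal(famf$minimum_size, 1L)
  expect_equal(famf$sets, list("a"))

  # every returned set is an FVS and is minimal (dropping any node breaks it)
  net <- double_toggle()
  fam2 <- enumerate_minimum_fvs(net)
  expect_equal(fam2$minimum_size, 2L)
  expect_equal(length(fam2$sets), 4L)   # one node from each toggle
  for (s in fam2$sets) {
    expect_true(is_fvs(net, s))
    for (v in s) expect_false(is_fvs(net, setdiff(s, v)))
  }
})

test_that("enumeration agrees with the brute-force oracle on a seeded sweep", {
  withr::local_seed(12)
  for (i in 1:60) {
    n <- sample(3:12, 1)
    net <- generate_network(synth_spec(n, sample(n:(2 * n), 1), seed = 9000 + i))
    a <- enumerate_minimum_fvs(net)
    b <- brute_force_minimum_fvs(net)
    expect_true(same_family(a, b), info = paste("graph", i))
  }
})

test_that("structural invariants hold on enumerated families", {
  withr::local_seed(13)
  for (i in 1:30) {
    n <- sample(4:10, 1)
    net <- generate_network(synth_spec(n, sample(n:(2 * n), 1), seed = 300 + i))
    fam <- enumerate_minimum_fvs(net)
    self_loops <- unique(net$edges$source[net$edges$source == net$edges$target])
    g <- as_igraph(net)
    scc <- igraph::components(g, mode = "strong")
    nontrivial <- names(which(table(scc$membership) > 1))
    cyclic_nodes <- union(node_ids(net)[scc$membership %in% nontrivial],
                          self_loops)
    for (s in fam$sets) {
      # every self-loop node is in every FVS
      expect_true(all(self_loops %in% s))
      # no FVS member lies outside all cycles
      expect_true(all(s %in% cyclic_nodes))
    }
  }
})

test_that("brute force refuses large inputs; acyclic family is the empty set", {
  big <- generate_network(synth_spec(20, 30, seed = 4))
  expect_error(brute_force_minimum_fvs(big), "refused")
  fam <- brute_force_minimum_fvs(random_dag(5, 4, seed = 2))
  expect_equal(fam$minimum_size, 0L)
  expect_equal(fam$sets, list(character(0)))
})

test_that("family JSON serialization carries sets and groups", {
  fam <- enumerate_minimum_fvs(double_toggle())
  js <- jsonlite::fromJSON(fvs_family_json(fam), simplifyVector = FALSE)
  expect_equal(js$minimum_size, 2L)
  expect_equal(length(js$sets), 4L)
  expect_equal(sort(lengths(js$groups)), c(2L, 2L))
})
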