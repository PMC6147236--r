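panel2 <- marker_panel(list(left = "u", right = "v"), tau = 0.5)

test_that("readout classification applies the threshold and subset rules", {
  panel <- marker_panel(list(
    epidermis = "Epi1", brain = c("Bco", "Celf3.a"), pan_neural = "Celf3.a"),
    tau = 0.5)
  expect_equal(classify_readout(c(Epi1 = 0.9, Bco = 0.1, Celf3.a = 0.1), panel),
               "epidermis")
  # brain + pan-neural both qualify; pan-neural defers to its superset
  expect_equal(classify_readout(c(Epi1 = 0.1, Bco = 0.9, Celf3.a = 0.9), panel),
               "brain")
  expect_equal(classify_readout(c(Epi1 = 0, Bco = 0, Celf3.a = 0), panel),
               "none")
  expect_equal(classify_readout(c(Epi1 = 0.9, Bco = 0.9, Celf3.a = 0.9), panel),
               "multiple")
  # pan-neural alone (Celf3.a high, Bco low) reads as pan-neural
  expect_equal(classify_readout(c(Epi1 = 0.1, Bco = 0.1, Celf3.a = 0.9), panel),
               "pan_neural")
  expect_error(classify_readout(c(Epi1 = 1), panel), "unknown marker")
  # invariance to panel order
  flipped <- marker_panel(rev(list(
    epidermis = "Epi1", brain = c("Bco", "Celf3.a"), pan_neural = "Celf3.a")),
    tau = 0.5)
  st <- c(Epi1 = 0.1, Bco = 0.9, Celf3.a = 0.9)
  expect_equal(classify_readout(st, panel), classify_readout(st, flipped))
})

test_that("clamping the full FVS steers fig1f onto either steady state", {
  m <- build_dynamics(get_fixture("fig1f")$network)
  at <- enumerate_attractors(m, n_inits = 30, seed = 7)
  expect_equal(length(at$attractors), 2L)
  for (i in 1:2) {
    rep_ <- verify_fvs_control(m, "a", at$attractors[[i]], n_inits = 30,
                               seed = 40 + i)
    expect_true(rep_$success)
    expect_lt(max(rep_$deviations), 1e-3)
  }
})

test_that("control verification enforces its hypotheses", {
  m <- build_dynamics(get_fixture("fig1f")$network)
  at <- enumerate_attractors(m, n_inits = 10, seed = 7)
  tgt <- at$attractors[[1]]
  expect_error(verify_fvs_control(m, "b", tgt), "not a feedback vertex set")
  fake <- tgt; fake$converged <- FALSE
  expect_error(verify_fvs_control(m, "a", fake), "converged")
})

test_that("an acyclic network is controlled by the empty FVS", {
  m <- build_dynamics(get_fixture("fig1e")$network)
  tgt <- find_steady_state(m, rep(0.2, 5))
  rep_ <- verify_fvs_control(m, character(0), tgt, n_inits = 10, seed = 5)
  expect_true(rep_$success)
})

test_that("clamping a proper non-FVS subset leaves residual multistability", {
  net <- double_toggle()
  m <- build_dynamics(net)
  at <- enumerate_attractors(m, n_inits = 40, seed = 17)
  expect_equal(length(at$attractors), 4L)   # product of two bistable pairs
  fvs <- enumerate_minimum_fvs(net)$sets[[1]]
  tgt <- at$attractors[[1]]
  fail <- demonstrate_subset_failure(m, fvs, fvs[1], tgt, n_inits = 20, seed = 19)
  expect_gte(fail$n_attractors, 2L)         # untouched toggle stays bistable
  # contrast: the full FVS collapses the system to one attractor
  full <- enumerate_attractors(m, n_inits = 20, seed = 23,
                               clamps = clamp_assignment(tgt$state[fvs]))
  expect_equal(length(full$attractors), 1L)
  # preconditions
  expect_error(demonstrate_subset_failure(m, fvs, fvs, tgt), "proper subset")
  expect_error(demonstrate_subset_failure(m, node_ids(net), fvs, tgt),
               "itself an FVS")
})

test_that("binary scan is complete, duplicate-free and exact on clamps", {
  m <- build_dynamics(get_fixture("toggle")$network)
  sc <- binary_scan(m, "u", panel2, n_inits = 3, seed = 5)
  expect_equal(length(sc$records), 2L)
  expect_setequal(sc$table$condition_code, c("u", "U"))
  expect_false(identical(sc$records[[1]]$readout, sc$records[[2]]$readout))
  for (r in sc$records) {
    expect_true(all(r$steady_state$state[names(r$clamps)] ==
                      as.numeric(r$clamps)))
  }
  # 2-node scan: 4 conditions, binary counting order on the given node order
  sc2 <- binary_scan(m, c("u", "v"), panel2, n_inits = 2, seed = 5)
  expect_equal(sc2$table$condition_code, c("uv", "uV", "Uv", "UV"))
})

test_that("a panel with no marker above threshold reads 'none'", {
  chain <- regulatory_network(c("p", "q"), data.frame(
    source = "p", target = "q", sign = "-"))
  m <- build_dynamics(chain, list(defaults = list(c_top = 1)))
  # p is clamped high, q is repressed to ~0: marker q below tau
  sc <- binary_scan(m, "p", marker_panel(list(tq = "q"), tau = 0.5),
                    n_inits = 2, seed = 3)
  expect_equal(sc$records[[2]]$condition_code, "P")
  expect_equal(sc$records[[2]]$readout, "none")
})

test_that("condition-code letters derive from display names with overrides", {
  net <- get_fixture("ciona")$network
  ids <- c("Foxa.a", "Foxd", "Neurog", "Zic-r.b", "Erk_signaling")
  auto <- condition_letters(net, ids)
  expect_equal(length(auto), 5L)
  expect_true(anyDuplicated(auto) == 0)    # collisions resolved
  lett <- condition_letters(net, ids, letters = c("A", "D", "N", "Z", "E"))
  expect_equal(lett, c("A", "D", "N", "Z", "E"))
})

test_that("scan CSV and JSON sidecar round-trip the records", {
  m <- build_dynamics(get_fixture("toggle")$network)
  sc <- binary_scan(m, c("u", "v"), panel2, n_inits = 2, seed = 5)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_scan(sc, csv, js)
  tab <- read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 4L)
  expect_equal(names(tab), c("condition_code", "u", "v", "readout", "residual"))
  side <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_equal(length(side), 4L)
  expect_equal(side[[1]]$condition_code, tab$condition_code[1])
})
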