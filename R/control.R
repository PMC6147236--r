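#' Tissue marker panel
#'
#' A list of tissue labels, each with the node ids of its marker genes,
#' plus an activity threshold `tau` expressed as a fraction of each
#' marker's maximum attainable activity. Used to label the steady state a
#' clamping condition reaches with the cell fate it resembles.
#'
#' @param tissues named list: tissue label -> character vector of marker ids
#' @param tau activity threshold in (0, 1) (default 0.5)
#' @return object of class `marker_panel`
#' @export
marker_panel <- function(tissues, tau = 0.5) {
  stopifnot(is.list(tissues), length(tissues) >= 1)
  if (is.null(names(tissues)) || anyDuplicated(names(tissues))) {
    stop("tissue labels must be unique and named")
  }
  tissues <- lapply(tissues, as.character)
  stopifnot(tau > 0, tau < 1)
  structure(list(tissues = tissues, tau = tau), class = "marker_panel")
}

#' Classify the tissue readout of a steady state
#'
#' A tissue qualifies when every one of its markers sits above
#' `tau * node_max`. When exactly one tissue qualifies its label is
#' returned; with several, a tissue whose marker set is a proper subset of
#' another qualifying tissue's markers defers to the superset (the
#' pan-neural panel defers to the brain panel when both light up). If more
#' than one tissue survives the subset rule the readout is `"multiple"`;
#' with none it is `"none"`.
#'
#' @param state a `steady_state` (must be converged) or named numeric vector
#' @param panel a [marker_panel]
#' @param node_max named numeric vector of per-node maximum activities
#'   (typically [state_box_upper]); defaults to 1 for every marker
#' @param tau threshold override; defaults to `panel$tau`
#' @return character label
#' @export
classify_readout <- function(state, panel, node_max = NULL, tau = panel$tau) {
  if (inherits(state, "steady_state")) {
    if (!isTRUE(state$converged)) stop("state is not converged")
    state <- state$state
  }
  markers <- unique(unlist(panel$tissues))
  missing <- setdiff(markers, names(state))
  if (length(missing)) stop("unknown marker id: ", paste(missing, collapse = ", "))
  if (is.null(node_max)) node_max <- stats::setNames(rep(1, length(markers)), markers)
  qualifies <- vapply(panel$tissues, function(m) {
    all(state[m] > tau * node_max[m])
  }, TRUE)
  qual <- names(panel$tissues)[qualifies]
  if (length(qual) > 1L) {
    drop <- vapply(qual, function(a) {
      any(vapply(setdiff(qual, a), function(b) {
        all(panel$tissues[[a]] %in% panel$tissues[[b]]) &&
          length(panel$tissues[[a]]) < length(panel$tissues[[b]])
      }, TRUE))
    }, TRUE)
    qual <- qual[!drop]
  }
  if (length(qual) == 0L) "none" else if (length(qual) == 1L) qual else "multiple"
}

#' Verify FVS clamping control toward a target attractor
#'
#' The structural-control property under the decay condition: clamping all
#' nodes of a feedback vertex set at their values in a steady state of the
#' unclamped system forces every trajectory to converge on that steady
#' state. This clamps `fvs` at `target`'s values, integrates from `n_inits`
#' seeded random initial states, and reports the per-run maximum deviation
#' of the non-FVS coordinates from the target.
#'
#' @param model a `dynamics_model`
#' @param fvs character vector of node ids; must satisfy [is_fvs]
#' @param target a converged `steady_state` of the unclamped model
#' @param n_inits number of random initial states (default 30)
#' @param seed integer seed
#' @param tol_attr attractor-identity tolerance (default 1e-3)
#' @return list with `success`, `deviations` (length `n_inits`),
#'   `n_converged`, `tolerance`, `seed`
#' @export
verify_fvs_control <- function(model, fvs, target, n_inits = 30, seed = 1,
                               tol_attr = 1e-3) {
  if (!inherits(target, "steady_state") || !isTRUE(target$converged)) {
    stop("target must be a converged steady_state")
  }
  if (!is_fvs(model$network, fvs)) {
    stop("the candidate set is not a feedback vertex set; the control ",
         "property's hypothesis fails")
  }
  clamps <- clamp_assignment(target$state[fvs])
  rest <- setdiff(model$ids, fvs)
  upper <- state_box_upper(model)
  inits <- with_seed(seed, {
    matrix(stats::runif(n_inits * model$n, 0, rep(pmax(upper, 1e-9), each = n_inits)),
           nrow = n_inits)
  })
  deviations <- rep(NA_real_, n_inits)
  n_conv <- 0L
  for (r in seq_len(n_inits)) {
    ss <- find_steady_state(model, inits[r, ], clamps = clamps)
    if (ss$converged) n_conv <- n_conv + 1L
    deviations[r] <- if (length(rest)) max(abs(ss$state[rest] - target$state[rest])) else 0
  }
  list(success = n_conv == n_inits && all(deviations <= tol_attr),
       deviations = deviations, n_converged = n_conv,
       tolerance = tol_attr, seed = seed)
}

#' Demonstrate that a proper FVS subset does not control the dynamics
#'
#' Clamps only `proper_subset` (at its values in `target`) and counts the
#' distinct attractors of the remaining system. A count of two or more
#' demonstrates non-control: fixing part of an FVS leaves residual
#' feedback, hence residual multistability.
#'
#' @param model a `dynamics_model`
#' @param fvs the full FVS (character vector)
#' @param proper_subset proper subset of `fvs` that is itself NOT an FVS
#' @param target a converged `steady_state` supplying the clamp values
#' @param n_inits random starts for the attractor sweep (default 20)
#' @param seed integer seed
#' @param tol_attr attractor-identity tolerance
#' @return list with `n_attractors`, `attractor_set`, `subset`, `seed`
#' @export
demonstrate_subset_failure <- function(model, fvs, proper_subset, target,
                                       n_inits = 20, seed = 1, tol_attr = 1e-3) {
  if (!all(proper_subset %in% fvs) || length(proper_subset) >= length(fvs)) {
    stop("proper_subset must be a proper subset of fvs")
  }
  if (is_fvs(model$network, proper_subset)) {
    stop("proper_subset is itself an FVS; no control failure is expected")
  }
  if (!inherits(target, "steady_state") || !isTRUE(target$converged)) {
    stop("target must be a converged steady_state")
  }
  clamps <- clamp_assignment(target$state[proper_subset])
  att <- enumerate_attractors(model, n_inits = n_inits, seed = seed,
                              clamps = clamps, tol_attr = tol_attr)
  list(n_attractors = length(att$attractors), attractor_set = att,
       subset = proper_subset, seed = seed)
}

#' Condition-code letters for a set of clamped nodes
#'
#' Default rule: the first alphanumeric character of each node's display
#' name, with an index appended on collisions. Upper case encodes a high
#' clamp, lower case a low clamp. Pass `letters` to override (e.g. the
#' A/D/N/Z/E letters conventional for the ascidian network).
#'
#' @param net a [regulatory_network]
#' @param ids node ids, in scan order
#' @param letters optional character vector of single letters (same length)
#' @return character vector of code letters (upper case)
#' @export
condition_letters <- function(net, ids, letters = NULL) {
  if (!is.null(letters)) {
    stopifnot(length(letters) == length(ids))
    return(toupper(letters))
  }
  disp <- net$nodes$display_name[match(ids, net$nodes$id)]
  lett <- toupper(substr(gsub("[^A-Za-z0-9]", "", disp), 1, 1))
  if (anyDuplicated(lett)) {
    for (l in unique(lett[duplicated(lett)])) {
      at <- which(lett == l)
      lett[at] <- paste0(l, seq_along(at))
    }
  }
  lett
}

#' Exhaustive binary clamping scan over an FVS
#'
#' Evaluates all `2^k` assignments of `{low, high}` clamp values to the `k`
#' FVS nodes, ordered by binary counting on the given node order (first
#' node = most significant bit; 0 = low). Each condition is integrated from
#' `n_inits` seeded random initial states; when all runs converge to the
#' same state (within `tol_attr`) the record holds that steady state and
#' its marker readout, otherwise the readout is `"nonconverged"` (for
#' integration failures) or `"ambiguous"` (for disagreeing endpoints) —
#' endpoints are never averaged.
#'
#' @param model a `dynamics_model`
#' @param fvs ordered character vector of FVS node ids (nonempty)
#' @param panel a [marker_panel]
#' @param low,high clamp levels, `low < high` (defaults 0 and 1, the binary
#'   abstraction of inactive/active on normalized activities)
#' @param n_inits random starts per condition (default 3)
#' @param seed integer seed
#' @param letters optional code-letter override (see [condition_letters])
#' @param tol_attr endpoint agreement tolerance
#' @return object of class `scan_result`: list of records, each with
#'   `condition_code`, `clamps`, `steady_state`, `readout`; plus a
#'   data.frame summary in `$table`
#' @export
binary_scan <- function(model, fvs, panel, low = 0, high = 1, n_inits = 3,
                        seed = 1, letters = NULL, tol_attr = 1e-3) {
  stopifnot(length(fvs) >= 1, low < high)
  unknown <- setdiff(fvs, model$ids)
  if (length(unknown)) stop("unknown node id: ", paste(unknown, collapse = ", "))
  k <- length(fvs)
  lett <- condition_letters(model$network, fvs, letters)
  node_max <- pmax(state_box_upper(model), high)
  records <- vector("list", 2^k)
  for (cond in 0:(2^k - 1)) {
    bits <- as.integer(intToBits(cond))[k:1]   # first node = MSB
    vals <- ifelse(bits == 1L, high, low)
    code <- paste(ifelse(bits == 1L, lett, tolower(lett)), collapse = "")
    clamps <- clamp_assignment(stats::setNames(vals, fvs))
    sss <- list()
    for (r in seq_len(n_inits)) {
      att_seed <- seed + 1000L * cond + r
      init <- with_seed(att_seed, stats::runif(model$n, 0, pmax(node_max, 1e-9)))
      sss[[r]] <- find_steady_state(model, init, clamps = clamps)
    }
    conv <- vapply(sss, function(s) isTRUE(s$converged), TRUE)
    if (!all(conv)) {
      ss <- sss[[which(!conv)[1]]]
      readout <- "nonconverged"
    } else {
      agree <- all(vapply(sss[-1], function(s) {
        max(abs(s$state - sss[[1]]$state)) <= tol_attr
      }, TRUE))
      ss <- sss[[1]]
      readout <- if (agree) {
        classify_readout(ss, panel, node_max = node_max)
      } else "ambiguous"
    }
    ss$label <- readout
    records[[cond + 1L]] <- list(condition_code = code, clamps = clamps,
                                 steady_state = ss, readout = readout)
  }
  table <- data.frame(
    condition_code = vapply(records, `[[`, "", "condition_code"),
    readout = vapply(records, `[[`, "", "readout"),
    residual = vapply(records, function(r) r$steady_state$residual, 0),
    stringsAsFactors = FALSE)
  for (j in seq_along(fvs)) {
    table[[fvs[j]]] <- vapply(records, function(r) unname(r$clamps[fvs[j]]), 0)
  }
  structure(list(records = records, table = table, fvs = fvs,
                 low = low, high = high, seed = seed),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %d conditions over FVS {%s}\n",
              length(x$records), paste(x$fvs, collapse = ", ")))
  print(x$table[, c("condition_code", "readout", "residual")])
  invisible(x)
}

#' Write a scan result to CSV (+ JSON sidecar with full steady states)
#'
#' @param scan a `scan_result`
#' @param csv_path CSV output path; columns: condition_code, one column per
#'   clamped node, readout, residual
#' @param json_path optional sidecar path with the full steady states
#' @return invisibly, `csv_path`
#' @export
write_scan <- function(scan, csv_path, json_path = NULL) {
  tab <- scan$table[, c("condition_code", scan$fvs, "readout", "residual")]
  utils::write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    side <- lapply(scan$records, function(r) {
      list(condition_code = r$condition_code,
           clamps = as.list(unclass(r$clamps)),
           readout = r$readout,
           converged = r$steady_state$converged,
           residual = r$steady_state$residual,
           state = as.list(r$steady_state$state))
    })
    writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), json_path)
  }
  invisible(csv_path)
}

#' Ensemble check of the FVS-control property
#'
#' Over `n_models` seeded random multistable decay-condition models:
#' clamp a minimum FVS at each discovered attractor's values and verify
#' recovery from random initial states; also clamp an equal-size random
#' non-FVS subset and count the attractors that remain. Returns per-model
#' results and the headline rates.
#'
#' @param n_models ensemble size
#' @param seed master seed; model `i` derives its seeds from it
#' @param n_inits_verify random starts per verification (default 30)
#' @param n_inits_attr random starts for attractor discovery (default 20)
#' @param spec_template a [synth_spec] whose seed field is overridden per
#'   model; defaults to 6 nodes, 10 edges, 2 toggle motifs
#' @return list with `fraction_controlled` (fraction of FVS-clamp runs that
#'   recovered the target), `n_subset_multistable` (models where the
#'   equal-size non-FVS subset left >= 2 attractors), `details`
#' @export
fvs_control_ensemble <- function(n_models = 50, seed = 1,
                                 n_inits_verify = 30, n_inits_attr = 20,
                                 spec_template = NULL) {
  if (is.null(spec_template)) {
    spec_template <- synth_spec(n_nodes = 6, n_edges = 10,
                                repression_fraction = 0.3,
                                n_toggle_motifs = 2, seed = 0)
  }
  details <- vector("list", n_models)
  n_runs <- 0L; n_ok <- 0L; n_subset_multi <- 0L
  for (i in seq_len(n_models)) {
    mseed <- seed + 101L * i
    spec <- spec_template; spec$seed <- mseed
    gen <- generate_multistable_model(spec, n_inits = n_inits_attr,
                                      attr_seed = mseed + 1L)
    model <- gen$model
    fam <- enumerate_minimum_fvs(model$network)
    fvs <- fam$sets[[1L]]
    ok_i <- TRUE
    for (a in seq_along(gen$attractors$attractors)) {
      tgt <- gen$attractors$attractors[[a]]
      rep_ <- verify_fvs_control(model, fvs, tgt,
                                 n_inits = n_inits_verify,
                                 seed = mseed + 10L + a)
      n_runs <- n_runs + 1L
      if (rep_$success) n_ok <- n_ok + 1L else ok_i <- FALSE
    }
    # random equal-size non-FVS subset (if one exists)
    subset_multi <- NA
    non_fvs <- with_seed(mseed + 77L, {
      found <- NULL
      for (try in 1:50) {
        cand <- sort(sample(model$ids, length(fvs)))
        if (!is_fvs(model$network, cand)) { found <- cand; break }
      }
      found
    })
    if (!is.null(non_fvs)) {
      tgt <- gen$attractors$attractors[[1L]]
      clamps <- clamp_assignment(tgt$state[non_fvs])
      att <- enumerate_attractors(model, n_inits = n_inits_attr,
                                  seed = mseed + 88L, clamps = clamps)
      subset_multi <- length(att$attractors) >= 2L
      if (isTRUE(subset_multi)) n_subset_multi <- n_subset_multi + 1L
    }
    details[[i]] <- list(seed = mseed, fvs = fvs,
                         n_attractors = length(gen$attractors$attractors),
                         controlled = ok_i, non_fvs_subset = non_fvs,
                         subset_multistable = subset_multi)
  }
  list(fraction_controlled = if (n_runs) n_ok / n_runs else NA_real_,
       n_runs = n_runs,
       n_subset_multistable = n_subset_multi,
       details = details)
}
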