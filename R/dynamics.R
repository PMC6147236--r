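#' Build a decay-condition ODE model on a network
#'
#' Every node `n` with regulators `I_n` evolves as
#' \deqn{\dot x_n = -d_n x_n + c_n + b_n\,\sigma(\beta_n (u_n - \theta_n)),
#'       \quad u_n = \sum_{i \in I_n} s_{in} w_{in} x_i,}
#' where `sigma` is the standard logistic, `s_in` is +1 for activating and
#' -1 for repressing edges (unknown counts as +1) and `w_in >= 0` is the
#' edge weight. Nodes without regulators ("top" nodes) follow the linear
#' decay `-d_n x_n + c_n` and converge on the unique equilibrium `c_n/d_n`
#' from any start. An AND-like product form is available via
#' `regulation = "product"`, replacing the logistic of the sum with a
#' product of per-edge logistic terms (activators `sigma(beta (w x_i -
#' 1/2))`, repressors `sigma(beta (1/2 - w x_i))`).
#'
#' Both forms satisfy the decay condition by construction: holding the
#' regulation input fixed, the partial derivative of the drift with respect
#' to a node's own activity is exactly `-d_n < 0`. Self-loops influence a
#' node only through the (bounded) regulation term. Consequently the box
#' `[0, (b_n + c_n)/d_n]` per coordinate is forward-invariant.
#'
#' Defaults: `d = 1`, `b = 1`, `c = 0` for regulated nodes and `c = 0.5`
#' for top nodes, `w = 1`, `beta = 10`, and threshold
#' `theta_n = 0.5 * sum_i s_in w_in` — half the signed input attained when
#' all regulators sit at activity one. Centering the threshold this way
#' makes canonical feedback motifs behave as expected: a mutual-repression
#' toggle is bistable, a positive auto-/cross-activation loop is bistable,
#' and a pure repression chain can still switch its target on when the
#' repressor is off.
#'
#' @param net a [regulatory_network]
#' @param params optional list of overrides: `defaults` (named list with
#'   any of `d`, `b`, `c`, `c_top`, `beta`, `w`, `theta`), `nodes` (named
#'   list, per node id, of per-node overrides `d`, `b`, `c`, `beta`,
#'   `theta`), `edges` (list of `list(source=, target=, w=)`), and
#'   `regulation` (`"sum"`, the default, or `"product"`).
#' @return an object of class `dynamics_model`
#' @export
build_dynamics <- function(net, params = list()) {
  ids <- node_ids(net)
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  def <- list(d = 1, b = 1, c = 0, c_top = 0.5, beta = 10, w = 1)
  for (nm in names(params$defaults)) def[[nm]] <- params$defaults[[nm]]
  regulation <- params$regulation %||% "sum"
  if (!regulation %in% c("sum", "product")) stop("unknown regulation form: ", regulation)

  has_in <- ids %in% net$edges$target
  d <- rep(def$d, n); b <- rep(def$b, n); beta <- rep(def$beta, n)
  c_ <- ifelse(has_in, def$c, def$c_top)

  w <- rep(def$w, nrow(net$edges))
  s <- ifelse(net$edges$sign == "repressing", -1, 1)
  if (!is.null(params$edges)) {
    for (ov in params$edges) {
      hit <- net$edges$source == ov$source & net$edges$target == ov$target
      if (!any(hit)) stop("edge override references unknown edge ",
                          ov$source, " -> ", ov$target)
      if (!is.null(ov$w)) w[hit] <- ov$w
    }
  }
  if (any(w < 0)) stop("edge weights must be nonnegative")

  # theta default: half the signed weight sum of the inputs
  theta <- vapply(seq_len(n), function(i) {
    e <- net$edges$target == ids[i]
    if (!any(e)) 0 else 0.5 * sum(s[e] * w[e])
  }, 0)
  if (!is.null(params$defaults$theta)) theta[has_in] <- params$defaults$theta

  if (!is.null(params$nodes)) {
    unknown <- setdiff(names(params$nodes), ids)
    if (length(unknown)) stop("node override references unknown node: ",
                              paste(unknown, collapse = ", "))
    for (id in names(params$nodes)) {
      ov <- params$nodes[[id]]; i <- idx[[id]]
      for (nm in intersect(names(ov), c("d", "b", "beta"))) {
        if (nm == "d") d[i] <- ov$d
        if (nm == "b") b[i] <- ov$b
        if (nm == "beta") beta[i] <- ov$beta
      }
      if (!is.null(ov$c)) c_[i] <- ov$c
      if (!is.null(ov$theta)) theta[i] <- ov$theta
    }
  }
  if (any(d <= 0)) stop("decay rates d must be positive")
  if (any(beta <= 0)) stop("steepness beta must be positive")
  if (any(b < 0) || any(c_ < 0)) stop("b and c must be nonnegative")

  # per-target input indices and signed weights
  src <- vector("list", n); sw <- vector("list", n); wts <- vector("list", n)
  sgn <- vector("list", n)
  for (i in seq_len(n)) {
    e <- which(net$edges$target == ids[i])
    src[[i]] <- unname(idx[net$edges$source[e]])
    sw[[i]] <- s[e] * w[e]
    wts[[i]] <- w[e]
    sgn[[i]] <- s[e]
  }
  # dense signed-weight matrix for the sum form: u = W %*% x
  W <- matrix(0, n, n)
  for (i in seq_len(n)) if (length(src[[i]])) W[i, src[[i]]] <- sw[[i]]

  structure(list(network = net, ids = ids, n = n,
                 d = d, b = b, c = c_, theta = theta, beta = beta,
                 has_in = has_in, W = W, src = src, sw = sw,
                 wts = wts, sgn = sgn,
                 regulation = regulation,
                 edge_w = w, edge_s = s),
            class = "dynamics_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dynamics_model <- function(x, ...) {
  cat(sprintf("<dynamics_model> %s: %d nodes (%d top), %s regulation\n",
              x$network$name, x$n, sum(!x$has_in), x$regulation))
  invisible(x)
}

#' Drift (right-hand side) of a dynamics model
#'
#' @param model a `dynamics_model`
#' @param x numeric state vector in node order (or named by node id)
#' @return numeric vector of time derivatives, named by node id
#' @export
drift <- function(model, x) {
  x <- as_state_values(model, x)
  reg <- if (model$regulation == "sum") {
    u <- as.vector(model$W %*% x)
    model$b * stats::plogis(model$beta * (u - model$theta))
  } else {
    vapply(seq_len(model$n), function(i) {
      if (!model$has_in[i]) return(0)
      h <- ifelse(model$sgn[[i]] > 0,
                  stats::plogis(model$beta[i] * (model$wts[[i]] * x[model$src[[i]]] - 0.5)),
                  stats::plogis(model$beta[i] * (0.5 - model$wts[[i]] * x[model$src[[i]]])))
      model$b[i] * prod(h)
    }, 0)
  }
  reg[!model$has_in] <- 0
  stats::setNames(-model$d * x + model$c + reg, model$ids)
}

as_state_values <- function(model, x) {
  if (!is.null(names(x))) {
    missing <- setdiff(model$ids, names(x))
    if (length(missing)) stop("state missing nodes: ", paste(missing, collapse = ", "))
    x <- x[model$ids]
  }
  if (length(x) != model$n) stop("state length ", length(x), " != ", model$n, " nodes")
  unname(as.numeric(x))
}

#' Upper corner of the forward-invariant box
#'
#' Per-coordinate maximum attainable activity `(b_n + c_n)/d_n` (with
#' `b_n` omitted for top nodes, whose regulation term is absent).
#'
#' @param model a `dynamics_model`
#' @return named numeric vector
#' @export
state_box_upper <- function(model) {
  stats::setNames((model$c + ifelse(model$has_in, model$b, 0)) / model$d,
                  model$ids)
}

#' Self-part derivative check (decay condition)
#'
#' Central finite difference of each node's drift with respect to its own
#' activity while the regulation input is held frozen. For this model
#' family the result is exactly `-d_n`; the numeric check is exposed so
#' generated models can be audited.
#'
#' @param model a `dynamics_model`
#' @param x state at which to evaluate
#' @param h finite-difference step
#' @return named numeric vector of derivatives (should be `<= -d_n + eps`)
#' @export
selfpart_derivative <- function(model, x, h = 1e-6) {
  x <- as_state_values(model, x)
  reg_at <- function(xx) drift(model, xx) + model$d * xx - model$c
  reg0 <- reg_at(x)    # frozen regulation input
  vapply(seq_len(model$n), function(i) {
    up <- x; up[i] <- up[i] + h
    dn <- x; dn[i] <- dn[i] - h
    fu <- -model$d[i] * up[i] + model$c[i] + reg0[i]
    fd <- -model$d[i] * dn[i] + model$c[i] + reg0[i]
    (fu - fd) / (2 * h)
  }, 0) -> out
  stats::setNames(out, model$ids)
}

#' Clamp assignment
#'
#' A named mapping from node ids to fixed activity values. Clamped
#' coordinates are removed from the ODE state and pinned exactly; they are
#' not approximated by stiff penalty terms.
#'
#' @param ... named values, or a single named numeric vector / list
#' @return an object of class `clamp_assignment` (named numeric vector)
#' @export
clamp_assignment <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) ||
      (length(args) == 1L && (is.numeric(args[[1]]) || is.list(args[[1]])) &&
       !is.null(names(args[[1]])))) {
    v <- unlist(args[[1]])
  } else {
    v <- unlist(args)
  }
  if (length(v) && (is.null(names(v)) || any(names(v) == ""))) {
    stop("clamp values must be named by node id")
  }
  v <- stats::setNames(as.numeric(v), names(v))
  if (length(v) && (any(!is.finite(v)) || any(v < 0))) {
    stop("clamp values must be finite and nonnegative")
  }
  structure(v, class = "clamp_assignment")
}

check_clamps <- function(model, clamps) {
  if (is.null(clamps)) return(clamp_assignment())
  if (!inherits(clamps, "clamp_assignment")) clamps <- clamp_assignment(clamps)
  unknown <- setdiff(names(clamps), model$ids)
  if (length(unknown)) stop("clamp references unknown node: ",
                            paste(unknown, collapse = ", "))
  clamps
}

# rhs on the free (unclamped) subsystem, for deSolve
free_rhs <- function(model, free_idx, full_template) {
  force(full_template)
  function(t, y, parms) {
    x <- full_template
    x[free_idx] <- y
    list(drift(model, x)[free_idx])
  }
}

#' Integrate the model
#'
#' Stiff-capable integration (deSolve, `lsoda`) with clamped coordinates
#' held exactly constant via subsystem reduction. The returned trajectory
#' includes the initial and final states.
#'
#' @param model a `dynamics_model`
#' @param init initial state (numeric vector in node order, or named)
#' @param t_max end time (> 0)
#' @param clamps optional [clamp_assignment]
#' @param n_out number of output time points (default 101)
#' @return data.frame with column `time` plus one column per node
#' @export
simulate <- function(model, init, t_max, clamps = NULL, n_out = 101) {
  stopifnot(t_max > 0)
  clamps <- check_clamps(model, clamps)
  x0 <- as_state_values(model, init)
  x0[match(names(clamps), model$ids)] <- as.numeric(clamps)
  free_idx <- which(!(model$ids %in% names(clamps)))
  times <- seq(0, t_max, length.out = max(2L, n_out))
  if (!length(free_idx)) {
    out <- matrix(rep(x0, each = length(times)), nrow = length(times))
  } else {
    sol <- suppressWarnings(
      deSolve::ode(y = x0[free_idx], times = times,
                   func = free_rhs(model, free_idx, x0),
                   parms = NULL, method = "lsoda",
                   rtol = 1e-9, atol = 1e-10, maxsteps = 20000))
    if (attr(sol, "istate")[1] < 0) {
      good <- which(stats::complete.cases(sol))
      last <- x0
      last[free_idx] <- sol[max(good), -1]
      cond <- structure(
        class = c("fvs_integration_error", "error", "condition"),
        list(message = paste0("integration failure; last good time ",
                              sol[max(good), 1]),
             call = sys.call(-1), last_state = last,
             last_time = sol[max(good), 1]))
      stop(cond)
    }
    out <- matrix(rep(x0, each = length(times)), nrow = length(times))
    out[, free_idx] <- sol[, -1, drop = FALSE]
  }
  df <- data.frame(time = times, out)
  names(df) <- c("time", model$ids)
  df
}

#' Find a steady state by integration plus Newton polishing
#'
#' Integrates until the max-norm drift on the unclamped subsystem drops
#' below `tol_ss` or the horizon is reached, doubling the horizon from
#' `t_max` up to `t_cap`, then polishes with a damped Newton iteration on
#' the free coordinates (numeric Jacobian). If the residual never reaches
#' `tol_ss` the result is flagged `converged = FALSE` — a non-stationary
#' point is never silently reported as steady.
#'
#' @param model a `dynamics_model`
#' @param init initial state
#' @param clamps optional [clamp_assignment]
#' @param tol_ss steady-state residual tolerance, max norm (default 1e-8)
#' @param t_max initial integration horizon (default 200)
#' @param t_cap maximum horizon after doubling (default 1600)
#' @param polish_from residual below which Newton polishing is attempted;
#'   from farther away polishing is skipped so that Newton cannot land on an
#'   unstable equilibrium the flow never reaches (default 1e-4)
#' @return an object of class `steady_state`: list with `state` (named
#'   numeric), `residual`, `converged`, `time`, `label`
#' @export
find_steady_state <- function(model, init, clamps = NULL, tol_ss = 1e-8,
                              t_max = 200, t_cap = 1600, polish_from = 1e-4) {
  clamps <- check_clamps(model, clamps)
  x <- as_state_values(model, init)
  x[match(names(clamps), model$ids)] <- as.numeric(clamps)
  free_idx <- which(!(model$ids %in% names(clamps)))
  residual_of <- function(x) {
    if (!length(free_idx)) 0 else max(abs(drift(model, x)[free_idx]))
  }
  t_used <- 0
  horizon <- t_max
  while (residual_of(x) > tol_ss && t_used < t_cap) {
    span <- min(horizon, t_cap - t_used)
    step <- tryCatch(
      simulate(model, x, span, clamps = clamps, n_out = 2),
      fvs_integration_error = function(c) c)
    if (inherits(step, "fvs_integration_error")) {
      # integrator gave up (e.g. a limit cycle demanding excessive steps):
      # keep the last good state and fall through to polishing; the result
      # is reported non-converged unless polishing truly lands on a root
      x <- step$last_state
      t_used <- t_used + step$last_time
      break
    }
    x <- as.numeric(step[nrow(step), -1])
    t_used <- t_used + span
    horizon <- horizon * 2
  }
  # polish only when integration already sits near a root: Newton started
  # from a far-away state (e.g. on a limit cycle) could jump to an unstable
  # equilibrium and masquerade as a reachable attractor
  if (length(free_idx)) {
    r <- residual_of(x)
    if (r > tol_ss && r <= polish_from) {
      x <- newton_polish(model, x, free_idx, tol_ss)
    }
  }
  res <- residual_of(x)
  structure(list(state = stats::setNames(x, model$ids),
                 residual = res,
                 converged = res <= tol_ss,
                 time = t_used, label = NULL),
            class = "steady_state")
}

# damped Newton on the free subsystem; returns the best point found
newton_polish <- function(model, x, free_idx, tol, max_iter = 50) {
  f <- function(xf) { y <- x; y[free_idx] <- xf; drift(model, y)[free_idx] }
  xf <- x[free_idx]
  Fv <- f(xf)
  for (it in seq_len(max_iter)) {
    if (max(abs(Fv)) <= tol) break
    m <- length(xf)
    J <- matrix(0, m, m)
    for (j in seq_len(m)) {
      h <- 1e-7 * (1 + abs(xf[j]))
      up <- xf; up[j] <- up[j] + h
      J[, j] <- (f(up) - Fv) / h
    }
    step <- tryCatch(solve(J, Fv), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lambda <- 1
    improved <- FALSE
    while (lambda > 1e-4) {
      cand <- xf - lambda * step
      Fc <- f(cand)
      if (all(is.finite(Fc)) && max(abs(Fc)) < max(abs(Fv))) {
        xf <- cand; Fv <- Fc; improved <- TRUE; break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  x[free_idx] <- xf
  x
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state> converged=%s residual=%.3g%s\n",
              x$converged, x$residual,
              if (!is.null(x$label)) paste0(" label=", x$label) else ""))
  print(round(x$state, 4))
  invisible(x)
}

#' Enumerate attractors from random initial states
#'
#' Runs [find_steady_state] from `n_inits` seeded uniform-random initial
#' states in the forward-invariant box and clusters the converged endpoints
#' at the attractor-identity tolerance (coordinate-wise). Deterministic
#' given `seed`.
#'
#' @param model a `dynamics_model`
#' @param n_inits number of random starts (>= 1)
#' @param seed integer seed (recorded in the result)
#' @param clamps optional [clamp_assignment]
#' @param tol_attr attractor-identity tolerance per coordinate (default 1e-3)
#' @param ... passed to [find_steady_state]
#' @return object of class `attractor_set`: list with `attractors` (list of
#'   `steady_state`), `basin_counts`, `n_nonconverged`, `seed`
#' @export
enumerate_attractors <- function(model, n_inits, seed, clamps = NULL,
                                 tol_attr = 1e-3, ...) {
  stopifnot(n_inits >= 1)
  clamps <- check_clamps(model, clamps)
  upper <- state_box_upper(model)
  inits <- with_seed(seed, {
    matrix(stats::runif(n_inits * model$n, 0, rep(pmax(upper, 1e-9), each = n_inits)),
           nrow = n_inits)
  })
  reps <- list(); counts <- integer(0); nonconv <- 0L
  for (r in seq_len(n_inits)) {
    ss <- find_steady_state(model, inits[r, ], clamps = clamps, ...)
    if (!ss$converged) { nonconv <- nonconv + 1L; next }
    hit <- 0L
    for (j in seq_along(reps)) {
      if (max(abs(ss$state - reps[[j]]$state)) <= tol_attr) { hit <- j; break }
    }
    if (hit) counts[hit] <- counts[hit] + 1L
    else { reps[[length(reps) + 1L]] <- ss; counts <- c(counts, 1L) }
  }
  structure(list(attractors = reps, basin_counts = counts,
                 n_nonconverged = nonconv, seed = seed),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  cat(sprintf("<attractor_set> %d attractor(s), basins %s, %d nonconverged (seed %s)\n",
              length(x$attractors), paste(x$basin_counts, collapse = "/"),
              x$n_nonconverged, x$seed))
  invisible(x)
}

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals do not disturb the
#' caller's RNG stream.
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Serialize a steady state to JSON (keyed by node id)
#' @param ss a `steady_state`
#' @param path optional output path
#' @return JSON string
#' @export
steady_state_json <- function(ss, path = NULL) {
  obj <- list(state = as.list(ss$state), residual = ss$residual,
              converged = ss$converged, label = ss$label)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
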