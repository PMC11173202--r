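new_is_scores <- function(scores, meta) {
  structure(list(scores = scores, meta = meta), class = "is_scores")
}

#' @export
print.is_scores <- function(x, ...) {
  cat(sprintf(
    "# IS scores (%s scheme): %d nodes, %d iterations, converged: %s, residual %.3g\n",
    x$meta$scheme, nrow(x$scores), x$meta$iterations, x$meta$converged,
    x$meta$residual))
  print(x$scores, ...)
  invisible(x)
}

#' Tidiers for spreadis result objects
#'
#' `tidy()` returns the per-node (or per-replicate) table of a result object;
#' `glance()` returns its one-row summary.
#'
#' @param x A result object (`is_scores`, `contagion_rates`, `null_result`,
#'   `eval_report`).
#' @param ... Unused.
#' @return A tibble.
#' @name tidy-spreadis
NULL

#' @rdname tidy-spreadis
#' @export
tidy.is_scores <- function(x, ...) {
  x$scores
}

#' @rdname tidy-spreadis
#' @export
glance.is_scores <- function(x, ...) {
  tibble::tibble(
    scheme = x$meta$scheme,
    iterations = x$meta$iterations,
    converged = x$meta$converged,
    residual = x$meta$residual,
    n_nodes = nrow(x$scores)
  )
}

#' Reconstruct node influence and susceptibility by the nonlinear IS iteration
#'
#' Solves the coupled fixed-point equations
#' \deqn{\hat I_i = \hat f_i / \sum_j A_{ij} \hat S_j, \qquad
#'       \hat S_j = \hat g_j / \sum_i A_{ij} \hat I_i}
#' by iteration, where `f_hat`/`g_hat` are the outgoing/incoming contagion
#' rates of `rates` and `A` is the adjacency of its edge set. Under the
#' product transmission model these equations identify each node's influence
#' and susceptibility up to a single multiplicative gauge (see
#' [gauge_normalize()]).
#'
#' Two update schemes are available. The default `"alternating"`
#' (Gauss-Seidel) scheme updates the influence vector from the current
#' susceptibilities and then the susceptibilities from the *new* influences;
#' it is stationary at exactly the same fixed points as the simultaneous
#' scheme and converges far more robustly. The `"jacobi"` scheme applies both
#' updates simultaneously from the previous iterate; it is retained for
#' fidelity to the map as usually written, but note that on a single edge it
#' provably oscillates between two gauge images of the fixed point from
#' generic initial conditions and therefore fails the convergence test.
#'
#' Nodes with `f_hat = 0` are pinned at influence 0 and nodes with
#' `g_hat = 0` at susceptibility 0; they still appear (with value zero) in
#' other nodes' denominator sums. Every node with `f_hat > 0` has an
#' out-neighbor with positive `omega`, hence positive susceptibility, so no
#' active denominator can vanish; this is asserted on every run.
#'
#' @param rates A `contagion_rates` object with at least one edge.
#' @param scheme `"alternating"` (default) or `"jacobi"`.
#' @param tol Convergence tolerance on the maximum relative change of any
#'   active score between consecutive iterations.
#' @param max_iter Iteration cap.
#' @param damping Mixing weight in `[0, 1)`: the new iterate is
#'   `(1 - damping) * update + damping * previous`. Default 0; `0.5` helps on
#'   hard instances.
#' @param init_influence,init_susceptibility Positive scalar initial values
#'   for the active entries of the two vectors. Rescaling the initial pair by
#'   `(c, 1/c)` rescales every Jacobi iterate by `(c, 1/c)` (gauge
#'   covariance) and leaves the normalized alternating result unchanged.
#' @param normalize_each_iter If `TRUE`, the gauge is fixed after every
#'   iteration by rescaling the influence vector to unit mean over its
#'   positive entries (susceptibility rescaled inversely).
#' @param quiet Suppress the non-convergence warning.
#' @return An `is_scores` object: `$scores` is a tibble
#'   (`user_id`, `influence`, `susceptibility`); `$meta` records the scheme,
#'   iteration count, convergence flag and final fixed-point residual. Use
#'   [tidy()] / [glance()] to extract either part.
#' @examples
#' rates <- contagion_rates(
#'   tibble::tibble(from = "i", to = "j", omega = 0.5)
#' )
#' run_is(rates)
#' @export
run_is <- function(rates, scheme = c("alternating", "jacobi"),
                   tol = 1e-8, max_iter = 10000L, damping = 0,
                   init_influence = 1, init_susceptibility = 1,
                   normalize_each_iter = FALSE, quiet = FALSE) {
  scheme <- match.arg(scheme)
  if (!inherits(rates, "contagion_rates")) {
    abort("`rates` must be a contagion_rates object.")
  }
  if (nrow(rates$edges) == 0) {
    abort("Cannot run the IS algorithm on an empty network.")
  }
  if (tol <= 0 || max_iter < 1) {
    abort("`tol` must be positive and `max_iter` at least 1.")
  }
  if (damping < 0 || damping >= 1) {
    abort("`damping` must lie in [0, 1).")
  }
  if (init_influence <= 0 || init_susceptibility <= 0) {
    abort("Initial values must be positive.")
  }
  m <- rates_matrices(rates)
  A <- m$A
  At <- Matrix::t(A)
  f <- m$f
  g <- m$g
  active_i <- f > 0
  active_s <- g > 0
  I <- ifelse(active_i, init_influence, 0)
  S <- ifelse(active_s, init_susceptibility, 0)

  upd_i <- function(S) {
    denom <- as.numeric(A %*% S)
    if (any(denom[active_i] <= 0)) {
      abort("Internal error: vanishing denominator for an active node.")
    }
    out <- numeric(m$n)
    out[active_i] <- f[active_i] / denom[active_i]
    out
  }
  upd_s <- function(I) {
    denom <- as.numeric(At %*% I)
    if (any(denom[active_s] <= 0)) {
      abort("Internal error: vanishing denominator for an active node.")
    }
    out <- numeric(m$n)
    out[active_s] <- g[active_s] / denom[active_s]
    out
  }

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (scheme == "alternating") {
      I_new <- upd_i(S)
      if (damping > 0) I_new <- (1 - damping) * I_new + damping * I
      S_new <- upd_s(I_new)
      if (damping > 0) S_new <- (1 - damping) * S_new + damping * S
    } else {
      I_new <- upd_i(S)
      S_new <- upd_s(I)
      if (damping > 0) {
        I_new <- (1 - damping) * I_new + damping * I
        S_new <- (1 - damping) * S_new + damping * S
      }
    }
    if (normalize_each_iter) {
      mu <- mean(I_new[I_new > 0])
      I_new <- I_new / mu
      S_new <- S_new * mu
    }
    delta <- max(c(abs(I_new[active_i] / I[active_i] - 1),
                   abs(S_new[active_s] / S[active_s] - 1), 0))
    I <- I_new
    S <- S_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  scores <- tibble::tibble(user_id = m$nodes, influence = I, susceptibility = S)
  res <- new_is_scores(
    scores,
    meta = list(scheme = scheme, iterations = iter, converged = converged,
                residual = NA_real_, tol = tol, damping = damping)
  )
  res$meta$residual <- fixed_point_residual(rates, res)
  if (!converged && !quiet) {
    warn(sprintf(
      "IS iteration did not converge within %d iterations (last relative change %.3g).",
      max_iter, delta))
  }
  res
}

#' Maximum relative violation of the IS fixed-point equations
#'
#' For every node with positive outgoing rate the influence equation is
#' checked in relative form, `|1 - (f_hat / sum_j A S) / I|`, and symmetrically
#' for susceptibility; the maximum over all active nodes is returned. The
#' residual is invariant under the gauge map `(I, S) -> (c I, S / c)`.
#'
#' @param rates A `contagion_rates` object.
#' @param scores An `is_scores` object (or tibble with `user_id`,
#'   `influence`, `susceptibility`) covering the rate nodes.
#' @return A non-negative scalar; 0 at an exact fixed point. A claimed zero
#'   score for an active node yields residual 1; a vanishing denominator
#'   yields `Inf`.
#' @export
fixed_point_residual <- function(rates, scores) {
  sc <- if (inherits(scores, "is_scores")) scores$scores else
    tibble::as_tibble(scores)
  m <- rates_matrices(rates)
  idx <- match(m$nodes, sc$user_id)
  if (any(is.na(idx))) {
    abort("`scores` must cover every node of `rates`.")
  }
  I <- sc$influence[idx]
  S <- sc$susceptibility[idx]
  denom_i <- as.numeric(m$A %*% S)
  denom_s <- as.numeric(Matrix::t(m$A) %*% I)
  res <- 0
  for (side in list(list(act = m$f > 0, x = I, rate = m$f, denom = denom_i),
                    list(act = m$g > 0, x = S, rate = m$g, denom = denom_s))) {
    act <- side$act
    if (!any(act)) next
    ideal <- ifelse(side$denom[act] > 0,
                    side$rate[act] / side$denom[act], Inf)
    x <- side$x[act]
    r <- ifelse(x > 0, abs(1 - ideal / x), 1)
    r[!is.finite(ideal)] <- Inf
    res <- max(res, r)
  }
  res
}

#' Fix the multiplicative gauge of IS scores
#'
#' The fixed-point equations determine influence and susceptibility only up
#' to the map `(I, S) -> (c I, S / c)`. This helper fixes the convention by
#' rescaling the influence vector to unit mean over its positive entries and
#' the susceptibility vector by the inverse factor, leaving every edge
#' product `I_i * S_j` (and all within-vector rankings) unchanged. The
#' operation is idempotent.
#'
#' @param scores An `is_scores` object with at least one positive influence.
#' @return The rescaled `is_scores`.
#' @export
gauge_normalize <- function(scores) {
  stopifnot(inherits(scores, "is_scores"))
  I <- scores$scores$influence
  if (!any(I > 0)) {
    abort("Cannot normalize: all influence scores are zero.")
  }
  mu <- mean(I[I > 0])
  scores$scores$influence <- I / mu
  scores$scores$susceptibility <- scores$scores$susceptibility * mu
  scores$meta$normalized <- TRUE
  scores
}

#' Brute-force solution of the IS fixed-point equations
#'
#' Independent oracle for small instances: solves the coupled equations
#' directly by damped Levenberg-Marquardt root-finding
#' ([minpack.lm::nls.lm()]) in log-space from many random restarts, keeping
#' the solution with the smallest fixed-point residual. The one-parameter
#' gauge freedom of each weakly connected component is removed by pinning the
#' influence of a reference node: by default the lowest-id node with positive
#' outgoing rate in each component, at value `pin_value`.
#'
#' @param rates A `contagion_rates` object on at most `max_nodes` nodes.
#' @param pin Optional node id to pin (must have positive outgoing rate); its
#'   component uses this reference, other components fall back to the
#'   default.
#' @param pin_value Influence value assigned to the pinned node(s).
#' @param tol Residual required of the returned solution.
#' @param n_restarts Number of random restarts.
#' @param max_nodes Size guard for this oracle.
#' @param seed Optional seed for the restarts.
#' @return An `is_scores` object (`scheme = "brute_force"`).
#' @export
brute_force_fixed_point <- function(rates, pin = NULL, pin_value = 1,
                                    tol = 1e-8, n_restarts = 25L,
                                    max_nodes = 12L, seed = NULL) {
  stopifnot(inherits(rates, "contagion_rates"))
  m <- rates_matrices(rates)
  if (m$n > max_nodes) {
    abort(sprintf("Brute-force oracle limited to %d nodes (got %d).",
                  max_nodes, m$n))
  }
  if (nrow(rates$edges) == 0) {
    abort("Cannot solve an empty network.")
  }
  active_i <- which(m$f > 0)
  active_s <- which(m$g > 0)

  g_ig <- as_igraph(diffusion_network(rates$edges[c("from", "to")],
                                      nodes = m$nodes))
  comp <- igraph::components(g_ig, mode = "weak")$membership
  comp <- comp[match(as.character(m$nodes), names(comp))]

  # One pinned influence node per weakly connected component that contains
  # active nodes: the user-specified reference where applicable, else the
  # lowest-id active node.
  pinned <- integer(0)
  pinned_value <- numeric(0)
  for (cc in sort(unique(comp[active_i]))) {
    members <- active_i[comp[active_i] == cc]
    choice <- members[order(m$nodes[members])][1L]
    value <- 1
    if (!is.null(pin) && any(m$nodes[members] == pin)) {
      choice <- members[m$nodes[members] == pin]
      value <- pin_value
    }
    pinned <- c(pinned, choice)
    pinned_value <- c(pinned_value, value)
  }
  if (!is.null(pin) && !any(m$nodes[pinned] == pin)) {
    abort("`pin` must name a node with positive outgoing rate.")
  }

  free_i <- setdiff(active_i, pinned)
  n_free <- length(free_i) + length(active_s)

  assemble <- function(par) {
    I <- numeric(m$n)
    S <- numeric(m$n)
    I[pinned] <- pinned_value
    if (length(free_i) > 0) I[free_i] <- exp(par[seq_along(free_i)])
    S[active_s] <- exp(par[length(free_i) + seq_along(active_s)])
    list(I = I, S = S)
  }
  resid_fn <- function(par) {
    v <- assemble(par)
    denom_i <- as.numeric(m$A %*% v$S)
    denom_s <- as.numeric(Matrix::t(m$A) %*% v$I)
    c((v$I[active_i] * denom_i[active_i] - m$f[active_i]) / m$f[active_i],
      (v$S[active_s] * denom_s[active_s] - m$g[active_s]) / m$g[active_s])
  }
  score_of <- function(par) {
    v <- assemble(par)
    sc <- tibble::tibble(user_id = m$nodes, influence = v$I,
                         susceptibility = v$S)
    res <- fixed_point_residual(rates, sc)
    list(scores = sc, residual = res)
  }

  best <- NULL
  with_seed_if(seed, {
    for (r in seq_len(n_restarts)) {
      start <- if (r == 1L) rep(0, n_free) else runif(n_free, -2, 2)
      fit <- try(minpack.lm::nls.lm(
        par = start, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)
      ), silent = TRUE)
      if (inherits(fit, "try-error")) next
      cand <- score_of(fit$par)
      if (is.null(best) || cand$residual < best$residual) {
        best <- cand
      }
      if (best$residual < tol) break
    }
  })
  if (is.null(best) || best$residual >= tol) {
    abort(sprintf(
      "Oracle failure: no fixed point with residual < %.1e found (best %.3g).",
      tol, if (is.null(best)) Inf else best$residual))
  }
  new_is_scores(best$scores,
                meta = list(scheme = "brute_force", iterations = NA_integer_,
                            converged = TRUE, residual = best$residual,
                            tol = tol, damping = NA_real_))
}
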