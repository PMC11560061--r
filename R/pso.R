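#' Particle swarm configuration
#'
#' Hyperparameters of the swarm minimizer.  Defaults follow the standard
#' PSO-2007 family: inertia `1/(2 ln 2)`, cognitive and social coefficients
#' `0.5 + ln 2`, and a random informer topology in which each particle informs
#' any other with probability `proportion_informed`, rebuilt after any
#' iteration without global improvement.  The study settings are swarm size
#' 200, proportion informed 0.2, convergence tolerance 1e-10 and box bounds
#' -6, 6 on the difficulty scale.
#'
#' @param swarm_size number of particles, >= 2.
#' @param proportion_informed probability in (0, 1] that one particle informs
#'   another.
#' @param convergence_tol stop when the global best has improved by less than
#'   this over the last `patience` iterations.
#' @param max_iterations iteration cap.
#' @param lower_bound,upper_bound box bounds applied to every coordinate.
#' @param inertia,cognitive_coef,social_coef velocity-update coefficients.
#' @param patience window length (iterations) for the convergence check.
#' @param seed integer seed; the run is fully reproducible given the seed.
#' @return An object of class `pso_config`.
#' @export
pso_config <- function(swarm_size = 200, proportion_informed = 0.2,
                       convergence_tol = 1e-10, max_iterations = 5000,
                       lower_bound = -6, upper_bound = 6,
                       inertia = 1 / (2 * log(2)),
                       cognitive_coef = 0.5 + log(2),
                       social_coef = 0.5 + log(2),
                       patience = 50, seed = 1L) {
  if (swarm_size < 2) stop("'swarm_size' must be >= 2", call. = FALSE)
  if (proportion_informed <= 0 || proportion_informed > 1)
    stop("'proportion_informed' must be in (0, 1]", call. = FALSE)
  if (convergence_tol <= 0) stop("'convergence_tol' must be > 0", call. = FALSE)
  if (!is.finite(lower_bound) || !is.finite(upper_bound) ||
      lower_bound >= upper_bound)
    stop("'lower_bound' must be < 'upper_bound'", call. = FALSE)
  if (max_iterations < 1 || patience < 1)
    stop("'max_iterations' and 'patience' must be >= 1", call. = FALSE)
  structure(list(swarm_size = as.integer(swarm_size),
                 proportion_informed = proportion_informed,
                 convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations),
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 inertia = inertia, cognitive_coef = cognitive_coef,
                 social_coef = social_coef, patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "pso_config")
}

# informer links: L[i, j] says particle i informs particle j; every particle
# informs itself
new_links <- function(s, p_informed) {
  L <- matrix(runif(s * s) < p_informed, s, s)
  diag(L) <- TRUE
  L
}

batch_evaluator <- function(objective) {
  if (inherits(objective, "case_objective")) {
    comps <- attr(objective, "comps")
    a <- attr(objective, "a")
    n1 <- attr(objective, "n1"); nc <- attr(objective, "nc")
    n2 <- attr(objective, "n2")
    function(X) crit_eval_swarm_cpp(X, a, comps$theta, comps$w, comps$form,
                                    n1, nc, n2)
  } else {
    function(X) apply(X, 1L, objective)
  }
}

check_finite_values <- function(fvals, X) {
  bad <- which(!is.finite(fvals))
  if (length(bad)) {
    stop("objective returned a non-finite value at x = (",
         paste(signif(X[bad[1L], ], 6), collapse = ", "), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Particle swarm minimization over a box
#'
#' Gradient-free minimizer: particles move under inertia plus random
#' attraction toward their own best position and the best position among their
#' informers.  Positions leaving the box are clamped to the bound with the
#' corresponding velocity component zeroed.  The informer topology is
#' regenerated after any iteration in which the global best did not improve.
#' Terminates when the global best improves by less than `convergence_tol`
#' over a `patience`-iteration window, or at `max_iterations`.
#'
#' @param objective function of a numeric vector of length `dim` returning a
#'   finite scalar; objectives built by [build_case_objective()] are evaluated
#'   through a fast batch path.
#' @param dim dimension of the search space, >= 1.
#' @param config a [pso_config()].
#' @return An object of class `optim_result`: `best_vector`, `best_value`,
#'   `iterations_used`, `converged`, `seed`, and the per-iteration `trace` of
#'   the global best (non-increasing).
#' @examples
#' res <- pso_minimize(function(x) sum((x - 1)^2), dim = 2,
#'                     pso_config(swarm_size = 40, max_iterations = 300,
#'                                lower_bound = -5, upper_bound = 5, seed = 7))
#' res$best_value
#' @export
pso_minimize <- function(objective, dim, config = pso_config()) {
  stopifnot(inherits(config, "pso_config"), dim >= 1)
  set.seed(config$seed)
  s <- config$swarm_size
  lb <- config$lower_bound; ub <- config$upper_bound
  rng <- ub - lb
  evalf <- batch_evaluator(objective)

  X <- matrix(runif(s * dim, lb, ub), s, dim)
  V <- matrix(runif(s * dim, -rng / 2, rng / 2), s, dim)
  fvals <- evalf(X)
  check_finite_values(fvals, X)
  P <- X
  pval <- fvals
  gidx <- which.min(pval)
  gbest <- P[gidx, ]
  gval <- pval[gidx]
  links <- new_links(s, config$proportion_informed)

  trace <- numeric(config$max_iterations)
  converged <- FALSE
  it <- 0L
  while (it < config$max_iterations) {
    it <- it + 1L
    # best informer of each particle (column j: rows i with L[i, j] inform j)
    PM <- matrix(pval, nrow = s, ncol = s)
    PM[!links] <- Inf
    best <- apply(PM, 2L, which.min)
    r1 <- matrix(runif(s * dim, 0, config$cognitive_coef), s, dim)
    r2 <- matrix(runif(s * dim, 0, config$social_coef), s, dim)
    V <- config$inertia * V + r1 * (P - X) + r2 * (P[best, , drop = FALSE] - X)
    X <- X + V
    out_lo <- X < lb
    out_hi <- X > ub
    V[out_lo | out_hi] <- 0
    X[out_lo] <- lb
    X[out_hi] <- ub

    fvals <- evalf(X)
    check_finite_values(fvals, X)
    imp <- fvals < pval
    if (any(imp)) {
      P[imp, ] <- X[imp, , drop = FALSE]
      pval[imp] <- fvals[imp]
    }
    gidx <- which.min(pval)
    if (pval[gidx] < gval) {
      gval <- pval[gidx]
      gbest <- P[gidx, ]
    } else {
      links <- new_links(s, config$proportion_informed)
    }
    trace[it] <- gval
    if (it > config$patience &&
        trace[it - config$patience] - gval < config$convergence_tol) {
      converged <- TRUE
      break
    }
  }

  structure(list(best_vector = gbest, best_value = gval,
                 iterations_used = it, converged = converged,
                 seed = config$seed, trace = trace[seq_len(it)]),
            class = "optim_result")
}

#' @export
print.optim_result <- function(x, ...) {
  cat("<optim_result> best value ", format(x$best_value), " after ",
      x$iterations_used, " iteration(s)",
      if (x$converged) " (converged)" else " (iteration cap)", "\n", sep = "")
  invisible(x)
}

#' Optimize a continuous difficulty configuration for one study case
#'
#' Runs the particle swarm on the case objective over the packed difficulty
#' vector (dimension `n1 + nc + n2`), then unpacks the solution into a
#' [growth_design()] and reports the per-role difficulties sorted ascending,
#' matching the way optimized designs are displayed.
#'
#' @inheritParams build_case_objective
#' @param config a [pso_config()].
#' @return A `solution_record`: case/scenario metadata, the criterion value,
#'   the sorted per-role difficulties, the unpacked design, and the underlying
#'   [pso_minimize()] result.
#' @export
optimize_continuous_design <- function(case_id, spec, config = pso_config()) {
  stopifnot(inherits(spec, "criterion_spec"))
  objective <- build_case_objective(case_id, spec)
  n <- spec$n1 + spec$nc + spec$n2
  res <- pso_minimize(objective, dim = n, config = config)
  design <- unpack_design(res$best_vector, spec$a_level,
                          spec$n1, spec$nc, spec$n2)
  solution_record(case_id = case_id, a_level = spec$a_level, d = spec$d,
                  method = "continuous", seed = config$seed,
                  criterion_value = res$best_value,
                  difficulties = list(unique1 = sort(design$unique1$b),
                                      common = sort(design$common$b),
                                      unique2 = sort(design$unique2$b)),
                  design = design, spec = spec, optim = res)
}

solution_record <- function(...) {
  structure(list(...), class = "solution_record")
}

#' @export
print.solution_record <- function(x, ...) {
  cat("<solution_record> case ", x$case_id, ", a = ",
      paste(format(unique(x$a_level)), collapse = "/"),
      ", d = ", x$d, ", method = ", x$method, "\n",
      "  criterion value: ", format(x$criterion_value), "\n", sep = "")
  for (role in names(x$difficulties)) {
    bs <- x$difficulties[[role]]
    if (length(bs))
      cat("  ", role, ": ", length(bs), " item(s), b in [",
          format(min(bs), digits = 4), ", ", format(max(bs), digits = 4),
          "]\n", sep = "")
  }
  invisible(x)
}
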