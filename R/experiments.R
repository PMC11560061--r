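# Deterministic seed derivation: mixes integer keys into a base seed with a
# Lehmer-style recurrence mod the Mersenne prime 2^31 - 1, so every (scenario,
# replicate) pair gets its own reproducible stream independent of run order.
derive_seed <- function(base, ...) {
  m <- 2147483647
  h <- as.numeric(base) %% m
  for (k in c(...)) {
    h <- (h * 48271 + (round(as.numeric(k)) %% m)) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

#' Sweep the four study cases over discrimination and growth-distance levels
#'
#' Runs [optimize_continuous_design()] for one case at every combination of
#' discrimination level and growth distance (the study grid is
#' `a = 0.5, 1, 1.5, 2` by `d = 0.5, 1, 1.5, 2, 2.5`, i.e. 20 runs per case).
#' Each run's seed is derived from `(seed, case, a, d)` only, so records do not
#' depend on execution order.
#'
#' @param case_id integer 1-4.
#' @param a_levels,d_values numeric vectors defining the sweep grid.
#' @param spec a [criterion_spec()] template; its `a_level` and `d` are
#'   replaced at every grid point.
#' @param pso_config a [pso_config()] template; its seed is replaced per run.
#' @param seed base seed for the sweep.
#' @return A list of `solution_record`s of class `case_sweep`.
#' @export
run_case_sweep <- function(case_id,
                           a_levels = c(0.5, 1, 1.5, 2),
                           d_values = c(0.5, 1, 1.5, 2, 2.5),
                           spec = criterion_spec(d = 1, a_level = 1),
                           pso_config = growthdesign::pso_config(),
                           seed = 1L) {
  records <- list()
  for (a in a_levels) {
    for (d in d_values) {
      sp <- spec
      sp$a_level <- rep_len(a, length(sp$a_level))
      sp$d <- d
      cfg <- pso_config
      cfg$seed <- derive_seed(seed, case_id, a * 1000, d * 1000)
      records[[length(records) + 1L]] <-
        optimize_continuous_design(case_id, sp, cfg)
    }
  }
  structure(records, class = "case_sweep")
}

#' Stability of the swarm solution under repetition
#'
#' Repeats one case optimization `reps` times from different random starts,
#' sorts each solution ascending within each role, and reports the
#' per-component mean and standard deviation of the sorted difficulty vectors.
#' Low standard deviations everywhere except near cluster edges indicate a
#' stable optimum.
#'
#' @inheritParams run_case_sweep
#' @param a_level,d scenario values substituted into `spec`.
#' @param reps number of repetitions, >= 2.
#' @param seeds optional integer vector of length `reps`; defaults to seeds
#'   derived from `seed` (identical seeds give identical runs, hence zero SDs).
#' @return A list of class `stability_result`: `mean` and `sd` (each of length
#'   `n1 + nc + n2`, in role packing order), the `solutions` matrix
#'   (`reps` rows), and the role of each component.
#' @export
stability_analysis <- function(case_id, a_level, d, reps,
                               spec = criterion_spec(d = d, a_level = a_level),
                               pso_config = growthdesign::pso_config(),
                               seed = 1L, seeds = NULL) {
  if (reps < 2) stop("'reps' must be >= 2", call. = FALSE)
  if (is.null(seeds)) seeds <- vapply(seq_len(reps), function(i)
    derive_seed(seed, case_id, a_level * 1000, d * 1000, i), integer(1))
  if (length(seeds) != reps) stop("'seeds' must have length 'reps'", call. = FALSE)
  sp <- spec
  sp$a_level <- rep_len(a_level, length(sp$a_level))
  sp$d <- d
  n <- sp$n1 + sp$nc + sp$n2
  sols <- matrix(NA_real_, nrow = reps, ncol = n)
  for (i in seq_len(reps)) {
    cfg <- pso_config
    cfg$seed <- seeds[i]
    rec <- optimize_continuous_design(case_id, sp, cfg)
    sols[i, ] <- c(rec$difficulties$unique1, rec$difficulties$common,
                   rec$difficulties$unique2)
  }
  structure(list(mean = colMeans(sols),
                 sd = apply(sols, 2L, sd),
                 solutions = sols,
                 role = rep.int(c("unique1", "common", "unique2"),
                                c(sp$n1, sp$nc, sp$n2)),
                 seeds = seeds),
            class = "stability_result")
}

# Growth objective over two explicit grids with per-item discriminations, on
# the fast batch-evaluation path.
make_growth_objective <- function(a, n1, nc, n2, grid1, grid2,
                                  standardize = FALSE) {
  comps <- growth_components(grid1, grid2)
  if (standardize) comps <- renorm(comps)
  make_criterion_objective(comps, a, n1, nc, n2)
}

#' Robustness of the optimum-in-average design to growth misspecification
#'
#' Per replicate: draw the item discriminations `a_i ~ lognormal(0, a_sdlog)`,
#' optimize the growth criterion once with ordinary `N(+/- d_design/2, 1)`
#' weights (design O) and once with optimum-in-average weights integrating a
#' `N(+/- d_design/2, prior_sd^2)` prior on the two means (design A).  Then,
#' for every candidate true distance, evaluate each design's asymptotic
#' standard deviation of the estimated growth on grids centered at the true
#' distance, and record the ratio `sigma_O / sigma_A`.  Ratios above one favor
#' the in-average design; sample sizes cancel in the ratio.
#'
#' @param d_design growth distance assumed when optimizing (study value 1).
#' @param true_d candidate true distances at which the designs are compared.
#' @param reps number of replicates (each with fresh discriminations).
#' @param prior_sd prior standard deviation of each population mean.
#' @param sizes integer `(n1, nc, n2)` role sizes.
#' @param l,half_width ability-grid resolution and span.
#' @param a_sdlog lognormal sdlog of the sampled discriminations.
#' @param pso_config a [pso_config()] template (seed replaced per fit).
#' @param seed base seed.
#' @return A list of class `ratio_table`: `ratios` (`reps` by
#'   `length(true_d)`), `true_d`, and the per-replicate seeds.
#' @export
uncertainty_ratio_experiment <- function(d_design = 1,
                                         true_d = seq(0.4, 1.6, by = 0.2),
                                         reps = 50, prior_sd = 0.2,
                                         sizes = c(30, 15, 30),
                                         l = 100, half_width = 4,
                                         a_sdlog = 0.25,
                                         pso_config = growthdesign::pso_config(),
                                         seed = 1L) {
  if (reps < 1) stop("'reps' must be >= 1", call. = FALSE)
  n1 <- sizes[1]; nc <- sizes[2]; n2 <- sizes[3]
  n <- n1 + nc + n2
  ratios <- matrix(NA_real_, nrow = reps, ncol = length(true_d))
  rep_seeds <- vapply(seq_len(reps), function(i) derive_seed(seed, 90001, i),
                      integer(1))
  for (i in seq_len(reps)) {
    set.seed(rep_seeds[i])
    a <- rlnorm(n, meanlog = 0, sdlog = a_sdlog)
    gO1 <- make_normal_grid(-d_design / 2, 1, l, half_width)
    gO2 <- make_normal_grid(+d_design / 2, 1, l, half_width)
    gA1 <- make_in_average_grid(-d_design / 2, prior_sd, l, half_width)
    gA2 <- make_in_average_grid(+d_design / 2, prior_sd, l, half_width)
    objO <- make_growth_objective(a, n1, nc, n2, gO1, gO2)
    objA <- make_growth_objective(a, n1, nc, n2, gA1, gA2)
    cfgO <- pso_config; cfgO$seed <- derive_seed(rep_seeds[i], 1)
    cfgA <- pso_config; cfgA$seed <- derive_seed(rep_seeds[i], 2)
    bO <- pso_minimize(objO, n, cfgO)$best_vector
    bA <- pso_minimize(objA, n, cfgA)$best_vector
    for (j in seq_along(true_d)) {
      gT1 <- make_normal_grid(-true_d[j] / 2, 1, l, half_width)
      gT2 <- make_normal_grid(+true_d[j] / 2, 1, l, half_width)
      objT <- make_growth_objective(a, n1, nc, n2, gT1, gT2)
      ratios[i, j] <- sqrt(objT(bO) / objT(bA))
    }
  }
  structure(list(ratios = ratios, true_d = true_d, seeds = rep_seeds,
                 d_design = d_design, prior_sd = prior_sd),
            class = "ratio_table")
}

#' @export
print.ratio_table <- function(x, ...) {
  cat("<ratio_table> ", nrow(x$ratios), " replicate(s), true d in [",
      min(x$true_d), ", ", max(x$true_d), "]\n", sep = "")
  med <- apply(x$ratios, 2L, median)
  print(data.frame(true_d = x$true_d, median_ratio = med), row.names = FALSE)
  invisible(x)
}

#' Maximum-likelihood ability estimation for dichotomous responses
#'
#' Estimates each examinee's ability from a 0/1 response matrix under the 2PL
#' model by Newton's method on the log-likelihood (strictly concave in theta),
#' with estimates clamped to `bounds`.  All-correct and all-incorrect response
#' patterns have no finite maximizer and end up at the bounds, flagged via the
#' `clamped` attribute.
#'
#' @param responses integer/logical matrix, examinees in rows, one column per
#'   item of `its`.
#' @param its the form's [items()].
#' @param bounds length-2 numeric search interval for the estimates.
#' @return Numeric vector of ability estimates with attribute `clamped`
#'   (logical vector).
#' @export
estimate_abilities <- function(responses, its, bounds = c(-6, 6)) {
  its <- as_items(its)
  responses <- as.matrix(responses)
  if (ncol(responses) != nrow(its))
    stop("'responses' must have one column per item", call. = FALSE)
  theta <- numeric(nrow(responses))
  for (iter in seq_len(100)) {
    x <- sweep(outer(theta, its$b, "-"), 2L, its$a, "*")
    p <- plogis(x)
    score <- rowSums(sweep(responses - p, 2L, its$a, "*"))
    info <- rowSums(sweep(p * (1 - p), 2L, its$a^2, "*"))
    step <- score / pmax(info, 1e-10)
    step <- pmin(pmax(step, -2), 2)   # damp early oversized steps
    theta <- pmin(pmax(theta + step, bounds[1]), bounds[2])
    if (max(abs(step)) < 1e-9) break
  }
  clamped <- theta <= bounds[1] | theta >= bounds[2]
  attr(theta, "clamped") <- clamped
  theta
}

#' Monte-Carlo validation of the asymptotic growth variance
#'
#' Draws `N` abilities per population from `N(-d/2, 1)` and `N(+d/2, 1)` (once,
#' so the variance is conditional on the abilities, matching the asymptotic
#' expression), then repeatedly simulates dichotomous 2PL responses, estimates
#' every ability by maximum likelihood, and forms the growth estimate
#' `mean(theta2) - mean(theta1)`.  The empirical variance of the estimate
#' across replicates is compared with the asymptotic prediction
#' [asymptotic_var_growth()] at the drawn abilities.
#'
#' @param design a [growth_design()].
#' @param d true growth distance.
#' @param N examinees per population, >= 100.
#' @param reps number of response replications, >= 100.
#' @param seed integer seed.
#' @return A list of class `mc_validation`: `empirical_var`, `predicted_var`,
#'   their `ratio`, the growth estimates `d_hat`, and the count of clamped
#'   ability estimates.
#' @export
mc_validate_variance <- function(design, d, N, reps, seed = 1L) {
  stopifnot(inherits(design, "growth_design"))
  if (N < 100 || reps < 100) stop("'N' and 'reps' must be >= 100", call. = FALSE)
  set.seed(seed)
  th1 <- rnorm(N, -d / 2, 1)
  th2 <- rnorm(N, +d / 2, 1)
  f1 <- form1_items(design)
  f2 <- form2_items(design)
  p1 <- plogis(sweep(outer(th1, f1$b, "-"), 2L, f1$a, "*"))
  p2 <- plogis(sweep(outer(th2, f2$b, "-"), 2L, f2$a, "*"))
  d_hat <- numeric(reps)
  n_clamped <- 0L
  for (r in seq_len(reps)) {
    x1 <- matrix(rbinom(length(p1), 1L, p1), nrow = N)
    x2 <- matrix(rbinom(length(p2), 1L, p2), nrow = N)
    e1 <- estimate_abilities(x1, f1)
    e2 <- estimate_abilities(x2, f2)
    n_clamped <- n_clamped + sum(attr(e1, "clamped")) + sum(attr(e2, "clamped"))
    d_hat[r] <- mean(e2) - mean(e1)
  }
  predicted <- asymptotic_var_growth(design, th1, th2)
  structure(list(empirical_var = var(d_hat), predicted_var = predicted,
                 ratio = var(d_hat) / predicted, d_hat = d_hat,
                 n_clamped = n_clamped, N = N, reps = reps, seed = seed),
            class = "mc_validation")
}

#' @export
print.mc_validation <- function(x, ...) {
  cat("<mc_validation> empirical Var(d_hat) = ", format(x$empirical_var),
      " | asymptotic = ", format(x$predicted_var),
      " | ratio = ", format(round(x$ratio, 3)), "\n", sep = "")
  invisible(x)
}
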