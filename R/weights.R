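#' Discrete ability grid
#'
#' A continuous ability distribution is replaced by target ability points with
#' normalized weights, turning a design criterion into a finite weighted sum.
#' Constructors such as [make_normal_grid()] are the usual entry points.
#'
#' @param points strictly increasing numeric vector of abilities.
#' @param weights non-negative numeric vector, same length as `points`;
#'   normalized internally to sum to one.
#' @return An object of class `ability_grid` with elements `points`, `weights`
#'   and `l` (the number of points).
#' @export
ability_grid <- function(points, weights) {
  points <- as.numeric(points)
  weights <- as.numeric(weights)
  if (length(points) < 1L || length(points) != length(weights))
    stop("'points' and 'weights' must be non-empty and of equal length",
         call. = FALSE)
  if (anyNA(points) || any(!is.finite(points)))
    stop("'points' must be finite", call. = FALSE)
  if (length(points) > 1L && any(diff(points) <= 0))
    stop("'points' must be strictly increasing", call. = FALSE)
  if (anyNA(weights) || any(weights < 0) || sum(weights) <= 0)
    stop("'weights' must be non-negative with positive sum", call. = FALSE)
  structure(list(points = points, weights = weights / sum(weights),
                 l = length(points)),
            class = "ability_grid")
}

#' @export
print.ability_grid <- function(x, ...) {
  cat("<ability_grid> ", x$l, " point(s) on [",
      format(min(x$points)), ", ", format(max(x$points)), "]\n", sep = "")
  invisible(x)
}

as_grid <- function(x) {
  if (inherits(x, c("ability_grid", "ability_weighting"))) return(x)
  stop("expected an ability grid", call. = FALSE)
}

#' Equidistant normal ability grid
#'
#' Builds `l` equidistant ability points spanning
#' `[mu - half_width, mu + half_width]` with weights proportional to the
#' `N(mu, sigma^2)` density at each point, normalized to sum to one.  With the
#' default half-width of 4 ability units the truncated mass of a unit-variance
#' normal is negligible (< 1e-4).
#'
#' @param mu mean of the ability distribution.
#' @param sigma standard deviation, > 0.
#' @param l number of grid points, >= 1 (a single point sits at `mu`).
#' @param half_width half the span of the grid, > 0.
#' @return An [ability_grid()].
#' @examples
#' make_normal_grid(0, 1, l = 5, half_width = 4)
#' @export
make_normal_grid <- function(mu, sigma, l, half_width = 4) {
  check_grid_args(mu, sigma, l, half_width, positive_sigma = TRUE)
  pts <- grid_points(mu, l, half_width)
  ability_grid(pts, dnorm(pts, mean = mu, sd = sigma))
}

grid_points <- function(mu, l, half_width) {
  if (l == 1L) mu else seq(mu - half_width, mu + half_width, length.out = l)
}

check_grid_args <- function(mu, sigma, l, half_width, positive_sigma) {
  if (!is.finite(mu)) stop("'mu' must be finite", call. = FALSE)
  if (!is.finite(sigma) || (if (positive_sigma) sigma <= 0 else sigma < 0))
    stop(if (positive_sigma) "'sigma' must be > 0" else "'sigma' must be >= 0",
         call. = FALSE)
  if (length(l) != 1L || is.na(l) || l < 1 || l != round(l))
    stop("'l' must be a positive integer", call. = FALSE)
  if (!is.finite(half_width) || half_width <= 0)
    stop("'half_width' must be > 0", call. = FALSE)
  invisible(TRUE)
}

#' Prior-integrated (optimum-in-average) weight density
#'
#' The optimum-in-average design places weight
#' \deqn{w_j = \int f(\theta_j \mid x, 1)\, f(x \mid \mu, \sigma^2)\, dx}
#' at each target ability, averaging the unit-variance ability density over a
#' normal prior on the unknown population mean.  The integral has the closed
#' form of the `N(mu, 1 + sigma^2)` density, which this function returns
#' (unnormalized).
#'
#' @param theta numeric vector of abilities.
#' @param mu_prior prior mean of the population mean ability.
#' @param sigma_prior prior standard deviation, >= 0 (0 recovers the ordinary
#'   unit-variance density).
#' @return Numeric vector of density values.
#' @export
in_average_density <- function(theta, mu_prior, sigma_prior) {
  if (!is.finite(mu_prior) || !is.finite(sigma_prior) || sigma_prior < 0)
    stop("'mu_prior' must be finite and 'sigma_prior' >= 0", call. = FALSE)
  dnorm(theta, mean = mu_prior, sd = sqrt(1 + sigma_prior^2))
}

#' Optimum-in-average ability grid
#'
#' Like [make_normal_grid()] but with prior-integrated weights: the weight at
#' each point is the marginal density of ability when the population mean has a
#' `N(mu_prior, sigma_prior^2)` prior and abilities have unit variance around
#' it.  The marginal is `N(mu_prior, 1 + sigma_prior^2)`, a heavier-tailed
#' reweighting of the ordinary grid; `sigma_prior = 0` reduces exactly to
#' `make_normal_grid(mu_prior, 1, l, half_width)`.
#'
#' @inheritParams in_average_density
#' @inheritParams make_normal_grid
#' @return An [ability_grid()].
#' @export
make_in_average_grid <- function(mu_prior, sigma_prior, l, half_width = 4) {
  check_grid_args(mu_prior, sigma_prior, l, half_width, positive_sigma = FALSE)
  pts <- grid_points(mu_prior, l, half_width)
  ability_grid(pts, in_average_density(pts, mu_prior, sigma_prior))
}

#' Percentile ability grid
#'
#' Target points are the `N(mu, sigma^2)` quantiles at the requested
#' percentiles; weights are proportional to the same density evaluated at those
#' quantiles (so for a location-shifted pair of equal-variance populations the
#' two members of a percentile pair carry equal weight after standardization).
#'
#' @param percentiles strictly increasing numeric vector, each in (0, 100).
#' @inheritParams make_normal_grid
#' @return An [ability_grid()].
#' @examples
#' make_percentile_grid(c(25, 50, 75), mu = 0, sigma = 1)
#' @export
make_percentile_grid <- function(percentiles, mu, sigma = 1) {
  if (length(percentiles) < 1L || anyNA(percentiles) ||
      any(percentiles <= 0) || any(percentiles >= 100))
    stop("'percentiles' must lie strictly between 0 and 100", call. = FALSE)
  if (length(percentiles) > 1L && any(diff(percentiles) <= 0))
    stop("'percentiles' must be strictly increasing", call. = FALSE)
  if (!is.finite(mu) || !is.finite(sigma) || sigma <= 0)
    stop("'mu' must be finite and 'sigma' > 0", call. = FALSE)
  pts <- qnorm(percentiles / 100, mean = mu, sd = sigma)
  ability_grid(pts, dnorm(pts, mean = mu, sd = sigma))
}

#' Combine weighting schemes into one standardized weighting
#'
#' Concatenates several grids, scaling each grid's (already normalized) weights
#' by its mass, and renormalizes so the total weight is one.  This is how
#' component criteria are standardized when combined into a single objective.
#' Duplicate points are allowed in the result, which is therefore returned as
#' an `ability_weighting` (points need not be strictly increasing).
#'
#' @param schemes a list; each element is a list with elements `grid` (an
#'   [ability_grid()] or `ability_weighting`) and `mass` (positive scalar).
#' @return An object of class `ability_weighting` with elements `points` and
#'   `weights` (summing to one).
#' @export
combine_schemes <- function(schemes) {
  if (!is.list(schemes) || length(schemes) == 0L)
    stop("'schemes' must be a non-empty list", call. = FALSE)
  pts <- numeric(0)
  wts <- numeric(0)
  for (s in schemes) {
    if (is.null(s$grid) || is.null(s$mass) || !is.finite(s$mass) || s$mass <= 0)
      stop("each scheme needs a 'grid' and a positive 'mass'", call. = FALSE)
    g <- as_grid(s$grid)
    pts <- c(pts, g$points)
    wts <- c(wts, s$mass * g$weights)
  }
  structure(list(points = pts, weights = wts / sum(wts), l = length(pts)),
            class = "ability_weighting")
}

#' @export
print.ability_weighting <- function(x, ...) {
  cat("<ability_weighting> ", x$l, " point(s), total mass 1\n", sep = "")
  invisible(x)
}
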