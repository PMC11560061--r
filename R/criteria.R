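#' Two-form growth design with anchor items
#'
#' The non-equivalent-groups anchor-test (NEAT) layout: Test form 1 consists of
#' its unique items plus the common (anchor) items, form 2 of the common items
#' plus its own unique items.  The anchors place both forms on one scale, so
#' growth between the two administrations is directly estimable.
#'
#' @param unique1 items unique to form 1 ([items()] or `NULL`).
#' @param common anchor items shared by both forms ([items()] or `NULL`).
#' @param unique2 items unique to form 2 ([items()] or `NULL`).
#' @return An object of class `growth_design` with elements `unique1`,
#'   `common`, `unique2` and counts `n1`, `nc`, `n2`.
#' @examples
#' growth_design(items(1, -0.5), items(1, 0), items(1, 0.5))
#' @export
growth_design <- function(unique1 = NULL, common = NULL, unique2 = NULL) {
  norm_role <- function(x) if (is.null(x)) items(1, 0)[0, , drop = FALSE] else as_items(x)
  u1 <- norm_role(unique1); cm <- norm_role(common); u2 <- norm_role(unique2)
  n1 <- nrow(u1); nc <- nrow(cm); n2 <- nrow(u2)
  if (n1 + nc < 1L || n2 + nc < 1L)
    stop("both forms must contain at least one item", call. = FALSE)
  structure(list(unique1 = u1, common = cm, unique2 = u2,
                 n1 = n1, nc = nc, n2 = n2),
            class = "growth_design")
}

#' @export
print.growth_design <- function(x, ...) {
  cat("<growth_design> n1 =", x$n1, "| nc =", x$nc, "| n2 =", x$n2, "\n")
  invisible(x)
}

#' Items of each test form
#'
#' @param design a [growth_design()].
#' @return An [items()] object: form 1 is `unique1` + `common`, form 2 is
#'   `common` + `unique2` (matching the packing order of difficulty vectors).
#' @export
form1_items <- function(design) {
  stopifnot(inherits(design, "growth_design"))
  items(c(design$unique1$a, design$common$a), c(design$unique1$b, design$common$b))
}

#' @rdname form1_items
#' @export
form2_items <- function(design) {
  stopifnot(inherits(design, "growth_design"))
  items(c(design$common$a, design$unique2$a), c(design$common$b, design$unique2$b))
}

#' Unpack a packed difficulty vector into a growth design
#'
#' Difficulty vectors are packed as (unique-1, common, unique-2), with the
#' anchor block in the middle.
#'
#' @param b numeric vector of length `n1 + nc + n2`.
#' @param a discriminations: a scalar (recycled) or a vector of the same
#'   packing and length as `b`.
#' @param n1,nc,n2 role sizes.
#' @return A [growth_design()].
#' @export
unpack_design <- function(b, a, n1, nc, n2) {
  n <- n1 + nc + n2
  if (length(b) != n)
    stop("difficulty vector has length ", length(b), ", expected ", n, call. = FALSE)
  a <- rep_len(as.numeric(a), n)
  idx1 <- seq_len(n1)
  idxc <- seq_len(nc) + n1
  idx2 <- seq_len(n2) + n1 + nc
  growth_design(
    unique1 = if (n1) items(a[idx1], b[idx1]),
    common  = if (nc) items(a[idxc], b[idxc]),
    unique2 = if (n2) items(a[idx2], b[idx2]))
}

#' Scenario parameters for a design criterion
#'
#' Collects the quantities that define an optimization scenario: the growth
#' distance `d` between the two administrations (population abilities are taken
#' as `N(-d/2, 1)` and `N(+d/2, 1)`), the constant discrimination level(s), the
#' role sizes, the ability-grid resolution, and the optional percentile set and
#' second-group shift used by the combined criteria.
#'
#' @param d mean ability growth, >= 0.
#' @param a_level item discrimination(s): scalar, or vector of length
#'   `n1 + nc + n2` in packing order.
#' @param n1,nc,n2 numbers of form-1 unique, common, and form-2 unique items.
#' @param l number of equidistant grid points per population.
#' @param half_width half-span of each population's grid, in ability units.
#' @param percentiles percentile set for the percentile criteria (cases 2, 3).
#' @param group_shift ability offset of the second group (case 4).
#' @param N1,N2 sample sizes, used by the variance expressions only (the
#'   criteria omit the constant `1/N^2` factors, which never move the argmin).
#' @return An object of class `criterion_spec`.
#' @export
criterion_spec <- function(d, a_level, n1 = 30, nc = 15, n2 = 30,
                           l = 100, half_width = 4,
                           percentiles = NULL, group_shift = NULL,
                           N1 = NULL, N2 = NULL) {
  if (!is.finite(d) || d < 0) stop("'d' must be >= 0", call. = FALSE)
  n <- n1 + nc + n2
  if (n1 < 0 || nc < 0 || n2 < 0 || n1 + nc < 1 || n2 + nc < 1)
    stop("both forms must be non-empty", call. = FALSE)
  if (!length(a_level) %in% c(1L, n))
    stop("'a_level' must be scalar or of length n1 + nc + n2", call. = FALSE)
  if (any(!is.finite(a_level)) || any(a_level <= 0))
    stop("'a_level' must be finite and > 0", call. = FALSE)
  if (!is.null(percentiles) &&
      (any(percentiles <= 0) || any(percentiles >= 100)))
    stop("'percentiles' must lie in (0, 100)", call. = FALSE)
  for (Nk in list(N1, N2))
    if (!is.null(Nk) && (!is.finite(Nk) || Nk < 1))
      stop("sample sizes must be >= 1", call. = FALSE)
  structure(list(d = d, a_level = as.numeric(a_level),
                 n1 = as.integer(n1), nc = as.integer(nc), n2 = as.integer(n2),
                 l = as.integer(l), half_width = half_width,
                 percentiles = percentiles, group_shift = group_shift,
                 N1 = N1, N2 = N2),
            class = "criterion_spec")
}

tif_or_stop <- function(its, theta) {
  tif <- test_information(its, theta)
  if (any(!is.finite(tif)) || any(tif <= 0))
    stop("test information is zero or non-finite at a grid point", call. = FALSE)
  tif
}

#' Weighted variance criterion for an estimated mean
#'
#' The criterion \eqn{\Psi_\mu = \sum_j w_j / \sum_i I_i(\theta_j)}: the
#' weighted sum over the ability grid of the inverse test information,
#' proportional to the asymptotic variance of the estimated mean ability.
#'
#' @param its test items ([items()]).
#' @param grid an [ability_grid()] (or `ability_weighting`) for the population.
#' @return Positive scalar; strictly decreases when any item is added.
#' @export
crit_mean <- function(its, grid) {
  its <- as_items(its)
  if (nrow(its) == 0L) stop("'its' must contain at least one item", call. = FALSE)
  grid <- as_grid(grid)
  val <- sum(grid$weights / tif_or_stop(its, grid$points))
  if (!is.finite(val)) stop("criterion evaluated to a non-finite value", call. = FALSE)
  val
}

#' Weighted variance criterion for mean ability growth
#'
#' The two-form criterion
#' \deqn{\Psi_d = \sum_j \frac{w_{j,1}}{TIF_1(\theta_{j,1})}
#'             + \sum_j \frac{w_{j,2}}{TIF_2(\theta_{j,2})},}
#' where form 1 (unique-1 + common items) is weighted over the first
#' population's grid and form 2 (common + unique-2) over the second's.  Anchor
#' items contribute to both terms.  Each grid's weights sum to one.
#'
#' @param design a [growth_design()].
#' @param grid1,grid2 ability grids for the populations at the two time points
#'   (conventionally centered at `-d/2` and `+d/2`).
#' @return Positive scalar.
#' @export
crit_growth <- function(design, grid1, grid2) {
  stopifnot(inherits(design, "growth_design"))
  grid1 <- as_grid(grid1); grid2 <- as_grid(grid2)
  val <- sum(grid1$weights / tif_or_stop(form1_items(design), grid1$points)) +
         sum(grid2$weights / tif_or_stop(form2_items(design), grid2$points))
  if (!is.finite(val)) stop("criterion evaluated to a non-finite value", call. = FALSE)
  val
}

#' Weighted variance criterion for percentile growth
#'
#' The percentile criterion evaluates each form's inverse information at the
#' population quantiles, with the density-proportional weights standardized
#' jointly across both sums (total mass one).
#'
#' @param design a [growth_design()].
#' @param pct_grid1,pct_grid2 percentile grids from [make_percentile_grid()]
#'   for the two populations.
#' @return Positive scalar.
#' @export
crit_percentile <- function(design, pct_grid1, pct_grid2) {
  stopifnot(inherits(design, "growth_design"))
  g1 <- as_grid(pct_grid1); g2 <- as_grid(pct_grid2)
  w <- c(g1$weights, g2$weights)
  w <- w / sum(w)
  i1 <- seq_along(g1$weights)
  val <- sum(w[i1] / tif_or_stop(form1_items(design), g1$points)) +
         sum(w[-i1] / tif_or_stop(form2_items(design), g2$points))
  if (!is.finite(val)) stop("criterion evaluated to a non-finite value", call. = FALSE)
  val
}

# Component table (theta, w, form) for a growth criterion over two grids.
growth_components <- function(grid1, grid2) {
  grid1 <- as_grid(grid1); grid2 <- as_grid(grid2)
  data.frame(theta = c(grid1$points, grid2$points),
             w = c(grid1$weights, grid2$weights),
             form = rep(c(1L, 2L), c(length(grid1$points), length(grid2$points))))
}

renorm <- function(comps, total = 1) {
  comps$w <- total * comps$w / sum(comps$w)
  comps
}

#' Build the objective function for one of the four study cases
#'
#' Returns a deterministic function mapping a packed difficulty vector (length
#' `n1 + nc + n2`, discriminations fixed at `spec$a_level`) to the case's
#' criterion value:
#' \describe{
#'   \item{Case 1}{mean-growth criterion over `l`-point normal grids at
#'     `N(-d/2, 1)` and `N(+d/2, 1)` (each grid's weights sum to one).}
#'   \item{Case 2}{case 1 combined with the percentile criterion for
#'     `spec$percentiles` (default 25, 75), equal mass per component criterion,
#'     total weight standardized to one.}
#'   \item{Case 3}{percentile criterion alone for `spec$percentiles`
#'     (default 25, 50, 75), jointly standardized.}
#'   \item{Case 4}{two groups sharing the design: group A at means `-d/2`,
#'     `+d/2`, group B with both grids shifted by `spec$group_shift`
#'     (default 0.25), equal mass, total weight standardized to one.}
#' }
#' The constant factors introduced by standardization rescale the objective and
#' never change the argmin.
#'
#' @param case_id integer 1-4.
#' @param spec a [criterion_spec()].
#' @return A function of class `case_objective`; attributes carry the component
#'   table, discriminations and role sizes used by the fast optimizer path.
#' @export
build_case_objective <- function(case_id, spec) {
  stopifnot(inherits(spec, "criterion_spec"))
  if (!case_id %in% 1:4) stop("'case_id' must be 1, 2, 3 or 4", call. = FALSE)
  d <- spec$d; l <- spec$l; hw <- spec$half_width
  g1 <- make_normal_grid(-d / 2, 1, l, hw)
  g2 <- make_normal_grid(+d / 2, 1, l, hw)

  pct_components <- function(p) {
    growth_components(make_percentile_grid(p, -d / 2, 1),
                      make_percentile_grid(p, +d / 2, 1))
  }

  comps <- switch(case_id,
    # case 1: Psi_d as printed, total mass 2 (one per population grid)
    growth_components(g1, g2),
    {
      p <- if (is.null(spec$percentiles)) c(25, 75) else spec$percentiles
      rbind(renorm(growth_components(g1, g2)), renorm(pct_components(p)))
    },
    {
      p <- if (is.null(spec$percentiles)) c(25, 50, 75) else spec$percentiles
      renorm(pct_components(p))
    },
    {
      shift <- if (is.null(spec$group_shift)) 0.25 else spec$group_shift
      gA <- renorm(growth_components(g1, g2))
      gB <- renorm(growth_components(
        make_normal_grid(-d / 2 + shift, 1, l, hw),
        make_normal_grid(+d / 2 + shift, 1, l, hw)))
      rbind(gA, gB)
    })
  if (case_id != 1L) comps <- renorm(comps)

  make_criterion_objective(comps, spec$a_level, spec$n1, spec$nc, spec$n2)
}

# Wrap a component table as a fast-evaluable objective over packed b-vectors.
make_criterion_objective <- function(comps, a_level, n1, nc, n2) {
  n <- n1 + nc + n2
  a <- rep_len(as.numeric(a_level), n)
  force(comps)
  f <- function(b) {
    if (length(b) != n)
      stop("difficulty vector has length ", length(b), ", expected ", n,
           call. = FALSE)
    crit_eval_swarm_cpp(matrix(as.numeric(b), nrow = 1L), a,
                        comps$theta, comps$w, comps$form, n1, nc, n2)[1L]
  }
  structure(f, class = c("case_objective", "function"),
            comps = comps, a = a, n1 = n1, nc = nc, n2 = n2)
}

#' Asymptotic variance of estimated mean ability growth
#'
#' The asymptotic variance of \eqn{\hat d = \hat\mu_2 - \hat\mu_1} at given
#' (fixed) examinee abilities,
#' \deqn{\mathrm{Var}(\hat d) = \frac{1}{N_1^2}\sum_j \frac{1}{TIF_1(\theta_{j,1})}
#'   + \frac{1}{N_2^2}\sum_j \frac{1}{TIF_2(\theta_{j,2})},}
#' assuming independent simple random samples at the two time points with
#' negligible covariance between the estimated means.
#'
#' @param design a [growth_design()].
#' @param abilities1 abilities of the `N1` examinees taking form 1 (may be
#'   empty together with a missing `N2` term for the single-form case).
#' @param abilities2 abilities of the `N2` examinees taking form 2.
#' @param N1,N2 sample sizes; default to the lengths of the ability vectors.
#' @return Non-negative scalar.
#' @export
asymptotic_var_growth <- function(design, abilities1, abilities2,
                                  N1 = length(abilities1),
                                  N2 = length(abilities2)) {
  stopifnot(inherits(design, "growth_design"))
  if (length(abilities1) != N1 || length(abilities2) != N2)
    stop("ability vectors must match N1, N2", call. = FALSE)
  v <- 0
  if (N1 > 0)
    v <- v + sum(1 / tif_or_stop(form1_items(design), abilities1)) / N1^2
  if (N2 > 0)
    v <- v + sum(1 / tif_or_stop(form2_items(design), abilities2)) / N2^2
  v
}

#' Asymptotic variance of estimated percentile growth
#'
#' \eqn{\mathrm{Var}(\hat d_p) = 1/TIF_1(\theta_{1p}) + 1/TIF_2(\theta_{2p})}
#' for the `p`th percentile points of the two populations.
#'
#' @param design a [growth_design()].
#' @param theta1p,theta2p the percentile abilities in the two populations.
#' @return Non-negative scalar.
#' @export
asymptotic_var_percentile <- function(design, theta1p, theta2p) {
  stopifnot(inherits(design, "growth_design"))
  1 / tif_or_stop(form1_items(design), theta1p) +
    1 / tif_or_stop(form2_items(design), theta2p)
}
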