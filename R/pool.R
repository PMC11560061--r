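#' Calibrated item pool
#'
#' A collection of calibrated 2PL items with stable unique identifiers, from
#' which discrete test assembly selects the two forms and the anchor block.
#'
#' @param item_id character (or coercible) vector of unique identifiers.
#' @param a,b item discriminations (> 0) and difficulties.
#' @return A data frame of class `item_pool` with columns `item_id`, `a`, `b`.
#' @export
item_pool <- function(item_id, a, b) {
  item_id <- as.character(item_id)
  if (anyDuplicated(item_id)) stop("item identifiers must be unique", call. = FALSE)
  n <- length(item_id)
  if (length(a) != n || length(b) != n)
    stop("'item_id', 'a', 'b' must have equal length", call. = FALSE)
  validate_items(as.numeric(a), as.numeric(b))
  structure(data.frame(item_id = item_id, a = as.numeric(a), b = as.numeric(b),
                       stringsAsFactors = FALSE),
            class = c("item_pool", "data.frame"))
}

#' @export
print.item_pool <- function(x, ...) {
  cat("<item_pool> ", nrow(x), " items | mean a = ",
      format(mean(x$a), digits = 4), " | mean b = ",
      format(mean(x$b), digits = 4), "\n", sep = "")
  invisible(x)
}

# Frozen generator constants: a truncated-lognormal meanlog solved once so the
# truncated mean matches the 1.14 target on [0.40, 1.90] at sdlog = 0.30.
.pool_a_meanlog <- 0.1224794
.pool_a_sdlog <- 0.30

#' Generate a synthetic calibrated item pool
#'
#' Emulates a large-scale assessment pool of dichotomous 2PL items:
#' discriminations follow a lognormal shape truncated to `a_range` (defaults
#' tuned so the mean is about 1.14), and difficulties follow a symmetric
#' bell-shaped (truncated normal) distribution on `b_range`, mean-centered so
#' the pool's difficulties average exactly zero.  Sampling uses inverse-CDF
#' draws, so the pool is reproducible given the seed.
#'
#' @param n_items number of items, >= 1.
#' @param seed integer seed.
#' @param a_range,b_range numeric length-2 ranges for the parameters.
#' @return An [item_pool()] with identifiers `"item001"`, ...
#' @examples
#' pool <- generate_synthetic_pool(248, seed = 1)
#' range(pool$a); mean(pool$b)
#' @export
generate_synthetic_pool <- function(n_items = 248, seed = 1L,
                                    a_range = c(0.40, 1.90),
                                    b_range = c(-1.56, 1.60)) {
  if (n_items < 1) stop("'n_items' must be >= 1", call. = FALSE)
  if (length(a_range) != 2L || a_range[1] >= a_range[2] || a_range[1] <= 0)
    stop("'a_range' must be an increasing positive range", call. = FALSE)
  if (length(b_range) != 2L || b_range[1] >= b_range[2])
    stop("'b_range' must be an increasing range", call. = FALSE)
  set.seed(seed)
  # inverse-CDF truncated lognormal for a
  pa <- plnorm(a_range, .pool_a_meanlog, .pool_a_sdlog)
  a <- qlnorm(runif(n_items, pa[1], pa[2]), .pool_a_meanlog, .pool_a_sdlog)
  # symmetric truncated normal for b, then mean-centered
  mu_b <- mean(b_range)
  sd_b <- diff(b_range) / 4
  pb <- pnorm(b_range, mu_b, sd_b)
  b <- qnorm(runif(n_items, pb[1], pb[2]), mu_b, sd_b)
  b <- b - mean(b)
  ids <- sprintf("item%03d", seq_len(n_items))
  item_pool(ids, a, b)
}

#' Center a pool's difficulties at zero
#'
#' Subtracts the mean difficulty, making the pool's scale comparable to
#' designs optimized around zero.  Idempotent; discriminations are unchanged.
#'
#' @param pool an [item_pool()].
#' @return The centered [item_pool()].
#' @export
center_difficulties <- function(pool) {
  pool <- as_pool(pool)
  pool$b <- pool$b - mean(pool$b)
  pool
}

as_pool <- function(x) {
  if (inherits(x, "item_pool")) return(x)
  if (is.data.frame(x) && all(c("item_id", "a", "b") %in% names(x)))
    return(item_pool(x$item_id, x$a, x$b))
  stop("expected an 'item_pool'", call. = FALSE)
}

#' Read / write an item pool as delimited text
#'
#' The pool format is a comma-separated table with header `item_id,a,b`.
#' Parameters are written with 12 significant digits so a round trip preserves
#' them to that precision.
#'
#' @param path file path.
#' @return `read_item_pool` returns an [item_pool()]; `write_item_pool`
#'   returns `path` invisibly.
#' @export
read_item_pool <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("item_id", "a", "b") %in% names(df)))
    stop("pool file must have columns item_id, a, b", call. = FALSE)
  item_pool(df$item_id, df$a, df$b)
}

#' @rdname read_item_pool
#' @param pool an [item_pool()].
#' @export
write_item_pool <- function(pool, path) {
  pool <- as_pool(pool)
  out <- data.frame(item_id = pool$item_id,
                    a = sprintf("%.12g", pool$a),
                    b = sprintf("%.12g", pool$b))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulated annealing configuration for pool assembly
#'
#' Defaults are the study settings: initial temperature 100 (acceptance
#' probability of uphill moves close to 1 in the first epochs), geometric
#' cooling `g(t) = alpha t` with `alpha = 0.8`, 5000 moves per epoch, 100
#' epochs (final temperature about 2e-8), and a 100,000-iteration greedy
#' refinement pass accepting strict improvements only.
#'
#' @param t0 initial temperature, > 0.
#' @param alpha cooling factor in (0, 1).
#' @param nrep moves per epoch, >= 1.
#' @param epochs number of temperature plateaus, >= 1.
#' @param greedy_iterations moves in the greedy refinement pass.
#' @param seed integer seed.
#' @return An object of class `sa_config`.
#' @export
sa_config <- function(t0 = 100, alpha = 0.8, nrep = 5000, epochs = 100,
                      greedy_iterations = 100000, seed = 1L) {
  if (!is.finite(t0) || t0 <= 0) stop("'t0' must be > 0", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  if (nrep < 1 || epochs < 1)
    stop("'nrep' and 'epochs' must be >= 1", call. = FALSE)
  structure(list(t0 = t0, alpha = alpha, nrep = as.integer(nrep),
                 epochs = as.integer(epochs),
                 greedy_iterations = as.integer(greedy_iterations),
                 seed = as.integer(seed)),
            class = "sa_config")
}

#' Temperature schedule of an annealing configuration
#'
#' The geometric cooling sequence actually used by [sa_select()]: epoch `k`
#' (1-based) runs at temperature `t0 * alpha^(k - 1)`, so after `k` completed
#' epochs the temperature is exactly `t0 * alpha^k`.
#'
#' @param config an [sa_config()].
#' @return Numeric vector of length `config$epochs`.
#' @export
sa_temperatures <- function(config) {
  stopifnot(inherits(config, "sa_config"))
  config$t0 * config$alpha^(seq_len(config$epochs) - 1L)
}

#' Growth criterion as a pool-assembly objective
#'
#' Wraps a pair of population ability grids as the objective minimized during
#' discrete assembly: the selected forms' weighted inverse test information
#' summed over both grids (the same quantity as [crit_growth()]).  Selection
#' engines recognize this object and evaluate swap moves incrementally.
#'
#' @inheritParams crit_growth
#' @return An object of class `design_criterion`.
#' @export
design_criterion <- function(grid1, grid2) {
  structure(list(comps = growth_components(grid1, grid2)),
            class = "design_criterion")
}

# Full evaluation of an assembly objective for a selection of pool rows.
pool_objective_value <- function(objective, pool, sel, sizes) {
  design <- selection_design(pool, sel, sizes)
  if (inherits(objective, "design_criterion")) {
    crit_from_components(objective$comps, design)
  } else {
    val <- objective(design)
    if (!is.finite(val)) stop("objective returned a non-finite value", call. = FALSE)
    val
  }
}

crit_from_components <- function(comps, design) {
  i1 <- comps$form == 1L
  sum(comps$w[i1] / tif_or_stop(form1_items(design), comps$theta[i1])) +
    sum(comps$w[!i1] / tif_or_stop(form2_items(design), comps$theta[!i1]))
}

selection_design <- function(pool, sel, sizes) {
  n1 <- sizes[1]; nc <- sizes[2]; n2 <- sizes[3]
  grab <- function(idx) if (length(idx)) items(pool$a[idx], pool$b[idx])
  growth_design(unique1 = grab(sel[seq_len(n1)]),
                common = grab(sel[seq_len(nc) + n1]),
                unique2 = grab(sel[seq_len(n2) + n1 + nc]))
}

check_sizes <- function(pool, sizes) {
  if (length(sizes) != 3L || any(sizes < 0) || any(sizes != round(sizes)))
    stop("'sizes' must be three non-negative integers (n1, nc, n2)", call. = FALSE)
  if (sizes[1] + sizes[2] < 1 || sizes[3] + sizes[2] < 1)
    stop("both forms must be non-empty", call. = FALSE)
  if (nrow(pool) <= sum(sizes))
    stop("pool must contain more items than the requested selection", call. = FALSE)
  invisible(TRUE)
}

# Item information of every pool item at every criterion component ability.
pool_info_matrix <- function(pool, comps) {
  x <- sweep(outer(pool$b, comps$theta, function(b, th) th - b), 1L, pool$a, "*")
  t <- exp(-abs(x))
  sweep(t / (1 + t)^2, 1L, pool$a^2, "*")
}

# Shared swap-neighborhood search used by both annealing and greedy descent.
#
# Every move consumes exactly three random draws (slot, replacement index,
# acceptance uniform) whether or not they are all used, so annealing at a
# near-zero temperature and greedy descent follow identical move streams under
# the same RNG state.
swap_search <- function(pool, sizes, objective, sel, schedule, greedy) {
  ntot <- sum(sizes)
  role <- rep.int(1:3, times = sizes)
  unsel <- setdiff(seq_len(nrow(pool)), sel)
  fast <- inherits(objective, "design_criterion")

  if (fast) {
    comps <- objective$comps
    M <- pool_info_matrix(pool, comps)
    idx1 <- which(comps$form == 1L)
    idx2 <- which(comps$form == 2L)
    w1 <- comps$w[idx1]; w2 <- comps$w[idx2]
    in1 <- role != 3L   # slots feeding form 1 (unique-1 + common)
    in2 <- role != 1L   # slots feeding form 2 (common + unique-2)
    tif1 <- colSums(M[sel[in1], idx1, drop = FALSE])
    tif2 <- colSums(M[sel[in2], idx2, drop = FALSE])
    value <- sum(w1 / tif1) + sum(w2 / tif2)
  } else {
    value <- pool_objective_value(objective, pool, sel, sizes)
  }

  best_sel <- sel
  best_value <- value
  trace <- numeric(length(schedule$t))
  accepted_values <- numeric(0)

  for (ep in seq_along(schedule$t)) {
    temp <- schedule$t[ep]
    nmoves <- schedule$nrep[ep]
    slot_draw <- sample.int(ntot, nmoves, replace = TRUE)
    repl_draw <- sample.int(length(unsel), nmoves, replace = TRUE)
    acc_draw <- runif(nmoves)
    for (k in seq_len(nmoves)) {
      s <- slot_draw[k]
      r <- repl_draw[k]
      new_item <- unsel[r]
      old_item <- sel[s]
      if (fast) {
        rs <- role[s]
        d1 <- if (rs != 3L) M[new_item, idx1] - M[old_item, idx1]
        d2 <- if (rs != 1L) M[new_item, idx2] - M[old_item, idx2]
        delta <- 0
        if (!is.null(d1)) delta <- delta + sum(w1 / (tif1 + d1)) - sum(w1 / tif1)
        if (!is.null(d2)) delta <- delta + sum(w2 / (tif2 + d2)) - sum(w2 / tif2)
      } else {
        sel_try <- sel
        sel_try[s] <- new_item
        new_value <- pool_objective_value(objective, pool, sel_try, sizes)
        delta <- new_value - value
      }
      accept <- if (greedy) delta < 0
                else delta <= 0 || acc_draw[k] < exp(-delta / temp)
      if (accept) {
        sel[s] <- new_item
        unsel[r] <- old_item
        if (fast) {
          if (!is.null(d1)) tif1 <- tif1 + d1
          if (!is.null(d2)) tif2 <- tif2 + d2
        }
        value <- value + delta
        if (greedy) accepted_values <- c(accepted_values, value)
        if (value < best_value) {
          best_value <- value
          best_sel <- sel
        }
      }
    }
    trace[ep] <- best_value
  }

  list(sel = best_sel, value = best_value, trace = trace,
       accepted_values = accepted_values)
}

make_pool_solution <- function(pool, sel, sizes, objective, trace, seed,
                               accepted_values = NULL) {
  n1 <- sizes[1]; nc <- sizes[2]; n2 <- sizes[3]
  structure(list(
    selected = list(unique1 = pool$item_id[sel[seq_len(n1)]],
                    common = pool$item_id[sel[seq_len(nc) + n1]],
                    unique2 = pool$item_id[sel[seq_len(n2) + n1 + nc]]),
    sel_idx = sel,
    sizes = sizes,
    criterion_value = pool_objective_value(objective, pool, sel, sizes),
    energy_trace = trace,
    accepted_values = accepted_values,
    seed = seed),
    class = "pool_solution")
}

#' @export
print.pool_solution <- function(x, ...) {
  cat("<pool_solution> n1 =", length(x$selected$unique1),
      "| nc =", length(x$selected$common),
      "| n2 =", length(x$selected$unique2),
      "| criterion =", format(x$criterion_value), "\n")
  invisible(x)
}

#' Select test items from a pool by simulated annealing
#'
#' Starts from a uniform random role-assigned selection of `n1 + nc + n2`
#' items.  Each move swaps the occupant of one uniformly chosen slot (its role
#' is preserved) with one uniformly chosen unselected pool item; improvements
#' (`delta <= 0`) are always accepted, uphill moves with probability
#' `exp(-delta / t)`.  After `nrep` moves the temperature cools by the factor
#' `alpha`; the best-ever selection is returned.  One seeded generator stream
#' drives the run, with the starting selection drawn first.
#'
#' @param pool an [item_pool()] larger than the selection.
#' @param sizes integer vector `(n1, nc, n2)` of role sizes.
#' @param objective a [design_criterion()] (evaluated incrementally) or a
#'   function taking a [growth_design()] and returning a finite scalar.
#' @param config an [sa_config()].
#' @return A `pool_solution`: per-role selected identifiers, the re-evaluated
#'   criterion value, and the per-epoch best-ever `energy_trace`.
#' @export
sa_select <- function(pool, sizes, objective, config = sa_config()) {
  pool <- as_pool(pool)
  check_sizes(pool, sizes)
  stopifnot(inherits(config, "sa_config"))
  set.seed(config$seed)
  sel <- sample.int(nrow(pool), sum(sizes))
  schedule <- list(t = sa_temperatures(config),
                   nrep = rep.int(config$nrep, config$epochs))
  res <- swap_search(pool, sizes, objective, sel, schedule, greedy = FALSE)
  make_pool_solution(pool, res$sel, sizes, objective, res$trace, config$seed)
}

#' Greedy refinement of a pool selection
#'
#' Runs the same swap neighborhood as [sa_select()] but accepts strictly
#' improving moves only, as a no-further-improvement check on an annealed
#' solution.  The returned criterion value is never larger than the start's.
#'
#' @param pool an [item_pool()].
#' @param start a `pool_solution` valid for `pool` (e.g. from [sa_select()]).
#' @inheritParams sa_select
#' @param iterations number of proposed moves.
#' @param seed integer seed, or `NULL` to continue from the current RNG state.
#' @return A `pool_solution`; `accepted_values` holds the strictly decreasing
#'   criterion values at accepted moves.
#' @export
greedy_refine <- function(pool, start, objective, iterations = 100000,
                          seed = NULL) {
  pool <- as_pool(pool)
  stopifnot(inherits(start, "pool_solution"))
  sizes <- start$sizes
  check_sizes(pool, sizes)
  if (!setequal(pool$item_id[start$sel_idx],
                unlist(start$selected, use.names = FALSE)))
    stop("'start' does not match 'pool'", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  schedule <- list(t = 0, nrep = as.integer(iterations))
  res <- swap_search(pool, sizes, objective, start$sel_idx, schedule,
                     greedy = TRUE)
  make_pool_solution(pool, res$sel, sizes, objective, res$trace,
                     seed %||% start$seed, accepted_values = res$accepted_values)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exhaustive role-assigned selection (oracle for small pools)
#'
#' Enumerates every disjoint assignment of `n1`, `nc`, `n2` pool items to the
#' three roles and returns the global minimum of the objective.  Ties are
#' broken by the lexicographically smallest identifier tuple (roles ordered
#' unique-1, common, unique-2, identifiers sorted within each role).  Guarded
#' to at most one million assignments.
#'
#' @inheritParams sa_select
#' @return A `pool_solution` at the global optimum.
#' @export
exhaustive_select <- function(pool, sizes, objective) {
  pool <- as_pool(pool)
  check_sizes(pool, sizes)
  np <- nrow(pool)
  n1 <- sizes[1]; nc <- sizes[2]; n2 <- sizes[3]
  total <- choose(np, n1) * choose(np - n1, nc) * choose(np - n1 - nc, n2)
  if (total > 1e6)
    stop("exhaustive enumeration guard exceeded (", format(total),
         " assignments)", call. = FALSE)
  ord <- order(pool$item_id)

  best_value <- Inf
  best_sel <- NULL
  combs <- function(pool_idx, k) {
    if (k == 0L) return(list(integer(0)))
    asplit(utils::combn(pool_idx, k), 2L)
  }
  for (u1 in combs(ord, n1)) {
    rest1 <- setdiff(ord, u1)
    for (cm in combs(rest1, nc)) {
      rest2 <- setdiff(rest1, cm)
      for (u2 in combs(rest2, n2)) {
        sel <- c(u1, cm, u2)
        val <- pool_objective_value(objective, pool, sel, sizes)
        if (val < best_value) {
          best_value <- val
          best_sel <- sel
        }
      }
    }
  }
  make_pool_solution(pool, best_sel, sizes, objective, trace = best_value,
                     seed = NA_integer_)
}
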