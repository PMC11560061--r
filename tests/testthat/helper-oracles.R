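# Independent oracles and small random fixtures, deliberately written with
# plain scalar loops so they share no code with the package's vectorized or
# compiled paths.

naive_prob <- function(a, b, theta) 1 / (1 + exp(-a * (theta - b)))

naive_tif <- function(its, theta) {
  total <- 0
  for (i in seq_len(nrow(its))) {
    x <- its$a[i] * (theta - its$b[i])
    # p and 1 - p each computed directly (forming 1 - p from p cancels badly
    # when p is near 1 and the tiny information term dominates 1/TIF)
    p <- 1 / (1 + exp(-x))
    q <- 1 / (1 + exp(x))
    total <- total + its$a[i]^2 * p * q
  }
  total
}

# double-loop growth criterion: sum_j w_j / TIF at each grid point, per form
naive_crit_growth <- function(design, grid1, grid2) {
  f1 <- rbind(design$unique1, design$common)
  f2 <- rbind(design$common, design$unique2)
  total <- 0
  for (j in seq_along(grid1$points))
    total <- total + grid1$weights[j] / naive_tif(f1, grid1$points[j])
  for (j in seq_along(grid2$points))
    total <- total + grid2$weights[j] / naive_tif(f2, grid2$points[j])
  total
}

random_design <- function(n1, nc, n2) {
  ra <- function(n) runif(n, 0.5, 2)
  rb <- function(n) runif(n, -3, 3)
  growth_design(if (n1) items(ra(n1), rb(n1)),
                if (nc) items(ra(nc), rb(nc)),
                if (n2) items(ra(n2), rb(n2)))
}

random_tiny_pool <- function(n) {
  item_pool(sprintf("tp%02d", seq_len(n)), runif(n, 0.5, 2), runif(n, -2, 2))
}

# small-problem annealing settings (search spaces of at most a few thousand
# assignments need far fewer moves than the full study schedule)
tiny_sa <- function(seed) {
  sa_config(t0 = 100, alpha = 0.8, nrep = 200, epochs = 30,
            greedy_iterations = 2000, seed = seed)
}
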