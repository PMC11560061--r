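role_colors <- c(unique1 = "#d62728", common = "#e6b422", unique2 = "#1f77b4")

#' Plot an optimized design's sorted difficulties by role
#'
#' Dot plot of the sorted item difficulties, one color per role (form-1 unique,
#' common, form-2 unique), the usual display for optimized growth designs.
#'
#' @param x a `solution_record`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.solution_record <- function(x, ...) {
  bs <- x$difficulties
  xs <- unlist(bs, use.names = FALSE)
  pos <- seq_along(xs)
  cols <- rep(role_colors[names(bs)], lengths(bs))
  graphics::plot(pos, xs, col = cols, pch = 19,
                 xlab = "sorted item index (unique1 | common | unique2)",
                 ylab = "item difficulty b",
                 main = sprintf("case %s, a = %s, d = %s",
                                x$case_id,
                                paste(format(unique(x$a_level)), collapse = "/"),
                                x$d), ...)
  graphics::legend("topleft", legend = names(role_colors),
                   col = role_colors, pch = 19, bty = "n")
  invisible(x)
}

#' Scatter plot of a pool with the selected items highlighted
#'
#' @param pool the [item_pool()] the selection was drawn from.
#' @param solution a `pool_solution`.
#' @export
plot_pool_selection <- function(pool, solution) {
  pool <- as_pool(pool)
  graphics::plot(pool$b, pool$a, pch = 19, col = "grey30",
                 xlab = "difficulty b", ylab = "discrimination a",
                 main = "item pool and selected items")
  for (r in names(solution$selected)) {
    idx <- match(solution$selected[[r]], pool$item_id)
    graphics::points(pool$b[idx], pool$a[idx], pch = 19, col = role_colors[[r]])
  }
  graphics::legend("topleft", legend = c(names(role_colors), "pool"),
                   col = c(role_colors, "grey30"), pch = 19, bty = "n")
  invisible(solution)
}

#' Box plots of the uncertainty-design ratio table
#'
#' One box per candidate true growth distance; ratios above one favor the
#' optimum-in-average design.
#'
#' @param x a `ratio_table`.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.ratio_table <- function(x, ...) {
  graphics::boxplot(x$ratios, names = format(x$true_d),
                    xlab = "true growth distance d",
                    ylab = expression(sigma[O] / sigma[A]), ...)
  graphics::abline(h = 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Mean and standard deviation of repeated optimizations
#'
#' Two panels: per-component means and standard deviations of the sorted
#' solutions across repetitions, colored by role.
#'
#' @param x a `stability_result`.
#' @param ... unused.
#' @export
plot.stability_result <- function(x, ...) {
  cols <- role_colors[x$role]
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$mean), x$mean, col = cols, pch = 19,
                 xlab = "component", ylab = "mean of sorted b")
  graphics::plot(seq_along(x$sd), x$sd, col = cols, pch = 19,
                 xlab = "component", ylab = "SD of sorted b")
  invisible(x)
}
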