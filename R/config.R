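# Run configuration: a flat, schema-checked yaml document with blocks
# scenario / optimizer / experiment / io / pool plus a top-level seed.
# Unknown keys are rejected so silent typos cannot change a run, and every
# run writes its resolved configuration (with a content hash) next to its
# outputs so it can be replayed bitwise.

.config_schema <- list(
  top = c("seed", "scenario", "optimizer", "experiment", "io", "pool"),
  scenario = c("case", "d", "a", "n1", "nc", "n2", "l", "half_width",
               "percentiles", "group_shift"),
  optimizer = c("pso", "sa"),
  pso = c("swarm_size", "proportion_informed", "convergence_tol",
          "max_iterations", "lower_bound", "upper_bound", "inertia",
          "cognitive_coef", "social_coef", "patience"),
  sa = c("t0", "alpha", "nrep", "epochs", "greedy_iterations"),
  experiment = c("reps", "true_d", "prior_sd", "d_design", "N", "a_sdlog"),
  io = c("pool", "out_dir", "design"),
  pool = c("n_items", "a_range", "b_range")
)

check_keys <- function(block, allowed, where) {
  if (is.null(block)) return(invisible(TRUE))
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    stop("unknown configuration key(s) in ", where, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Read and validate a run configuration
#'
#' Reads a yaml run configuration, rejects unknown keys, applies defaults and
#' optional overrides, and returns the resolved configuration used by the
#' `run_*` entry points (and the command-line script shipped in
#' `inst/cli/growthdesign.R`).
#'
#' @param path path to a yaml configuration file, or `NULL` for defaults only.
#' @param overrides named list merged over the file contents (e.g.
#'   `list(seed = 7)` from a `--seed` flag).
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration must be a yaml mapping", call. = FALSE)
  check_keys(cfg, .config_schema$top, "top level")
  for (blk in c("scenario", "experiment", "io", "pool"))
    check_keys(cfg[[blk]], .config_schema[[blk]], blk)
  check_keys(cfg$optimizer, .config_schema$optimizer, "optimizer")
  check_keys(cfg$optimizer$pso, .config_schema$pso, "optimizer$pso")
  check_keys(cfg$optimizer$sa, .config_schema$sa, "optimizer$sa")
  cfg <- modifyList(cfg, overrides)
  defaults <- list(
    seed = 1L,
    # note: scenario$d has no default — design runs must state the growth
    # distance explicitly
    scenario = list(case = 1L, a = 1, n1 = 30L, nc = 15L, n2 = 30L,
                    l = 100L, half_width = 4),
    optimizer = list(pso = list(), sa = list()),
    experiment = list(reps = 50L, true_d = seq(0.4, 1.6, by = 0.2),
                      prior_sd = 0.2, d_design = 1, N = 500L, a_sdlog = 0.25),
    io = list(out_dir = "."),
    pool = list(n_items = 248L, a_range = c(0.40, 1.90),
                b_range = c(-1.56, 1.60)))
  cfg <- modifyList(defaults, cfg)
  structure(cfg, class = c("run_config", "list"))
}

config_spec <- function(cfg) {
  sc <- cfg$scenario
  criterion_spec(d = sc$d, a_level = sc$a, n1 = sc$n1, nc = sc$nc, n2 = sc$n2,
                 l = sc$l, half_width = sc$half_width,
                 percentiles = sc$percentiles, group_shift = sc$group_shift)
}

config_pso <- function(cfg) {
  do.call(pso_config, c(cfg$optimizer$pso, list(seed = cfg$seed)))
}

config_sa <- function(cfg) {
  do.call(sa_config, c(cfg$optimizer$sa, list(seed = cfg$seed)))
}

# FNV-1a over the serialized configuration: a stable content fingerprint
# embedded in every artifact so outputs can be matched to their exact inputs.
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(cfg[order(names(cfg))]), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

write_resolved_config <- function(cfg, out_dir, stem) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  resolved <- unclass(cfg)
  resolved$config_hash <- config_hash(cfg)
  path <- file.path(out_dir, paste0(stem, "-config.yaml"))
  yaml::write_yaml(resolved, path)
  path
}

out_stem <- function(cfg, what) {
  sprintf("%s-seed%d-%s", what, cfg$seed, config_hash(cfg))
}

#' Run a continuous design optimization from a configuration
#'
#' Thin wrappers over the package functions for scripted use: each validates
#' its configuration, executes one study operation, and writes its results
#' (delimited tables, a figure where applicable, and the resolved
#' configuration) into `io$out_dir`.
#'
#' @param cfg a [read_run_config()] object.
#' @return The result object of the underlying function, invisibly; the
#'   written file paths are attached as attribute `files`.
#' @export
run_design_continuous <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$scenario$d)) stop("scenario$d is required", call. = FALSE)
  rec <- optimize_continuous_design(cfg$scenario$case, config_spec(cfg),
                                    config_pso(cfg))
  out <- cfg$io$out_dir
  stem <- out_stem(cfg, sprintf("case%d", cfg$scenario$case))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  tab <- data.frame(role = rep(names(rec$difficulties),
                               lengths(rec$difficulties)),
                    b = unlist(rec$difficulties, use.names = FALSE))
  csv <- file.path(out, paste0(stem, ".csv"))
  write.csv(cbind(tab, criterion = rec$criterion_value, seed = rec$seed),
            csv, row.names = FALSE)
  fig <- file.path(out, paste0(stem, ".png"))
  grDevices::png(fig, width = 900, height = 500)
  plot(rec)
  grDevices::dev.off()
  files <- c(csv, fig, write_resolved_config(cfg, out, stem))
  invisible(structure(rec, files = files))
}

#' @rdname run_design_continuous
#' @export
run_make_pool <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  pool <- generate_synthetic_pool(cfg$pool$n_items, seed = cfg$seed,
                                  a_range = cfg$pool$a_range,
                                  b_range = cfg$pool$b_range)
  out <- cfg$io$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stem <- out_stem(cfg, "pool")
  path <- cfg$io$pool %||% file.path(out, paste0(stem, ".csv"))
  write_item_pool(pool, path)
  files <- c(path, write_resolved_config(cfg, out, stem))
  invisible(structure(pool, files = files))
}

#' @rdname run_design_continuous
#' @export
run_design_pool <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$io$pool)) stop("io$pool is required", call. = FALSE)
  if (is.null(cfg$scenario$d)) stop("scenario$d is required", call. = FALSE)
  pool <- center_difficulties(read_item_pool(cfg$io$pool))
  sc <- cfg$scenario
  obj <- design_criterion(make_normal_grid(-sc$d / 2, 1, sc$l, sc$half_width),
                          make_normal_grid(+sc$d / 2, 1, sc$l, sc$half_width))
  sizes <- c(sc$n1, sc$nc, sc$n2)
  sacfg <- config_sa(cfg)
  sol <- sa_select(pool, sizes, obj, sacfg)
  ref <- greedy_refine(pool, sol, obj, iterations = sacfg$greedy_iterations)
  out <- cfg$io$out_dir
  stem <- out_stem(cfg, sprintf("pool-design-d%s", sc$d))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sel <- data.frame(role = rep(names(ref$selected), lengths(ref$selected)),
                    item_id = unlist(ref$selected, use.names = FALSE))
  sel <- merge(sel, pool, by = "item_id", sort = FALSE)
  csv <- file.path(out, paste0(stem, ".csv"))
  write.csv(cbind(sel, criterion_sa = sol$criterion_value,
                  criterion_refined = ref$criterion_value, seed = cfg$seed),
            csv, row.names = FALSE)
  fig <- file.path(out, paste0(stem, ".png"))
  grDevices::png(fig, width = 900, height = 500)
  plot_pool_selection(pool, ref)
  grDevices::dev.off()
  files <- c(csv, fig, write_resolved_config(cfg, out, stem))
  invisible(structure(ref, files = files))
}

#' @rdname run_design_continuous
#' @export
run_uncertainty <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  ex <- cfg$experiment
  sc <- cfg$scenario
  rt <- uncertainty_ratio_experiment(
    d_design = ex$d_design, true_d = ex$true_d, reps = ex$reps,
    prior_sd = ex$prior_sd, sizes = c(sc$n1, sc$nc, sc$n2),
    l = sc$l, half_width = sc$half_width, a_sdlog = ex$a_sdlog,
    pso_config = config_pso(cfg), seed = cfg$seed)
  out <- cfg$io$out_dir
  stem <- out_stem(cfg, "uncertainty")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  long <- data.frame(replicate = rep(seq_len(nrow(rt$ratios)),
                                     times = ncol(rt$ratios)),
                     true_d = rep(rt$true_d, each = nrow(rt$ratios)),
                     ratio = as.vector(rt$ratios))
  csv <- file.path(out, paste0(stem, ".csv"))
  write.csv(long, csv, row.names = FALSE)
  fig <- file.path(out, paste0(stem, ".png"))
  grDevices::png(fig, width = 700, height = 500)
  plot(rt)
  grDevices::dev.off()
  files <- c(csv, fig, write_resolved_config(cfg, out, stem))
  invisible(structure(rt, files = files))
}

#' @rdname run_design_continuous
#' @export
run_stability <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$scenario$d)) stop("scenario$d is required", call. = FALSE)
  sc <- cfg$scenario
  st <- stability_analysis(sc$case, a_level = sc$a, d = sc$d,
                           reps = cfg$experiment$reps, spec = config_spec(cfg),
                           pso_config = config_pso(cfg), seed = cfg$seed)
  out <- cfg$io$out_dir
  stem <- out_stem(cfg, "stability")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(out, paste0(stem, ".csv"))
  write.csv(data.frame(component = seq_along(st$mean), role = st$role,
                       mean = st$mean, sd = st$sd),
            csv, row.names = FALSE)
  fig <- file.path(out, paste0(stem, ".png"))
  grDevices::png(fig, width = 900, height = 450)
  plot(st)
  grDevices::dev.off()
  files <- c(csv, fig, write_resolved_config(cfg, out, stem))
  invisible(structure(st, files = files))
}

#' @rdname run_design_continuous
#' @export
run_validate_variance <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$scenario$d)) stop("scenario$d is required", call. = FALSE)
  sc <- cfg$scenario
  design <- if (!is.null(cfg$io$design)) {
    read_design(cfg$io$design)
  } else {
    # a reasonable three-cluster layout at the scenario's a and d
    growth_design(items(sc$a, rep(-sc$d / 2, sc$n1)),
                  items(sc$a, rep(0, sc$nc)),
                  items(sc$a, rep(+sc$d / 2, sc$n2)))
  }
  mc <- mc_validate_variance(design, d = sc$d, N = cfg$experiment$N,
                             reps = cfg$experiment$reps, seed = cfg$seed)
  out <- cfg$io$out_dir
  stem <- out_stem(cfg, "mc-validate")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(out, paste0(stem, ".csv"))
  write.csv(data.frame(empirical_var = mc$empirical_var,
                       predicted_var = mc$predicted_var, ratio = mc$ratio,
                       N = mc$N, reps = mc$reps, n_clamped = mc$n_clamped,
                       seed = mc$seed),
            csv, row.names = FALSE)
  files <- c(csv, write_resolved_config(cfg, out, stem))
  invisible(structure(mc, files = files))
}

#' Read / write a growth design as delimited text
#'
#' Format: csv with columns `role` (`unique1`, `common`, `unique2`), `a`, `b`.
#'
#' @param path file path.
#' @return `read_design` returns a [growth_design()].
#' @export
read_design <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("role", "a", "b") %in% names(df)))
    stop("design file must have columns role, a, b", call. = FALSE)
  if (!all(df$role %in% c("unique1", "common", "unique2")))
    stop("design roles must be unique1, common, unique2", call. = FALSE)
  grab <- function(r) {
    sub <- df[df$role == r, , drop = FALSE]
    if (nrow(sub)) items(sub$a, sub$b)
  }
  growth_design(grab("unique1"), grab("common"), grab("unique2"))
}

#' @rdname read_design
#' @param design a [growth_design()].
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "growth_design"))
  df <- do.call(rbind, lapply(c("unique1", "common", "unique2"), function(r) {
    it <- design[[r]]
    if (nrow(it)) data.frame(role = r, a = it$a, b = it$b)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
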