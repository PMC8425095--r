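# Scenario configuration, replicated execution and cross-replicate
# aggregation of per-year population statistics.

#' Define a simulation scenario
#'
#' A scenario couples a genetic parameter setup with a selection strategy, a
#' polyandry level and replication settings. The study design of the
#' simulator crosses setups 1-4 with strategies M (mass) and L (within
#' maternal line) and polyandry levels 1 and 8 (plus 16 for setup 1).
#'
#' @param setup A [genetic_setup()] object or a preset id in 1..4.
#' @param strategy `"M"`/`"mass"` or `"L"`/`"within_line"` (or `"random"`
#'   for the drift-only control).
#' @param n_drones Polyandry level nD.
#' @param n_replicates Number of independent replicates.
#' @param years Number of simulated birth cohorts.
#' @param ... Further arguments forwarded to [scheme_config()].
#' @return A list of class `scenario_spec` with elements `setup`, `config`,
#'   `n_replicates` and `label`.
#' @export
scenario_spec <- function(setup = 1L, strategy = c("L", "M", "random"),
                          n_drones = 8L, n_replicates = 160L,
                          years = 23L, ...) {
  setup_id <- NA_integer_
  if (!inherits(setup, "genetic_setup")) {
    setup_id <- as.integer(setup)
    setup <- preset_genetic_setup(setup_id)
  }
  strategy <- match.arg(strategy[1L],
                        c("L", "M", "random", "within_line", "mass"))
  strat_cfg <- switch(strategy,
                      L = "within_line", within_line = "within_line",
                      M = "mass", mass = "mass",
                      random = "within_line")
  cfg <- scheme_config(n_drones_per_queen = n_drones,
                       selection_strategy = strat_cfg,
                       total_years = years,
                       random_selection = identical(strategy, "random"), ...)
  lab <- sprintf("setup%s-%s-nD%d",
                 ifelse(is.na(setup_id), "custom", setup_id),
                 switch(strat_cfg, within_line = "L", mass = "M"),
                 as.integer(n_drones))
  if (identical(strategy, "random")) lab <- paste0(lab, "-random")
  structure(list(setup = setup, setup_id = setup_id, config = cfg,
                 n_replicates = as.integer(n_replicates), label = lab),
            class = "scenario_spec")
}

#' Parse a scenario preset label
#'
#' Labels have the form `"setup<1-4>-<M|L>-nD<k>"`, e.g. `"setup1-M-nD1"`.
#'
#' @param label Preset string.
#' @param ... Forwarded to [scenario_spec()].
#' @return A `scenario_spec`.
#' @export
scenario_preset <- function(label, ...) {
  m <- regmatches(label,
                  regexec("^setup([1-4])-(M|L)-nD([0-9]+)$", label))[[1L]]
  if (!length(m)) stop("unrecognized preset label: ", label)
  scenario_spec(setup = as.integer(m[2L]), strategy = m[3L],
                n_drones = as.integer(m[4L]), ...)
}

#' Run a scenario over replicates
#'
#' Executes [run_replicate()] `n_replicates` times with per-replicate seeds
#' derived deterministically from `seed`, and aggregates the per-year
#' statistics across replicates (mean and standard deviation over
#' replicates of each per-replicate statistic).
#'
#' @param spec A [scenario_spec()].
#' @param seed Master seed (integer).
#' @return An object of class `scenario_result`: list with `spec`,
#'   `replicates` (list of per-replicate data.frames), `summary`
#'   (per-year data.frame of cross-replicate means and SDs, columns
#'   suffixed `_mean` / `_sd`), and `seed`.
#' @export
run_scenario <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, spec$n_replicates)
  reps <- lapply(rep_seeds, function(s)
    run_replicate(spec$setup, spec$config, seed = s))
  stats_cols <- setdiff(names(reps[[1L]]), c("year", "perf_year"))
  summ <- data.frame(year = reps[[1L]]$year, perf_year = reps[[1L]]$perf_year)
  for (cl in stats_cols) {
    m <- vapply(reps, function(r) r[[cl]], numeric(nrow(summ)))
    summ[[paste0(cl, "_mean")]] <- rowMeans(m)
    summ[[paste0(cl, "_sd")]] <- apply(m, 1L, stats::sd)
  }
  structure(list(spec = spec, replicates = reps, summary = summ, seed = seed),
            class = "scenario_result")
}

#' Run several scenarios
#'
#' @param specs List of [scenario_spec()] objects.
#' @param seed Master seed; each scenario uses a seed derived from it.
#' @return Named list of `scenario_result` objects (names = scenario labels).
#' @export
run_scenarios <- function(specs, seed = 1L) {
  set.seed(seed)
  sc_seeds <- sample.int(.Machine$integer.max, length(specs))
  out <- Map(function(sp, s) run_scenario(sp, seed = s), specs, sc_seeds)
  names(out) <- vapply(specs, function(sp) sp$label, character(1))
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario %s: %d replicates, %d years\n", x$spec$label,
              length(x$replicates), nrow(x$summary)))
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf("  final mean F = %.1f%%, mean P = %.2f\n",
              100 * last$mean_F_mean, last$mean_P_mean))
  invisible(x)
}

#' Standardized endpoint statistics of a scenario
#'
#' Standardizes performance by the analytic initial phenotypic standard
#' deviation (square root of [phenotypic_variance()]) and breeding values by
#' their initial genetic standard deviations, per replicate, then averages
#' over replicates. Returns the endpoint row (last birth year) in the layout
#' of the simulator's final summary tables.
#'
#' @param result A `scenario_result`.
#' @return A one-row data.frame: final-year mean inbreeding in percent
#'   (`F_pct`), standardized performance (`P_std`), standardized direct and
#'   maternal breeding values (`bv_dir_std`, `bv_mat_std`), phenotypic and
#'   genetic variances, and the direct-maternal correlation, each with a
#'   cross-replicate SD column (suffix `_sd`).
#' @export
standardize_endpoint <- function(result) {
  stopifnot(inherits(result, "scenario_result"))
  setup <- result$spec$setup
  nD <- result$spec$config$n_drones_per_queen
  s_p <- sqrt(phenotypic_variance(setup, nD))
  s_dir <- sqrt(setup$var_dir)
  s_mat <- sqrt(setup$var_mat)
  if (s_p == 0 || s_dir == 0 || s_mat == 0)
    stop("standardization requires positive initial variances")
  last <- vapply(result$replicates, function(r) {
    i <- nrow(r)
    c(F_pct = 100 * r$mean_F[i], P_std = r$mean_P[i] / s_p,
      bv_dir_std = r$mean_bv_dir[i] / s_dir,
      bv_mat_std = r$mean_bv_mat[i] / s_mat,
      var_P = r$var_P[i], var_bv_dir = r$var_bv_dir[i],
      var_bv_mat = r$var_bv_mat[i], cor_bv = r$cor_bv[i])
  }, numeric(8L))
  out <- as.data.frame(as.list(rowMeans(last)))
  sds <- apply(last, 1L, stats::sd)
  names(sds) <- paste0(names(sds), "_sd")
  cbind(out, as.data.frame(as.list(sds)),
        data.frame(scenario = result$spec$label,
                   n_replicates = length(result$replicates)))
}

#' Annual rate of increase of mean queen inbreeding
#'
#' Least-squares slope of mean inbreeding (in percent) against year over a
#' window, by default years 7 to the last simulated year, where the
#' trajectory is close to linear.
#'
#' @param x A `scenario_result`, a per-replicate data.frame from
#'   [run_replicate()], or a numeric vector of yearly mean F (proportions)
#'   indexed by year starting at 1.
#' @param from,to Year window (inclusive).
#' @return Slope in percentage points of F per year. For a
#'   `scenario_result` the slope of the cross-replicate mean trajectory is
#'   returned with attributes `replicate_slopes` and `se` (standard error of
#'   the mean of per-replicate slopes).
#' @export
inbreeding_slope <- function(x, from = 7L, to = NULL) {
  slope1 <- function(f_series) {
    yrs <- seq_along(f_series)
    t2 <- if (is.null(to)) max(yrs) else to
    if (from < 1L || t2 > max(yrs) || from >= t2)
      stop("slope window outside the simulated series")
    w <- yrs >= from & yrs <= t2
    unname(stats::coef(stats::lm(I(100 * f_series[w]) ~ yrs[w]))[2L])
  }
  if (inherits(x, "scenario_result")) {
    sl <- slope1(x$summary$mean_F_mean)
    rep_sl <- vapply(x$replicates, function(r) slope1(r$mean_F), numeric(1))
    attr(sl, "replicate_slopes") <- rep_sl
    attr(sl, "se") <- stats::sd(rep_sl) / sqrt(length(rep_sl))
    return(sl)
  }
  if (is.data.frame(x)) return(slope1(x$mean_F))
  slope1(x)
}

#' Write scenario outputs to disk
#'
#' Writes one CSV per scenario with the per-year cross-replicate summary,
#' one CSV with the standardized endpoint rows of all scenarios, and a JSON
#' manifest (labels, seeds, configuration, package version).
#'
#' @param results Named list of `scenario_result` objects (as returned by
#'   [run_scenarios()]), possibly empty.
#' @param path Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_scenario_outputs <- function(results, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in names(results)) {
    f <- file.path(path, paste0(nm, "-trajectory.csv"))
    utils::write.csv(results[[nm]]$summary, f, row.names = FALSE)
    written <- c(written, f)
  }
  if (length(results)) {
    ep <- do.call(rbind, lapply(results, standardize_endpoint))
    f <- file.path(path, "endpoints.csv")
    utils::write.csv(ep, f, row.names = FALSE)
    written <- c(written, f)
  }
  manifest <- list(
    package = "beebreedsim",
    version = as.character(utils::packageVersion("beebreedsim")),
    scenarios = lapply(unname(results), function(r) list(
      label = r$spec$label, seed = r$seed,
      n_replicates = length(r$replicates),
      n_drones = r$spec$config$n_drones_per_queen,
      selection_strategy = r$spec$config$selection_strategy,
      years = r$spec$config$total_years,
      var_dir = r$spec$setup$var_dir, var_mat = r$spec$setup$var_mat,
      corr_dir_mat = r$spec$setup$corr_dir_mat,
      var_residual = r$spec$setup$var_residual))
  )
  f <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  written <- c(written, f)
  invisible(written)
}
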