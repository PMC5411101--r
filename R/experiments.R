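# Figure-level experiments: sweeps over TF or competitor copy number,
# master-curve collapse reports, and JSON configuration loading.

sweep_row <- function(model, engine, n_cells, burn_in, seed, m_max, tol,
                      n_boot, want_pmf = FALSE) {
  if (engine == "cme") {
    sol <- cme_steady_state(model, m_max = m_max, tol = tol)
    mom <- cme_moments(sol)
    row <- data.frame(mean = mom$mean, variance = mom$variance,
                      fano = mom$fano, fold_change = mom$fold_change,
                      se_mean = NA_real_, se_variance = NA_real_,
                      n_cells = NA_integer_)
    pmf <- if (want_pmf) mrna_pmf(sol)
  } else {
    pop <- sample_population(model, n_cells = n_cells, burn_in = burn_in,
                             seed = seed)
    row <- population_moments(pop, n_boot = n_boot, seed = seed)
    pmf <- if (want_pmf) {
      tab <- tabulate(pop$states$m + 1L)
      setNames(tab / sum(tab), seq_along(tab) - 1L)
    }
  }
  list(row = row, pmf = pmf)
}

#' Sweep summary statistics over the TF copy number
#'
#' Recomputes the steady-state mRNA summary for each TF copy number in
#' `ntf_values`, holding all other parameters at the template's values. With
#' `engine = "cme"` the moments are exact (solver truncation error only); with
#' `engine = "ssa"` they are population estimates with bootstrap standard
#' errors.
#'
#' @param model Template [tf_model()]; its `n_tf` is overridden per row.
#' @param ntf_values Strictly increasing non-negative TF copy numbers.
#' @param engine `"cme"` or `"ssa"`.
#' @param n_cells,burn_in SSA population settings (see [sample_population()]).
#' @param seed Master seed; row i uses `seed + i - 1` for its replicates.
#' @param m_max,tol CME truncation settings (see [cme_steady_state()]).
#' @param n_boot Bootstrap resamples for SSA standard errors.
#' @return Data frame (class `tf_sweep`) with one row per swept value:
#'   `n_tf`, `n_promoters`, `n_competitors`, `mode`, `mean`, `variance`,
#'   `fano`, `fold_change`, `se_mean`, `se_variance`, `n_cells`, `seed`.
#' @export
#' @examples
#' m <- do.call(tf_model, c(list(n_tf = 1, n_promoters = 2), ecoli_rates()))
#' sweep_tf(m, c(1, 2, 4), engine = "cme")
sweep_tf <- function(model, ntf_values, engine = c("cme", "ssa"),
                     n_cells = 10000, burn_in = NULL, seed = 1,
                     m_max = NULL, tol = 1e-8, n_boot = 1000) {
  stopifnot(inherits(model, "tf_model"))
  engine <- match.arg(engine)
  check_swept(ntf_values, "ntf_values")
  rows <- lapply(seq_along(ntf_values), function(i) {
    mi <- model; mi$n_tf <- as.integer(ntf_values[i])
    out <- sweep_row(mi, engine, n_cells, burn_in, seed + i - 1, m_max, tol,
                     n_boot)$row
    cbind(data.frame(n_tf = mi$n_tf, n_promoters = mi$n_promoters,
                     n_competitors = mi$n_competitors, mode = mi$mode),
          out, seed = seed + i - 1)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tf_sweep", "data.frame")
  out
}

#' Sweep over the number of competitor sites
#'
#' Like [sweep_tf()] but varying `n_competitors` at fixed TF copy number, and
#' additionally returning the full mRNA pmf and its [count_modes()] report for
#' every swept value (the multimodality scan).
#'
#' @inheritParams sweep_tf
#' @param nc_values Strictly increasing non-negative competitor-site counts.
#' @param smoothing_window,prominence Mode-detection settings
#'   (see [count_modes()]).
#' @return List of class `tf_nc_sweep`: `table` (as in [sweep_tf()], keyed by
#'   `n_competitors`, plus `n_modes`), `pmfs` (named list of pmf vectors),
#'   `modes` (named list of `mode_report`s).
#' @export
sweep_competitors <- function(model, nc_values, engine = c("cme", "ssa"),
                              n_cells = 10000, burn_in = NULL, seed = 1,
                              m_max = NULL, tol = 1e-8, n_boot = 1000,
                              smoothing_window = 5L, prominence = 0.05) {
  stopifnot(inherits(model, "tf_model"))
  engine <- match.arg(engine)
  check_swept(nc_values, "nc_values")
  pmfs <- list(); modes <- list()
  rows <- lapply(seq_along(nc_values), function(i) {
    mi <- model; mi$n_competitors <- as.integer(nc_values[i])
    res <- sweep_row(mi, engine, n_cells, burn_in, seed + i - 1, m_max, tol,
                     n_boot, want_pmf = TRUE)
    key <- as.character(mi$n_competitors)
    pmfs[[key]] <<- res$pmf
    modes[[key]] <<- count_modes(res$pmf / sum(res$pmf),
                                 smoothing_window = smoothing_window,
                                 prominence = prominence)
    cbind(data.frame(n_competitors = mi$n_competitors, n_tf = mi$n_tf,
                     n_promoters = mi$n_promoters, mode = mi$mode),
          res$row, n_modes = modes[[key]]$n_modes, seed = seed + i - 1)
  })
  structure(list(table = do.call(rbind, rows), pmfs = pmfs, modes = modes),
            class = "tf_nc_sweep")
}

#' @export
print.tf_nc_sweep <- function(x, ...) {
  print(x$table)
  invisible(x)
}

check_swept <- function(x, name) {
  if (length(x) == 0 || any(x < 0) || any(x != round(x)) ||
      any(diff(x) <= 0) && length(x) > 1)
    stop(sprintf("'%s' must be non-empty, non-negative, strictly increasing",
                 name), call. = FALSE)
}

#' Residuals of (mean, variance) points against the master curve
#'
#' For each per-promoter point, the relative deviation of the observed
#' variance per promoter from the [master_curve_variance()] prediction at its
#' mean per promoter:
#' `residual = |var/N_P - curve(mean/N_P)| / max(curve(mean/N_P), eps)`.
#'
#' @param points Data frame with columns `n_promoters`, `mean`, `variance`
#'   (totals over all promoter copies).
#' @param r,gamma,k_off Promoter rates defining the curve.
#' @param mode `"activator"` or `"repressor"`.
#' @param eps Floor for the denominator.
#' @return Object of class `collapse_report`: `points` (input plus
#'   `mean_per_promoter`, `var_per_promoter`, `predicted`, `residual`) and
#'   `max_residual`.
#' @export
collapse_residuals <- function(points, r, gamma, k_off,
                               mode = c("activator", "repressor"),
                               eps = 1e-9) {
  mode <- match.arg(mode)
  if (!is.data.frame(points) || nrow(points) == 0)
    stop("'points' must be a non-empty data frame", call. = FALSE)
  need <- c("n_promoters", "mean", "variance")
  if (!all(need %in% names(points)))
    stop("'points' needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  mpp <- points$mean / points$n_promoters
  vpp <- points$variance / points$n_promoters
  pred <- master_curve_variance(mpp, r, gamma, k_off, mode)
  resid <- abs(vpp - pred) / pmax(pred, eps)
  out <- cbind(points, mean_per_promoter = mpp, var_per_promoter = vpp,
               predicted = pred, residual = resid)
  structure(list(points = out, max_residual = max(resid), mode = mode),
            class = "collapse_report")
}

#' @export
print.collapse_report <- function(x, ...) {
  cat(sprintf("master-curve collapse (%s): %d points, max relative residual %.3g\n",
              x$mode, nrow(x$points), x$max_residual))
  invisible(x)
}

# simulation-setting keys accepted in configs alongside the model fields
.setting_fields <- c("engine", "n_cells", "burn_in", "t_end", "seed", "m_max",
                     "tol", "smoothing_window", "prominence")

.default_settings <- function() {
  list(engine = "cme", n_cells = 10000L, burn_in = NULL, t_end = 10000,
       seed = 1L, m_max = NULL, tol = 1e-8, smoothing_window = 5L,
       prominence = 0.05)
}

#' Load a model plus simulation settings from a JSON config
#'
#' The config is a flat JSON object mixing [tf_model()] fields with the
#' simulation settings `engine`, `n_cells`, `burn_in`, `t_end`, `seed`,
#' `m_max`, `tol`, `smoothing_window`, `prominence`. Unknown keys are
#' rejected; missing settings get defaults.
#'
#' @param path Path to the JSON file.
#' @return List with elements `model` (a validated `tf_model`) and `settings`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), c(.model_fields, .setting_fields))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  model <- do.call(tf_model, raw[intersect(names(raw), .model_fields)])
  settings <- modifyList(.default_settings(),
                         raw[intersect(names(raw), .setting_fields)])
  list(model = model, settings = settings)
}
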