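#' Simulate one exact stochastic trajectory
#'
#' Samples a path of the continuous-time Markov chain defined by
#' [propensities()] with the Gillespie direct method. The default initial
#' condition is all promoters and competitor sites free and no mRNA. With
#' `recording = "events"` every reaction event is recorded; with
#' `recording = "grid"` the state is sampled on a fixed grid of spacing `dt`.
#' Identical `(model, t_end, seed, recording)` give a bit-identical trajectory.
#'
#' @param model A [tf_model()].
#' @param t_end End time in seconds (>= 0).
#' @param seed Integer master seed.
#' @param recording `"events"` or `"grid"`.
#' @param dt Grid spacing in seconds (grid mode only).
#' @param init Optional [tf_state()] to start from.
#' @return Object of class `tf_trajectory`: list with `records` (data frame
#'   with columns `time`, `s_1..s_NP`, `c`, `m_1..m_NP`, `n`, `m`), `model`,
#'   `seed`, `recording`.
#' @export
#' @examples
#' m <- do.call(tf_model, c(list(n_tf = 1), ecoli_rates()))
#' tr <- simulate_trajectory(m, t_end = 2000, seed = 1)
#' head(tr$records)
simulate_trajectory <- function(model, t_end, seed,
                                recording = c("events", "grid"), dt = 60,
                                init = NULL) {
  stopifnot(inherits(model, "tf_model"))
  recording <- match.arg(recording)
  if (!is.numeric(t_end) || length(t_end) != 1L || is.na(t_end) || t_end < 0)
    stop("'t_end' must be a single non-negative time (s)", call. = FALSE)
  if (recording == "grid" && (!is.numeric(dt) || dt <= 0))
    stop("'dt' must be a positive grid spacing (s)", call. = FALSE)
  init <- init %||% tf_state(model)
  stopifnot(inherits(init, "tf_state"))
  mat <- .ssa_trajectory_cpp(unclass(model), t_end, as.double(seed),
                             if (recording == "events") 0L else 1L, dt,
                             init$occupancy, init$c, init$mrna)
  np <- model$n_promoters
  colnames(mat) <- c("time", paste0("s_", seq_len(np)), "c",
                     paste0("m_", seq_len(np)))
  rec <- as.data.frame(mat)
  rec$n <- rowSums(rec[, paste0("s_", seq_len(np)), drop = FALSE])
  rec$m <- rowSums(rec[, paste0("m_", seq_len(np)), drop = FALSE])
  structure(list(records = rec, model = model, seed = seed,
                 recording = recording),
            class = "tf_trajectory")
}

#' @export
print.tf_trajectory <- function(x, ...) {
  cat(sprintf("SSA trajectory: %d records (%s), t in [0, %g] s, seed %s\n",
              nrow(x$records), x$recording, max(x$records$time), format(x$seed)))
  invisible(x)
}

#' Steady-state snapshot across an isogenic population
#'
#' Runs `n_cells` independent replicates of the model, each on its own
#' deterministically derived random stream, and records every replicate's
#' state at `t = burn_in`. This emulates sampling mRNA copy numbers across a
#' population of genetically identical cells at stationarity.
#'
#' @inheritParams simulate_trajectory
#' @param n_cells Number of independent replicates (>= 0).
#' @param burn_in Simulated time (s) before the snapshot; defaults to
#'   `10 / gamma`, about ten mRNA lifetimes. A warning is issued below that.
#' @return Object of class `tf_population`: list with `states` (data frame
#'   with columns `replicate`, `s_*`, `c`, `m_*`, `n`, `m`), `model`,
#'   `n_cells`, `burn_in`, `seed`.
#' @export
#' @examples
#' m <- do.call(tf_model, c(list(n_tf = 1), ecoli_rates()))
#' pop <- sample_population(m, n_cells = 200, seed = 1)
#' mean(pop$states$m)
sample_population <- function(model, n_cells, burn_in = NULL, seed,
                              init = NULL) {
  stopifnot(inherits(model, "tf_model"))
  if (!is.numeric(n_cells) || n_cells < 0 || n_cells != round(n_cells))
    stop("'n_cells' must be a non-negative integer", call. = FALSE)
  burn_in <- burn_in %||% (10 / model$gamma)
  if (burn_in < 10 / model$gamma)
    warning("burn_in shorter than 10/gamma; the snapshot may not be stationary")
  init <- init %||% tf_state(model)
  np <- model$n_promoters
  mat <- .ssa_population_cpp(unclass(model), as.integer(n_cells), burn_in,
                             as.double(seed), init$occupancy, init$c, init$mrna)
  colnames(mat) <- c(paste0("s_", seq_len(np)), "c", paste0("m_", seq_len(np)))
  st <- as.data.frame(mat)
  st <- cbind(replicate = seq_len(nrow(st)), st)
  st$n <- rowSums(st[, paste0("s_", seq_len(np)), drop = FALSE])
  st$m <- rowSums(st[, paste0("m_", seq_len(np)), drop = FALSE])
  structure(list(states = st, model = model, n_cells = as.integer(n_cells),
                 burn_in = burn_in, seed = seed),
            class = "tf_population")
}

#' @export
print.tf_population <- function(x, ...) {
  cat(sprintf("population sample: %d cells at t = %g s (seed %s)\n",
              x$n_cells, x$burn_in, format(x$seed)))
  if (x$n_cells > 0)
    cat(sprintf("  mRNA: mean %.3f, var %.3f, Fano %.3f\n",
                mean(x$states$m), var(x$states$m),
                fano(mean(x$states$m), var(x$states$m))))
  invisible(x)
}

#' @rdname sample_population
#' @param object A [tf_model()].
#' @param nsim Number of replicate cells.
#' @param ... Passed on to [sample_population()] (e.g. `burn_in`).
#' @export
simulate.tf_model <- function(object, nsim = 1, seed = 1, ...) {
  sample_population(object, n_cells = nsim, seed = seed, ...)
}

#' Summary statistics of a population's total mRNA count
#'
#' Mean, variance, Fano factor and fold change of the total mRNA copy number
#' across replicates, with bootstrap standard errors for mean and variance.
#'
#' @param pop A [sample_population()] result.
#' @param n_boot Bootstrap resamples for the standard errors (0 to skip).
#' @param seed Seed for the bootstrap resampling.
#' @return One-row data frame: `mean`, `variance`, `fano`, `fold_change`,
#'   `se_mean`, `se_variance`, `n_cells`.
#' @export
population_moments <- function(pop, n_boot = 1000, seed = 1) {
  stopifnot(inherits(pop, "tf_population"))
  m <- pop$states$m
  mu <- mean(m); v <- var(m)
  se <- c(NA_real_, NA_real_)
  if (n_boot > 0 && length(m) > 1) {
    se <- with_seed(seed, {
      bs <- replicate(n_boot, {
        x <- m[sample.int(length(m), replace = TRUE)]
        c(mean(x), var(x))
      })
      apply(bs, 1, stats::sd)
    })
  }
  data.frame(mean = mu, variance = v, fano = fano(mu, v),
             fold_change = fold_change(mu, pop$model),
             se_mean = se[1], se_variance = se[2], n_cells = pop$n_cells)
}

#' Write a trajectory or population sample to disk
#'
#' The trajectory is written as TSV (columns `time`, `n`, `c`, `m`, plus the
#' per-promoter `s_i`, `m_i`), the population as CSV (columns `replicate`,
#' `n`, `c`, `m`, `m_i`). A JSON sidecar `<path>.json` carries the model,
#' seed and sampling settings for provenance.
#'
#' @param x A `tf_trajectory` or `tf_population`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ssa <- function(x, path) {
  if (inherits(x, "tf_trajectory")) {
    np <- x$model$n_promoters
    cols <- c("time", "n", "c", "m", paste0("s_", seq_len(np)),
              paste0("m_", seq_len(np)))
    utils::write.table(x$records[, cols], path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    side <- list(model = unclass(x$model)[.model_fields], seed = x$seed,
                 recording = x$recording)
  } else if (inherits(x, "tf_population")) {
    np <- x$model$n_promoters
    cols <- c("replicate", "n", "c", "m", paste0("m_", seq_len(np)))
    utils::write.csv(x$states[, cols], path, row.names = FALSE, quote = FALSE)
    side <- list(model = unclass(x$model)[.model_fields], seed = x$seed,
                 n_cells = x$n_cells, burn_in = x$burn_in)
  } else stop("'x' must be a tf_trajectory or tf_population", call. = FALSE)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
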