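# Closed-form moments for one promoter, the variance-versus-mean master
# curves, a second-order moment-closure approximation for multiple promoters,
# and distribution summaries (Fano factor, fold change, mode counting,
# sample correlation).

#' Exact telegraph-model mRNA moments for a single promoter
#'
#' Closed-form steady-state mean and variance for one promoter with no
#' competitor sites and zero basal rate (the regime where the expressions are
#' exact). With `q = k_on N_TF` and `b = r / gamma`:
#' activator `<m> = b q / (q + k_off)`,
#' `Fano = 1 + k_off r / ((q + k_off)(gamma + q + k_off))`;
#' repressor `<m> = b k_off / (q + k_off)`,
#' `Fano = 1 + q r / ((q + k_off)(gamma + q + k_off))`.
#'
#' @param model A [tf_model()] with `n_promoters = 1`, `n_competitors = 0`,
#'   `r_basal = 0`.
#' @return List with `mean`, `variance`, `fano`, `fold_change`.
#' @export
#' @examples
#' m <- do.call(tf_model, c(list(n_tf = 1), ecoli_rates()))
#' analytic_moments(m)   # mean 16.2, variance 169.8975
analytic_moments <- function(model) {
  stopifnot(inherits(model, "tf_model"))
  if (model$n_promoters != 1L || model$n_competitors != 0L ||
      model$r_basal != 0)
    stop("analytic_moments is exact only for n_promoters = 1, ",
         "n_competitors = 0, r_basal = 0", call. = FALSE)
  q <- model$k_on * model$n_tf
  koff <- model$k_off
  b <- model$r / model$gamma
  if (q + koff == 0)  # no binding kinetics at all: promoter frozen unbound
    return(frozen_moments(model))
  p_on <- if (model$mode == "activator") q / (q + koff) else koff / (q + koff)
  mu <- b * p_on
  burst <- if (model$mode == "activator") koff else q
  f <- 1 + burst * model$r / ((q + koff) * (model$gamma + q + koff))
  list(mean = mu, variance = mu * f, fano = if (mu > 0) f else NaN,
       fold_change = fold_change(mu, model))
}

frozen_moments <- function(model) {
  mu <- if (model$mode == "repressor") model$r / model$gamma else 0
  list(mean = mu, variance = mu, fano = if (mu > 0) 1 else NaN,
       fold_change = fold_change(mu, model))
}

#' Master curve: variance as a function of the mean
#'
#' The single-promoter variance-versus-mean relation obtained by eliminating
#' the effective binding rate `k_on N_TF` between the closed-form mean and
#' variance. With `b = r / gamma`:
#' activator `var = m + m (b - m)^2 gamma / (gamma (b - m) + b k_off)`;
#' repressor `var = m + m^2 (b - m) gamma / (gamma m + b k_off)`.
#' By construction the curve does not involve the binding rate, the TF copy
#' number, or the number/strength of competitor sites.
#'
#' @param mean Mean mRNA count(s), in `[0, r/gamma]`.
#' @param r,gamma,k_off Kinetic rates (s^-1).
#' @param mode `"activator"` or `"repressor"`.
#' @return Predicted variance(s).
#' @export
#' @examples
#' rates <- ecoli_rates()
#' master_curve_variance(16.2, rates$r, rates$gamma, rates$k_off, "activator")
master_curve_variance <- function(mean, r, gamma, k_off,
                                  mode = c("activator", "repressor")) {
  mode <- match.arg(mode)
  b <- r / gamma
  if (any(mean < -1e-12 | mean > b * (1 + 1e-12)))
    stop("'mean' must lie in [0, r/gamma]", call. = FALSE)
  mean <- pmin(pmax(mean, 0), b)
  if (mode == "activator")
    mean + mean * (b - mean)^2 * gamma / (gamma * (b - mean) + b * k_off)
  else
    mean + mean^2 * (b - mean) * gamma / (gamma * mean + b * k_off)
}

#' Fold change of mean expression
#'
#' Mean mRNA count divided by its maximum `N_P r / gamma` (the fully active
#' limit). The denominator keeps `r`, not `r_basal`, also for leaky
#' activators.
#'
#' @param mean Mean mRNA count(s) (>= 0).
#' @param model A [tf_model()].
#' @return Fold change in `[0, ~1]`.
#' @export
fold_change <- function(mean, model) {
  stopifnot(inherits(model, "tf_model"))
  if (any(mean < 0)) stop("'mean' must be non-negative", call. = FALSE)
  mean / (model$n_promoters * model$r / model$gamma)
}

#' Fano factor
#'
#' `variance / mean`; `NaN` for zero mean (undefined, returned rather than
#' raised so sweep tables can hold it).
#'
#' @param mean,variance Moments of a count distribution.
#' @return Dimensionless Fano factor (1 for Poisson).
#' @export
fano <- function(mean, variance) {
  ifelse(mean > 0, variance / mean, NaN)
}

#' Approximate mRNA moments by second-order moment closure
#'
#' For multiple promoters sharing TFs (no competitor sites) the moment
#' hierarchy of the master equation does not close: the equation for the
#' occupancy-mRNA cross moment `<n m>` involves `<n^2 m>`. This routine closes
#' it at second order by projecting `n^2` onto `n` (third-order joint
#' structure beyond the linear regression is dropped):
#' `<n^2 m> ~ <n^2><m> + beta cov(n, m)` with
#' `beta = cov(n^2, n) / var(n)`. Occupancy-marginal moments are taken from
#' the exact finite birth-death binding chain. The closure is exact for
#' `n_promoters = 1` (where `n^2 = n`) and reproduces the closed-form
#' single-promoter results; for more promoters the variance carries a
#' systematic approximation error.
#'
#' @param model A [tf_model()] with `n_competitors = 0`.
#' @return List with `mean`, `variance`, `fano`, `fold_change`.
#' @export
closure_moments <- function(model) {
  stopifnot(inherits(model, "tf_model"))
  if (model$n_competitors != 0L)
    stop("closure_moments is implemented for n_competitors = 0", call. = FALSE)
  NP <- model$n_promoters; NT <- model$n_tf
  kon <- model$k_on; koff <- model$k_off; g <- model$gamma
  # exact occupancy moments from the stationary birth-death chain in n
  occ <- occupancy_distribution(model)
  nv <- occ$n; pn <- occ$probability
  mu1 <- sum(nv * pn)
  mu2 <- sum(nv^2 * pn)
  mu3 <- sum(nv^3 * pn)
  # transcription propensity T(n) = t0 + t1 n
  if (model$mode == "activator") {
    t0 <- model$r_basal * NP; t1 <- model$r - model$r_basal
  } else {
    t0 <- model$r * NP; t1 <- -model$r
  }
  mean_m <- (t0 + t1 * mu1) / g
  var_n <- mu2 - mu1^2
  if (var_n <= .Machine$double.eps) {      # frozen occupancy: Poisson mRNA
    return(list(mean = mean_m, variance = mean_m,
                fano = fano(mean_m, mean_m),
                fold_change = fold_change(mean_m, model)))
  }
  beta <- (mu3 - mu2 * mu1) / var_n
  # steady state of d<nm>/dt = 0:
  #   kon(NT NP <m> - (NT+NP)<nm> + <n^2 m>) - koff<nm> + <n T(n)> - g<nm> = 0
  # with <n^2 m> = mu2 <m> + beta (<nm> - mu1 <m>)
  nTn <- t0 * mu1 + t1 * mu2
  coef_nm <- kon * ((NT + NP) - beta) + koff + g
  const <- kon * (NT * NP + mu2 - beta * mu1) * mean_m + nTn
  nm <- const / coef_nm
  # d<m^2>/dt = 0: 2<T(n) m> + <T(n)> + g<m> - 2g<m^2> = 0
  Tm <- t0 * mean_m + t1 * nm
  m2 <- (2 * Tm + (t0 + t1 * mu1) + g * mean_m) / (2 * g)
  v <- m2 - mean_m^2
  list(mean = mean_m, variance = v, fano = fano(mean_m, v),
       fold_change = fold_change(mean_m, model))
}

#' Count modes of an mRNA copy-number distribution
#'
#' Smooths the integer-support pmf with a centered moving average (partial
#' windows at the edges) and reports local maxima — including boundary maxima,
#' so a peak at m = 0 counts — whose topographic prominence is at least
#' `prominence` times the highest smoothed value. Plateaus are merged to a
#' single mode at their leftmost index.
#'
#' @param pmf Probabilities on integer support `0:(length(pmf)-1)` (or named
#'   by their counts); must sum to 1 within 1e-6.
#' @param smoothing_window Moving-average window (default 5; rounded up to
#'   odd).
#' @param prominence Minimum prominence as a fraction of the highest smoothed
#'   probability (default 0.05).
#' @return Object of class `mode_report`: list with `n_modes`,
#'   `mode_locations` (mRNA counts, ascending), `mode_heights` (smoothed
#'   probabilities), `smoothing_window`, `prominence_threshold`.
#' @export
#' @examples
#' count_modes(dpois(0:100, 30))                     # one mode near 30
#' count_modes(0.5 * dpois(0:120, 30) + 0.5 * dpois(0:120, 60))
count_modes <- function(pmf, smoothing_window = 5L, prominence = 0.05) {
  supp <- if (!is.null(names(pmf))) as.numeric(names(pmf)) else
    seq_along(pmf) - 1
  pmf <- as.numeric(pmf)
  if (length(pmf) == 0 || any(pmf < -1e-12))
    stop("'pmf' must be a non-empty non-negative vector", call. = FALSE)
  if (abs(sum(pmf) - 1) > 1e-6)
    stop("'pmf' must be normalized (sums to 1 within 1e-6)", call. = FALSE)
  w <- max(1L, as.integer(smoothing_window))
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  n <- length(pmf)
  smooth <- vapply(seq_len(n), function(i) {
    j <- max(1L, i - h):min(n, i + h)
    mean(pmf[j])
  }, numeric(1))

  # local maxima with plateau merging (leftmost index of each plateau)
  peaks <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && smooth[j + 1L] == smooth[i]) j <- j + 1L
    left_ok <- i == 1L || smooth[i - 1L] < smooth[i]
    right_ok <- j == n || smooth[j + 1L] < smooth[i]
    if (left_ok && right_ok && smooth[i] > 0) peaks <- c(peaks, i)
    i <- j + 1L
  }
  # topographic prominence: drop from the peak to the highest saddle that
  # separates it from higher ground; a side with no higher ground does not
  # constrain, and the global maximum keeps its full height as prominence
  prom <- vapply(peaks, function(p) {
    ls <- if (p > 1L) smooth[1:(p - 1L)] else numeric(0)
    hl <- which(ls > smooth[p])
    key_l <- if (length(hl)) min(ls[max(hl):(p - 1L)]) else NA_real_
    rs <- if (p < n) smooth[(p + 1L):n] else numeric(0)
    hr <- which(rs > smooth[p])
    key_r <- if (length(hr)) min(rs[1:min(hr)]) else NA_real_
    sdl <- c(key_l, key_r)
    sdl <- sdl[!is.na(sdl)]
    smooth[p] - if (length(sdl)) max(sdl) else 0
  }, numeric(1))
  keep <- prom >= prominence * max(smooth)
  if (!any(keep)) keep[which.max(smooth[peaks])] <- TRUE  # global mode stays
  peaks <- peaks[keep]
  structure(list(n_modes = length(peaks), mode_locations = supp[peaks],
                 mode_heights = smooth[peaks], smoothing_window = w,
                 prominence_threshold = prominence),
            class = "mode_report")
}

#' @export
print.mode_report <- function(x, ...) {
  cat(sprintf("%d mode(s) at m = %s (window %d, prominence >= %.3g of max)\n",
              x$n_modes, paste(x$mode_locations, collapse = ", "),
              x$smoothing_window, x$prominence_threshold))
  invisible(x)
}

#' Sample Pearson correlation between two promoters' mRNA counts
#'
#' @param pop A [sample_population()] result from a two-promoter model with at
#'   least two replicates.
#' @return Pearson correlation of `(m_1, m_2)` across replicates; `NaN` when
#'   either pool has zero variance.
#' @export
promoter_correlation <- function(pop) {
  stopifnot(inherits(pop, "tf_population"))
  if (pop$model$n_promoters != 2L)
    stop("promoter_correlation requires n_promoters = 2", call. = FALSE)
  if (pop$n_cells < 2L)
    stop("need at least two replicates", call. = FALSE)
  m1 <- pop$states$m_1; m2 <- pop$states$m_2
  if (var(m1) == 0 || var(m2) == 0) return(NaN)
  cor(m1, m2)
}
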