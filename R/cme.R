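# Exact steady-state solvers: the finite TF-binding chain, the truncated
# chemical master equation over (n, c, m), and Markov-modulated moment systems
# that give truncation-free mRNA moments and the two-promoter correlation.

# Reachable aggregate occupancy pairs (n bound promoters, c bound competitors).
occ_pairs <- function(model) {
  out <- do.call(rbind, lapply(0:min(model$n_promoters, model$n_tf), function(n) {
    cmax <- min(model$n_competitors, model$n_tf - n)
    data.frame(n = n, c = 0:cmax)
  }))
  out[order(out$n, out$c), , drop = FALSE]
}

# Dense generator of the aggregate (n, c) binding chain; Q[i, j] = rate i -> j.
occ_generator <- function(model, pairs) {
  K <- nrow(pairs)
  idx <- function(n, c) which(pairs$n == n & pairs$c == c)
  Q <- matrix(0, K, K)
  for (i in seq_len(K)) {
    n <- pairs$n[i]; c_ <- pairs$c[i]
    f <- model$n_tf - n - c_
    if (n < model$n_promoters && f > 0)
      Q[i, idx(n + 1, c_)] <- model$k_on * f * (model$n_promoters - n)
    if (n > 0) Q[i, idx(n - 1, c_)] <- model$k_off * n
    if (c_ < model$n_competitors && f > 0)
      Q[i, idx(n, c_ + 1)] <- model$k_on_c * f * (model$n_competitors - c_)
    if (c_ > 0) Q[i, idx(n, c_ - 1)] <- model$k_off_c * c_
  }
  diag(Q) <- -rowSums(Q)
  Q
}

stationary_of <- function(Q) {
  K <- nrow(Q)
  A <- t(Q)
  A[K, ] <- 1
  b <- numeric(K); b[K] <- 1
  solve(A, b)
}

#' Stationary distribution of the TF-binding subsystem
#'
#' Exact steady-state joint law of (bound promoters `n`, bound competitor
#' sites `c`), which is independent of the mRNA dynamics (transcription does
#' not feed back on binding). Computed by solving the stationary linear system
#' of the finite chain and cross-checked against the closed-form
#' detailed-balance (product-form) weights
#' `P(n, c) propto C(N_P, n) C(N_C, c) N_TF! / (N_TF - n - c)! *
#' (k_on/k_off)^n (k_on_c/k_off_c)^c`; the two routes must agree to 1e-10.
#'
#' @param model A [tf_model()].
#' @return Object of class `tf_occupancy`: data frame with columns `n`, `c`,
#'   `probability`, plus attribute `product_form` holding the closed-form
#'   probabilities.
#' @export
occupancy_distribution <- function(model) {
  stopifnot(inherits(model, "tf_model"))
  if (model$k_off == 0 && model$k_on > 0 && model$n_tf > 0)
    warning("k_off = 0: promoter binding is absorbing; ",
            "the distribution degenerates to maximal occupancy")
  pairs <- occ_pairs(model)
  p_lin <- stationary_of(occ_generator(model, pairs))
  p_pf <- product_form_occupancy(model, pairs)
  if (!is.null(p_pf) && max(abs(p_lin - p_pf)) > 1e-10)
    stop("internal check failed: linear-solve and product-form stationary ",
         "distributions disagree", call. = FALSE)
  out <- cbind(pairs, probability = p_lin)
  attr(out, "product_form") <- p_pf
  class(out) <- c("tf_occupancy", "data.frame")
  out
}

# Closed-form equilibrium weights of the reversible binding chain (log space).
# Returns NULL when an unbinding rate is zero (degenerate equilibrium).
product_form_occupancy <- function(model, pairs = occ_pairs(model)) {
  if ((model$k_off == 0 && model$k_on > 0 && model$n_tf > 0) ||
      (model$k_off_c == 0 && model$k_on_c > 0 && model$n_competitors > 0 &&
       model$n_tf > 0))
    return(NULL)
  lratio <- function(num, den, count) {
    # count * log(num/den) with the convention 0 * log(0) = 0
    out <- ifelse(count == 0, 0, count * (log(num) - log(den)))
    out[count > 0 & num == 0] <- -Inf
    out
  }
  lw <- lchoose(model$n_promoters, pairs$n) +
    lchoose(model$n_competitors, pairs$c) +
    lfactorial(model$n_tf) - lfactorial(model$n_tf - pairs$n - pairs$c) +
    lratio(model$k_on, model$k_off, pairs$n) +
    lratio(model$k_on_c, model$k_off_c, pairs$c)
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Exact steady state of the truncated chemical master equation
#'
#' Solves the stationary linear system of the full generator on the aggregate
#' `(n, c, m)` lattice with the mRNA count truncated at `m_max` (transcription
#' is dropped at the boundary, so the truncated chain is a proper generator).
#' Aggregate transcription propensity is `r*n + r_basal*(N_P - n)` for
#' activators and `r*(N_P - n)` for repressors; decay is `gamma m`. The
#' truncation is enlarged (doubling `m_max`) until the probability mass at the
#' boundary is below `tol`.
#'
#' @param model A [tf_model()].
#' @param m_max Initial mRNA truncation; default
#'   `ceil(N_P r / gamma + 10 sqrt(N_P r / gamma))`.
#' @param tol Acceptable probability mass at the truncation boundary.
#' @param max_doublings Retries before giving up with a truncation error.
#' @return Object of class `tf_cme`: list with `prob` (matrix, rows = occupancy
#'   pairs, columns = m = 0..m_max), `pairs`, `m_max`, `tail_mass`, `model`.
#' @seealso [mrna_pmf()], [cme_moments()], [occupancy_marginal()]
#' @export
#' @examples
#' m <- do.call(tf_model, c(list(n_tf = 1), ecoli_rates()))
#' sol <- cme_steady_state(m)
#' cme_moments(sol)
cme_steady_state <- function(model, m_max = NULL, tol = 1e-8,
                             max_doublings = 8L) {
  stopifnot(inherits(model, "tf_model"))
  b <- model$n_promoters * max(model$r, model$r_basal) / model$gamma
  m_max <- m_max %||% ceiling(b + 10 * sqrt(b + 1))
  if (m_max < 1) stop("'m_max' must be >= 1", call. = FALSE)
  for (try in 0:max_doublings) {
    sol <- cme_solve_once(model, as.integer(m_max))
    if (sol$tail_mass < tol) return(sol)
    m_max <- 2L * m_max
  }
  stop(sprintf(
    "m_max insufficient: tail mass %.3e above tol %.1e after %d doublings",
    sol$tail_mass, tol, max_doublings), call. = FALSE)
}

cme_solve_once <- function(model, m_max) {
  pairs <- occ_pairs(model)
  K <- nrow(pairs)
  M <- m_max + 1L
  nstate <- K * M
  gidx <- function(p, m) (p - 1L) * M + m + 1L   # m is a 0-based count
  pair_id <- function(n, c) match(paste(n, c), paste(pairs$n, pairs$c))
  f <- model$n_tf - pairs$n - pairs$c
  trans <- if (model$mode == "activator")
    model$r * pairs$n + model$r_basal * (model$n_promoters - pairs$n)
  else model$r * (model$n_promoters - pairs$n)

  from <- to <- integer(0); rate <- numeric(0)
  add_pair_jump <- function(p, p2, rt) {
    if (is.na(p2) || rt <= 0) return()
    from <<- c(from, gidx(p, 0:m_max))
    to <<- c(to, gidx(p2, 0:m_max))
    rate <<- c(rate, rep(rt, M))
  }
  for (p in seq_len(K)) {
    n <- pairs$n[p]; c_ <- pairs$c[p]
    add_pair_jump(p, pair_id(n + 1, c_),
                  model$k_on * f[p] * (model$n_promoters - n))
    add_pair_jump(p, pair_id(n - 1, c_), model$k_off * n)
    add_pair_jump(p, pair_id(n, c_ + 1),
                  model$k_on_c * f[p] * (model$n_competitors - c_))
    add_pair_jump(p, pair_id(n, c_ - 1), model$k_off_c * c_)
    if (trans[p] > 0) {         # m -> m + 1, reflecting at m_max
      from <- c(from, gidx(p, 0:(m_max - 1)))
      to <- c(to, gidx(p, 1:m_max))
      rate <- c(rate, rep(trans[p], m_max))
    }
    from <- c(from, gidx(p, 1:m_max))   # decay m -> m - 1
    to <- c(to, gidx(p, 0:(m_max - 1)))
    rate <- c(rate, model$gamma * (1:m_max))
  }
  # dP/dt = A P with A[to, from] = rate and diagonal outflow
  A <- Matrix::sparseMatrix(i = to, j = from, x = rate,
                            dims = c(nstate, nstate))
  A <- A - Matrix::Diagonal(x = Matrix::colSums(A))
  A[nstate, ] <- 1
  rhs <- numeric(nstate); rhs[nstate] <- 1
  P <- as.numeric(Matrix::solve(A, rhs))
  P[P < 0 & P > -1e-12] <- 0
  prob <- matrix(P, nrow = K, ncol = M, byrow = TRUE)
  structure(list(prob = prob, pairs = pairs, m_max = as.integer(m_max),
                 tail_mass = sum(prob[, M]), model = model),
            class = "tf_cme")
}

#' @export
print.tf_cme <- function(x, ...) {
  mom <- cme_moments(x)
  cat(sprintf("CME steady state: %d occupancy pairs x m <= %d (tail mass %.2e)\n",
              nrow(x$pairs), x$m_max, x$tail_mass))
  cat(sprintf("  <m> = %.4f, var(m) = %.4f, Fano = %.4f\n",
              mom$mean, mom$variance, mom$fano))
  invisible(x)
}

#' Marginals and moments of a CME solution
#'
#' `mrna_pmf()` returns the steady-state pmf of the total mRNA count,
#' `occupancy_marginal()` the joint (n, c) marginal, and `cme_moments()` the
#' mean, variance, Fano factor and fold change of the mRNA marginal.
#'
#' @param x A [cme_steady_state()] result.
#' @return `mrna_pmf`: named numeric vector over m = 0..m_max.
#' @export
mrna_pmf <- function(x) {
  stopifnot(inherits(x, "tf_cme"))
  setNames(colSums(x$prob), 0:x$m_max)
}

#' @rdname mrna_pmf
#' @export
occupancy_marginal <- function(x) {
  stopifnot(inherits(x, "tf_cme"))
  cbind(x$pairs, probability = rowSums(x$prob))
}

#' @rdname mrna_pmf
#' @export
cme_moments <- function(x) {
  pmf <- mrna_pmf(x)
  mv <- pmf_moments(pmf)
  list(mean = mv[["mean"]], variance = mv[["variance"]],
       fano = fano(mv[["mean"]], mv[["variance"]]),
       fold_change = fold_change(mv[["mean"]], x$model))
}

#' Mean and variance of an integer-support pmf
#'
#' @param pmf Numeric probabilities over counts `0:(length(pmf) - 1)` (or with
#'   integer names giving the support).
#' @return Named vector `mean`, `variance`.
#' @export
pmf_moments <- function(pmf) {
  supp <- if (!is.null(names(pmf))) as.numeric(names(pmf)) else seq_along(pmf) - 1
  mu <- sum(supp * pmf)
  c(mean = mu, variance = sum(supp^2 * pmf) - mu^2)
}

#' Write a CME distribution to CSV
#'
#' Columns `(n, c, m, probability)`, or `(m, probability)` with
#' `marginal = TRUE`; a JSON sidecar carries the model, `m_max` and tail mass.
#'
#' @param x A [cme_steady_state()] result.
#' @param path Output CSV path.
#' @param marginal Write only the mRNA marginal.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(x, path, marginal = FALSE) {
  stopifnot(inherits(x, "tf_cme"))
  df <- if (marginal) {
    data.frame(m = 0:x$m_max, probability = as.numeric(mrna_pmf(x)))
  } else {
    data.frame(n = rep(x$pairs$n, times = x$m_max + 1L),
               c = rep(x$pairs$c, times = x$m_max + 1L),
               m = rep(0:x$m_max, each = nrow(x$pairs)),
               probability = as.numeric(x$prob))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(model = unclass(x$model)[.model_fields],
                            m_max = x$m_max, tail_mass = x$tail_mass),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Truncation-free steady-state mRNA moments
#'
#' Exact mean and variance of the total mRNA count for any copy numbers,
#' obtained without truncating the mRNA axis: conditional on the finite
#' binding chain, mRNA is a Markov-modulated linear birth-death process, so
#' its conditional first and second moments satisfy closed finite linear
#' systems on the (n, c) occupancy states. Serves as an independent
#' cross-check of [cme_steady_state()].
#'
#' @param model A [tf_model()].
#' @return List with `mean` and `variance` of the total mRNA count.
#' @export
exact_moments <- function(model) {
  stopifnot(inherits(model, "tf_model"))
  pairs <- occ_pairs(model)
  Q <- occ_generator(model, pairs)
  K <- nrow(Q)
  pi_ <- stationary_of(Q)
  a <- if (model$mode == "activator")
    model$r * pairs$n + model$r_basal * (model$n_promoters - pairs$n)
  else model$r * (model$n_promoters - pairs$n)
  g <- model$gamma
  QT <- t(Q)
  u <- solve(g * diag(K) - QT, a * pi_)                    # E[m 1_j]
  z <- solve(2 * g * diag(K) - QT, a * (2 * u + pi_) + g * u) # E[m^2 1_j]
  mu <- sum(u)
  list(mean = mu, variance = sum(z) - mu^2)
}

#' Exact correlation between two promoters' mRNA pools
#'
#' Steady-state Pearson correlation of the mRNA counts (m_1, m_2) produced by
#' two identical promoter copies sharing TFs (and competitor sites). Computed
#' exactly: on the per-promoter occupancy chain over states (s_1, s_2, c) the
#' conditional moments of the two Markov-modulated mRNA pools satisfy closed
#' linear systems, so no state-space truncation is involved.
#'
#' @param model A [tf_model()] with `n_promoters = 2`.
#' @return Pearson correlation in `[-1, 1]` (`NaN` when an mRNA pool has zero
#'   variance).
#' @export
#' @examples
#' rates <- ecoli_rates()
#' m <- do.call(tf_model, c(list(n_tf = 3, n_promoters = 2, n_competitors = 5),
#'                          rates))
#' cme_promoter_correlation(m)
cme_promoter_correlation <- function(model) {
  stopifnot(inherits(model, "tf_model"))
  if (model$n_promoters != 2L)
    stop("cme_promoter_correlation requires n_promoters = 2", call. = FALSE)
  states <- expand.grid(s1 = 0:1, s2 = 0:1, c = 0:model$n_competitors)
  states <- states[states$s1 + states$s2 + states$c <= model$n_tf, ,
                   drop = FALSE]
  K <- nrow(states)
  idx <- function(s1, s2, c) which(states$s1 == s1 & states$s2 == s2 &
                                     states$c == c)
  Q <- matrix(0, K, K)
  for (i in seq_len(K)) {
    s1 <- states$s1[i]; s2 <- states$s2[i]; c_ <- states$c[i]
    f <- model$n_tf - s1 - s2 - c_
    if (s1 == 0 && f > 0) Q[i, idx(1, s2, c_)] <- model$k_on * f
    if (s1 == 1) Q[i, idx(0, s2, c_)] <- model$k_off
    if (s2 == 0 && f > 0) Q[i, idx(s1, 1, c_)] <- model$k_on * f
    if (s2 == 1) Q[i, idx(s1, 0, c_)] <- model$k_off
    if (c_ < model$n_competitors && f > 0)
      Q[i, idx(s1, s2, c_ + 1)] <- model$k_on_c * f * (model$n_competitors - c_)
    if (c_ > 0) Q[i, idx(s1, s2, c_ - 1)] <- model$k_off_c * c_
  }
  diag(Q) <- -rowSums(Q)
  pi_ <- stationary_of(Q)
  act <- function(s) if (model$mode == "activator")
    model$r * s + model$r_basal * (1 - s) else model$r * (1 - s)
  a1 <- act(states$s1); a2 <- act(states$s2)
  g <- model$gamma
  QT <- t(Q)
  u <- solve(g * diag(K) - QT, a1 * pi_)
  v <- solve(g * diag(K) - QT, a2 * pi_)
  z1 <- solve(2 * g * diag(K) - QT, a1 * (2 * u + pi_) + g * u)
  z2 <- solve(2 * g * diag(K) - QT, a2 * (2 * v + pi_) + g * v)
  w <- solve(2 * g * diag(K) - QT, a1 * v + a2 * u)
  mu1 <- sum(u); mu2 <- sum(v)
  var1 <- sum(z1) - mu1^2; var2 <- sum(z2) - mu2^2
  cov12 <- sum(w) - mu1 * mu2
  if (var1 <= 0 || var2 <= 0) return(NaN)
  cov12 / sqrt(var1 * var2)
}

#' Total variation distance between two discrete distributions
#'
#' `TV(p, q) = sum(abs(p - q)) / 2`; the shorter vector is padded with zeros.
#'
#' @param p,q Non-negative probability vectors.
#' @return Distance in `[0, 1]`.
#' @export
total_variation <- function(p, q) {
  if (any(p < 0) || any(q < 0))
    stop("probabilities must be non-negative", call. = FALSE)
  n <- max(length(p), length(q))
  sum(abs(c(p, numeric(n - length(p))) - c(q, numeric(n - length(q))))) / 2
}
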