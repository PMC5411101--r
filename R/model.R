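#' Reference kinetic rates for an E. coli promoter
#'
#' Binding/unbinding, transcription and mRNA decay rates realistic for
#' bacterial promoters, used as defaults throughout: `k_on = 0.0027` per TF per
#' promoter, `k_off = 0.0023` per TF-promoter complex, `r` = 0.33 per
#' transcribing promoter and `gamma = 0.011` per mRNA molecule (all s^-1).
#' At these rates an always-on promoter makes `r/gamma = 30` mRNAs on average.
#'
#' @return Named list with elements `k_on`, `k_off`, `r`, `gamma` (s^-1).
#' @export
#' @examples
#' do.call(tf_model, c(list(n_tf = 1), ecoli_rates()))
ecoli_rates <- function() {
  list(k_on = 0.0027, k_off = 0.0023, r = 0.33, gamma = 0.011)
}

#' Specify a TF-sharing transcription model
#'
#' Constructs and validates the full parameterization of one competition
#' scenario: `n_tf` transcription factors shared between `n_promoters`
#' identical single-binding-site promoter copies and `n_competitors` decoy
#' sites. A TF binds a free promoter at rate `k_on` per TF per promoter and
#' unbinds at `k_off` per complex; competitor sites bind/unbind at `k_on_c` /
#' `k_off_c` (defaulting to the promoter rates). An activator-bound promoter
#' transcribes at rate `r` (activator-free promoters at the basal rate
#' `r_basal`, zero by default); a repressor-free promoter transcribes at `r`.
#' Each mRNA decays at rate `gamma`. Copy numbers are exact conserved integers.
#'
#' @param n_tf TF copy number (N_TF >= 0).
#' @param n_promoters Number of identical promoter copies (N_P >= 1).
#' @param n_competitors Number of competitor (decoy) sites (N_C >= 0).
#' @param k_on,k_off Promoter binding/unbinding rates (s^-1).
#' @param k_on_c,k_off_c Competitor-site binding/unbinding rates (s^-1);
#'   default equal to the promoter rates.
#' @param r Transcription rate per transcribing promoter (s^-1).
#' @param r_basal Basal transcription rate per activator-free promoter (s^-1;
#'   activator mode only, default 0).
#' @param gamma mRNA decay rate per molecule (s^-1, > 0).
#' @param mode `"activator"` or `"repressor"`.
#' @return Object of class `tf_model`.
#' @export
#' @examples
#' m <- tf_model(n_tf = 1, n_promoters = 1, k_on = 0.0027, k_off = 0.0023,
#'               r = 0.33, gamma = 0.011, mode = "activator")
#' m
tf_model <- function(n_tf, n_promoters = 1L, n_competitors = 0L,
                     k_on, k_off, k_on_c = k_on, k_off_c = k_off,
                     r, r_basal = 0, gamma,
                     mode = c("activator", "repressor")) {
  mode <- match.arg(mode)
  chk_count <- function(x, name, min = 0L) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
      stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
    as.integer(x)
  }
  chk_rate <- function(x, name, strict = FALSE) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || (strict && x <= 0))
      stop(sprintf("'%s' must be a single %s rate (s^-1)", name,
                   if (strict) "positive" else "non-negative"), call. = FALSE)
    as.numeric(x)
  }
  spec <- list(
    n_tf          = chk_count(n_tf, "n_tf"),
    n_promoters   = chk_count(n_promoters, "n_promoters", min = 1L),
    n_competitors = chk_count(n_competitors, "n_competitors"),
    k_on    = chk_rate(k_on, "k_on"),
    k_off   = chk_rate(k_off, "k_off"),
    k_on_c  = chk_rate(k_on_c, "k_on_c"),
    k_off_c = chk_rate(k_off_c, "k_off_c"),
    r       = chk_rate(r, "r", strict = TRUE),
    r_basal = chk_rate(r_basal, "r_basal"),
    gamma   = chk_rate(gamma, "gamma", strict = TRUE),
    mode    = mode
  )
  if (spec$mode == "repressor" && spec$r_basal > 0)
    stop("'r_basal' must be 0 in repressor mode", call. = FALSE)
  structure(spec, class = "tf_model")
}

#' @export
print.tf_model <- function(x, ...) {
  cat(sprintf("TF-sharing transcription model (%s)\n", x$mode))
  cat(sprintf("  copy numbers: N_TF = %d, N_P = %d, N_C = %d\n",
              x$n_tf, x$n_promoters, x$n_competitors))
  cat(sprintf("  promoter:   k_on = %g, k_off = %g s^-1\n", x$k_on, x$k_off))
  if (x$n_competitors > 0)
    cat(sprintf("  competitor: k_on_c = %g, k_off_c = %g s^-1\n", x$k_on_c, x$k_off_c))
  cat(sprintf("  expression: r = %g, r_basal = %g, gamma = %g s^-1 (r/gamma = %g)\n",
              x$r, x$r_basal, x$gamma, x$r / x$gamma))
  invisible(x)
}

#' @export
summary.tf_model <- function(object, ...) {
  mom <- exact_moments(object)
  occ <- occupancy_distribution(object)
  en <- sum(occ$n * occ$probability)
  out <- list(model = object, mean = mom$mean, variance = mom$variance,
              fano = fano(mom$mean, mom$variance),
              fold_change = fold_change(mom$mean, object),
              mean_occupancy = en)
  class(out) <- "summary.tf_model"
  out
}

#' @export
print.summary.tf_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("steady state: <m> = %.4f, var(m) = %.4f, Fano = %.4f, fold change = %.4f\n",
              x$mean, x$variance, x$fano, x$fold_change))
  cat(sprintf("              <n> (bound promoters) = %.4f\n", x$mean_occupancy))
  invisible(x)
}

# field order used for (de)serialization and config parsing
.model_fields <- c("n_tf", "n_promoters", "n_competitors", "k_on", "k_off",
                   "k_on_c", "k_off_c", "r", "r_basal", "gamma", "mode")

#' Serialize a model to JSON
#'
#' Writes the model as a flat JSON object with exactly the constructor's field
#' names. [model_from_json()] is the inverse; unknown keys are rejected.
#'
#' @param model A [tf_model()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "tf_model"))
  js <- jsonlite::toJSON(unclass(model)[.model_fields], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname model_to_json
#' @param json JSON string or path to a JSON file.
#' @export
model_from_json <- function(json) {
  raw <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), .model_fields)
  if (length(unknown))
    stop("unknown model field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(tf_model, raw)
}

#' Instantaneous microstate of the system
#'
#' A state records which promoter copies are TF-bound, how many competitor
#' sites are bound, and the mRNA count attributed to each promoter. TF
#' conservation `n + c <= N_TF` and non-negativity are enforced.
#'
#' @param model A [tf_model()].
#' @param occupancy Integer 0/1 vector of length `n_promoters`.
#' @param bound_competitors Number of TF-bound competitor sites.
#' @param mrna Integer vector of per-promoter mRNA counts.
#' @param time Time in seconds.
#' @return Object of class `tf_state` with aggregates `n`, `c`, `m`.
#' @export
tf_state <- function(model, occupancy = integer(model$n_promoters),
                     bound_competitors = 0L,
                     mrna = integer(model$n_promoters), time = 0) {
  stopifnot(inherits(model, "tf_model"))
  occupancy <- as.integer(occupancy)
  mrna <- as.integer(mrna)
  if (length(occupancy) != model$n_promoters || any(!occupancy %in% c(0L, 1L)))
    stop("'occupancy' must be a 0/1 vector of length n_promoters", call. = FALSE)
  if (length(mrna) != model$n_promoters || any(mrna < 0L))
    stop("'mrna' must be non-negative counts of length n_promoters", call. = FALSE)
  c_ <- as.integer(bound_competitors)
  if (c_ < 0L || c_ > model$n_competitors)
    stop("'bound_competitors' must be in [0, n_competitors]", call. = FALSE)
  n <- sum(occupancy)
  if (n + c_ > model$n_tf)
    stop("inconsistent state: n + c exceeds n_tf (TF conservation)", call. = FALSE)
  structure(list(occupancy = occupancy, bound_competitors = c_, mrna = mrna,
                 time = as.numeric(time), n = n, c = c_, m = sum(mrna)),
            class = "tf_state")
}

#' Number of free (unbound) TFs
#'
#' @param state A [tf_state()].
#' @param model The corresponding [tf_model()].
#' @return `N_TF - n - c` (always >= 0 for a consistent state).
#' @export
free_tf <- function(state, model) {
  stopifnot(inherits(state, "tf_state"), inherits(model, "tf_model"))
  f <- model$n_tf - state$n - state$c
  if (f < 0) stop("inconsistent state: n + c exceeds n_tf", call. = FALSE)
  f
}

#' Reaction channels and propensities at a state
#'
#' Lists every reaction channel of the model with its propensity evaluated at
#' `state`, including zero-propensity channels. Channels, in fixed order:
#' per-promoter TF binding (`k_on * F * (1 - s_i)`, `F` the free-TF count) and
#' unbinding (`k_off * s_i`), competitor binding (`k_on_c * F * (N_C - c)`) and
#' unbinding (`k_off_c * c`), per-promoter transcription (activator:
#' `r*s_i + r_basal*(1 - s_i)`; repressor: `r*(1 - s_i)`), and
#' per-promoter mRNA decay (`gamma * m_i`).
#'
#' @inheritParams free_tf
#' @return Data frame with columns `kind`, `promoter` (NA for competitor
#'   channels) and `propensity`.
#' @export
propensities <- function(state, model) {
  f <- free_tf(state, model)
  s <- state$occupancy
  np <- model$n_promoters
  transcribe <- if (model$mode == "activator")
    model$r * s + model$r_basal * (1 - s) else model$r * (1 - s)
  data.frame(
    kind = c(rep("bind_promoter", np), rep("unbind_promoter", np),
             "bind_competitor", "unbind_competitor",
             rep("transcribe", np), rep("degrade", np)),
    promoter = c(seq_len(np), seq_len(np), NA, NA, seq_len(np), seq_len(np)),
    propensity = c(model$k_on * f * (1 - s),
                   model$k_off * s,
                   model$k_on_c * f * (model$n_competitors - state$c),
                   model$k_off_c * state$c,
                   transcribe,
                   model$gamma * state$mrna),
    stringsAsFactors = FALSE
  )
}
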