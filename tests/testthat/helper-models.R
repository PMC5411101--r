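# Model fixtures built in code. All use the package's reference E. coli rates
# unless overridden; `fast_rates()` raises k_on above gamma (the regime where
# a two-promoter system is unimodal without competitors).

make_model <- function(mode, n_tf, n_promoters = 1, n_competitors = 0,
                       .rates = ecoli_rates(), ...) {
  args <- modifyList(
    c(list(n_tf = n_tf, n_promoters = n_promoters,
           n_competitors = n_competitors, mode = mode), .rates),
    list(...))
  do.call(tf_model, args)
}

act_model <- function(n_tf, n_promoters = 1, n_competitors = 0, ...)
  make_model("activator", n_tf, n_promoters, n_competitors, ...)

rep_model <- function(n_tf, n_promoters = 1, n_competitors = 0, ...)
  make_model("repressor", n_tf, n_promoters, n_competitors, ...)

fast_rates <- function() modifyList(ecoli_rates(), list(k_on = 0.027))

# empirical pmf of total mRNA over 0:(nbins-1)
empirical_pmf <- function(pop, nbins) {
  tabulate(pop$states$m + 1L, nbins = nbins) / nrow(pop$states)
}

# per-promoter (n_promoters, mean, variance) points along the master curve,
# computed with the truncation-free exact moment solver
curve_points <- function(mode, n_promoters, ntf_values, n_competitors = 0,
                         rate_scale = 1) {
  rows <- lapply(ntf_values, function(nt) {
    m <- make_model(mode, nt, n_promoters, n_competitors,
                    k_on_c = ecoli_rates()$k_on * rate_scale,
                    k_off_c = ecoli_rates()$k_off * rate_scale)
    mom <- exact_moments(m)
    data.frame(n_promoters = n_promoters, n_tf = nt,
               n_competitors = n_competitors, mean = mom$mean,
               variance = mom$variance)
  })
  do.call(rbind, rows)
}
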