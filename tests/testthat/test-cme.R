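test_that("binding occupancy matches the two-state balance and edge cases", {
  m <- act_model(n_tf = 1)
  occ <- occupancy_distribution(m)
  # P(bound) = k_on / (k_on + k_off) for one TF and one promoter
  expect_equal(occ$probability[occ$n == 1], 0.0027 / 0.005, tolerance = 1e-12)
  occ0 <- occupancy_distribution(act_model(n_tf = 0, n_competitors = 3))
  expect_identical(nrow(occ0), 1L)
  expect_equal(occ0$probability, 1)
  # two promoters, three TFs: complex number supported on exactly {0, 1, 2}
  occ2 <- occupancy_distribution(act_model(n_tf = 3, n_promoters = 2))
  expect_identical(sort(unique(occ2$n)), 0:2)
  expect_true(all(occ2$probability > 0))
  expect_warning(occupancy_distribution(act_model(n_tf = 1, k_off = 0)),
                 "absorbing")
})

test_that("linear solve agrees with product form and detailed balance holds", {
  grid <- expand.grid(nt = c(1, 3, 5), np = c(1, 3), nc = c(0, 2, 3))
  for (i in seq_len(nrow(grid))) {
    m <- act_model(n_tf = grid$nt[i], n_promoters = grid$np[i],
                   n_competitors = grid$nc[i], k_on_c = 0.004,
                   k_off_c = 0.001)
    occ <- occupancy_distribution(m)   # errors internally above 1e-10
    pf <- attr(occ, "product_form")
    expect_equal(occ$probability, pf, tolerance = 1e-10)
    expect_equal(sum(occ$probability), 1, tolerance = 1e-12)
    # net stationary flux across every promoter-binding edge is zero
    for (j in seq_len(nrow(occ))) {
      n <- occ$n[j]; cc <- occ$c[j]
      fwd <- occ$probability[j] * m$k_on * (m$n_tf - n - cc) *
        (m$n_promoters - n)
      k <- which(occ$n == n + 1 & occ$c == cc)
      if (length(k) == 1) {
        bwd <- occ$probability[k] * m$k_off * (n + 1)
        expect_lt(abs(fwd - bwd), 1e-10)
      } else {
        expect_equal(fwd, 0)   # target state outside the conservation lattice
      }
    }
  }
})

test_that("CME steady state reproduces the exact single-promoter moments", {
  for (mode in c("activator", "repressor")) {
    m <- make_model(mode, n_tf = 1)
    sol <- cme_steady_state(m, m_max = 150)
    mom <- cme_moments(sol)
    ref <- analytic_moments(m)
    expect_equal(mom$mean, ref$mean, tolerance = 1e-6)
    expect_equal(mom$variance, ref$variance, tolerance = 1e-6)
    expect_equal(sum(mrna_pmf(sol)), 1, tolerance = 1e-9)
  }
})

test_that("unregulated repressor promoter is Poisson with r/gamma mRNAs", {
  m <- rep_model(n_tf = 0)
  sol <- cme_steady_state(m)
  pmf <- mrna_pmf(sol)
  expect_lt(total_variation(pmf, dpois(0:sol$m_max, 30)), 1e-8)
  mom <- cme_moments(sol)
  expect_equal(mom$fano, 1, tolerance = 1e-6)
  expect_equal(mom$mean, 30, tolerance = 1e-6)
})

test_that("the CME occupancy marginal equals the binding-chain distribution", {
  m <- act_model(n_tf = 3, n_promoters = 2, n_competitors = 2)
  sol <- cme_steady_state(m)
  marg <- occupancy_marginal(sol)
  occ <- occupancy_distribution(m)
  expect_equal(marg$probability, occ$probability, tolerance = 1e-8)
})

test_that("CME moments are converged in the truncation (Cauchy criterion)", {
  m <- act_model(n_tf = 1)
  m150 <- cme_moments(cme_steady_state(m, m_max = 150))
  m300 <- cme_moments(cme_steady_state(m, m_max = 300))
  expect_lt(abs(m150$mean - m300$mean), 1e-8)
  expect_lt(abs(m150$variance - m300$variance), 1e-7)
  # and the truncation machinery reports/expands as promised
  expect_error(cme_steady_state(m, m_max = 2, max_doublings = 0),
               "tail mass")
  sol <- cme_steady_state(m, m_max = 2)   # auto-doubles until converged
  expect_gte(sol$m_max, 64)
  expect_lt(sol$tail_mass, 1e-8)
})

test_that("truncation-free moments agree with the truncated CME solve", {
  for (m in list(act_model(n_tf = 3, n_promoters = 2, n_competitors = 2),
                 rep_model(n_tf = 2, n_promoters = 2),
                 act_model(n_tf = 5, n_promoters = 1, n_competitors = 5,
                           r_basal = 0.02))) {
    a <- exact_moments(m)
    b <- cme_moments(cme_steady_state(m, tol = 1e-10))
    expect_equal(a$mean, b$mean, tolerance = 1e-7)
    expect_equal(a$variance, b$variance, tolerance = 1e-6)
  }
})

test_that("total variation distance behaves as a metric on pmfs", {
  expect_equal(total_variation(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(total_variation(c(1, 0), c(0, 1)), 1)
  expect_equal(total_variation(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_equal(total_variation(c(1), c(0, 0, 1)), 1)  # zero-padding
  expect_error(total_variation(c(-0.1, 1.1), c(1, 0)), "non-negative")
})

test_that("exact two-promoter correlation shows the titration signature", {
  fr <- fast_rates()
  corr_nc <- function(nc, n_tf = 3)
    cme_promoter_correlation(make_model("activator", n_tf, 2, nc,
                                        .rates = fr))
  # abundant TFs: promoters express independently
  expect_lt(abs(corr_nc(0, n_tf = 50)), 1e-3)
  curve <- vapply(c(0, 1, 2, 3, 5, 10, 30, 200), corr_nc, numeric(1))
  expect_lt(min(curve), -0.1)                      # intermediate minimum
  expect_lt(abs(curve[length(curve)]), 0.1 * abs(min(curve)))  # decays away
  expect_lt(abs(curve[1]), 0.05)                   # starts near zero
  expect_error(cme_promoter_correlation(act_model(n_tf = 1)), "n_promoters")
})

test_that("exact correlation is confirmed by SSA sampling", {
  m <- make_model("activator", 3, 2, 5, .rates = fast_rates())
  exact <- cme_promoter_correlation(m)
  pop <- sample_population(m, 4000, burn_in = 4000, seed = 17)
  est <- promoter_correlation(pop)
  se <- (1 - exact^2) / sqrt(4000)
  expect_lt(abs(est - exact), 4 * se)
})

test_that("distribution writer emits joint and marginal CSVs with sidecar", {
  m <- act_model(n_tf = 1)
  sol <- cme_steady_state(m, m_max = 120)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "joint.csv")
  write_distribution(sol, f1)
  joint <- read.csv(f1)
  expect_identical(names(joint), c("n", "c", "m", "probability"))
  expect_equal(sum(joint$probability), 1, tolerance = 1e-9)
  f2 <- file.path(dir, "marg.csv")
  write_distribution(sol, f2, marginal = TRUE)
  marg <- read.csv(f2)
  expect_identical(names(marg), c("m", "probability"))
  side <- jsonlite::fromJSON(paste0(f2, ".json"))
  expect_identical(side$m_max, sol$m_max)
})
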