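test_that("TF sweeps validate input and return one row per value", {
  m <- act_model(n_tf = 1, n_promoters = 2)
  one <- sweep_tf(m, 3, engine = "cme")
  expect_identical(nrow(one), 1L)
  expect_identical(one$n_tf, 3L)
  expect_error(sweep_tf(m, c(3, 2)), "strictly increasing")
  expect_error(sweep_tf(m, numeric(0)), "non-empty")
  expect_error(sweep_tf(m, 1:3, engine = "exact"), "arg")
})

test_that("variance and Fano peak near TF-promoter parity (exact engine)", {
  sw <- sweep_tf(act_model(n_tf = 1, n_promoters = 4), 1:12, engine = "cme")
  expect_true(sw$n_tf[which.max(sw$variance)] %in% 3:5)
  expect_true(sw$n_tf[which.max(sw$fano)] %in% 3:5)
  # fold change rises monotonically toward 1
  expect_true(all(diff(sw$fold_change) > 0))
  expect_true(max(sw$fold_change) < 1)
  swr <- sweep_tf(rep_model(n_tf = 1, n_promoters = 4), 1:12, engine = "cme")
  expect_true(swr$n_tf[which.max(swr$variance)] %in% 3:5)
  # repressor Fano peaks above parity
  expect_gt(swr$n_tf[which.max(swr$fano)], 4)
  expect_true(all(diff(swr$fold_change) < 0))
})

test_that("SSA and CME engines agree within Monte Carlo error", {
  m <- act_model(n_tf = 2, n_promoters = 2)
  exact <- sweep_tf(m, c(1, 3), engine = "cme")
  est <- sweep_tf(m, c(1, 3), engine = "ssa", n_cells = 3000,
                  burn_in = 4000, seed = 5, n_boot = 300)
  expect_true(all(abs(est$mean - exact$mean) < 3.5 * est$se_mean))
  expect_true(all(abs(est$variance - exact$variance) < 3.5 * est$se_variance))
})

test_that("competitor sweeps carry pmfs and mode reports", {
  m <- make_model("activator", 3, 2, 0, .rates = fast_rates())
  sw <- sweep_competitors(m, c(0, 4, 8), engine = "cme")
  expect_identical(nrow(sw$table), 3L)
  expect_identical(sw$table$n_modes, c(1L, 2L, 2L))
  expect_named(sw$pmfs, c("0", "4", "8"))
  expect_equal(sum(sw$pmfs[["8"]]), 1, tolerance = 1e-8)
  # mode count transition is robust to the smoothing window
  for (w in c(3, 9)) {
    sww <- sweep_competitors(m, c(0, 8), engine = "cme",
                             smoothing_window = w)
    expect_identical(sww$table$n_modes, c(1L, 2L))
  }
})

test_that("single-promoter points hug the master curve; two promoters do not", {
  rt <- ecoli_rates()
  ntf <- c(1, 2, 3, 5, 8, 12, 20)
  p1 <- rbind(curve_points("activator", 1, ntf),
              curve_points("activator", 1, ntf, n_competitors = 5),
              curve_points("activator", 1, ntf, n_competitors = 5,
                           rate_scale = 5))
  r1 <- collapse_residuals(p1, rt$r, rt$gamma, rt$k_off, "activator")
  expect_lt(r1$max_residual, 0.05)
  pts2 <- do.call(rbind, lapply(1:10, function(nc) {
    mom <- exact_moments(act_model(n_tf = 3, n_promoters = 2,
                                   n_competitors = nc))
    data.frame(n_promoters = 2, mean = mom$mean, variance = mom$variance)
  }))
  r2 <- collapse_residuals(pts2, rt$r, rt$gamma, rt$k_off, "activator")
  expect_gt(r2$max_residual, 3 * r1$max_residual)
  # exact point on the curve has zero residual
  mom <- analytic_moments(act_model(n_tf = 4))
  r0 <- collapse_residuals(data.frame(n_promoters = 1, mean = mom$mean,
                                      variance = mom$variance),
                           rt$r, rt$gamma, rt$k_off, "activator")
  expect_lt(r0$max_residual, 1e-12)
  expect_error(collapse_residuals(data.frame(), rt$r, rt$gamma, rt$k_off),
               "non-empty")
})

test_that("JSON configs round-trip models with settings and reject junk", {
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "cfg.json")
  writeLines(jsonlite::toJSON(list(n_tf = 2, n_promoters = 1, k_on = 0.0027,
                                   k_off = 0.0023, r = 0.33, gamma = 0.011,
                                   mode = "activator", n_cells = 500,
                                   engine = "ssa"),
                              auto_unbox = TRUE), cfg)
  got <- load_config(cfg)
  expect_s3_class(got$model, "tf_model")
  expect_identical(got$settings$n_cells, 500L)
  expect_identical(got$settings$engine, "ssa")
  expect_identical(got$settings$tol, 1e-8)  # default fills in
  writeLines(jsonlite::toJSON(list(n_tf = 2, k_on = 0.0027, k_off = 0.0023,
                                   r = 0.33, mode = "activator"),
                              auto_unbox = TRUE), cfg)
  expect_error(load_config(cfg), "gamma")
  writeLines(jsonlite::toJSON(list(n_tf = 2, k_on = 0.0027, k_off = 0.0023,
                                   r = 0.33, gamma = 0.011,
                                   mode = "activator", typo_key = 1),
                              auto_unbox = TRUE), cfg)
  expect_error(load_config(cfg), "typo_key")
  expect_error(load_config(file.path(dir, "absent.json")), "not found")
})
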