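test_that("identical chains give a scale reduction factor of exactly 1", {
  set.seed(1)
  m <- matrix(rnorm(500), ncol = 2, dimnames = list(NULL, c("a", "b")))
  res <- psrf(list(m, m, m))
  expect_equal(res$psrf, c(1, 1), tolerance = 1e-12)
})

test_that("well-separated chains are flagged far above the 1.1 gate", {
  set.seed(2)
  a <- matrix(rnorm(1000, 0, 1), ncol = 1, dimnames = list(NULL, "x"))
  b <- matrix(rnorm(1000, 10, 1), ncol = 1, dimnames = list(NULL, "x"))
  expect_gt(psrf(list(a, b))$psrf, 5)
})

test_that("psrf matches a naive two-loop reference on random chains", {
  naive_psrf <- function(chains) {
    m <- length(chains); n <- length(chains[[1]])
    means <- numeric(m); vars <- numeric(m)
    for (j in 1:m) {
      mu <- 0
      for (x in chains[[j]]) mu <- mu + x / n
      v <- 0
      for (x in chains[[j]]) v <- v + (x - mu)^2 / (n - 1)
      means[j] <- mu; vars[j] <- v
    }
    grand <- mean(means)
    B <- 0
    for (j in 1:m) B <- B + n * (means[j] - grand)^2 / (m - 1)
    W <- mean(vars)
    max(1, sqrt(((n - 1) / n * W + B / n) / W))
  }
  set.seed(3)
  for (i in 1:5) {
    chains <- lapply(1:3, function(j) rnorm(50, mean = j * runif(1)))
    mats <- lapply(chains, function(v) matrix(v, dimnames = list(NULL, "p")))
    expect_equal(psrf(mats)$psrf, naive_psrf(chains), tolerance = 1e-12)
  }
  expect_error(psrf(list(matrix(rnorm(50), dimnames = list(NULL, "p")))),
               "2 chains")
})

test_that("psrf agrees with the coda implementation on fitted draws", {
  p <- tl_point_estimates()
  tab <- simulate_responses(p, sim_design("two_level", 40, 3, seed = 12))$table
  fit <- fit_aig_model(tab, settings = mcmc_settings(2, 6000, seed = 12))
  ours <- fit$convergence
  mc <- coda::mcmc.list(lapply(split(seq_along(fit$draws$chain),
                                     fit$draws$chain), function(i)
    coda::mcmc(fit$draws$pars[i, setdiff(colnames(fit$draws$pars),
                                         "rho_alpha.2.3")])))
  gd <- coda::gelman.diag(mc, autoburnin = FALSE, multivariate = FALSE)
  ref <- gd$psrf[, 1]
  ours <- ours[match(names(ref), ours$parameter), ]
  # coda multiplies by a sampling-variability df correction absent from the
  # classic ratio, so agreement is approximate and improves with chain length
  expect_true(all(abs(ours$psrf - ref) < 0.1))
  expect_true(all((ours$psrf < 1.1) == (ref < 1.1)))
})

test_that("posterior summaries match closed-form and brute-force quantiles", {
  const <- matrix(5, 200, 1, dimnames = list(NULL, "c"))
  s <- posterior_summary(const)
  expect_equal(s$median, 5); expect_equal(s$lower, 5); expect_equal(s$upper, 5)

  set.seed(4)
  z <- matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "z"))
  s <- posterior_summary(z)
  expect_lt(abs(s$lower - (-1.96)), 0.1)
  expect_lt(abs(s$upper - 1.96), 0.1)

  # type-7 quantile reference: linear interpolation of order statistics
  ref_quantile <- function(x, p) {
    x <- sort(x); n <- length(x)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
  }
  set.seed(5)
  x <- matrix(rexp(501), ncol = 1, dimnames = list(NULL, "x"))
  s <- posterior_summary(x)
  expect_equal(s$lower, ref_quantile(x, 0.025), tolerance = 1e-12)
  expect_equal(s$median, ref_quantile(x, 0.5), tolerance = 1e-12)
  expect_equal(s$upper, ref_quantile(x, 0.975), tolerance = 1e-12)
})

test_that("the same seed reproduces a fit bit for bit", {
  p <- cc_point_estimates()
  tab <- simulate_responses(p, sim_design("cross_classified", 25, 3, seed = 9))$table
  f1 <- fit_aig_model(tab, settings = quick_settings(seed = 77))
  f2 <- fit_aig_model(tab, settings = quick_settings(seed = 77))
  expect_identical(f1$draws$pars, f2$draws$pars)
  expect_identical(f1$summary, f2$summary)
  f3 <- fit_aig_model(tab, settings = quick_settings(seed = 78))
  expect_false(identical(f1$draws$pars, f3$draws$pars))
})

test_that("the reference loading is pinned at 1 and never sampled", {
  p <- cc_point_estimates()
  tab <- simulate_responses(p, sim_design("cross_classified", 25, 3, seed = 9))$table
  fit <- fit_aig_model(tab, settings = quick_settings(seed = 1))
  expect_false("lam.1" %in% colnames(fit$draws$pars))
  fitc <- fit_aig_model(tab, settings = quick_settings(seed = 1),
                        fix_loadings = TRUE)
  expect_true(all(fitc$draws$pars[, "lam.2"] == 1))
  expect_true(all(fitc$draws$pars[, "lam.3"] == 1))
})

test_that("variance draws stay positive and rho is clipped to [-1, 1]", {
  p <- cc_point_estimates()
  tab <- simulate_responses(p, sim_design("cross_classified", 30, 3, seed = 2))$table
  fit <- fit_aig_model(tab, settings = quick_settings(seed = 3))
  pars <- fit$draws$pars
  vc <- c(grep("^var_", colnames(pars), value = TRUE),
          "cov_alpha.2.2", "cov_alpha.3.3")
  expect_true(all(pars[, vc] > 0))
  expect_true(all(abs(pars[, "rho_alpha.2.3"]) <= 1))
})

test_that("with no data the sampler reproduces its intercept prior", {
  pr <- priors(mu_mean = 3, mu_var = 4, lam_mean = 1, lam_var = 0.25,
               ig_shape = 3, ig_scale = 4, iw_df = 8, iw_scale = diag(2) * 6)
  empty <- data.frame(subject_id = character(0), radical_level = integer(0),
                      incidental_id = character(0), score = numeric(0))
  fit <- fit_aig_model(empty, priors = pr,
                       settings = mcmc_settings(2, 4000, seed = 6),
                       design = "two_level", n_radicals = 3, n_subjects = 4)
  mu_draws <- fit$draws$pars[, c("mu.1", "mu.2", "mu.3")]
  n_eff <- length(mu_draws)  # prior draws are iid across iterations
  expect_lt(abs(mean(mu_draws) - 3), 4 * 2 / sqrt(n_eff))
  expect_lt(abs(sd(as.vector(mu_draws)) - 2), 0.2)
})

test_that("degenerate designs fail with informative errors", {
  p <- cc_point_estimates()
  tab <- simulate_responses(p, sim_design("cross_classified", 10, 3, seed = 1))$table
  one <- tab[tab$subject_id == "s0001", ]
  expect_error(fit_aig_model(one, settings = quick_settings()), "2 subjects")
  flat <- tab; flat$score <- 7
  expect_error(fit_aig_model(flat, settings = quick_settings()), "constant")
  empty <- tab[0, ]
  expect_error(fit_aig_model(empty, settings = quick_settings()), "empty")
})

test_that("missing scores are dropped from the likelihood, not imputed", {
  p <- cc_point_estimates()
  tab <- simulate_responses(p, sim_design("cross_classified", 30, 3, seed = 21))$table
  tab_miss <- inject_missing(tab, 7, seed = 2)
  fit <- fit_aig_model(tab_miss, settings = quick_settings(seed = 5))
  expect_equal(fit$data_info$n_rows, nrow(tab) - 7L)
  expect_true(all(fit$convergence$psrf < 1.5))
})

test_that("a two-level fit matches a cross-classified fit when incidental variance is zero", {
  p <- cc_point_estimates()
  p$var_beta[] <- 0  # no incidental effects: the models should agree
  tab_cc <- simulate_responses(p, sim_design("cross_classified", 120, 3,
                                             seed = 14))$table
  fit_cc <- fit_aig_model(tab_cc, settings = mcmc_settings(2, 3000, seed = 3))
  p_tl <- p; p_tl$design <- "two_level"
  tab_tl <- simulate_responses(p_tl, sim_design("two_level", 120, 3,
                                                seed = 14))$table
  fit_tl <- fit_aig_model(tab_tl, settings = mcmc_settings(2, 3000, seed = 3))
  for (r in 1:3) {
    nm <- paste0("var_gamma.", r)
    ci_cc <- fit_cc$summary[fit_cc$summary$parameter == nm, c("lower", "upper")]
    ci_tl <- fit_tl$summary[fit_tl$summary$parameter == nm, c("lower", "upper")]
    expect_lt(max(ci_cc$lower, ci_tl$lower), min(ci_cc$upper, ci_tl$upper))
  }
})

test_that("simulation-based calibration ranks are uniform at small scale", {
  # truths drawn from the same (proper) priors the sampler uses; for the
  # single non-reference level the inverse-Wishart scalar is IG(df/2, s/2)
  pr <- priors(mu_mean = 10, mu_var = 1, lam_mean = 1, lam_var = 0.04,
               ig_shape = 4, ig_scale = 9, iw_df = 8, iw_scale = matrix(12))
  n_rep <- 24L
  track <- c("mu.1", "mu.2", "var_gamma.1", "var_gamma.2")
  ranks <- matrix(NA_real_, n_rep, length(track),
                  dimnames = list(NULL, track))
  set.seed(123)
  seeds <- sample.int(1e6, n_rep)
  for (i in seq_len(n_rep)) {
    set.seed(seeds[i])
    truth <- model_params("two_level",
                          mu = rnorm(2, 10, 1),
                          lam = c(1, rnorm(1, 1, 0.2)),
                          var_eta = 1 / rgamma(1, 4, rate = 9),
                          cov_alpha = matrix(1 / rgamma(1, 4, rate = 6)),
                          var_gamma = 1 / rgamma(2, 4, rate = 9))
    tab <- simulate_responses(truth, sim_design("two_level", 40, 3,
                                                seed = seeds[i] + 1L))$table
    fit <- fit_aig_model(tab, priors = pr,
                         settings = mcmc_settings(2, 1600, thin = 4,
                                                  seed = seeds[i] + 2L))
    cfg <- params_to_config(truth)
    for (nm in track)
      ranks[i, nm] <- mean(fit$draws$pars[, nm] < cfg[[nm]])
  }
  for (nm in track) {
    ks <- suppressWarnings(stats::ks.test(ranks[, nm], "punif"))
    expect_gt(ks$p.value, 0.005)
    expect_gt(mean(ranks[, nm] > 0.025 & ranks[, nm] < 0.975), 0.7)
  }
})
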