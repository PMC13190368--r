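test_that("implied moments reduce to pure noise when only gamma varies", {
  p <- model_params("cross_classified", mu = c(11, 9, 7),
                    var_eta = 0, var_gamma = c(2, 3, 4))
  m <- implied_moments(p, 2)
  expect_equal(unname(m$mean), rep(c(11, 9, 7), each = 2))
  expect_equal(unname(m$within_subject_cov),
               diag(rep(c(2, 3, 4), each = 2)))
})

test_that("implied moments reproduce the reported component sums", {
  m <- implied_moments(cc_point_estimates(), 3)
  # level-1 slot variance = var_eta + var_beta_1 + var_gamma_1
  expect_equal(unname(m$within_subject_cov["r1_i1", "r1_i1"]), 15.007)
  # reference <-> level-2 covariance = lam_2 * var_eta
  expect_equal(round(m$within_subject_cov["r1_i1", "r2_i1"], 3), 6.116)
  # same level, different incidental: lam_2^2 var_eta + var_alpha_2
  expect_equal(m$within_subject_cov["r2_i1", "r2_i2"],
               0.898^2 * 6.811 + 0.530)
  # cross non-reference levels: lam_2 lam_3 var_eta + cov_alpha_23
  expect_equal(m$within_subject_cov["r2_i1", "r3_i1"],
               0.898 * 0.525 * 6.811 + 0.814 * sqrt(0.530 * 1.714))
  # cross-subject covariance on a shared incidental is the incidental variance
  expect_equal(unname(m$cross_subject_same_incidental_cov),
               c(0.160, 0.400, 0.066))
  expect_equal(unname(implied_moments(tl_point_estimates(),
                                      3)$cross_subject_same_incidental_cov),
               c(0, 0, 0))
})

test_that("implied slot variance is the exact sum of its four components", {
  set.seed(41)
  for (i in 1:20) {
    A <- matrix(rnorm(4), 2)
    p <- model_params("cross_classified",
                      mu = rnorm(3, 10, 3),
                      lam = c(1, runif(2, 0.2, 1.5)),
                      var_eta = runif(1, 0.1, 9),
                      cov_alpha = crossprod(A),
                      var_beta = runif(3, 0, 2),
                      var_gamma = runif(3, 0.1, 9))
    m <- implied_moments(p, 3)
    va <- c(0, diag(p$cov_alpha))
    expected <- unname(p$lam^2 * p$var_eta + va + p$var_beta + p$var_gamma)
    expect_equal(unname(diag(m$within_subject_cov)),
                 rep(expected, each = 3), tolerance = 1e-12)
    S <- m$within_subject_cov
    expect_equal(S, t(S))
    expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("invalid parameter sets are rejected", {
  expect_error(model_params("cross_classified", mu = c(1, 2, 3),
                            var_eta = -1, var_gamma = c(1, 1, 1)),
               "non-negative")
  expect_error(model_params("cross_classified", mu = c(1, 2, 3),
                            var_eta = 1,
                            cov_alpha = matrix(c(1, 2, 2, 1), 2),
                            var_gamma = c(1, 1, 1)),
               "semi-definite")
  expect_error(model_params("cross_classified", mu = c(1, 2),
                            lam = c(0.9, 1), var_eta = 1,
                            var_gamma = c(1, 1)),
               "reference")
  expect_error(model_params("two_level", mu = c(1, 2), var_eta = 1,
                            var_beta = c(0.5, 0), var_gamma = c(1, 1)),
               "two-level")
})

test_that("consistency coefficients match hand arithmetic and limits", {
  expect_equal(round(rcon(0.898, 6.811, 0.530), 3), 0.912)
  expect_equal(rcon(0.7, 4, 0), 1)
  expect_equal(rcon(0, 4, 2), 0)
  expect_equal(round(l2con(6.811, 0.160), 3), 0.977)
  expect_equal(round(l2con(0.898^2 * 6.811 + 0.530, 0.400), 3), 0.938)
  expect_equal(l2con(3.7, 0), 1)
  expect_equal(round(l1con(5.339, 0, 7.813, "two_level"), 3), 0.406)
  expect_equal(round(l1con(6.811, 0.160, 8.036), 3), 0.454)
  expect_equal(l1con(2.2, 0, 0), 1)
})

test_that("degenerate and design-mismatched coefficients raise typed errors", {
  expect_error(rcon(0, 4, 0), class = "nst_undefined_coefficient")
  expect_error(l2con(0, 0), class = "nst_undefined_coefficient")
  expect_error(l1con(0, 0, 0), class = "nst_undefined_coefficient")
  expect_error(l2con(5, 0.1, design = "two_level"),
               class = "nst_design_mismatch")
})

test_that("coefficient invariants hold across random parameter draws", {
  set.seed(92)
  for (i in 1:50) {
    sv <- runif(1, 0.05, 10)
    vb <- runif(1, 0, 3)
    vg <- runif(1, 0.01, 10)
    c2 <- l2con(sv, vb)
    c1 <- l1con(sv, vb, vg)
    expect_true(c1 >= 0 && c1 <= 1 && c2 >= 0 && c2 <= 1)
    expect_lte(c1, c2)
  }
  # monotonicity
  r_vals <- vapply(seq(0, 5, 0.5), function(va) rcon(0.9, 5, va), 0)
  expect_true(all(diff(r_vals) < 0))
  l2_vals <- vapply(seq(0, 5, 0.5), function(vb) l2con(4, vb), 0)
  expect_true(all(diff(l2_vals) < 0))
  # invariance to a constant shift of all intercepts
  p <- cc_point_estimates()
  p_shift <- p; p_shift$mu <- p$mu + 100
  expect_equal(consistency_plugin(p_shift), consistency_plugin(p))
})

test_that("per-draw consistency summaries collapse correctly on constant draws", {
  p <- cc_point_estimates()
  dm <- constant_draws_matrix(p, n = 40L)
  cons <- consistency_from_draws(make_draws(dm))
  plug <- consistency_plugin(p)
  merged <- merge(cons, plug, by = c("coefficient", "level"))
  expect_equal(merged$median, merged$value)
  expect_equal(merged$lower, merged$value)
  expect_equal(merged$upper, merged$value)
})

test_that("per-draw consistency matches a brute-force loop over draws", {
  set.seed(7)
  n <- 300L
  pars <- cbind(
    "mu.1" = rnorm(n, 11), "mu.2" = rnorm(n, 9), "mu.3" = rnorm(n, 7),
    "lam.2" = rnorm(n, 0.9, 0.05), "lam.3" = rnorm(n, 0.5, 0.05),
    "var_eta" = runif(n, 4, 9),
    "cov_alpha.2.2" = runif(n, 0.1, 1), "cov_alpha.2.3" = rnorm(n, 0.3, 0.1),
    "cov_alpha.3.3" = runif(n, 0.5, 2),
    "var_beta.1" = runif(n, 0.01, 1), "var_beta.2" = runif(n, 0.01, 1),
    "var_beta.3" = runif(n, 0.01, 1),
    "var_gamma.1" = runif(n, 4, 9), "var_gamma.2" = runif(n, 4, 9),
    "var_gamma.3" = runif(n, 4, 9))
  cons <- consistency_from_draws(make_draws(pars))

  brute <- function(coefficient, level) {
    vals <- vapply(seq_len(n), function(d) {
      va <- if (level == 1) 0 else pars[d, paste0("cov_alpha.", level, ".", level)]
      lam <- if (level == 1) 1 else pars[d, paste0("lam.", level)]
      sv <- lam^2 * pars[d, "var_eta"] + va
      switch(coefficient,
             rcon = lam^2 * pars[d, "var_eta"] / sv,
             l2con = sv / (sv + pars[d, paste0("var_beta.", level)]),
             l1con = sv / (sv + pars[d, paste0("var_beta.", level)] +
                             pars[d, paste0("var_gamma.", level)]))
    }, 0)
    stats::median(vals)
  }
  for (i in seq_len(nrow(cons)))
    expect_equal(cons$median[i], brute(cons$coefficient[i], cons$level[i]),
                 tolerance = 1e-12)
  # per-draw ordering invariant under cross-classified sampling
  dm <- attr(cons, "draws")
  for (r in 1:3)
    expect_true(all(dm[, paste0("l1con.", r)] <=
                      dm[, paste0("l2con.", r)] + 1e-12))
  expect_true(all(dm >= 0 & dm <= 1))
})

test_that("draws lacking a required parameter raise a schema error", {
  p <- cc_point_estimates()
  dm <- constant_draws_matrix(p, n = 20L)
  dm <- dm[, setdiff(colnames(dm), "var_beta.2")]
  expect_error(consistency_from_draws(make_draws(dm)),
               class = "nst_schema_error")
  # and a design flag that conflicts with the draws is refused
  expect_error(consistency_from_draws(make_draws(dm), design = "two_level"),
               class = "nst_design_mismatch")
})

test_that("parameter sets round-trip through flat JSON and YAML configs", {
  p <- cc_point_estimates()
  cfg <- params_to_config(p)
  expect_equal(cfg$`mu.1`, 11.106)
  expect_equal(cfg$`cov_alpha.2.3`, 0.814 * sqrt(0.530 * 1.714))
  p2 <- params_from_config(cfg)
  expect_equal(p2, p)
  for (ext in c("json", "yaml")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_params(p, path)
    expect_equal(read_params(path), p, tolerance = 1e-9)
  }
  # two-level round trip has no var_beta keys
  cfg2 <- params_to_config(tl_point_estimates())
  expect_false(any(grepl("^var_beta", names(cfg2))))
  expect_equal(params_from_config(cfg2), tl_point_estimates())
})
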