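# Shared fixtures: parameter sets at the reported posterior medians of the
# figural short-term memory studies, and small helpers for building draw
# objects by hand.

cc_point_estimates <- function() {
  model_params(
    design = "cross_classified",
    mu = c(11.106, 9.358, 7.351),
    lam = c(1, 0.898, 0.525),
    var_eta = 6.811,
    cov_alpha = {
      cov23 <- 0.814 * sqrt(0.530 * 1.714)  # from the reported correlation
      matrix(c(0.530, cov23, cov23, 1.714), 2, 2)
    },
    var_beta = c(0.160, 0.400, 0.066),
    var_gamma = c(8.036, 6.508, 5.133))
}

tl_point_estimates <- function() {
  model_params(
    design = "two_level",
    mu = c(11.331, 9.702, 7.655),
    lam = c(1, 0.916, 0.598),
    var_eta = 5.339,
    cov_alpha = {
      cov23 <- 0.827 * sqrt(0.474 * 1.492)
      matrix(c(0.474, cov23, cov23, 1.492), 2, 2)
    },
    var_gamma = c(7.813, 6.292, 5.365))
}

# hand-built draws object (three radical levels, reference level 1)
make_draws <- function(pars, design = "cross_classified",
                       n_radicals = 3L, chains = 1L) {
  n <- nrow(pars)
  structure(list(pars = pars,
                 chain = rep(seq_len(chains), each = n / chains),
                 iteration = rep(seq_len(n / chains), chains),
                 design = design, n_radicals = n_radicals,
                 reference_level = 1L,
                 latent_beta = NULL, incidentals = NULL),
            class = "nst_draws")
}

# draws matrix with every model parameter constant at the values of `params`
constant_draws_matrix <- function(params, n = 50L) {
  cfg <- params_to_config(params)
  cfg <- cfg[setdiff(names(cfg), c("design", "reference_level"))]
  nm <- names(cfg)
  # duplicate upper-triangle covariance keys into the draw naming scheme
  m <- matrix(rep(unlist(cfg), each = n), nrow = n,
              dimnames = list(NULL, nm))
  m
}

quick_settings <- function(seed = 1L, n_iter = 1000L, n_chains = 2L)
  mcmc_settings(n_chains = n_chains, n_iter = n_iter, seed = seed)
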