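#' Parameter-recovery experiment
#'
#' Repeatedly simulates data from a known parameter set, fits the matching
#' model, and records whether each 95% equal-tailed credibility interval
#' covers the generating value. With a correctly implemented sampler the
#' per-parameter coverage should be close to the nominal 95%.
#'
#' @param params Generating [model_params()].
#' @param n_subjects,n_incidentals_per_level Design sizes for each replicate.
#' @param n_replicates Number of simulate-and-fit replicates (default 10).
#' @param settings An [mcmc_settings()] object; its seed is combined with the
#'   replicate index so replicates are independent but reproducible.
#' @param priors An [priors()] object.
#' @param seed Master seed.
#' @return A list with `coverage` (data frame: parameter, truth, times
#'   covered, n_replicates) and `details` (per-replicate summary rows).
#' @export
recovery_experiment <- function(params, n_subjects, n_incidentals_per_level = 3L,
                                n_replicates = 10L,
                                settings = mcmc_settings(),
                                priors = noisestab::priors(),
                                seed = 1L) {
  truth <- params_to_config(params)
  truth <- truth[setdiff(names(truth), c("design", "reference_level"))]
  details <- list()
  for (rep in seq_len(n_replicates)) {
    sim <- sim_design(params$design, n_subjects, n_incidentals_per_level,
                      seed = seed + 1000L * rep)
    table <- simulate_responses(params, sim)$table
    st <- settings
    st$seed <- seed + 1000L * rep + 1L
    fit <- fit_aig_model(table, priors = priors, settings = st,
                         design = params$design,
                         reference_level = params$reference_level,
                         store_latent_beta = FALSE)
    s <- fit$summary
    s <- s[s$parameter %in% names(truth), ]
    s$truth <- unlist(truth[s$parameter])
    s$covered <- s$lower <= s$truth & s$truth <= s$upper
    s$replicate <- rep
    s$max_psrf <- max(fit$convergence$psrf)
    details[[rep]] <- s
  }
  det <- do.call(rbind, details)
  cov <- stats::aggregate(covered ~ parameter, det, sum)
  cov$truth <- unlist(truth[cov$parameter])
  cov$n_replicates <- n_replicates
  list(coverage = cov[, c("parameter", "truth", "covered", "n_replicates")],
       details = det)
}
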