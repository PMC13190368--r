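#' Prior specification for the Gibbs sampler
#'
#' Conjugate, weakly informative defaults: normal(0, 1e6) priors for the
#' intercepts and the free loadings, inverse-gamma(0.001, 0.001) for every
#' scalar variance, and an inverse-Wishart with `R` degrees of freedom and an
#' identity scale for the radical-effect covariance (dimension = number of
#' non-reference levels). All are overridable.
#'
#' @param mu_mean,mu_var Normal prior for each intercept.
#' @param lam_mean,lam_var Normal prior for each free loading.
#' @param ig_shape,ig_scale Inverse-gamma shape and scale for the scalar
#'   variances.
#' @param iw_df,iw_scale Inverse-Wishart degrees of freedom and scale matrix
#'   for the radical-effect covariance; `NULL` (default) resolves at fit time
#'   to the number of radical levels and the identity matrix.
#' @return An object of class `nst_priors`.
#' @export
priors <- function(mu_mean = 0, mu_var = 1e6,
                   lam_mean = 0, lam_var = 1e6,
                   ig_shape = 0.001, ig_scale = 0.001,
                   iw_df = NULL, iw_scale = NULL) {
  if (mu_var <= 0 || lam_var <= 0 || ig_shape <= 0 || ig_scale <= 0)
    stop("prior variances and inverse-gamma hyperparameters must be positive")
  structure(list(mu_mean = mu_mean, mu_var = mu_var,
                 lam_mean = lam_mean, lam_var = lam_var,
                 ig_shape = ig_shape, ig_scale = ig_scale,
                 iw_df = iw_df, iw_scale = iw_scale),
            class = "nst_priors")
}

#' MCMC settings
#'
#' @param n_chains Number of chains (>= 2, so the potential scale reduction
#'   factor is defined). Default 3.
#' @param n_iter Iterations per chain (default 20000).
#' @param warmup_fraction Fraction of each chain discarded as warm-up
#'   (default 0.5, i.e. the first half).
#' @param thin Thinning interval (>= 1).
#' @param seed Integer seed; identical seed and settings give bit-identical
#'   draws.
#' @return An object of class `nst_mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 3L, n_iter = 20000L,
                          warmup_fraction = 0.5, thin = 1L, seed = 1L) {
  n_chains <- as.integer(n_chains); n_iter <- as.integer(n_iter)
  thin <- as.integer(thin)
  if (n_chains < 2L) stop("`n_chains` must be at least 2")
  if (thin < 1L) stop("`thin` must be at least 1")
  if (warmup_fraction < 0 || warmup_fraction >= 1)
    stop("`warmup_fraction` must be in [0, 1)")
  retained <- floor(n_iter * (1 - warmup_fraction) / thin)
  if (retained < 100L)
    stop("settings retain fewer than 100 draws per chain")
  structure(list(n_chains = n_chains, n_iter = n_iter,
                 warmup_fraction = warmup_fraction, thin = thin,
                 seed = as.integer(seed)),
            class = "nst_mcmc_settings")
}

#' Fit an AIG measurement model by blocked Gibbs sampling
#'
#' Estimates the cross-classified or two-level measurement model on a
#' long-format response table by cycling through the conjugate full
#' conditionals: per-subject ability \eqn{\eta_s} (normal), the per-subject
#' radical-effect block \eqn{(\alpha_{s2},\dots)} (multivariate normal),
#' incidental effects \eqn{\beta_{ir}} (normal; cross-classified only), the
#' intercepts \eqn{\mu_r} (normal), the free loadings \eqn{\lambda_r}
#' (normal, a regression on the current abilities), the scalar variances
#' (inverse gamma) and the radical-effect covariance (inverse Wishart). The
#' loading at the reference level is fixed to 1 on every iteration, which
#' resolves the scale and sign indeterminacy of \eqn{\eta}. Missing scores
#' contribute no likelihood terms (rows are omitted; missing at random).
#'
#' Chains are initialized at the per-level sample means (intercepts),
#' loadings 1, half the per-level sample variance (variances), and latent
#' values 0, overdispersed by chain-specific jitter (additive normal with
#' scale 0.5 for location parameters, log-normal with scale 0.5 for
#' variances) so the scale-reduction diagnostic is honest.
#'
#' @param table A response table (see [simulate_responses()] or
#'   [read_response_table()]).
#' @param priors An [priors()] object.
#' @param settings An [mcmc_settings()] object.
#' @param design Sampling design; defaults to the table's `design` attribute.
#' @param reference_level Radical level whose loading is fixed at 1.
#' @param fix_loadings If `TRUE`, all loadings are constrained to 1 and never
#'   updated (useful for comparing against closed-form moment estimators on
#'   balanced data).
#' @param store_latent_beta Keep the per-draw incidental effects (needed by
#'   [bppc()]; cross-classified only). Default `TRUE`.
#' @param n_radicals,n_subjects Structural dimensions, only required when
#'   `table` has zero rows (prior-sampling mode used to verify that with no
#'   data the sampler reproduces its priors).
#' @return An object of class `nst_fit`: list with `draws` (`nst_draws`),
#'   `summary` (per-parameter posterior median and 95% equal-tailed interval,
#'   from [posterior_summary()]), `convergence` (per-parameter PSRF, from
#'   [psrf()]), `priors`, `settings`, and `data_info`.
#' @export
fit_aig_model <- function(table, priors = noisestab::priors(),
                          settings = mcmc_settings(),
                          design = NULL, reference_level = 1L,
                          fix_loadings = FALSE, store_latent_beta = TRUE,
                          n_radicals = NULL, n_subjects = NULL) {
  stopifnot(inherits(priors, "nst_priors"),
            inherits(settings, "nst_mcmc_settings"))
  if (is.null(design)) design <- attr(table, "design")
  if (is.null(design)) stop("`design` must be given or carried by the table")
  design <- match.arg(design, c("cross_classified", "two_level"))
  cross <- design == "cross_classified"

  table <- table[!is.na(table$score), , drop = FALSE]  # MAR row omission
  n <- nrow(table)
  if (n == 0L) {
    if (is.null(n_radicals) || is.null(n_subjects))
      stop("an empty table needs explicit `n_radicals` and `n_subjects`")
    R <- as.integer(n_radicals); N <- as.integer(n_subjects)
    subjects <- subject_ids(N)
    incidentals <- data.frame(incidental_id = character(0),
                              radical_level = integer(0))
    sub0 <- integer(0); lev0 <- integer(0); inc0 <- integer(0)
    y <- numeric(0)
  } else {
    if (!is.numeric(table$score)) stop("scores must be numeric")
    R <- if (is.null(n_radicals)) max(table$radical_level)
         else as.integer(n_radicals)
    subjects <- sort(unique(table$subject_id))
    N <- length(subjects)
    if (N < 2L)
      stop("degenerate design: at least 2 subjects are required")
    for (r in seq_len(R))
      if (!any(table$radical_level == r))
        stop("degenerate design: no observations for radical level ", r)
    if (stats::var(table$score) == 0)
      stop("degenerate design: all scores are constant")
    y <- as.numeric(table$score)
    sub0 <- match(table$subject_id, subjects) - 1L
    lev0 <- as.integer(table$radical_level) - 1L
    incidentals <- unique(table[, c("incidental_id", "radical_level")])
    incidentals <- incidentals[order(incidentals$radical_level,
                                     incidentals$incidental_id), ]
    rownames(incidentals) <- NULL
    inc0 <- match(table$incidental_id, incidentals$incidental_id) - 1L
  }
  ref <- as.integer(reference_level)
  if (ref < 1L || ref > R) stop("`reference_level` must index a radical level")
  q <- R - 1L
  nonref <- setdiff(seq_len(R), ref)

  iw_df <- priors$iw_df %||% R
  iw_scale <- priors$iw_scale %||% diag(max(q, 1L))
  if (q > 0L && iw_df <= q - 1)
    stop("inverse-Wishart degrees of freedom must exceed ", q - 1,
         " for a proper prior")
  cprior <- list(mu_mean = priors$mu_mean, mu_var = priors$mu_var,
                 lam_mean = priors$lam_mean, lam_var = priors$lam_var,
                 ig_shape = priors$ig_shape, ig_scale = priors$ig_scale,
                 iw_df = iw_df, iw_scale = as.matrix(iw_scale))

  # initialization from per-level sample moments
  mu0 <- vapply(seq_len(R), function(r) {
    v <- y[lev0 + 1L == r]
    if (length(v)) mean(v) else priors$mu_mean
  }, 0)
  v0 <- vapply(seq_len(R), function(r) {
    v <- y[lev0 + 1L == r]
    if (length(v) > 1L) stats::var(v) else 1
  }, 0)
  v0[v0 <= 0] <- 1

  n_warmup <- as.integer(floor(settings$n_iter * settings$warmup_fraction))
  n_keep <- (settings$n_iter - n_warmup) %/% settings$thin

  par_names <- c(paste0("mu.", seq_len(R)),
                 if (!fix_loadings) paste0("lam.", nonref),
                 "var_eta",
                 if (q > 0L) {
                   nm <- character(0)
                   for (a in seq_along(nonref)) for (b in seq_along(nonref))
                     if (a <= b) nm <- c(nm, paste0("cov_alpha.", nonref[a],
                                                    ".", nonref[b]))
                   nm
                 },
                 if (cross) paste0("var_beta.", seq_len(R)),
                 paste0("var_gamma.", seq_len(R)))

  set.seed(settings$seed)
  pars_list <- vector("list", settings$n_chains)
  beta_list <- vector("list", settings$n_chains)
  jitters <- 0L
  for (ch in seq_len(settings$n_chains)) {
    init <- list(
      mu = mu0 + stats::rnorm(R, 0, 0.5),
      lam = {
        l <- rep(1, R)
        if (!fix_loadings && q > 0L)
          l[nonref] <- 1 + stats::rnorm(q, 0, 0.5)
        l
      },
      var_eta = 0.5 * v0[ref] * exp(stats::rnorm(1, 0, 0.5)),
      var_beta = 0.1 * v0 * exp(stats::rnorm(R, 0, 0.5)),
      var_gamma = 0.5 * v0 * exp(stats::rnorm(R, 0, 0.5)),
      cov_alpha = diag(0.25 * v0[nonref] * exp(stats::rnorm(max(q, 1L), 0, 0.5)),
                       nrow = max(q, 1L)))
    res <- .gibbs_chain(y, sub0, lev0, inc0,
                        as.integer(incidentals$radical_level) - 1L,
                        N, R, nrow(incidentals), cross, ref - 1L,
                        cprior, init,
                        settings$n_iter, n_warmup, settings$thin,
                        fix_loadings, store_latent_beta)
    pars <- res$pars
    colnames(pars) <- par_names
    if (fix_loadings && q > 0L) {
      lamc <- matrix(1, nrow(pars), q,
                     dimnames = list(NULL, paste0("lam.", nonref)))
      pars <- cbind(pars, lamc)
    }
    pars_list[[ch]] <- pars
    if (store_latent_beta && cross) {
      colnames(res$beta) <- incidentals$incidental_id
      beta_list[[ch]] <- res$beta
    }
    jitters <- jitters + res$jitter_retries
  }
  if (jitters > 0L)
    message("inverse-Wishart step needed ", jitters,
            " jittered retries to stay positive definite")

  pars <- do.call(rbind, pars_list)
  # derived radical-effect correlations, clipped to [-1, 1]
  if (q > 1L) {
    for (a in seq_along(nonref)) for (b in seq_along(nonref)) {
      if (a >= b) next
      ra <- nonref[a]; rb <- nonref[b]
      rho <- pars[, paste0("cov_alpha.", ra, ".", rb)] /
        sqrt(pars[, paste0("cov_alpha.", ra, ".", ra)] *
             pars[, paste0("cov_alpha.", rb, ".", rb)])
      pars <- cbind(pars, pmin(1, pmax(-1, rho)))
      colnames(pars)[ncol(pars)] <- paste0("rho_alpha.", ra, ".", rb)
    }
  }

  draws <- structure(
    list(pars = pars,
         chain = rep(seq_len(settings$n_chains), each = n_keep),
         iteration = rep(seq_len(n_keep), settings$n_chains),
         design = design, n_radicals = R, reference_level = ref,
         latent_beta = if (store_latent_beta && cross)
           do.call(rbind, beta_list) else NULL,
         incidentals = incidentals),
    class = "nst_draws")

  structure(
    list(draws = draws,
         summary = posterior_summary(draws),
         convergence = psrf(draws),
         priors = priors, settings = settings,
         data_info = list(design = design, n_subjects = N, n_rows = n,
                          n_radicals = R, reference_level = ref,
                          subjects = subjects, incidentals = incidentals)),
    class = "nst_fit")
}

#' @export
print.nst_fit <- function(x, ...) {
  cat("AIG measurement-model fit (", x$data_info$design, "): ",
      x$data_info$n_subjects, " subjects, ", x$data_info$n_rows,
      " scores, ", x$settings$n_chains, " chains x ", x$settings$n_iter,
      " iterations\n", sep = "")
  s <- merge(x$summary, x$convergence, by = "parameter", sort = FALSE)
  print(s, digits = 4, row.names = FALSE)
  invisible(x)
}

chain_matrices <- function(draws) {
  if (inherits(draws, "nst_draws"))
    return(lapply(split(seq_along(draws$chain), draws$chain),
                  function(i) draws$pars[i, , drop = FALSE]))
  if (is.list(draws) && all(vapply(draws, is.matrix, TRUE))) return(draws)
  stop("`draws` must be an nst_draws object or a list of per-chain matrices")
}

#' Potential scale reduction factor (Gelman-Rubin)
#'
#' The standard between/within-chain variance ratio: with `m` chains of `n`
#' retained draws each, \eqn{W} the mean within-chain variance and \eqn{B/n}
#' the variance of the chain means, the estimate is
#' \eqn{\sqrt{((n-1)/n\,W + B/n)/W}}, floored at 1 (the formula can dip a
#' hair below 1 when the chains agree more than chance would have it).
#' Values below 1.1 are conventionally taken as converged.
#'
#' @param draws An `nst_draws` object, or a list of per-chain draw matrices
#'   with identical column names.
#' @return A data frame with columns `parameter` and `psrf`.
#' @export
psrf <- function(draws) {
  chains <- chain_matrices(draws)
  m <- length(chains)
  if (m < 2L) stop("PSRF requires at least 2 chains")
  n <- nrow(chains[[1]])
  if (n < 10L) stop("PSRF requires at least 10 retained draws per chain")
  pn <- colnames(chains[[1]])
  vals <- vapply(pn, function(p) {
    x <- vapply(chains, function(cm) cm[, p], numeric(n))  # n x m
    W <- mean(apply(x, 2, stats::var))
    B <- n * stats::var(colMeans(x))
    if (W <= 0) return(1)
    max(1, sqrt(((n - 1) / n * W + B / n) / W))
  }, 0)
  data.frame(parameter = pn, psrf = unname(vals))
}

#' Posterior summary: median and 95% equal-tailed credibility interval
#'
#' Pools retained draws across chains and reports, per parameter, the
#' posterior mean, median and the 2.5% / 97.5% empirical quantiles
#' (equal-tailed interval; `stats::quantile` type 7).
#'
#' @param draws An `nst_draws` object or a draw matrix with named columns.
#' @param prob Interval mass (default 0.95).
#' @return A data frame with columns `parameter`, `mean`, `median`, `lower`,
#'   `upper`.
#' @export
posterior_summary <- function(draws, prob = 0.95) {
  pars <- if (inherits(draws, "nst_draws")) draws$pars else as.matrix(draws)
  if (nrow(pars) == 0L) stop("no draws to summarize")
  qs <- c((1 - prob) / 2, 0.5, 1 - (1 - prob) / 2)
  qm <- t(apply(pars, 2, stats::quantile, probs = qs, names = FALSE))
  data.frame(parameter = colnames(pars),
             mean = unname(colMeans(pars)),
             median = qm[, 2], lower = qm[, 1], upper = qm[, 3],
             row.names = NULL)
}
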