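#' Bayesian posterior predictive check via chi-square discrepancies
#'
#' For a subsample of retained draws (default 500, evenly spaced), computes
#' the likelihood-ratio chi-square discrepancy of the data against the
#' draw's parameters: with incidental effects conditioned on their current
#' posterior draws, subjects are independent multivariate normals over their
#' item slots, so
#' \deqn{\chi^2(\mathrm{data};\theta) = -2\log L(\mathrm{data};\theta)
#'  + 2\log L(\mathrm{data};\widehat{\mathrm{sat}}),}
#' where the saturated reference fits an unrestricted mean vector and
#' covariance matrix per slot pattern (groups too small to support a
#' saturated estimate contribute their model log-likelihood alone, equally on
#' both sides). A replicated dataset of identical design is simulated from
#' the same draw (incidental effects held fixed) and the difference
#' \eqn{\Delta\chi^2 = \chi^2(\mathrm{obs}) - \chi^2(\mathrm{rep})} is
#' recorded. The posterior predictive p-value is the fraction of draws whose
#' replicated discrepancy is at least the observed one; values near 0.5
#' indicate good fit, values near 0 or 1 indicate misfit.
#'
#' The sign convention is observed-minus-replicated; the result also carries
#' the opposite sign so either convention can be read off directly. Like any
#' second-moment discrepancy, the check is sensitive to violations of the
#' implied mean and covariance structure, not to pure distributional-shape
#' violations that leave those moments intact.
#'
#' @param fit An `nst_fit` produced from `table`'s design (cross-classified
#'   fits must have been run with `store_latent_beta = TRUE`).
#' @param table The response table the model was fit to.
#' @param seed Integer seed for the replicated datasets.
#' @param n_draws Number of retained draws to evaluate (evenly spaced;
#'   default 500). At least 100 retained draws must be available.
#' @return An object of class `nst_ppc`: list with `delta_draws`
#'   (observed minus replicated discrepancies), `mean_delta`, `interval_95`,
#'   `mean_delta_rep_minus_obs`, `ppp`, and `n_draws_used`.
#' @export
bppc <- function(fit, table, seed = 1L, n_draws = 500L) {
  stopifnot(inherits(fit, "nst_fit"))
  design <- fit$data_info$design
  tdesign <- attr(table, "design")
  if (!is.null(tdesign) && !identical(tdesign, design))
    stop(errorCondition(
      paste0("fit design (", design, ") does not match table design (",
             tdesign, ")"),
      class = c("nst_design_mismatch", "error")))
  cross <- design == "cross_classified"
  draws <- fit$draws
  n_total <- nrow(draws$pars)
  if (n_total < 100L) stop("too few retained draws for a predictive check")
  if (cross && is.null(draws$latent_beta))
    stop("cross-classified predictive checks need stored incidental-effect draws")

  table <- table[!is.na(table$score), , drop = FALSE]
  R <- fit$data_info$n_radicals
  ref <- fit$data_info$reference_level
  nonref <- setdiff(seq_len(R), ref)
  q <- length(nonref)

  # per-subject blocks, rows ordered by level then incidental
  ord <- order(table$subject_id, table$radical_level, table$incidental_id)
  table <- table[ord, , drop = FALSE]
  idx_by_subject <- split(seq_len(nrow(table)), table$subject_id)
  patt_key <- vapply(idx_by_subject, function(i)
    paste(table$radical_level[i], collapse = ","), "")
  groups <- split(idx_by_subject, patt_key)

  use <- unique(round(seq(1, n_total, length.out = min(n_draws, n_total))))
  y <- table$score
  lev <- table$radical_level
  beta_cols <- if (cross) match(table$incidental_id,
                                colnames(draws$latent_beta)) else NULL

  p <- draws$pars
  lam_of <- function(d) {
    l <- rep(1, R)
    for (r in nonref) l[r] <- p[d, paste0("lam.", r)]
    l
  }
  cov_of <- function(d) {
    ca <- matrix(0, R, R)
    for (a in seq_along(nonref)) for (b in seq_along(nonref)) {
      ra <- nonref[a]; rb <- nonref[b]
      ca[ra, rb] <- ca[rb, ra] <-
        p[d, paste0("cov_alpha.", min(ra, rb), ".", max(ra, rb))]
    }
    ca
  }

  # -2 log-likelihood of centred per-subject score vectors under the draw's
  # implied covariance
  neg2ll_model <- function(scores, lam, ca, var_eta, var_gamma) {
    D <- 0
    for (g in groups) {
      rows1 <- g[[1]]
      rl <- lev[rows1]
      k <- length(rl)
      S <- outer(lam[rl], lam[rl]) * var_eta + ca[rl, rl, drop = FALSE]
      diag(S) <- diag(S) + var_gamma[rl]
      U <- chol(S)
      logdet <- 2 * sum(log(diag(U)))
      E <- t(vapply(g, function(i) scores[i], numeric(k)))
      Z <- E %*% backsolve(U, diag(k))
      quad <- rowSums(Z^2)
      D <- D + sum(k * log(2 * pi) + logdet + quad)
    }
    D
  }

  # -2 log-likelihood of the saturated per-pattern MVN (free mean and
  # covariance, ML divisor n); groups too small for a saturated estimate
  # contribute 0 here and their model term alone on both sides
  neg2ll_saturated <- function(raw_scores) {
    D <- 0
    for (g in groups) {
      k <- length(g[[1]])
      n_g <- length(g)
      if (n_g < k + 2L) next
      E <- t(vapply(g, function(i) raw_scores[i], numeric(k)))
      E <- sweep(E, 2, colMeans(E))
      Sml <- crossprod(E) / n_g
      ld <- determinant(Sml, logarithm = TRUE)
      if (ld$sign <= 0) next
      D <- D + n_g * (k * log(2 * pi) + as.numeric(ld$modulus) + k)
    }
    D
  }
  sat_obs <- neg2ll_saturated(y)

  set.seed(as.integer(seed))
  delta <- numeric(length(use))
  rep_ge_obs <- logical(length(use))
  nr <- nrow(table)
  subj <- match(table$subject_id, names(idx_by_subject))
  N <- length(idx_by_subject)
  for (j in seq_along(use)) {
    d <- use[j]
    lam <- lam_of(d)
    ca <- cov_of(d)
    var_eta <- p[d, "var_eta"]
    var_gamma <- vapply(seq_len(R), function(r) p[d, paste0("var_gamma.", r)], 0)
    mu <- vapply(seq_len(R), function(r) p[d, paste0("mu.", r)], 0)
    mean_row <- mu[lev] + if (cross) draws$latent_beta[d, beta_cols] else 0
    chi2_obs <- neg2ll_model(y - mean_row, lam, ca, var_eta, var_gamma) -
      sat_obs

    # replicate data of identical design from this draw (beta held fixed;
    # within a slot pattern the row means are column-constant, so the
    # saturated term may be evaluated on the centred replicate directly)
    eta <- stats::rnorm(N, 0, sqrt(var_eta))
    alpha <- matrix(0, N, R)
    if (q > 0L)
      alpha[, nonref] <- matrix(stats::rnorm(N * q), N) %*%
        chol_psd(ca[nonref, nonref, drop = FALSE])
    y_rep_centered <- lam[lev] * eta[subj] + alpha[cbind(subj, lev)] +
      stats::rnorm(nr) * sqrt(var_gamma[lev])
    chi2_rep <- neg2ll_model(y_rep_centered, lam, ca, var_eta, var_gamma) -
      neg2ll_saturated(y_rep_centered)

    delta[j] <- chi2_obs - chi2_rep
    rep_ge_obs[j] <- chi2_rep >= chi2_obs
  }
  structure(
    list(delta_draws = delta,
         mean_delta = mean(delta),
         interval_95 = unname(stats::quantile(delta, c(0.025, 0.975))),
         mean_delta_rep_minus_obs = -mean(delta),
         ppp = mean(rep_ge_obs),
         n_draws_used = length(use),
         convention = "delta = chi2(observed) - chi2(replicated)"),
    class = "nst_ppc")
}

#' @export
print.nst_ppc <- function(x, ...) {
  cat("Posterior predictive check (", x$n_draws_used, " draws)\n", sep = "")
  cat(sprintf("  M(delta) = %.3f  95%% interval = [%.3f, %.3f]  (%s)\n",
              x$mean_delta, x$interval_95[1], x$interval_95[2], x$convention))
  cat(sprintf("  posterior predictive p = %.3f\n", x$ppp))
  invisible(x)
}

summarize_contrast <- function(name, d) {
  ci <- unname(stats::quantile(d, c(0.025, 0.975)))
  data.frame(name = name, median = stats::median(d),
             lower = ci[1], upper = ci[2],
             excludes_zero = ci[1] > 0 || ci[2] < 0)
}

#' Posterior contrasts between radical-level intercepts
#'
#' Per-draw pairwise differences \eqn{\mu_r - \mu_{r'}} for all `r < r'`,
#' summarized as median and 95% equal-tailed interval; a difference is
#' flagged significant when the interval excludes zero.
#'
#' @param fit An `nst_fit`.
#' @return A data frame with one row per pair (`name`, `median`, `lower`,
#'   `upper`, `excludes_zero`), with the per-draw difference matrix attached
#'   as attribute `"draws"`.
#' @export
intercept_contrasts <- function(fit) {
  stopifnot(inherits(fit, "nst_fit"))
  R <- fit$data_info$n_radicals
  if (R < 2L) stop("intercept contrasts need at least 2 radical levels")
  p <- fit$draws$pars
  out <- list(); dm <- list()
  for (r in seq_len(R - 1L)) for (rp in (r + 1L):R) {
    d <- p[, paste0("mu.", r)] - p[, paste0("mu.", rp)]
    nm <- paste0("mu", r, "_minus_mu", rp)
    out[[nm]] <- summarize_contrast(nm, d)
    dm[[nm]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "draws") <- do.call(cbind, dm)
  res
}

#' Posterior differences of shared parameters across two independent fits
#'
#' Forms the posterior distribution of \eqn{\theta_A - \theta_B} for
#' parameters present in both fits by randomly pairing equal-length
#' subsamples of the two (independent) sets of draws without replacement.
#'
#' @param fit_a,fit_b Fits from independent samples.
#' @param param_names Character vector of draw-column names present in both
#'   fits (e.g. `"var_eta"`, `"var_gamma.1"`, `"lam.2"`).
#' @param seed Integer seed governing the random pairing.
#' @return A data frame as in [intercept_contrasts()], one row per parameter,
#'   with the per-draw differences attached as attribute `"draws"`.
#' @export
cross_model_differences <- function(fit_a, fit_b, param_names, seed = 1L) {
  stopifnot(inherits(fit_a, "nst_fit"), inherits(fit_b, "nst_fit"))
  pa <- fit_a$draws$pars; pb <- fit_b$draws$pars
  miss <- setdiff(param_names, intersect(colnames(pa), colnames(pb)))
  if (length(miss))
    stop(errorCondition(
      paste0("unknown parameter(s): ", paste(miss, collapse = ", ")),
      class = c("nst_schema_error", "error")))
  n <- min(nrow(pa), nrow(pb))
  set.seed(as.integer(seed))
  ia <- sample.int(nrow(pa), n)
  ib <- sample.int(nrow(pb), n)
  out <- list(); dm <- list()
  for (nm in param_names) {
    d <- pa[ia, nm] - pb[ib, nm]
    key <- paste0(nm, "_a_minus_b")
    out[[key]] <- summarize_contrast(key, d)
    dm[[key]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "draws") <- do.call(cbind, dm)
  res
}

#' Welch two-sample and one-sample t-tests
#'
#' Thin wrappers around [stats::t.test()]: `welch_t` performs the two-sample
#' test without the homoscedasticity assumption (Welch-Satterthwaite degrees
#' of freedom), `one_sample_t` tests a sample mean against `mu0`. Both
#' two-sided.
#'
#' @param x,y Numeric samples (at least 2 observations each).
#' @param mu0 Null value for the one-sample test.
#' @return A list with elements `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples need at least 2 observations")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("both samples have zero variance; the Welch statistic is undefined")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' @rdname welch_t
#' @export
one_sample_t <- function(x, mu0) {
  if (length(x) < 2L) stop("the sample needs at least 2 observations")
  if (stats::var(x) == 0) stop("zero-variance sample; t is undefined")
  ht <- stats::t.test(x, mu = mu0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
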