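#' Consistency coefficients of the AIG measurement models
#'
#' Three relative variance components quantify, per radical level, how much of
#' the observed-score variance is subject-level signal:
#' \describe{
#'   \item{RCon}{\eqn{\lambda_r^2\sigma_\eta^2 / (\lambda_r^2\sigma_\eta^2 +
#'     \sigma_{\alpha r}^2)}: the consistency with which ability variance at
#'     the reference radical level re-manifests at a non-reference level.}
#'   \item{L2Con}{\eqn{(\lambda_r^2\sigma_\eta^2 + \sigma_{\alpha r}^2) /
#'     (\lambda_r^2\sigma_\eta^2 + \sigma_{\alpha r}^2 + \sigma_{\beta r}^2)}:
#'     subject-level variance relative to all level-2 variance; only
#'     meaningful under cross-classified sampling, where incidental effects
#'     are estimable.}
#'   \item{L1Con}{subject-level variance relative to total observed variance
#'     \eqn{\lambda_r^2\sigma_\eta^2 + \sigma_{\alpha r}^2 + \sigma_{\beta r}^2
#'     + \sigma_{\gamma r}^2} (no \eqn{\sigma_{\beta r}^2} term under the
#'     two-level design).}
#' }
#' A zero denominator raises an undefined-coefficient error (condition class
#' `nst_undefined_coefficient`): the coefficient is 0/0, not 0.
#'
#' @param lam_r Loading of level r on the reference ability.
#' @param var_eta Reference-level ability variance.
#' @param var_alpha_r Radical-effect residual variance at level r.
#' @param subject_var_r Subject-level variance at level r, i.e.
#'   \eqn{\lambda_r^2\sigma_\eta^2 + \sigma_{\alpha r}^2}.
#' @param var_beta_r Incidental-effect variance at level r.
#' @param var_gamma_r Noise variance at level r.
#' @param design `"cross_classified"` or `"two_level"`; [l2con()] refuses the
#'   latter because the incidental variance it conditions on is not estimable
#'   there.
#' @return A proportion in `[0, 1]`.
#' @examples
#' rcon(0.898, 6.811, 0.530)          # 0.912
#' l2con(6.811, 0.160)                # 0.977
#' l1con(5.339, 0, 7.813, "two_level") # 0.406
#' @name consistency
NULL

undefined_coefficient <- function(what) {
  stop(errorCondition(
    paste0(what, " is undefined: zero denominator (0/0)"),
    class = c("nst_undefined_coefficient", "error")))
}

#' @rdname consistency
#' @export
rcon <- function(lam_r, var_eta, var_alpha_r) {
  if (var_eta < 0 || var_alpha_r < 0) stop("variances must be non-negative")
  sig <- lam_r^2 * var_eta
  den <- sig + var_alpha_r
  if (den <= 0) undefined_coefficient("RCon")
  sig / den
}

#' @rdname consistency
#' @export
l2con <- function(subject_var_r, var_beta_r, design = "cross_classified") {
  if (identical(design, "two_level"))
    stop(errorCondition(
      "L2Con is not meaningful under the two-level design: incidental effects are confounded with noise",
      class = c("nst_design_mismatch", "error")))
  if (subject_var_r < 0 || var_beta_r < 0) stop("variances must be non-negative")
  den <- subject_var_r + var_beta_r
  if (den <= 0) undefined_coefficient("L2Con")
  subject_var_r / den
}

#' @rdname consistency
#' @export
l1con <- function(subject_var_r, var_beta_r, var_gamma_r,
                  design = "cross_classified") {
  if (identical(design, "two_level") && var_beta_r != 0)
    stop(errorCondition(
      "under the two-level design var_beta is structurally zero",
      class = c("nst_design_mismatch", "error")))
  if (subject_var_r < 0 || var_beta_r < 0 || var_gamma_r < 0)
    stop("variances must be non-negative")
  den <- subject_var_r + var_beta_r + var_gamma_r
  if (den <= 0) undefined_coefficient("L1Con")
  subject_var_r / den
}

#' Plug-in consistency coefficients from a parameter set
#'
#' Evaluates RCon, L2Con and L1Con at a single parameter point (e.g. posterior
#' medians). Note that a plug-in ratio of medians generally differs in the
#' third decimal from the median of per-draw ratios computed by
#' [consistency_from_draws()]; both are exposed deliberately.
#'
#' @param params An [model_params()] object.
#' @return A data frame with columns `coefficient`, `level`, `value`.
#' @examples
#' p <- model_params("cross_classified", mu = c(11, 9, 7), lam = c(1, .898, .525),
#'                   var_eta = 6.811, cov_alpha = diag(c(0.530, 1.714)),
#'                   var_beta = c(.160, .400, .066),
#'                   var_gamma = c(8.036, 6.508, 5.133))
#' consistency_plugin(p)
#' @export
consistency_plugin <- function(params) {
  stopifnot(inherits(params, "nst_params"))
  R <- params$n_radicals
  nonref <- nonreference_levels(params)
  var_alpha <- numeric(R)
  if (length(nonref)) var_alpha[nonref] <- diag(params$cov_alpha)
  sv <- params$lam^2 * params$var_eta + var_alpha
  rows <- list()
  for (r in nonref)
    rows[[length(rows) + 1L]] <- data.frame(
      coefficient = "rcon", level = r,
      value = rcon(params$lam[r], params$var_eta, var_alpha[r]))
  if (params$design == "cross_classified")
    for (r in seq_len(R))
      rows[[length(rows) + 1L]] <- data.frame(
        coefficient = "l2con", level = r,
        value = l2con(sv[r], params$var_beta[r]))
  for (r in seq_len(R))
    rows[[length(rows) + 1L]] <- data.frame(
      coefficient = "l1con", level = r,
      value = l1con(sv[r], params$var_beta[r], params$var_gamma[r],
                    params$design))
  do.call(rbind, rows)
}

#' Posterior consistency coefficients from MCMC draws
#'
#' Evaluates each consistency coefficient on every retained posterior draw and
#' summarizes the per-draw values by their median and 95% equal-tailed
#' credibility interval. This is the summary the credibility intervals of the
#' coefficients are based on; it differs (in the third decimal, typically)
#' from plugging posterior medians into the formulas.
#'
#' @param draws An `nst_draws` object (see [fit_aig_model()]).
#' @param design Design the draws were fit under; defaults to the design
#'   recorded in `draws` and must match it.
#' @param prob Credibility-interval mass (default 0.95, equal-tailed).
#' @return A data frame of class `nst_consistency` with columns `coefficient`
#'   (`rcon`/`l2con`/`l1con`), `level`, `median`, `lower`, `upper`, plus the
#'   matrix of per-draw values as attribute `"draws"`.
#' @export
consistency_from_draws <- function(draws, design = NULL, prob = 0.95) {
  stopifnot(inherits(draws, "nst_draws"))
  if (is.null(design)) design <- draws$design
  if (!identical(design, draws$design))
    stop(errorCondition(
      paste0("draws were produced under the ", draws$design, " design"),
      class = c("nst_design_mismatch", "error")))
  R <- draws$n_radicals
  ref <- draws$reference_level
  nonref <- setdiff(seq_len(R), ref)
  p <- draws$pars
  need <- function(nm) {
    miss <- setdiff(nm, colnames(p))
    if (length(miss))
      stop(errorCondition(
        paste0("draws lack required parameters: ", paste(miss, collapse = ", ")),
        class = c("nst_schema_error", "error")))
    p[, nm, drop = FALSE]
  }
  var_eta <- need("var_eta")[, 1]
  lam <- matrix(1, nrow(p), R)
  va <- matrix(0, nrow(p), R)
  for (r in nonref) {
    lam[, r] <- need(paste0("lam.", r))[, 1]
    va[, r] <- need(paste0("cov_alpha.", r, ".", r))[, 1]
  }
  vb <- matrix(0, nrow(p), R)
  if (design == "cross_classified")
    for (r in seq_len(R)) vb[, r] <- need(paste0("var_beta.", r))[, 1]
  vg <- matrix(0, nrow(p), R)
  for (r in seq_len(R)) vg[, r] <- need(paste0("var_gamma.", r))[, 1]
  sv <- lam^2 * var_eta + va

  per_draw <- list()
  for (r in nonref)
    per_draw[[paste0("rcon.", r)]] <- (lam[, r]^2 * var_eta) / sv[, r]
  if (design == "cross_classified")
    for (r in seq_len(R))
      per_draw[[paste0("l2con.", r)]] <- sv[, r] / (sv[, r] + vb[, r])
  for (r in seq_len(R))
    per_draw[[paste0("l1con.", r)]] <- sv[, r] / (sv[, r] + vb[, r] + vg[, r])
  dm <- do.call(cbind, per_draw)
  # degenerate 0/0 draws become an explicit undefined marker, not 0
  dm[!is.finite(dm)] <- NA_real_

  qs <- c((1 - prob) / 2, 0.5, 1 - (1 - prob) / 2)
  summ <- t(apply(dm, 2, stats::quantile, probs = qs, na.rm = TRUE,
                  names = FALSE))
  parts <- strsplit(colnames(dm), ".", fixed = TRUE)
  out <- data.frame(
    coefficient = vapply(parts, `[`, "", 1L),
    level = as.integer(vapply(parts, `[`, "", 2L)),
    median = summ[, 2], lower = summ[, 1], upper = summ[, 3],
    row.names = NULL)
  attr(out, "draws") <- dm
  class(out) <- c("nst_consistency", class(out))
  out
}
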