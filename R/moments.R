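#' Model-implied moments of the observed item scores
#'
#' Computes the mean vector and within-subject covariance matrix over the item
#' slots (one slot per radical level x incidental position) implied by a
#' parameter set, together with the cross-subject covariance induced on a
#' shared incidental. Because every latent component manifesting in a score is
#' orthogonal, the implied variance of each slot is the exact sum
#' \deqn{\sigma^2_{Y_{sir}} = \lambda_r^2\sigma_\eta^2 + \sigma_{\alpha r}^2 +
#' \sigma_{\beta r}^2 + \sigma_{\gamma r}^2,}
#' and the off-diagonal entries follow from which latent components two slots
#' share: two slots of the same subject at the same level share
#' \eqn{\lambda_r^2\sigma_\eta^2 + \sigma_{\alpha r}^2}; two slots at distinct
#' non-reference levels share \eqn{\lambda_r\lambda_{r'}\sigma_\eta^2 +
#' \sigma_{\alpha_r\alpha_{r'}}}; a reference and a non-reference slot share
#' \eqn{\lambda_r\sigma_\eta^2}. Incidental effects never contribute to
#' within-subject covariances because no incidental is repeated across radical
#' levels; across subjects a shared incidental contributes
#' \eqn{\sigma_{\beta r}^2} (zero under the two-level design).
#'
#' @param params An [model_params()] object.
#' @param n_incidentals_per_level Number of incidental positions per radical
#'   level (default 3).
#' @return A list of class `nst_moments` with elements `mean` (named vector
#'   over slots, ordered by level then incidental position),
#'   `within_subject_cov` (matrix over the same slots),
#'   `cross_subject_same_incidental_cov` (per-level vector), and `slots`
#'   (data frame mapping slot to level and incidental position).
#' @examples
#' p <- model_params("cross_classified", mu = c(11, 9, 7), lam = c(1, .9, .5),
#'                   var_eta = 6.8, cov_alpha = diag(c(0.5, 1.7)),
#'                   var_beta = c(.16, .4, .07), var_gamma = c(8, 6.5, 5.1))
#' m <- implied_moments(p, 3)
#' diag(m$within_subject_cov)[1]  # Eq-8 style component sum for level 1
#' @export
implied_moments <- function(params, n_incidentals_per_level = 3L) {
  stopifnot(inherits(params, "nst_params"))
  I <- as.integer(n_incidentals_per_level)
  if (I < 1L) stop("`n_incidentals_per_level` must be at least 1")
  R <- params$n_radicals
  ref <- params$reference_level
  nonref <- nonreference_levels(params)
  # per-level alpha variance / cross-level alpha covariance, reference rows 0
  var_alpha <- numeric(R)
  cov_alpha_full <- matrix(0, R, R)
  if (length(nonref)) {
    cov_alpha_full[nonref, nonref] <- params$cov_alpha
    var_alpha <- diag(cov_alpha_full)
  }
  slots <- expand.grid(incidental = seq_len(I), level = seq_len(R))[, 2:1]
  slots <- slots[order(slots$level, slots$incidental), , drop = FALSE]
  rownames(slots) <- NULL
  slot_names <- paste0("r", slots$level, "_i", slots$incidental)
  K <- nrow(slots)
  lam <- params$lam
  S <- matrix(NA_real_, K, K, dimnames = list(slot_names, slot_names))
  for (a in seq_len(K)) for (b in seq_len(K)) {
    r <- slots$level[a]; rp <- slots$level[b]
    v <- lam[r] * lam[rp] * params$var_eta + cov_alpha_full[r, rp]
    if (a == b) v <- v + params$var_beta[r] + params$var_gamma[r]
    S[a, b] <- v
  }
  mean_vec <- stats::setNames(params$mu[slots$level], slot_names)
  cross <- if (params$design == "cross_classified") params$var_beta
           else rep(0, R)
  structure(
    list(mean = mean_vec,
         within_subject_cov = S,
         cross_subject_same_incidental_cov = stats::setNames(
           cross, paste0("r", seq_len(R))),
         slots = slots),
    class = "nst_moments")
}
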