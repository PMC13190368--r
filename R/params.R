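#' Population parameters of the AIG measurement models
#'
#' Bundles every population parameter of the cross-classified or two-level
#' classical-test-theory measurement model for automatic item generation:
#' per-radical-level intercepts \eqn{\mu_r}, loadings \eqn{\lambda_r} of each
#' level's ability on the reference-level ability \eqn{\eta_s} (the loading at
#' the reference level is fixed at 1), the subject-ability variance
#' \eqn{\sigma_\eta^2}, the covariance matrix of the radical-effect residuals
#' \eqn{\alpha_{sr}} over the non-reference levels, per-level incidental-effect
#' variances \eqn{\sigma_{\beta r}^2} (structurally zero under the two-level
#' design, where incidental effects are confounded with noise), and per-level
#' noise variances \eqn{\sigma_{\gamma r}^2}.
#'
#' @param design `"cross_classified"` or `"two_level"`.
#' @param mu Numeric vector of intercepts, one per radical level (score units).
#' @param lam Numeric vector of loadings, same length as `mu`; the entry at
#'   `reference_level` must equal 1 exactly.
#' @param var_eta Subject-ability variance at the reference level (>= 0).
#' @param cov_alpha Symmetric positive semi-definite matrix of the
#'   radical-effect residuals over the non-reference levels, in increasing
#'   level order; a scalar is accepted when there is a single non-reference
#'   level. Defaults to the zero matrix.
#' @param var_beta Per-level incidental-effect variances (>= 0). Under the
#'   two-level design all entries must be zero (the default).
#' @param var_gamma Per-level noise variances (>= 0): the confound of the
#'   subject-incidental interaction with measurement error.
#' @param reference_level Index of the reference radical level (default 1).
#'
#' @return An object of class `nst_params`.
#' @examples
#' p <- model_params(
#'   design = "cross_classified",
#'   mu = c(11.106, 9.358, 7.351),
#'   lam = c(1, 0.898, 0.525),
#'   var_eta = 6.811,
#'   cov_alpha = matrix(c(0.530, 0.776, 0.776, 1.714), 2, 2),
#'   var_beta = c(0.160, 0.400, 0.066),
#'   var_gamma = c(8.036, 6.508, 5.133)
#' )
#' p
#' @export
model_params <- function(design = c("cross_classified", "two_level"),
                         mu,
                         lam = rep(1, length(mu)),
                         var_eta,
                         cov_alpha = NULL,
                         var_beta = rep(0, length(mu)),
                         var_gamma,
                         reference_level = 1L) {
  design <- match.arg(design)
  R <- length(mu)
  if (R < 1L) stop("at least one radical level is required")
  reference_level <- as.integer(reference_level)
  if (reference_level < 1L || reference_level > R)
    stop("reference_level must index a radical level")
  if (length(lam) != R) stop("`lam` must have one entry per radical level")
  if (lam[reference_level] != 1)
    stop("the loading at the reference level must equal 1 exactly")
  if (is.null(cov_alpha)) cov_alpha <- matrix(0, R - 1L, R - 1L)
  if (is.numeric(cov_alpha) && !is.matrix(cov_alpha) && length(cov_alpha) == 1L)
    cov_alpha <- matrix(cov_alpha, 1L, 1L)
  cov_alpha <- as.matrix(cov_alpha)
  if (!all(dim(cov_alpha) == R - 1L))
    stop("`cov_alpha` must be a ", R - 1L, "x", R - 1L,
         " matrix over the non-reference levels")
  if (nrow(cov_alpha) > 0L) {
    if (max(abs(cov_alpha - t(cov_alpha))) > 1e-8 * (1 + max(abs(cov_alpha))))
      stop("`cov_alpha` must be symmetric")
    cov_alpha <- (cov_alpha + t(cov_alpha)) / 2
    ev <- eigen(cov_alpha, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(1, abs(ev)))
      stop("`cov_alpha` must be positive semi-definite")
  }
  if (length(var_beta) != R || length(var_gamma) != R)
    stop("`var_beta` and `var_gamma` must have one entry per radical level")
  if (var_eta < 0 || any(var_beta < 0) || any(var_gamma < 0))
    stop("variances must be non-negative")
  if (design == "two_level" && any(var_beta != 0))
    stop("under the two-level design `var_beta` is structurally zero: ",
         "incidental effects cannot be separated from noise")
  nonref <- setdiff(seq_len(R), reference_level)
  dimnames(cov_alpha) <- list(nonref, nonref)
  structure(
    list(design = design,
         n_radicals = R,
         mu = as.numeric(mu),
         lam = as.numeric(lam),
         var_eta = as.numeric(var_eta),
         cov_alpha = cov_alpha,
         var_beta = as.numeric(var_beta),
         var_gamma = as.numeric(var_gamma),
         reference_level = reference_level),
    class = "nst_params"
  )
}

#' @export
print.nst_params <- function(x, ...) {
  cat("AIG measurement-model parameters (", x$design, ", ",
      x$n_radicals, " radical levels, reference level ", x$reference_level,
      ")\n", sep = "")
  cat("  mu:        ", paste(format(x$mu), collapse = "  "), "\n")
  cat("  lam:       ", paste(format(x$lam), collapse = "  "), "\n")
  cat("  var_eta:   ", format(x$var_eta), "\n")
  if (x$n_radicals > 1L) {
    cat("  cov_alpha (non-reference levels ",
        paste(rownames(x$cov_alpha), collapse = ", "), "):\n", sep = "")
    print(x$cov_alpha)
  }
  if (x$design == "cross_classified")
    cat("  var_beta:  ", paste(format(x$var_beta), collapse = "  "), "\n")
  cat("  var_gamma: ", paste(format(x$var_gamma), collapse = "  "), "\n")
  invisible(x)
}

#' Indices of the non-reference radical levels
#' @param params An `nst_params` object.
#' @return Integer vector of level indices excluding the reference level.
#' @keywords internal
nonreference_levels <- function(params) {
  setdiff(seq_len(params$n_radicals), params$reference_level)
}

#' Flatten model parameters to a key-value configuration
#'
#' The flat representation uses dotted keys (`mu.1`, `lam.2`, `var_eta`,
#' `cov_alpha.2.3`, `var_beta.1`, `var_gamma.1`, `design`,
#' `reference_level`) so a parameter set can be stored as JSON or YAML and
#' diffed line by line. Loadings are stored only for the non-reference levels
#' (the reference loading is identically 1) and `cov_alpha` entries only for
#' r <= r'.
#'
#' @param params An `nst_params` object.
#' @return A named list of scalars.
#' @seealso [params_from_config()], [write_params()], [read_params()]
#' @export
params_to_config <- function(params) {
  stopifnot(inherits(params, "nst_params"))
  R <- params$n_radicals
  out <- list(design = params$design,
              reference_level = params$reference_level)
  for (r in seq_len(R)) out[[paste0("mu.", r)]] <- params$mu[r]
  for (r in nonreference_levels(params))
    out[[paste0("lam.", r)]] <- params$lam[r]
  out$var_eta <- params$var_eta
  nonref <- nonreference_levels(params)
  for (a in seq_along(nonref)) for (b in seq_along(nonref)) {
    if (a <= b)
      out[[paste0("cov_alpha.", nonref[a], ".", nonref[b])]] <-
        params$cov_alpha[a, b]
  }
  if (params$design == "cross_classified")
    for (r in seq_len(R)) out[[paste0("var_beta.", r)]] <- params$var_beta[r]
  for (r in seq_len(R)) out[[paste0("var_gamma.", r)]] <- params$var_gamma[r]
  out
}

#' Rebuild model parameters from a flat key-value configuration
#'
#' @param config Named list as produced by [params_to_config()].
#' @return An `nst_params` object.
#' @export
params_from_config <- function(config) {
  keys <- names(config)
  grab <- function(prefix) {
    k <- grep(paste0("^", prefix, "\\.[0-9]+$"), keys, value = TRUE)
    idx <- as.integer(sub(paste0("^", prefix, "\\."), "", k))
    v <- numeric(if (length(idx)) max(idx) else 0L)
    v[idx] <- unlist(config[k])
    list(idx = idx, v = v)
  }
  mu <- grab("mu")$v
  R <- length(mu)
  if (R == 0L) stop("configuration lacks `mu.<r>` keys")
  ref <- if (!is.null(config$reference_level))
    as.integer(config$reference_level) else 1L
  lam <- rep(1, R)
  lg <- grab("lam")
  lam[lg$idx] <- lg$v[lg$idx]
  nonref <- setdiff(seq_len(R), ref)
  ca <- matrix(0, R - 1L, R - 1L)
  for (a in seq_along(nonref)) for (b in seq_along(nonref)) {
    key <- paste0("cov_alpha.", min(nonref[a], nonref[b]), ".",
                  max(nonref[a], nonref[b]))
    if (!is.null(config[[key]])) ca[a, b] <- config[[key]]
  }
  vb <- rep(0, R)
  vbg <- grab("var_beta")
  vb[vbg$idx] <- vbg$v[vbg$idx]
  vg <- grab("var_gamma")$v
  if (length(vg) != R) stop("configuration lacks `var_gamma.<r>` keys")
  model_params(design = config$design %||% "cross_classified",
               mu = mu, lam = lam,
               var_eta = config$var_eta %||% stop("configuration lacks `var_eta`"),
               cov_alpha = ca, var_beta = vb, var_gamma = vg,
               reference_level = ref)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write model parameters to a JSON or YAML file
#'
#' @param params An `nst_params` object.
#' @param path Output path; the format is chosen from the extension
#'   (`.json`, or `.yaml`/`.yml`).
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  cfg <- params_to_config(params)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(cfg, path, precision = 15L)
  } else {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read model parameters from a JSON or YAML file
#'
#' @param path Path to a file written by [write_params()] (or hand-edited in
#'   the same flat key-value dialect).
#' @return An `nst_params` object.
#' @export
read_params <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  params_from_config(cfg)
}
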