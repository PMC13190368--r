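#' Simulation design for synthetic response tables
#'
#' Describes the sampling design under which a synthetic study is generated:
#' how many subjects, how many incidental realizations per radical level
#' (under cross-classified sampling these are shared by all subjects; under
#' two-level sampling every subject receives their own unique set), the seed,
#' and an optional score post-processing step.
#'
#' @param design `"cross_classified"` or `"two_level"`.
#' @param n_subjects Number of subjects (>= 2).
#' @param n_incidentals_per_level Incidental realizations per radical level
#'   (>= 1); default 3, the per-level item count of the figural short-term
#'   memory studies the models were built for.
#' @param seed Integer seed; a single seed governs every random stream (the
#'   latent components are drawn in the fixed documented order eta, alpha,
#'   beta, gamma from one generator stream, so partial structures are
#'   reproducible).
#' @param score_postprocess `"none"` (default; scores stay continuous, the
#'   scale the model assumes) or `"round_clip_0_20"` (round to integers and
#'   clip to the 0-20 count range of a 20-emblem item; this biases moments
#'   and is provided only for realism checks).
#' @param confound_beta Under `two_level` only: if `TRUE`, a parameter set
#'   with positive incidental variance is accepted and the incidental
#'   variance is folded into the noise (gamma variance becomes
#'   \eqn{\sigma_{\beta r}^2 + \sigma_{\gamma r}^2}), mirroring the fact that
#'   incidental effects are inexpressible in that design. Default `FALSE`:
#'   the generator refuses positive `var_beta` under `two_level`.
#' @param items_per_subject Optional `n_subjects` x `n_radicals` integer
#'   matrix of per-subject per-level item counts for an unbalanced two-level
#'   design; default balanced.
#' @return An object of class `nst_sim_design`.
#' @export
sim_design <- function(design = c("cross_classified", "two_level"),
                       n_subjects,
                       n_incidentals_per_level = 3L,
                       seed = 1L,
                       score_postprocess = c("none", "round_clip_0_20"),
                       confound_beta = FALSE,
                       items_per_subject = NULL) {
  design <- match.arg(design)
  score_postprocess <- match.arg(score_postprocess)
  n_subjects <- as.integer(n_subjects)
  n_incidentals_per_level <- as.integer(n_incidentals_per_level)
  if (n_subjects < 2L) stop("`n_subjects` must be at least 2")
  if (n_incidentals_per_level < 1L)
    stop("`n_incidentals_per_level` must be at least 1")
  if (!is.null(items_per_subject)) {
    if (design != "two_level")
      stop("unbalanced per-subject item counts are only supported under the two-level design")
    items_per_subject <- as.matrix(items_per_subject)
    if (nrow(items_per_subject) != n_subjects || any(items_per_subject < 0))
      stop("`items_per_subject` must be an n_subjects x n_radicals matrix of non-negative counts")
  }
  structure(list(design = design, n_subjects = n_subjects,
                 n_incidentals_per_level = n_incidentals_per_level,
                 seed = as.integer(seed),
                 score_postprocess = score_postprocess,
                 confound_beta = isTRUE(confound_beta),
                 items_per_subject = items_per_subject),
            class = "nst_sim_design")
}

subject_ids <- function(n) sprintf("s%04d", seq_len(n))

#' Simulate a synthetic response table and its latent state
#'
#' Draws a long-format response table with exactly the statistical structure
#' the measurement models assume: subject abilities
#' \eqn{\eta_s \sim N(0, \sigma_\eta^2)}, radical-effect residuals
#' \eqn{(\alpha_{s2},\dots) \sim N(0, \Sigma_\alpha)}, incidental effects
#' \eqn{\beta_{ir} \sim N(0, \sigma_{\beta r}^2)} (shared across subjects
#' under cross-classified sampling; refused under two-level sampling unless
#' `confound_beta` folds them into the noise), and noise
#' \eqn{\gamma_{sir} \sim N(0, \sigma_{\gamma r}^2)}, assembled as
#' \eqn{Y_{sir} = \mu_r + \lambda_r\eta_s + \alpha_{sr} + \beta_{ir} +
#' \gamma_{sir}}.
#'
#' Identical seed and design give bit-identical output. Identifiers are
#' deterministic strings (`s0001`; incidentals `r2_i03` under cross-classified
#' sampling and `s0001_r2_i03` under two-level sampling) so tables diff
#' cleanly; no incidental identifier is ever repeated across radical levels.
#'
#' @param params An [model_params()] object; its design must match `sim`'s.
#' @param sim An [sim_design()] object.
#' @return A list with elements `table` (a validated response table; data
#'   frame with columns `subject_id`, `radical_level`, `incidental_id`,
#'   `score` and attribute `design`) and `latent` (list with `eta`, `alpha`,
#'   `beta`, `gamma`).
#' @examples
#' p <- model_params("cross_classified", mu = c(11, 9, 7), lam = c(1, .9, .5),
#'                   var_eta = 6.8, cov_alpha = diag(c(.5, 1.7)),
#'                   var_beta = c(.16, .4, .07), var_gamma = c(8, 6.5, 5.1))
#' out <- simulate_responses(p, sim_design("cross_classified", 20, seed = 7))
#' head(out$table)
#' @export
simulate_responses <- function(params, sim) {
  stopifnot(inherits(params, "nst_params"), inherits(sim, "nst_sim_design"))
  if (!identical(params$design, sim$design))
    stop(errorCondition(
      paste0("parameter design (", params$design,
             ") does not match simulation design (", sim$design, ")"),
      class = c("nst_design_mismatch", "error")))
  if (sim$design == "two_level" && any(params$var_beta > 0) &&
      !sim$confound_beta)
    stop(errorCondition(
      paste0("incidental effects are inexpressible under two-level sampling; ",
             "set `confound_beta = TRUE` to fold var_beta into the noise variance"),
      class = c("nst_design_mismatch", "error")))

  R <- params$n_radicals
  N <- sim$n_subjects
  I <- sim$n_incidentals_per_level
  ref <- params$reference_level
  nonref <- nonreference_levels(params)
  sid <- subject_ids(N)

  var_gamma_eff <- params$var_gamma
  if (sim$design == "two_level" && sim$confound_beta)
    var_gamma_eff <- var_gamma_eff + params$var_beta

  set.seed(sim$seed)
  # stream order is fixed and documented: eta, alpha, beta, gamma
  eta <- stats::rnorm(N, 0, sqrt(params$var_eta))
  alpha <- matrix(0, N, R)
  if (length(nonref)) {
    L <- chol_psd(params$cov_alpha)
    alpha[, nonref] <- matrix(stats::rnorm(N * length(nonref)), N) %*% L
  }
  colnames(alpha) <- paste0("r", seq_len(R))

  if (sim$design == "cross_classified") {
    beta <- data.frame(
      incidental_id = as.vector(vapply(seq_len(R), function(r)
        sprintf("r%d_i%02d", r, seq_len(I)), character(I))),
      radical_level = rep(seq_len(R), each = I),
      value = stats::rnorm(R * I) *
        rep(sqrt(params$var_beta), each = I))
    counts <- matrix(I, N, R)
  } else {
    beta <- NULL
    counts <- if (is.null(sim$items_per_subject)) matrix(I, N, R)
              else sim$items_per_subject
  }

  # rows ordered by subject, then level, then incidental position
  subj_idx <- rep(seq_len(N), times = rowSums(counts))
  lev <- unlist(lapply(seq_len(N), function(s)
    rep(seq_len(R), times = counts[s, ])), use.names = FALSE)
  pos <- unlist(lapply(seq_len(N), function(s)
    unlist(lapply(seq_len(R), function(r) seq_len(counts[s, r])))),
    use.names = FALSE)
  if (sim$design == "cross_classified") {
    inc_id <- sprintf("r%d_i%02d", lev, pos)
    beta_row <- beta$value[match(inc_id, beta$incidental_id)]
  } else {
    inc_id <- sprintf("%s_r%d_i%02d", sid[subj_idx], lev, pos)
    beta_row <- 0
  }
  gamma <- stats::rnorm(length(lev)) * sqrt(var_gamma_eff[lev])
  score <- params$mu[lev] + params$lam[lev] * eta[subj_idx] +
    alpha[cbind(subj_idx, lev)] + beta_row + gamma
  if (sim$score_postprocess == "round_clip_0_20")
    score <- pmin(20, pmax(0, round(score)))

  table <- data.frame(subject_id = sid[subj_idx],
                      radical_level = lev,
                      incidental_id = inc_id,
                      score = score,
                      stringsAsFactors = FALSE)
  attr(table, "design") <- sim$design
  class(table) <- c("nst_table", class(table))
  list(table = table,
       latent = list(eta = stats::setNames(eta, sid),
                     alpha = alpha[, nonref, drop = FALSE],
                     beta = beta,
                     gamma = gamma))
}

# Cholesky factor that tolerates positive semi-definite input
chol_psd <- function(S) {
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(out)) return(out)
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  t(e$vectors %*% (t(e$vectors) * sqrt(ev)))
}

#' Latin-square presentation orders
#'
#' Builds the presentation-order metadata used to counterbalance item order
#' across subjects: items are distributed into blocks, each containing one
#' item per radical level. The first block is a warm-up with the same
#' easiest-to-hardest order for every condition; in every later block the
#' orders across conditions form a Latin square (each level appears exactly
#' once at each position). Presentation order is pure metadata: order effects
#' are not part of the measurement models.
#'
#' @param n_conditions Number of order conditions subjects are randomized to.
#' @param n_blocks Number of blocks (each holding one item per level).
#' @param levels Number of radical levels; must equal `n_conditions` so the
#'   rotated blocks form proper Latin squares.
#' @return A data frame with columns `condition`, `block`, `position`,
#'   `radical_level`.
#' @examples
#' latin_square_orders(3, 3, 3)
#' @export
latin_square_orders <- function(n_conditions, n_blocks, levels) {
  n_conditions <- as.integer(n_conditions)
  n_blocks <- as.integer(n_blocks)
  levels <- as.integer(levels)
  if (n_conditions != levels)
    stop("a Latin-square order plan requires `n_conditions == levels`")
  if (n_blocks < 1L) stop("`n_blocks` must be at least 1")
  rows <- list()
  for (b in seq_len(n_blocks)) for (cnd in seq_len(n_conditions)) {
    ord <- if (b == 1L) seq_len(levels)  # warm-up: easiest first, for everyone
           else ((seq_len(levels) - 1L + (cnd - 1L) + (b - 2L)) %% levels) + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cnd, block = b, position = seq_len(levels),
      radical_level = ord)
  }
  do.call(rbind, rows)
}

#' Mark scores missing at random
#'
#' Reproducibly marks `n_missing` uniformly chosen scores as missing (`NA`),
#' emulating technical dropouts during data collection.
#'
#' @param table A response table.
#' @param n_missing Number of scores to blank (must be below the row count).
#' @param seed Integer seed.
#' @return The table with `n_missing` scores set to `NA`.
#' @export
inject_missing <- function(table, n_missing, seed = 1L) {
  n_missing <- as.integer(n_missing)
  if (n_missing >= nrow(table))
    stop("`n_missing` must be smaller than the number of rows")
  if (n_missing == 0L) return(table)
  set.seed(as.integer(seed))
  idx <- sample.int(nrow(table), n_missing)
  table$score[idx] <- NA_real_
  table
}
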