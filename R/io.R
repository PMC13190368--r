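#' Read a long-format response table from CSV
#'
#' The canonical data format is a UTF-8 CSV with header
#' `subject_id,radical_level,incidental_id,score`, one row per presented
#' item; a missing score is an empty field. On reading, the table is
#' validated (duplicate subject-incidental pairs, incidentals reused across
#' radical levels, and non-numeric scores raise row-addressed errors) and the
#' sampling design is auto-detected from the incidental-sharing pattern: if
#' any incidental was seen by more than one subject the data are
#' cross-classified, otherwise two-level. A declared design is cross-checked
#' against the detected one.
#'
#' @param path Path to the CSV file.
#' @param design Optional declared design (`"cross_classified"` or
#'   `"two_level"`); a conflict with the sharing pattern is an error.
#' @return A response table: data frame with attribute `design`.
#' @export
read_response_table <- function(path, design = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", na.strings = NULL,
                         fileEncoding = "UTF-8")
  need <- c("subject_id", "radical_level", "incidental_id", "score")
  if (!identical(names(raw), need))
    stop("header must be exactly `", paste(need, collapse = ","), "`")
  lev <- suppressWarnings(as.integer(raw$radical_level))
  bad <- which(is.na(lev) | lev < 1L)
  if (length(bad))
    stop("non-positive or non-integer radical_level in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  score_chr <- raw$score
  score <- suppressWarnings(as.numeric(score_chr))
  bad <- which(is.na(score) & score_chr != "")
  if (length(bad))
    stop("non-numeric score in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  table <- data.frame(subject_id = raw$subject_id,
                      radical_level = lev,
                      incidental_id = raw$incidental_id,
                      score = score,
                      stringsAsFactors = FALSE)
  validate_response_table(table, design = design)
}

#' Validate a response table and stamp its design
#'
#' @param table Data frame with the canonical columns.
#' @param design Optional declared design to cross-check.
#' @return The table with attribute `design` set, classed `nst_table`.
#' @export
validate_response_table <- function(table, design = NULL) {
  dup <- duplicated(table[, c("subject_id", "incidental_id")])
  if (any(dup))
    stop("duplicate (subject, incidental) pair(s) in row(s) ",
         paste(utils::head(which(dup), 5), collapse = ", "))
  lev_of <- tapply(table$radical_level, table$incidental_id,
                   function(v) length(unique(v)))
  reused <- names(lev_of)[lev_of > 1L]
  if (length(reused))
    stop("incidental(s) reused across radical levels: ",
         paste(utils::head(reused, 5), collapse = ", "))
  n_subj_per_inc <- tapply(table$subject_id, table$incidental_id,
                           function(v) length(unique(v)))
  detected <- if (any(n_subj_per_inc > 1L)) "cross_classified" else "two_level"
  if (!is.null(design)) {
    design <- match.arg(design, c("cross_classified", "two_level"))
    if (design == "two_level" && detected == "cross_classified") {
      shared <- names(n_subj_per_inc)[n_subj_per_inc > 1L]
      stop(errorCondition(
        paste0("declared two_level but incidental(s) seen by multiple ",
               "subjects (cross-classified pattern): ",
               paste(utils::head(shared, 5), collapse = ", ")),
        class = c("nst_design_mismatch", "error")))
    }
    if (design == "cross_classified" && detected == "two_level" &&
        length(unique(table$subject_id)) > 1L)
      warning("declared cross_classified but no incidental is shared ",
              "across subjects; the table looks two-level")
    detected <- design
  }
  attr(table, "design") <- detected
  if (!inherits(table, "nst_table")) class(table) <- c("nst_table", class(table))
  table
}

#' Write a response table to CSV
#'
#' Inverse of [read_response_table()]: canonical header, missing scores as
#' empty fields, UTF-8, newline-terminated. Writing a table read from a
#' canonical file reproduces it byte for byte.
#'
#' @param table A response table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(table, path) {
  out <- data.frame(subject_id = table$subject_id,
                    radical_level = table$radical_level,
                    incidental_id = table$incidental_id,
                    score = ifelse(is.na(table$score), "",
                                   as.character(table$score)))
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

nst_log <- function(..., level = "INFO") {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ", ...)
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates simulate (or load) -> fit -> convergence gate (all potential
#' scale reduction factors below 1.1) -> consistency summary -> intercept
#' contrasts -> optional posterior predictive check, and writes a JSON report
#' (machine-readable) plus a plain-text report. The run is deterministic
#' given the configured seed: the simulation uses `seed`, the sampler
#' `seed + 1`, the predictive check `seed + 2`, and every seed is echoed in
#' the report, which therefore suffices to rerun the analysis. Progress is
#' logged to stderr; reports go only to files and the return value.
#'
#' @param config A configuration list, or a path to a YAML or JSON file.
#'   Fields: `design`; `seed`; either `data` (CSV path) or `simulation`
#'   (`params` as a flat key-value block or a path, `n_subjects`,
#'   `n_incidentals_per_level`); optional `estimation` (`n_chains`, `n_iter`,
#'   `warmup_fraction`, `thin`, `fix_loadings`, plus prior overrides under
#'   `priors`); optional `analysis` (`consistency`, `contrasts`, `ppc`,
#'   `ppc_draws`); optional `output` (`dir`, `prefix`).
#' @return Invisibly, a list with the fit, the analysis tables, the
#'   convergence status (`converged`) and the report paths. A convergence
#'   failure still emits the reports, with status `"not_converged"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  design <- match.arg(config$design, c("cross_classified", "two_level"))
  seed <- as.integer(config$seed %||% 1L)
  est <- config$estimation %||% list()
  ana <- config$analysis %||% list()
  outdir <- (config$output %||% list())$dir %||% "."
  prefix <- (config$output %||% list())$prefix %||% "noisestab"
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  sim_block <- NULL
  if (!is.null(config$data)) {
    nst_log("loading response table from ", config$data)
    table <- read_response_table(config$data, design = design)
  } else if (!is.null(config$simulation)) {
    sb <- config$simulation
    params <- if (is.character(sb$params)) read_params(sb$params)
              else params_from_config(c(sb$params, list(design = design)))
    if (!identical(params$design, design))
      stop(errorCondition("simulation parameter design conflicts with the run design",
                          class = c("nst_design_mismatch", "error")))
    sim <- sim_design(design, n_subjects = sb$n_subjects,
                      n_incidentals_per_level = sb$n_incidentals_per_level %||% 3L,
                      seed = seed,
                      confound_beta = isTRUE(sb$confound_beta))
    nst_log("simulating ", sim$n_subjects, " subjects (", design, ")")
    table <- simulate_responses(params, sim)$table
    sim_block <- list(params = params_to_config(params),
                      n_subjects = sim$n_subjects,
                      n_incidentals_per_level = sim$n_incidentals_per_level,
                      seed = seed)
  } else stop("config needs either a `data` path or a `simulation` block")

  pr <- do.call(priors, est$priors %||% list())
  settings <- mcmc_settings(n_chains = est$n_chains %||% 3L,
                            n_iter = est$n_iter %||% 20000L,
                            warmup_fraction = est$warmup_fraction %||% 0.5,
                            thin = est$thin %||% 1L,
                            seed = seed + 1L)
  nst_log("fitting (", settings$n_chains, " chains x ", settings$n_iter,
          " iterations)")
  fit <- fit_aig_model(table, priors = pr, settings = settings,
                       design = design,
                       fix_loadings = isTRUE(est$fix_loadings))

  max_psrf <- max(fit$convergence$psrf)
  converged <- max_psrf < 1.1
  nst_log("maximum PSRF = ", format(max_psrf, digits = 4),
          if (converged) " (converged)" else " (NOT converged)")

  report <- list(
    status = if (converged) "ok" else "not_converged",
    design = design,
    seeds = list(simulation = seed, mcmc = seed + 1L, ppc = seed + 2L),
    data = list(n_subjects = fit$data_info$n_subjects,
                n_rows = fit$data_info$n_rows,
                n_radicals = fit$data_info$n_radicals,
                source = config$data %||% "simulated"),
    simulation = sim_block,
    settings = unclass(settings),
    max_psrf = max_psrf,
    convergence = fit$convergence,
    posterior = fit$summary)

  bundle <- list(fit = fit, converged = converged)
  if (!identical(ana$consistency %||% TRUE, FALSE)) {
    cons <- consistency_from_draws(fit$draws)
    report$consistency <- as.data.frame(cons)
    bundle$consistency <- cons
  }
  if (!identical(ana$contrasts %||% TRUE, FALSE)) {
    ctr <- intercept_contrasts(fit)
    report$contrasts <- as.data.frame(ctr)
    bundle$contrasts <- ctr
  }
  if (isTRUE(ana$ppc)) {
    nst_log("posterior predictive check")
    ppc <- bppc(fit, table, seed = seed + 2L,
                n_draws = ana$ppc_draws %||% 500L)
    report$ppc <- list(mean_delta_obs_minus_rep = ppc$mean_delta,
                       mean_delta_rep_minus_obs = ppc$mean_delta_rep_minus_obs,
                       interval_95 = ppc$interval_95,
                       ppp = ppc$ppp, n_draws_used = ppc$n_draws_used)
    bundle$ppc <- ppc
  }

  json_path <- file.path(outdir, paste0(prefix, "_report.json"))
  txt_path <- file.path(outdir, paste0(prefix, "_report.txt"))
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  writeLines(text_report(report), txt_path)
  nst_log("reports written to ", json_path, " and ", txt_path)
  bundle$report <- report
  bundle$paths <- list(json = json_path, text = txt_path)
  invisible(bundle)
}

text_report <- function(report) {
  fmt_tab <- function(df) utils::capture.output(print(df, digits = 4,
                                                      row.names = FALSE))
  c(paste0("noisestab pipeline report (", report$design, ") - status: ",
           report$status),
    paste0("subjects: ", report$data$n_subjects, "  scores: ",
           report$data$n_rows, "  source: ", report$data$source),
    paste0("seeds: simulation=", report$seeds$simulation, " mcmc=",
           report$seeds$mcmc, " ppc=", report$seeds$ppc),
    paste0("max PSRF: ", format(report$max_psrf, digits = 4),
           " (gate < 1.1)"),
    "", "Posterior summary:", fmt_tab(report$posterior),
    if (!is.null(report$consistency))
      c("", "Consistency coefficients:", fmt_tab(report$consistency)),
    if (!is.null(report$contrasts))
      c("", "Intercept contrasts:", fmt_tab(report$contrasts)),
    if (!is.null(report$ppc))
      c("", sprintf("PPC: M(delta obs-rep) = %.3f  [%.3f, %.3f]  ppp = %.3f",
                    report$ppc$mean_delta_obs_minus_rep,
                    report$ppc$interval_95[1], report$ppc$interval_95[2],
                    report$ppc$ppp)))
}
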