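#' Read / write long-format choice data
#'
#' CSV schema: `respondent_id,task,stage,attribute,level,row,available,chosen`,
#' one row per available alternative per choice occasion. Reading validates
#' the exploded structure: stages `best`, `worst`, `second_best`,
#' `second_worst` with availability-set sizes 7, 6, 5 and 4, distinct
#' display rows, and exactly one chosen row per occasion.
#'
#' @param choices an `ascot_choices` data frame.
#' @param path file path.
#' @return `read_choices` returns an `ascot_choices`; `write_choices`
#'   returns `path` invisibly.
#' @export
write_choices <- function(choices, path) {
  utils::write.csv(as.data.frame(choices), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_choices
#' @export
read_choices <- function(path) {
  df <- utils::read.csv(path)
  need <- c("respondent_id", "task", "stage", "attribute", "level", "row",
            "available", "chosen")
  if (!all(need %in% colnames(df)))
    stop("choices CSV must contain columns: ", paste(need, collapse = ", "))
  validate_choices(df)
  class(df) <- c("ascot_choices", "data.frame")
  df
}

validate_choices <- function(df) {
  if (!all(df$stage %in% STAGES))
    stop("schema error: unknown stage value(s) ",
         paste(unique(setdiff(df$stage, STAGES)), collapse = ", "))
  key <- paste(df$respondent_id, df$task, df$stage)
  sizes <- tapply(seq_len(nrow(df)), key, length)
  expect <- STAGE_SIZES[vapply(strsplit(names(sizes), " "), function(x)
    x[3], "")]
  bad <- which(sizes != expect)
  if (length(bad)) {
    first <- names(sizes)[bad[1]]
    row1 <- which(key == first)[1]
    stop("schema error at row ", row1, ": occasion '", first, "' has ",
         sizes[bad[1]], " alternatives (expected ", expect[bad[1]], ")")
  }
  nch <- tapply(df$chosen, key, sum)
  if (any(nch != 1L)) {
    first <- names(nch)[which(nch != 1L)[1]]
    stop("schema error: occasion '", first, "' has ",
         nch[which(nch != 1L)[1]], " chosen rows (expected 1)")
  }
  rowdup <- tapply(df$row, key, anyDuplicated)
  if (any(rowdup > 0))
    stop("schema error: duplicated display rows in occasion '",
         names(rowdup)[which(rowdup > 0)[1]], "'")
  invisible(df)
}

#' End-to-end valuation pipeline on synthetic data
#'
#' Runs the full study sequence on synthetic data: generate the 32-profile
#' OMEP, simulate the respondent cohort, simulate the exploded BWS choices
#' under the configured true parameters, fit the basic MNL and the
#' (taste-adjusted) S-MNL, post-stratify the attribute-level coefficients to
#' the population margins, and normalise/anchor them into the preference
#' weight table. All artifacts are written to `out_dir` as plain CSV/JSON
#' together with a manifest (seed, sizes, file hashes); reruns with the same
#' config are bit-identical.
#'
#' @param config list with elements `seed` (integer), `n_respondents`,
#'   `margins` (table or YAML path; default bundled), `true_params`
#'   (a [bws_params]; default the published S-MNL estimates),
#'   `scale_covars`, `interactions` (data frame or NULL),
#'   `switch_pairs`, `example_states` (character vector of states to score).
#' @param out_dir artifact directory, created if needed.
#' @param quiet suppress progress messages?
#' @return invisibly, a list with the fitted models, weights and artifact
#'   paths.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("ascotbws"),
                         quiet = FALSE) {
  cfg <- utils::modifyList(list(
    seed = 1L,
    n_respondents = 1005L,
    margins = NULL,
    true_params = finnish_carer_estimates("II"),
    scale_covars = c("hgood", "eduhigh", "tmlong", "learning"),
    interactions = NULL,
    switch_pairs = list(c("PERC", 1, 2)),
    example_states = c("3442434", "1231321")
  ), config)
  say <- function(...) if (!quiet) message("[ascotbws] ", ...)
  margins <- cfg$margins
  if (is.null(margins)) margins <- default_margins()
  else if (is.character(margins)) {
    if (!file.exists(margins))
      stop("cohort stage: margins file '", margins, "' does not exist")
    margins <- default_margins(margins)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  say("design: generating 32-profile OMEP")
  plan <- generate_omep(seed = cfg$seed)
  chk <- verify_design(plan)
  if (!chk$pass) stop("design stage: generated plan failed verification")
  write_design(plan, file.path(out_dir, "design.csv"))

  say("cohort: simulating ", cfg$n_respondents, " respondents")
  cohort <- simulate_respondents(cfg$n_respondents, margins, seed = cfg$seed)
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  say("choices: simulating exploded BWS data")
  choices <- simulate_dataset(cohort, plan, cfg$true_params, seed = cfg$seed)
  write_choices(choices, file.path(out_dir, "choices.csv"))

  say("fit: basic MNL")
  fit_mnl <- fit_model(choices, cohort, model = "mnl")
  say("fit: S-MNL (scale: ", paste(cfg$scale_covars, collapse = ", "), ")")
  fit_smnl <- fit_model(choices, cohort, model = "smnl",
                        scale_covars = cfg$scale_covars,
                        interactions = cfg$interactions)
  lr <- lr_test(fit_mnl, fit_smnl)

  say("weights: post-stratification, normalisation, anchoring")
  adj <- adjust_for_population(fit_smnl, margins)
  weights <- preference_weights(adj$beta, adj$se,
                                switch_pairs = cfg$switch_pairs)
  scores <- stats::setNames(
    vapply(cfg$example_states, function(s) score_state(weights, s), 0),
    cfg$example_states)

  write_fit_json(fit_smnl, file.path(out_dir, "fit.json"))
  write_weights_json(weights, scores, file.path(out_dir, "weights.json"))

  report <- list(
    seed = cfg$seed,
    n_respondents = nrow(cohort),
    n_occasions = fit_smnl$n_occasions,
    loglik_mnl = fit_mnl$loglik,
    loglik_smnl = fit_smnl$loglik,
    rho2_0_mnl = pseudo_r2(fit_mnl),
    rho2_0_smnl = pseudo_r2(fit_smnl),
    lr_statistic = lr$statistic, lr_df = lr$df, lr_p = lr$p_value,
    example_scores = as.list(scores)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  artifacts <- c("design.csv", "cohort.csv", "choices.csv", "fit.json",
                 "weights.json", "report.json")
  manifest <- list(
    seed = cfg$seed,
    n_respondents = cfg$n_respondents,
    package_version = as.character(utils::packageVersion("ascotbws")),
    files = lapply(stats::setNames(artifacts, artifacts), function(f)
      unname(tools::md5sum(file.path(out_dir, f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done: artifacts in ", out_dir)
  invisible(list(plan = plan, cohort = cohort, choices = choices,
                 fit_mnl = fit_mnl, fit_smnl = fit_smnl, lr = lr,
                 weights = weights, scores = scores, report = report,
                 out_dir = out_dir))
}

write_fit_json <- function(fit, path) {
  obj <- list(
    model = fit$model,
    estimates = as.list(fit$estimates),
    se_robust = as.list(fit$se),
    vcov = fit$vcov,
    loglik = fit$loglik,
    loglik_null = fit$loglik_null,
    rho2_0 = fit$rho2_0,
    n_occasions = fit$n_occasions,
    n_clusters = fit$n_clusters,
    converged = fit$converged,
    iterations = fit$iterations,
    gradient_norm = fit$gradient_norm,
    gamma = fit$gamma
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}

write_weights_json <- function(weights, scores, path) {
  obj <- list(table = weights$table,
              constants = weights$constants,
              switched = weights$switched,
              example_scores = as.list(scores))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
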