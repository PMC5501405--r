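#' Configuration for a full pipeline run
#'
#' @param schema `dce_schema` (or path to a schema JSON).
#' @param n_sets,n_blocks Design size.
#' @param design_restarts Random restarts of the design search.
#' @param cohort A [cohort_config()].
#' @param true_models Named list of [true_model()]s per disease group
#'   (`asthma`, `copd`) used when simulating.
#' @param spec A [rol_spec()] for estimation.
#' @param mcmc An [mcmc_config()] (its seed is overridden by the derived
#'   stage seed).
#' @param seed Master seed; every stage derives its own substream from it.
#' @param out_dir Output directory (created if missing).
#' @return List of class `run_config`.
#' @export
run_config <- function(schema = inhaler_schema(), n_sets = 36L, n_blocks = 3L,
                       design_restarts = 20L,
                       cohort = cohort_config(),
                       true_models = list(asthma = study_true_model("asthma"),
                                          copd = study_true_model("copd")),
                       spec = rol_spec(),
                       mcmc = mcmc_config(),
                       seed = 1L, out_dir = tempfile("dce_run_")) {
  if (is.character(schema)) schema <- read_schema(schema)
  structure(list(schema = schema, n_sets = n_sets, n_blocks = n_blocks,
                 design_restarts = design_restarts, cohort = cohort,
                 true_models = true_models, spec = spec, mcmc = mcmc,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Run the full study pipeline
#'
#' Chains design generation, cohort simulation, two-step choice simulation,
#' stratified estimation with a disease-interaction pre-test, covariate
#' interaction models, and WTP inference; writes every stage artifact as CSV
#' (plus JSON sidecars) under `config$out_dir`. Reruns with the same config
#' are bit-identical for all CSV outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return A `study_report` list: `design_diagnostics`, `cohort_summary`,
#'   `interaction_test`, `fits` (per group), `fit_tables`,
#'   `covariate_table`, `wtp` (per group), `wtp_comparison`, `provenance`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[pipeline] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(design = derive_seed(config$seed, 1L),
                cohort = derive_seed(config$seed, 2L),
                simulate = derive_seed(config$seed, 3L),
                mcmc = derive_seed(config$seed, 4L))

  say("design: searching ", config$n_sets, " sets in ", config$n_blocks,
      " blocks")
  design <- search_design(config$schema, config$n_sets, config$n_blocks,
                          seed = seeds$design,
                          n_restarts = config$design_restarts)
  write_design(design, file.path(config$out_dir, "design.csv"))

  say("cohort: simulating respondents")
  cohort <- generate_respondents(config$cohort, seed = seeds$cohort)
  write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))

  say("simulate: two-step choices per respondent block")
  groups <- list(asthma = cohort[cohort$disease == "asthma", ],
                 copd = cohort[cohort$disease == "COPD", ])
  rankings <- do.call(rbind, lapply(names(groups), function(g) {
    if (nrow(groups[[g]]) == 0L) return(NULL)
    as.data.frame(simulate_study(groups[[g]], design, config$true_models[[g]],
                                 seed = seeds$simulate))
  }))
  rankings <- rankings[order(rankings$respondent_id, rankings$set_id,
                             rankings$rank), ]
  rownames(rankings) <- NULL
  class(rankings) <- c("dce_rankings", "data.frame")
  write_rankings(rankings, file.path(config$out_dir, "rankings.csv"))

  say("fit: disease-interaction pre-test and stratified fits")
  itest <- test_disease_interactions(rankings, cohort, config$spec)
  fits <- lapply(names(groups), function(g) {
    fit_rol(rankings[rankings$respondent_id %in% groups[[g]]$respondent_id, ],
            cohort, config$spec)
  })
  names(fits) <- names(groups)
  fit_tables <- lapply(fits, fit_table)
  for (g in names(fit_tables)) {
    write.csv(fit_tables[[g]],
              file.path(config$out_dir, paste0("fit_", g, ".csv")),
              row.names = FALSE)
    jsonlite::write_json(
      list(log_likelihood = fits[[g]]$log_likelihood,
           sigma_re = fits[[g]]$sigma_re,
           converged = fits[[g]]$converged,
           vcov = fits[[g]]$vcov),
      file.path(config$out_dir, paste0("fit_", g, ".json")),
      auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  }

  say("fit: covariate x status-quo interaction table")
  cov_table <- covariate_interaction_table(rankings, cohort, config$spec)
  write.csv(cov_table, file.path(config$out_dir, "covariate_interactions.csv"),
            row.names = FALSE)

  say("wtp: MCMC credibility intervals per group")
  wtp <- lapply(names(fits), function(g) {
    cfg <- config$mcmc
    cfg$seed <- derive_seed(seeds$mcmc, match(g, names(fits)))
    enc <- encode(rankings[rankings$respondent_id %in%
                             groups[[g]]$respondent_id, ], cohort, config$spec)
    draws <- mcmc_sample(fits[[g]], enc, cfg)
    write.csv(as.data.frame(unclass(draws)),
              file.path(config$out_dir, paste0("mcmc_draws_", g, ".csv")),
              row.names = FALSE)
    terms <- setdiff(names(fits[[g]]$estimates), c("cost", "log_sigma"))
    terms <- terms[!grepl(" x ", terms)]
    wtp_credible(draws, terms, point = fits[[g]]$estimates, group = g)
  })
  names(wtp) <- names(fits)
  for (g in names(wtp)) {
    write.csv(wtp[[g]], file.path(config$out_dir, paste0("wtp_", g, ".csv")),
              row.names = FALSE)
  }
  wtp_cmp <- compare_groups(wtp$asthma, wtp$copd)
  write.csv(wtp_cmp, file.path(config$out_dir, "wtp_comparison.csv"),
            row.names = FALSE)

  csum <- cohort_summary(cohort)
  write.csv(csum, file.path(config$out_dir, "cohort_summary.csv"),
            row.names = FALSE)

  provenance <- list(master_seed = config$seed, stage_seeds = seeds,
                     package_version = as.character(utils::packageVersion("inhalerdce")),
                     r_version = R.version.string,
                     timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(provenance, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  report <- structure(list(
    design = design,
    design_diagnostics = design$diagnostics,
    cohort_summary = csum,
    interaction_test = itest,
    fits = fits,
    fit_tables = fit_tables,
    covariate_table = cov_table,
    wtp = wtp,
    wtp_comparison = wtp_cmp,
    provenance = provenance
  ), class = "study_report")
  writeLines(utils::capture.output(print(report)),
             file.path(config$out_dir, "report.txt"))
  say("done: artifacts in ", config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("==== DCE study report ====\n\n-- Design --\n")
  print(x$design_diagnostics)
  cat("\n-- Cohort --\n")
  print(x$cohort_summary, digits = 4, row.names = FALSE)
  cat("\n-- Disease x attribute interactions --\n")
  print(x$interaction_test)
  for (g in names(x$fit_tables)) {
    cat("\n-- Marginal utilities (", g, ") --\n", sep = "")
    print(x$fit_tables[[g]], digits = 4, row.names = FALSE)
  }
  cat("\n-- Covariate x status-quo interactions (p-values) --\n")
  print(as.data.frame(x$covariate_table), digits = 4, row.names = FALSE)
  for (g in names(x$wtp)) {
    cat("\n-- Willingness to pay (", g, ", EUR/month) --\n", sep = "")
    print(as.data.frame(x$wtp[[g]]), digits = 4, row.names = FALSE)
  }
  cat("\n-- WTP comparison (copd - asthma) --\n")
  print(x$wtp_comparison, digits = 4, row.names = FALSE)
  cat("\nSeeds: master ", x$provenance$master_seed, "\n", sep = "")
  invisible(x)
}

#' Validate a long-format choice/ranking table
#'
#' Checks the export contract: every (respondent, set) record has exactly the
#' three alternatives A, B, current; `rank` is a permutation of 1-3; all
#' attribute levels belong to the schema; and the recorded two-step choices
#' are consistent with the ranking (the step-2 winner is ranked first and the
#' relative order of A and B matches step 1).
#'
#' @param x Path to a rankings CSV, or the data.frame itself.
#' @param schema Attribute schema to validate levels against.
#' @return data.frame of violations (`respondent_id`, `set_id`, `problem`);
#'   zero rows when the file is valid.
#' @export
validate_choice_csv <- function(x, schema = inhaler_schema()) {
  data <- if (is.character(x)) read_rankings(x) else x
  probs <- list()
  add <- function(rid, sid, msg) {
    probs[[length(probs) + 1L]] <<- data.frame(
      respondent_id = rid, set_id = sid, problem = msg,
      stringsAsFactors = FALSE)
  }
  for (a in schema) {
    if (!a$name %in% names(data)) {
      add(NA, NA, paste0("missing attribute column '", a$name, "'"))
      next
    }
    if (a$kind == "categorical") {
      bad <- !data[[a$name]] %in% a$levels
      for (i in which(bad)) {
        add(data$respondent_id[i], data$set_id[i],
            paste0("unknown level '", data[[a$name]][i], "' for ", a$name))
      }
    }
  }
  for (key in split(seq_len(nrow(data)),
                    interaction(data$respondent_id, data$set_id, drop = TRUE))) {
    d <- data[key, ]
    rid <- d$respondent_id[1L]; sid <- d$set_id[1L]
    if (nrow(d) != 3L || anyDuplicated(d$alt_id) ||
        !setequal(d$alt_id, c("A", "B", "current"))) {
      add(rid, sid, "alternatives are not exactly {A, B, current}")
      next
    }
    if (!identical(sort(d$rank), 1:3)) {
      add(rid, sid, paste0("rank (", paste(d$rank, collapse = ","),
                           ") is not a permutation of 1:3"))
      next
    }
    top <- d$alt_id[d$rank == 1L]
    s1 <- d$step1_choice[1L]; s2 <- d$step2_choice[1L]
    if (s2 == "current" && top != "current") {
      add(rid, sid, "step-2 chose current but current is not ranked first")
    }
    if (s2 == "winner" && top != s1) {
      add(rid, sid, "step-2 kept the step-1 winner but it is not ranked first")
    }
    ra <- d$rank[d$alt_id == "A"]; rb <- d$rank[d$alt_id == "B"]
    if ((s1 == "A") != (ra < rb)) {
      add(rid, sid, "relative order of A and B contradicts step-1 choice")
    }
  }
  out <- if (length(probs)) do.call(rbind, probs) else
    data.frame(respondent_id = integer(0), set_id = integer(0),
               problem = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
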