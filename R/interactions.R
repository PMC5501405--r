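#' Test disease x attribute interactions
#'
#' Fits the pooled model and the pooled model with every attribute (and the
#' status-quo dummy) interacted with disease, reports a Wald chi-square
#' p-value per interaction block and an overall likelihood-ratio test, and
#' recommends stratified per-disease fits when any block is significant.
#'
#' @param data Ranking records for both disease groups.
#' @param cohort Cohort table with a `disease` column.
#' @param spec Base [rol_spec()] (its interaction settings are overridden).
#' @param alpha Significance level for the stratify recommendation.
#' @return List of class `rol_interaction_test`: `block_p` (named per
#'   attribute), `lrt_stat`, `lrt_df`, `lrt_p`, `stratify`, `fit_pooled`,
#'   `fit_interacted`.
#' @export
test_disease_interactions <- function(data, cohort, spec = rol_spec(),
                                      alpha = 0.05) {
  if (length(unique(cohort$disease)) < 2L) {
    stop("disease interactions inestimable: single-group data", call. = FALSE)
  }
  spec0 <- spec
  spec0$disease_interactions <- character(0)
  spec0$sq_interactions <- character(0)
  spec1 <- spec0
  spec1$disease_interactions <- c(
    vapply(spec$schema, `[[`, character(1), "name"),
    if (spec$include_status_quo_constant) "current_inhaler")

  fit0 <- fit_rol(data, cohort, spec0)
  fit1 <- fit_rol(data, cohort, spec1)

  int_terms <- grep(" x COPD$", names(fit1$estimates), value = TRUE)
  blocks <- sub(":.*", "", sub(" x COPD$", "", int_terms))
  blocks[blocks == "current_inhaler"] <- "current_inhaler"
  block_p <- vapply(unique(blocks), function(b) {
    tt <- int_terms[blocks == b]
    est <- fit1$estimates[tt]
    V <- fit1$vcov[tt, tt, drop = FALSE]
    stat <- drop(t(est) %*% solve(V) %*% est)
    pchisq(stat, df = length(tt), lower.tail = FALSE)
  }, numeric(1))

  lrt_stat <- 2 * (fit1$log_likelihood - fit0$log_likelihood)
  lrt_df <- length(int_terms)
  structure(list(
    block_p = block_p,
    lrt_stat = lrt_stat, lrt_df = lrt_df,
    lrt_p = pchisq(lrt_stat, df = lrt_df, lower.tail = FALSE),
    stratify = any(block_p < alpha),
    fit_pooled = fit0, fit_interacted = fit1
  ), class = "rol_interaction_test")
}

#' @export
print.rol_interaction_test <- function(x, ...) {
  cat("Disease x attribute interaction test\n")
  cat("  LRT: stat ", format(x$lrt_stat, digits = 5), " on ", x$lrt_df,
      " df, p = ", format(x$lrt_p, digits = 4), "\n", sep = "")
  print(data.frame(attribute = names(x$block_p),
                   wald_p = unname(x$block_p), row.names = NULL), digits = 4)
  cat(if (x$stratify) "=> stratified per-disease fits recommended\n"
      else "=> pooled fit acceptable\n")
  invisible(x)
}

#' Covariate x status-quo interaction table
#'
#' For each covariate, refits the model with that covariate interacted with
#' the status-quo (current-inhaler) dummy, and tabulates Wald p-values for
#' every attribute, the status-quo constant, and the interaction itself
#' (a block chi-square when the covariate codes to more than one column,
#' e.g. satisfaction).
#'
#' @param data Ranking records.
#' @param cohort Cohort table.
#' @param spec Base [rol_spec()].
#' @param covariates Covariates to test.
#' @return data.frame of class `rol_covariate_table`: one row per model term
#'   (attributes, current inhaler, interaction), one column per covariate.
#' @export
covariate_interaction_table <- function(data, cohort, spec = rol_spec(),
                                        covariates = c("gender", "age",
                                                       "disease",
                                                       "income_band",
                                                       "satisfaction")) {
  an <- vapply(spec$schema, `[[`, character(1), "name")
  cols <- lapply(covariates, function(cov) {
    sp <- spec
    sp$sq_interactions <- cov
    sp$disease_interactions <- character(0)
    fit <- fit_rol(data, cohort, sp)
    attr_p <- vapply(an, function(a) {
      tt <- grep(paste0("^", a, "($|:)"), names(fit$estimates), value = TRUE)
      tt <- setdiff(tt, grep(" x ", tt, value = TRUE))
      est <- fit$estimates[tt]
      V <- fit$vcov[tt, tt, drop = FALSE]
      stat <- drop(t(est) %*% solve(V) %*% est)
      pchisq(stat, df = length(tt), lower.tail = FALSE)
    }, numeric(1))
    sq_p <- fit$p_values["current_inhaler"]
    it <- grep("^current_inhaler x ", names(fit$estimates), value = TRUE)
    est <- fit$estimates[it]
    V <- fit$vcov[it, it, drop = FALSE]
    stat <- drop(t(est) %*% solve(V) %*% est)
    int_p <- pchisq(stat, df = length(it), lower.tail = FALSE)
    c(attr_p, current_inhaler = unname(sq_p), sq_interaction = int_p)
  })
  out <- as.data.frame(cols)
  names(out) <- covariates
  out <- cbind(term = rownames(out), out)
  rownames(out) <- NULL
  class(out) <- c("rol_covariate_table", "data.frame")
  out
}
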