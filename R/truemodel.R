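#' True utility parameters for simulation
#'
#' Bundles the parameters of the rank-ordered logit data-generating process:
#' marginal utilities on the dummy coding of the six device attributes, the
#' cost coefficient (utility per EUR/month), the status-quo
#' (current-inhaler) constant, and the SD of the patient-level random effect
#' that shifts the status-quo constant per respondent.
#'
#' @param beta Named vector of marginal utilities; names must be the
#'   categorical entries of [schema_terms()] for `schema`.
#' @param beta_cost Utility per EUR/month of extra out-of-pocket cost
#'   (negative in any sane preference structure).
#' @param delta_sq Status-quo constant: utility bonus of keeping the current
#'   inhaler when all attributes are equal.
#' @param sigma_re SD (>= 0) of the normal patient random effect on the
#'   status-quo constant.
#' @param schema The `dce_schema` the coding refers to.
#' @return List of class `true_model`.
#' @export
true_model <- function(beta, beta_cost, delta_sq = 0, sigma_re = 0,
                       schema = inhaler_schema()) {
  terms <- schema_terms(schema)
  cont <- vapply(schema, function(a) a$kind == "continuous", logical(1))
  cat_terms <- setdiff(terms, vapply(schema[cont], `[[`, character(1), "name"))
  if (is.null(names(beta)) || !setequal(names(beta), cat_terms)) {
    stop("beta must be named with exactly the categorical coded terms:\n  ",
         paste(cat_terms, collapse = ", "), call. = FALSE)
  }
  if (sigma_re < 0) stop("sigma_re must be >= 0", call. = FALSE)
  structure(list(beta = beta[cat_terms], beta_cost = beta_cost,
                 delta_sq = delta_sq, sigma_re = sigma_re, schema = schema),
            class = "true_model")
}

#' Reference marginal-utility estimates used as simulation defaults
#'
#' The per-group coefficient sets estimated in the published inhaler-device
#' preference study, usable as "true" parameters when simulating study-scale
#' data: ease of use 1 step / 2-3 steps, accurate dose counter, dose
#' confirmation by lactose taste, two mouthpiece-hygiene contrasts,
#' any-position handling, usability during breathing difficulties, the cost
#' coefficient per EUR/month and the current-inhaler constant.
#'
#' @param group `"asthma"` or `"copd"`.
#' @param sigma_re Random-effect SD to attach (the study reports none).
#' @return A [true_model()].
#' @export
study_true_model <- function(group = c("asthma", "copd"), sigma_re = 0.5) {
  group <- match.arg(group)
  sch <- inhaler_schema()
  if (group == "asthma") {
    beta <- c("ease_of_use:1 step" = 0.55,
              "ease_of_use:2 to 3 steps" = 0.281,
              "dose_counter:Yes" = 0.377,
              "dose_confirmation:Taste of lactose" = 0.333,
              "hygiene:Mouthpiece can be replaced" = -0.032,
              "hygiene:Mouthpiece can be washed" = 0.026,
              "flexibility:Any position" = 0.164,
              "breathing_difficulties:Yes" = 0.5)
    true_model(beta, beta_cost = -0.114, delta_sq = 0.207,
               sigma_re = sigma_re, schema = sch)
  } else {
    beta <- c("ease_of_use:1 step" = 0.282,
              "ease_of_use:2 to 3 steps" = 0.203,
              "dose_counter:Yes" = 0.419,
              "dose_confirmation:Taste of lactose" = 0.362,
              "hygiene:Mouthpiece can be replaced" = -0.028,
              "hygiene:Mouthpiece can be washed" = -0.073,
              "flexibility:Any position" = -0.03,
              "breathing_difficulties:Yes" = 0.549)
    true_model(beta, beta_cost = -0.067, delta_sq = 0.137,
               sigma_re = sigma_re, schema = sch)
  }
}

# full coefficient vector on the coded columns (cost slot filled in)
true_model_coef <- function(model) {
  terms <- schema_terms(model$schema)
  out <- setNames(numeric(length(terms)), terms)
  out[names(model$beta)] <- model$beta
  cont <- vapply(model$schema, function(a) a$kind == "continuous", logical(1))
  for (nm in vapply(model$schema[cont], `[[`, character(1), "name")) {
    out[nm] <- model$beta_cost
  }
  out
}
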