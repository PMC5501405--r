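#' Specify a rank-ordered logit model
#'
#' @param schema Attribute schema giving the dummy coding (reference levels).
#' @param include_status_quo_constant Add the current-inhaler dummy capturing
#'   status-quo preference at equal attributes.
#' @param random_effect `"status_quo"` for a normal patient-level effect on
#'   the status-quo constant (integrated by Gauss-Hermite quadrature), or
#'   `"none"` for the plain exploded logit.
#' @param disease_interactions Character vector of attribute names to
#'   interact with disease (COPD vs asthma), or `TRUE` for all attributes
#'   plus the status-quo dummy.
#' @param sq_interactions Character vector of cohort covariates
#'   (`"gender"`, `"age"`, `"disease"`, `"income_band"`, `"satisfaction"`)
#'   to interact with the status-quo dummy.
#' @param quadrature_nodes Number of Gauss-Hermite nodes (>= 1).
#' @return List of class `rol_spec`.
#' @export
rol_spec <- function(schema = inhaler_schema(),
                     include_status_quo_constant = TRUE,
                     random_effect = c("status_quo", "none"),
                     disease_interactions = character(0),
                     sq_interactions = character(0),
                     quadrature_nodes = 15L) {
  random_effect <- match.arg(random_effect)
  if (quadrature_nodes < 1L) stop("quadrature_nodes must be >= 1", call. = FALSE)
  an <- vapply(schema, `[[`, character(1), "name")
  if (isTRUE(disease_interactions)) {
    disease_interactions <- c(an, if (include_status_quo_constant) "current_inhaler")
  }
  bad <- setdiff(disease_interactions, c(an, "current_inhaler"))
  if (length(bad)) {
    stop("unknown attributes in disease_interactions: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ok_cov <- c("gender", "age", "disease", "income_band", "satisfaction")
  bad <- setdiff(sq_interactions, ok_cov)
  if (length(bad)) {
    stop("unknown covariates in sq_interactions: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(schema = schema,
                 include_status_quo_constant = include_status_quo_constant,
                 random_effect = random_effect,
                 disease_interactions = disease_interactions,
                 sq_interactions = sq_interactions,
                 quadrature_nodes = as.integer(quadrature_nodes)),
            class = "rol_spec")
}

# numeric coding of a cohort covariate for status-quo interactions;
# returns a one-or-more-column matrix per respondent row of `cov_df`
code_covariate <- function(cov, cov_df) {
  switch(cov,
    gender = cbind("female" = as.numeric(cov_df$gender == "female")),
    age = cbind("age_c" = cov_df$age - mean(cov_df$age)),
    disease = cbind("COPD" = as.numeric(cov_df$disease == "COPD")),
    income_band = {
      sc <- c("<EUR22,500" = 1, "EUR25,000-34,999" = 2, "EUR35,000-49,999" = 3,
              "EUR50,000-74,999" = 4, "EUR75,000+" = 5, "No answer" = NA)
      v <- sc[cov_df$income_band]
      cbind("income_score" = v - mean(v, na.rm = TRUE))
    },
    satisfaction = cbind(
      "satisfaction_neutral" = as.numeric(cov_df$satisfaction == "neutral"),
      "satisfaction_satisfied" = as.numeric(cov_df$satisfaction == "satisfied")),
    stop("unknown covariate '", cov, "'", call. = FALSE))
}

#' Encode ranking data for estimation
#'
#' Turns long-format ranking records (three rows per respondent x set) into
#' the coded arrays the likelihood consumes: dummy columns per non-reference
#' level, cost as its numeric EUR/month increment, the status-quo dummy and
#' any requested interaction columns; rows of each record are ordered by rank
#' so the explosion stages read off directly.
#'
#' Respondents with a missing interaction covariate (e.g. income "No answer")
#' are dropped with a message when that covariate is in the model.
#'
#' @param data A `dce_rankings` data.frame.
#' @param cohort Cohort table (required for disease/covariate interactions).
#' @param spec A [rol_spec()].
#' @return List of class `rol_encoded`: `X`, `resp` (0-based respondent index
#'   per record), `sq` (status-quo indicator per row), `n_resp`, `terms`,
#'   `respondent_ids`, `n_records`.
#' @export
encode <- function(data, cohort = NULL, spec = rol_spec()) {
  stopifnot(is.data.frame(data))
  need <- c("respondent_id", "set_id", "alt_id", "rank")
  if (!all(need %in% names(data))) {
    stop("ranking data must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  data <- data[order(data$respondent_id, data$set_id, data$rank), ]
  rec <- interaction(data$respondent_id, data$set_id, drop = TRUE)
  sizes <- table(rec)
  if (any(sizes != 3L)) {
    stop("every (respondent, set) record needs exactly 3 alternatives; bad: ",
         names(sizes)[which(sizes != 3L)[1L]], call. = FALSE)
  }
  rk <- tapply(data$rank, rec, function(r) identical(sort(r), 1:3))
  if (!all(unlist(rk))) {
    stop("rank must be a permutation of 1:3 within every record; bad: ",
         names(rk)[which(!unlist(rk))[1L]], call. = FALSE)
  }

  X <- code_profiles(data, spec$schema)
  sq <- as.numeric(data$alt_id == "current")
  if (spec$include_status_quo_constant) {
    X <- cbind(X, current_inhaler = sq)
  }

  keep_resp <- NULL
  if (length(spec$disease_interactions) || length(spec$sq_interactions)) {
    if (is.null(cohort)) {
      stop("interactions requested but no cohort table supplied", call. = FALSE)
    }
    m <- match(data$respondent_id, cohort$respondent_id)
    if (anyNA(m)) stop("respondents missing from cohort table", call. = FALSE)
    cov_df <- cohort[m, , drop = FALSE]

    if (length(spec$disease_interactions)) {
      if (length(unique(cohort$disease)) < 2L) {
        stop("disease interactions inestimable: single-group data", call. = FALSE)
      }
      copd <- as.numeric(cov_df$disease == "COPD")
      for (aname in spec$disease_interactions) {
        cols <- if (aname == "current_inhaler") "current_inhaler" else
          grep(paste0("^", aname, "($|:)"), colnames(X), value = TRUE)
        Xi <- X[, cols, drop = FALSE] * copd
        colnames(Xi) <- paste0(cols, " x COPD")
        X <- cbind(X, Xi)
      }
    }
    if (length(spec$sq_interactions)) {
      for (cov in spec$sq_interactions) {
        Z <- code_covariate(cov, cov_df)
        if (any(apply(Z, 2L, function(z) sd(z, na.rm = TRUE) == 0 ||
                      all(is.na(z))))) {
          stop("covariate '", cov,
               "' is constant: collinear with the status-quo constant",
               call. = FALSE)
        }
        Xi <- Z * sq
        colnames(Xi) <- paste0("current_inhaler x ", colnames(Z))
        X <- cbind(X, Xi)
        if (anyNA(Xi)) {
          drop_ids <- unique(data$respondent_id[rowSums(is.na(Xi)) > 0])
          message("dropping ", length(drop_ids),
                  " respondent(s) with missing '", cov, "'")
          keep <- !data$respondent_id %in% drop_ids
          data <- data[keep, , drop = FALSE]
          X <- X[keep, , drop = FALSE]
          sq <- sq[keep]
          cov_df <- cov_df[keep, , drop = FALSE]
        }
      }
    }
  }

  ids <- unique(data$respondent_id)
  resp_per_rec <- data$respondent_id[seq(1L, nrow(data), by = 3L)]
  structure(list(
    X = X,
    resp = match(resp_per_rec, ids) - 1L,
    sq = sq,
    n_resp = length(ids),
    terms = colnames(X),
    respondent_ids = ids,
    n_records = nrow(data) / 3L
  ), class = "rol_encoded")
}
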