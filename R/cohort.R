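#' Cohort configuration
#'
#' Marginal covariate distributions for the simulated respondent population,
#' one set per disease group. Defaults emulate the published study sample:
#' 201 asthma and 93 COPD respondents; mean (SD) ages 40.30 (13.44) and
#' 48.48 (15.16) years truncated at 18; female fractions 0.6866 and 0.5484;
#' current-device split 47/53 between the two study dry-powder inhalers;
#' income-band frequencies as observed; monthly out-of-pocket treatment cost
#' Gamma-distributed with means EUR 11.89 and 22.11 (SDs 21.93, 37.37); HUI3
#' utility Beta-distributed with means 0.71 and 0.54 (SDs 0.25, 0.30).
#' Satisfaction with the current inhaler: 52%/46% satisfied, remainder split
#' between neutral and unsatisfied.
#'
#' @param n_asthma,n_copd Group sizes.
#' @param asthma,copd Named lists overriding any of the per-group settings
#'   (`age_mean`, `age_sd`, `p_female`, `p_device_a`, `income_probs`,
#'   `cost_mean`, `cost_sd`, `hui3_mean`, `hui3_sd`, `satisfaction_probs`).
#' @param n_blocks Number of design blocks respondents are rotated through.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_asthma = 201L, n_copd = 93L,
                          asthma = list(), copd = list(), n_blocks = 3L) {
  income_bands <- c("<EUR22,500", "EUR25,000-34,999", "EUR35,000-49,999",
                    "EUR50,000-74,999", "EUR75,000+", "No answer")
  base_asthma <- list(
    age_mean = 40.30, age_sd = 13.44, p_female = 0.6866, p_device_a = 0.47,
    income_probs = setNames(c(0.4826, 0.1940, 0.1493, 0.0746, 0.0100, 0.0896) /
                              sum(c(0.4826, 0.1940, 0.1493, 0.0746, 0.0100, 0.0896)),
                            income_bands),
    cost_mean = 11.89, cost_sd = 21.93, hui3_mean = 0.71, hui3_sd = 0.25,
    satisfaction_probs = c(satisfied = 0.52, neutral = 0.30, unsatisfied = 0.18))
  base_copd <- list(
    age_mean = 48.48, age_sd = 15.16, p_female = 0.5484, p_device_a = 0.47,
    income_probs = setNames(c(0.4301, 0.1505, 0.1613, 0.0753, 0.0645, 0.1183) /
                              sum(c(0.4301, 0.1505, 0.1613, 0.0753, 0.0645, 0.1183)),
                            income_bands),
    cost_mean = 22.11, cost_sd = 37.37, hui3_mean = 0.54, hui3_sd = 0.30,
    satisfaction_probs = c(satisfied = 0.46, neutral = 0.34, unsatisfied = 0.20))
  cfg <- list(n_asthma = as.integer(n_asthma), n_copd = as.integer(n_copd),
              asthma = modifyList(base_asthma, asthma),
              copd = modifyList(base_copd, copd),
              n_blocks = as.integer(n_blocks))
  for (g in c("asthma", "copd")) {
    for (pp in c("income_probs", "satisfaction_probs")) {
      pr <- cfg[[g]][[pp]]
      if (abs(sum(pr) - 1) > 1e-6 || any(pr < 0)) {
        stop(g, " ", pp, " must be nonnegative and sum to 1", call. = FALSE)
      }
      cfg[[g]][[pp]] <- pr / sum(pr)
    }
  }
  structure(cfg, class = "cohort_config")
}

# moment-matched helper distributions for bounded/nonneg covariates
rgamma_ms <- function(n, mean, sd) {
  shape <- (mean / sd)^2
  rgamma(n, shape = shape, scale = sd^2 / mean)
}
rbeta_ms <- function(n, mean, sd) {
  v <- sd^2
  k <- mean * (1 - mean) / v - 1
  k <- max(k, 1e-6)
  rbeta(n, shape1 = mean * k, shape2 = (1 - mean) * k)
}

#' Simulate a respondent cohort
#'
#' Draws covariates independently from the configured per-group marginals and
#' assigns respondents to design blocks round-robin after a seed-controlled
#' shuffle, so block sizes are as equal as possible within each group.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the cohort is deterministic given the seed.
#' @return data.frame of class `dce_cohort`, one row per respondent:
#'   `respondent_id`, `disease`, `age`, `gender`, `income_band`,
#'   `satisfaction`, `current_inhaler`, `current_cost`, `hui3`, `block_id`.
#' @export
generate_respondents <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_asthma < 0L || config$n_copd < 0L) {
    stop("group sizes must be >= 0", call. = FALSE)
  }
  with_seed(seed, {
    one_group <- function(n, disease, g) {
      if (n == 0L) return(NULL)
      age <- g$age_mean + g$age_sd * rnorm(n)
      age <- pmax(round(age), 18)
      data.frame(
        disease = disease,
        age = age,
        gender = ifelse(runif(n) < g$p_female, "female", "male"),
        income_band = sample(names(g$income_probs), n, replace = TRUE,
                             prob = g$income_probs),
        satisfaction = sample(names(g$satisfaction_probs), n, replace = TRUE,
                              prob = g$satisfaction_probs),
        current_inhaler = ifelse(runif(n) < g$p_device_a,
                                 "device-A", "device-B"),
        current_cost = rgamma_ms(n, g$cost_mean, g$cost_sd),
        hui3 = rbeta_ms(n, g$hui3_mean, g$hui3_sd),
        stringsAsFactors = FALSE)
    }
    cohort <- rbind(one_group(config$n_asthma, "asthma", config$asthma),
                    one_group(config$n_copd, "COPD", config$copd))
    if (is.null(cohort)) {
      cohort <- data.frame(disease = character(0), age = numeric(0),
                           gender = character(0), income_band = character(0),
                           satisfaction = character(0),
                           current_inhaler = character(0),
                           current_cost = numeric(0), hui3 = numeric(0))
    }
    n <- nrow(cohort)
    cohort <- cbind(respondent_id = seq_len(n), cohort)
    block_id <- integer(n)
    if (n > 0L) {
      ord <- sample.int(n)
      block_id[ord] <- rep_len(seq_len(config$n_blocks), n)
    }
    cohort$block_id <- block_id
    class(cohort) <- c("dce_cohort", "data.frame")
    cohort
  })
}

#' Attribute profiles of the respondents' current inhalers
#'
#' The fixed attribute description shown to a respondent for their own
#' device. The study instrument never published these descriptions, so they
#' are configurable; the defaults describe two plausible dry-powder inhalers:
#' both need 2 to 3 preparation steps, must be held in a certain position,
#' have a dry-cloth-only mouthpiece and cannot be used during breathing
#' difficulties; device-A has no accurate dose counter and no lactose taste,
#' device-B has an accurate counter and a lactose taste. The cost increment
#' of the current inhaler is always 0 (its cost is the respondent's current
#' level of expenditure).
#'
#' @return Named list of one-row data.frames keyed by device label.
#' @export
default_device_profiles <- function() {
  list(
    "device-A" = data.frame(
      ease_of_use = "2 to 3 steps", dose_counter = "No",
      dose_confirmation = "No taste of lactose",
      hygiene = "Cleaned with a dry cloth", flexibility = "Certain position",
      breathing_difficulties = "No", cost = 0, stringsAsFactors = FALSE),
    "device-B" = data.frame(
      ease_of_use = "2 to 3 steps", dose_counter = "Yes",
      dose_confirmation = "Taste of lactose",
      hygiene = "Cleaned with a dry cloth", flexibility = "Certain position",
      breathing_difficulties = "No", cost = 0, stringsAsFactors = FALSE)
  )
}

#' Look up the current-inhaler profile of a respondent
#'
#' @param respondent One row of a `dce_cohort`.
#' @param profile_map Named list of profiles per device label, as
#'   [default_device_profiles()].
#' @return One-row data.frame of attribute levels (cost increment 0).
#' @export
current_profile <- function(respondent, profile_map = default_device_profiles()) {
  dev <- respondent$current_inhaler
  if (length(dev) != 1L || is.null(profile_map[[dev]])) {
    stop("no current-inhaler profile configured for device label '",
         paste(dev, collapse = ","), "'", call. = FALSE)
  }
  profile_map[[dev]]
}

#' Summarise a cohort in the study's demographics layout
#'
#' @param cohort A `dce_cohort`.
#' @return data.frame with one row per statistic and columns per group.
#' @export
cohort_summary <- function(cohort) {
  groups <- split(cohort, factor(cohort$disease, c("asthma", "COPD")))
  groups$Total <- cohort
  stat <- function(g) {
    c(n = nrow(g),
      age_mean = mean(g$age), age_sd = sd(g$age),
      female_pct = 100 * mean(g$gender == "female"),
      deviceA_pct = 100 * mean(g$current_inhaler == "device-A"),
      cost_mean = mean(g$current_cost), cost_sd = sd(g$current_cost),
      hui3_mean = mean(g$hui3), hui3_sd = sd(g$hui3),
      satisfied_pct = 100 * mean(g$satisfaction == "satisfied"))
  }
  out <- as.data.frame(lapply(groups, stat))
  names(out) <- names(groups)
  cbind(statistic = rownames(out), out, row.names = NULL)
}
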