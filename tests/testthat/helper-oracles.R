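# Independent oracles and small fixtures shared across the test files.
# Everything here is deliberately written by direct enumeration / explicit
# arithmetic, independent of the package's own computational paths.

# exploded-logit probability of observing `ranking` (a permutation of
# seq_along(u)) given utilities u, by literal stage-wise computation
oracle_rank_prob <- function(u, ranking) {
  p <- 1
  remaining <- ranking
  for (s in seq_len(length(u) - 1L)) {
    p <- p * exp(u[remaining[1L]]) / sum(exp(u[remaining]))
    remaining <- remaining[-1L]
  }
  p
}

# probabilities of all permutations of the alternatives
oracle_perm_probs <- function(u) {
  perms <- all_permutations(length(u))
  vapply(perms, function(pr) oracle_rank_prob(u, pr), numeric(1))
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (k in seq_len(n)) {
    for (sub in all_permutations(n - 1L)) {
      rest <- setdiff(seq_len(n), k)
      out[[length(out) + 1L]] <- c(k, rest[sub])
    }
  }
  out
}

# brute-force MNL information matrix and D-efficiency: explicit probability
# vectors, diag matrices and determinant arithmetic, no shortcut algebra
oracle_info_matrix <- function(design, beta = NULL) {
  X <- code_profiles(design$profiles, design$schema, center_continuous = TRUE)
  p <- ncol(X)
  if (is.null(beta)) beta <- rep(0, p)
  M <- matrix(0, p, p)
  for (s in unique(design$profiles$set_id)) {
    Xs <- X[design$profiles$set_id == s, , drop = FALSE]
    u <- as.vector(Xs %*% beta)
    pr <- exp(u) / sum(exp(u))
    M <- M + t(Xs) %*% (diag(pr) - pr %*% t(pr)) %*% Xs
  }
  M
}

oracle_d_efficiency <- function(design, beta = NULL) {
  M <- oracle_info_matrix(design, beta)
  d <- det(M)
  if (d <= 0) 0 else d^(1 / ncol(M)) / design$n_sets
}

# one-record encoded object with prescribed utilities: alternative A carries
# the "1 step" dummy, B the "2 to 3 steps" dummy and the current inhaler its
# status-quo dummy, so three free coefficients set the three utilities
encode_single <- function(ranking = c("A", "B", "current"),
                          spec = rol_spec(schema = inhaler_schema(),
                                          include_status_quo_constant = TRUE,
                                          random_effect = "none")) {
  base <- data.frame(
    ease_of_use = "More than 4 steps", dose_counter = "No",
    dose_confirmation = "No taste of lactose",
    hygiene = "Cleaned with a dry cloth", flexibility = "Certain position",
    breathing_difficulties = "No", cost = 0, stringsAsFactors = FALSE)
  alts <- c("A", "B", "current")
  rows <- base[rep(1, 3), ]
  rows$ease_of_use <- c("1 step", "2 to 3 steps", "More than 4 steps")
  dat <- cbind(data.frame(respondent_id = 1L, block_id = 1L, set_id = 1L,
                          alt_id = alts), rows,
               data.frame(rank = match(alts, ranking),
                          step1_choice = "A", step2_choice = "winner"))
  encode(dat, cohort = NULL, spec = spec)
}

# minimal schemas and designs --------------------------------------------

binary_schema <- function() {
  attribute_schema(attribute_spec("feature", c("on", "off"),
                                  reference_level = "off"))
}

toy_schema <- function() {
  attribute_schema(
    attribute_spec("shape", c("round", "square"), reference_level = "square"),
    attribute_spec("colour", c("red", "green", "blue"),
                   reference_level = "blue"),
    attribute_spec("price", c(0, 2, 4), kind = "continuous"))
}

# hand-built design: explicit profile rows, one block
manual_design <- function(schema, profile_rows) {
  n_sets <- length(profile_rows) / 2L
  df <- do.call(rbind, profile_rows)
  profiles <- cbind(data.frame(block_id = 1L,
                               set_id = rep(seq_len(n_sets), each = 2L),
                               alt_id = rep(1:2, n_sets)),
                    df)
  choice_design(profiles, schema)
}

# study-scale fixture shared by several files (built once per test run)
fixture_env <- new.env()
study_fixture <- function() {
  if (is.null(fixture_env$des)) {
    fixture_env$des <- search_design(inhaler_schema(), 36, 3, seed = 7,
                                     n_restarts = 4)
    fixture_env$coh <- generate_respondents(cohort_config(), seed = 11)
  }
  list(design = fixture_env$des, cohort = fixture_env$coh)
}

# small all-in-one simulated study for fast fitting tests
small_study <- function(n_asthma = 40, n_copd = 0, n_sets = 8, seed = 5,
                        model = study_true_model("asthma", sigma_re = 0),
                        model_copd = study_true_model("copd", sigma_re = 0)) {
  des <- search_design(inhaler_schema(), n_sets, 1, seed = seed,
                       n_restarts = 2)
  coh <- generate_respondents(
    cohort_config(n_asthma, n_copd, n_blocks = 1), seed = seed + 1)
  groups <- split(coh, coh$disease)
  dat <- do.call(rbind, lapply(names(groups), function(g) {
    tm <- if (g == "COPD") model_copd else model
    as.data.frame(simulate_study(groups[[g]], des, tm, seed = seed + 2))
  }))
  class(dat) <- c("dce_rankings", "data.frame")
  list(design = des, cohort = coh, data = dat)
}
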