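test_that("ranking likelihood matches closed-form toy cases", {
  spec <- rol_spec(random_effect = "none")
  # all utilities equal -> every ranking has probability 1/6
  enc <- encode_single()
  th <- rep(0, ncol(enc$X))
  expect_equal(ranking_loglik(th, enc, spec), log(1 / 6), tolerance = 1e-12)

  # utilities (ln 2, 0, 0) and ranking (A, B, current):
  # P = (2/4) * (1/2) = 0.25
  names(th) <- enc$terms
  th["ease_of_use:1 step"] <- log(2)
  th["ease_of_use:2 to 3 steps"] <- 0
  expect_equal(ranking_loglik(th, enc, spec), log(0.25), tolerance = 1e-12)

  # parameter vector must match the coded dimension (+1 with a random effect)
  expect_error(ranking_loglik(c(th, 0), enc, spec), "expected")
  expect_error(ranking_loglik(th, enc, rol_spec()), "expected")
})

test_that("exploded probabilities match permutation enumeration to 1e-12", {
  spec <- rol_spec(random_effect = "none")
  alts <- c("A", "B", "current")
  set.seed(8)
  for (rep in 1:20) {
    th_util <- rnorm(3, 0, 1.2)        # utilities of A, B, current
    perm <- sample(3)
    enc <- encode_single(ranking = alts[perm])
    th <- setNames(rep(0, ncol(enc$X)), enc$terms)
    th["ease_of_use:1 step"] <- th_util[1]
    th["ease_of_use:2 to 3 steps"] <- th_util[2]
    th["current_inhaler"] <- th_util[3]
    p_pkg <- exp(ranking_loglik(th, enc, spec))
    p_oracle <- oracle_rank_prob(th_util, perm)
    expect_equal(p_pkg, p_oracle, tolerance = 1e-12)
    # conservation over all 6 rankings
    expect_equal(sum(oracle_perm_probs(th_util)), 1, tolerance = 1e-12)
    total <- sum(vapply(all_permutations(3), function(pr)
      exp(ranking_loglik(th, encode_single(ranking = alts[pr]), spec)),
      numeric(1)))
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("sigma -> 0 quadrature reduces to the plain exploded logit", {
  st <- small_study(n_asthma = 25, n_sets = 6, seed = 61)
  for (nodes in c(3, 15, 41)) {
    spec_re <- rol_spec(quadrature_nodes = nodes)
    spec0 <- rol_spec(random_effect = "none")
    enc_re <- encode(st$data, st$cohort, spec_re)
    enc0 <- encode(st$data, st$cohort, spec0)
    th <- c(rnorm(ncol(enc0$X), 0, 0.3), -40)   # log_sigma = -40 ~ sigma 0
    expect_equal(ranking_loglik(th, enc_re, spec_re),
                 ranking_loglik(th[-length(th)], enc0, spec0),
                 tolerance = 1e-10)
  }
})

test_that("ranking probabilities are location invariant", {
  # adding a constant utility to all three alternatives of every record
  # (an extra all-ones column) leaves the likelihood unchanged
  st <- small_study(n_asthma = 15, n_sets = 6, seed = 71)
  spec <- rol_spec(random_effect = "none")
  enc <- encode(st$data, st$cohort, spec)
  th <- rnorm(ncol(enc$X), 0, 0.4)
  base <- ranking_loglik(th, enc, spec)
  enc_shift <- enc
  enc_shift$X <- cbind(enc$X, shift = 1)
  for (const in c(-3.3, 0.7, 12)) {
    expect_equal(ranking_loglik(c(th, const), enc_shift, spec), base,
                 tolerance = 1e-10)
  }
})

test_that("encoding produces documented columns, products and errors", {
  st <- small_study(n_asthma = 10, n_copd = 10, n_sets = 4, seed = 81)
  spec <- rol_spec()
  enc <- encode(st$data, st$cohort, spec)
  expect_equal(enc$n_records, nrow(st$data) / 3)
  expect_true("current_inhaler" %in% enc$terms)
  # status-quo indicator marks exactly the current alternative
  expect_equal(enc$sq, as.numeric(
    st$data$alt_id[order(st$data$respondent_id, st$data$set_id,
                         st$data$rank)] == "current"))

  # interaction column is the elementwise product dummy x 1[COPD]
  spec_i <- rol_spec(disease_interactions = "flexibility")
  enc_i <- encode(st$data, st$cohort, spec_i)
  ordd <- st$data[order(st$data$respondent_id, st$data$set_id, st$data$rank), ]
  copd <- as.numeric(st$cohort$disease[match(ordd$respondent_id,
                                             st$cohort$respondent_id)] == "COPD")
  expect_equal(unname(enc_i$X[, "flexibility:Any position x COPD"]),
               unname(enc_i$X[, "flexibility:Any position"] * copd))

  # malformed records are rejected with pointers
  bad <- st$data
  bad$rank[1:3] <- c(1L, 1L, 2L)
  expect_error(encode(bad, st$cohort, spec), "permutation")
  bad2 <- st$data[-1, ]
  expect_error(encode(bad2, st$cohort, spec), "exactly 3")
  bad3 <- st$data
  bad3$hygiene[2] <- "unknown-level"
  expect_error(encode(bad3, st$cohort, spec), "unknown-level")
})

test_that("null data recover null coefficients within 3 SEs", {
  tm0 <- study_true_model("asthma", sigma_re = 0)
  tm0$beta[] <- 0; tm0$beta_cost <- 0; tm0$delta_sq <- 0
  st <- small_study(n_asthma = 120, n_sets = 10, seed = 91, model = tm0)
  fit <- fit_rol(st$data, st$cohort, rol_spec(random_effect = "none"))
  expect_true(fit$converged)
  z <- abs(fit$estimates / fit$std_errors)
  expect_true(all(z < 3.5), label = "all null-data z-scores below 3.5")
})

test_that("sigma=0 MLE agrees with a stratified conditional-logit oracle", {
  skip_if_not_installed("survival")
  st <- small_study(n_asthma = 60, n_sets = 8, seed = 101)
  spec <- rol_spec(random_effect = "none")
  fit <- fit_rol(st$data, st$cohort, spec)

  # independent route: explode each ranking into its two MNL stages and fit
  # a conditional logit across stage-strata with survival::clogit
  d <- st$data[order(st$data$respondent_id, st$data$set_id, st$data$rank), ]
  X <- code_profiles(d, spec$schema)
  X <- cbind(X, current_inhaler = as.numeric(d$alt_id == "current"))
  i1 <- seq(1, nrow(d), by = 3)
  stage1 <- data.frame(y = rep(c(1, 0, 0), length(i1)),
                       stratum = rep(seq_along(i1), each = 3))
  X1 <- X[as.vector(t(cbind(i1, i1 + 1, i1 + 2))), ]
  stage2 <- data.frame(y = rep(c(1, 0), length(i1)),
                       stratum = length(i1) + rep(seq_along(i1), each = 2))
  X2 <- X[as.vector(t(cbind(i1 + 1, i1 + 2))), ]
  dd <- rbind(cbind(stage1, X1), cbind(stage2, X2))
  names(dd) <- make.names(names(dd))
  fml <- stats::as.formula(paste(
    "survival::Surv(rep(1, nrow(dd)), y) ~",
    paste(setdiff(names(dd), c("y", "stratum")), collapse = " + "),
    "+ survival::strata(stratum)"))
  cl <- survival::coxph(fml, data = dd, method = "exact")
  expect_equal(unname(fit$estimates), unname(coef(cl)), tolerance = 1e-4)
  expect_equal(unname(fit$std_errors), unname(sqrt(diag(vcov(cl)))),
               tolerance = 1e-3)
})

test_that("sigma is estimated near zero on sigma=0 data", {
  st <- small_study(n_asthma = 80, n_sets = 8, seed = 111)  # sigma_re = 0 DGP
  fit_re <- fit_rol(st$data, st$cohort, rol_spec(quadrature_nodes = 9))
  fit0 <- fit_rol(st$data, st$cohort, rol_spec(random_effect = "none"))
  expect_lt(fit_re$sigma_re, 0.15)
  expect_lt(abs(fit_re$log_likelihood - fit0$log_likelihood), 0.5)
})

test_that("odds ratios and Wald tests follow their definitions", {
  fake <- structure(list(
    estimates = c(a = 0, b = 1.96, log_sigma = -1),
    std_errors = c(a = 1, b = 1, log_sigma = 0.5)), class = "rol_fit")
  expect_equal(unname(odds_ratios(fake)), c(1, exp(1.96)))
  p <- wald_tests(fake)
  expect_equal(unname(p["a"]), 1)
  expect_equal(unname(p["b"]), 0.05, tolerance = 1e-3)
  fake$std_errors["a"] <- 0
  expect_error(wald_tests(fake), "degenerate")
})
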