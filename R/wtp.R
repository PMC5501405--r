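#' Willingness-to-pay point estimate
#'
#' WTP for an attribute change is its marginal utility divided by the
#' marginal utility of keeping one euro per month, i.e.
#' `estimate(term) / (-estimate(cost))`. Invariant under joint rescaling of
#' all utility coefficients.
#'
#' @param fit A `rol_fit` (or any object with named `estimates`).
#' @param term Coefficient name, e.g. `"ease_of_use:1 step"`.
#' @param cost_term Name of the cost coefficient.
#' @return EUR/month scalar.
#' @export
wtp_point <- function(fit, term, cost_term = "cost") {
  est <- if (inherits(fit, "rol_fit")) fit$estimates else fit
  if (!term %in% names(est)) stop("unknown term '", term, "'", call. = FALSE)
  bc <- est[[cost_term]]
  if (!is.finite(bc) || bc >= 0) {
    stop("cost coefficient is ", format(bc),
         " (>= 0): WTP undefined; not silently sign-flipped", call. = FALSE)
  }
  unname(est[[term]] / (-bc))
}

#' MCMC settings
#'
#' @param n_iter Total iterations.
#' @param burn_in Discarded initial iterations (< n_iter).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param proposal_scale Scalar multiplier on the Cholesky factor of the MLE
#'   covariance used as random-walk proposal (default the usual
#'   `2.38 / sqrt(p)` rule).
#' @param seed Integer seed (required for reproducible chains).
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 30000L, burn_in = 5000L, thin = 5L,
                        proposal_scale = NULL, seed = 1L) {
  if (burn_in >= n_iter) stop("burn_in must be < n_iter", call. = FALSE)
  if (thin < 1L) stop("thin must be >= 1", call. = FALSE)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), proposal_scale = proposal_scale,
                 seed = seed),
            class = "mcmc_config")
}

#' Random-walk Metropolis sampling of the model parameters
#'
#' Samples the exploded-logit posterior under flat (improper) priors on the
#' utility coefficients (and on `log(sigma)`), initialised at the MLE with a
#' multivariate-normal proposal built from the scaled MLE covariance. Used to
#' propagate estimation uncertainty into WTP ratios.
#'
#' @param fit A converged `rol_fit`.
#' @param encoded The [encode()] result the fit was computed on (re-encoded
#'   automatically when `data`/`cohort` are given instead).
#' @param config An [mcmc_config()].
#' @param data,cohort Alternative to `encoded`: raw tables to re-encode.
#' @param log_post Optional replacement log-posterior `function(theta)`
#'   (used in tests against a conjugate target); defaults to the model
#'   log-likelihood.
#' @return Matrix of class `rol_draws` (retained draws x parameters) with
#'   attributes `acceptance_rate` and `config`.
#' @export
mcmc_sample <- function(fit, encoded = NULL, config = mcmc_config(),
                        data = NULL, cohort = NULL, log_post = NULL) {
  theta0 <- fit$estimates
  V <- fit$vcov
  if (is.null(log_post)) {
    if (is.null(encoded)) {
      if (is.null(data)) stop("need `encoded` or `data`", call. = FALSE)
      encoded <- encode(data, cohort, fit$spec)
    }
    spec <- fit$spec
    re <- spec$random_effect == "status_quo"
    gh <- if (re) gauss_hermite_rule(spec$quadrature_nodes) else list(z = 0, w = 1)
    log_post <- function(th) rol_loglik_cpp(encoded$X, encoded$resp,
                                            encoded$sq, encoded$n_resp, th,
                                            gh$z, gh$w, re, FALSE)$loglik
  }
  k <- length(theta0)
  if (any(!is.finite(V))) stop("fit has no usable covariance", call. = FALSE)
  sc <- config$proposal_scale %||% (2.38 / sqrt(k))
  L <- t(chol((V + t(V)) / 2)) * sc

  keep_idx <- seq(config$burn_in + 1L, config$n_iter, by = config$thin)
  draws <- matrix(NA_real_, length(keep_idx), k,
                  dimnames = list(NULL, names(theta0)))
  with_seed(config$seed, {
    cur <- as.numeric(theta0)
    cur_lp <- log_post(cur)
    acc <- 0L
    ki <- 1L
    for (it in seq_len(config$n_iter)) {
      prop <- cur + drop(L %*% rnorm(k))
      lp <- log_post(prop)
      if (is.finite(lp) && log(runif(1)) < lp - cur_lp) {
        cur <- prop; cur_lp <- lp; acc <- acc + 1L
      }
      if (ki <= length(keep_idx) && it == keep_idx[ki]) {
        draws[ki, ] <- cur
        ki <- ki + 1L
      }
    }
    rate <- acc / config$n_iter
    if (rate < 0.1 || rate > 0.6) {
      warning(sprintf(
        "Metropolis acceptance rate %.2f outside [0.1, 0.6]; consider rescaling the proposal",
        rate))
    }
    structure(draws, class = c("rol_draws", "matrix", "array"),
              acceptance_rate = rate, config = config)
  })
}

#' WTP posterior summary from MCMC draws
#'
#' Per-draw ratio `term / (-cost)`; reports the posterior mean and the
#' central 95% credibility interval (2.5th/97.5th percentiles). Draws with a
#' non-negative cost coefficient (where the ratio is undefined) are excluded
#' and counted.
#'
#' @param draws A `rol_draws` matrix.
#' @param term Coefficient name (or vector of names).
#' @param cost_term Name of the cost coefficient column.
#' @param point Optional named vector of point estimates to carry along.
#' @param group Optional group label.
#' @return data.frame of class `wtp_result`: `term`, `point`,
#'   `posterior_mean`, `ci_low`, `ci_high`, `n_draws`, `n_excluded`, `group`.
#' @export
wtp_credible <- function(draws, term, cost_term = "cost", point = NULL,
                         group = NA_character_) {
  stopifnot(cost_term %in% colnames(draws))
  ok <- draws[, cost_term] < 0
  n_excl <- sum(!ok)
  if (n_excl > 0) {
    message(n_excl, " of ", nrow(draws),
            " draws had cost coefficient >= 0; excluded from WTP summaries")
  }
  d <- draws[ok, , drop = FALSE]
  rows <- lapply(term, function(tm) {
    if (!tm %in% colnames(draws)) stop("unknown term '", tm, "'", call. = FALSE)
    ratio <- d[, tm] / (-d[, cost_term])
    qs <- unname(quantile(ratio, c(0.025, 0.975), names = FALSE))
    data.frame(term = tm,
               point = if (is.null(point)) NA_real_ else
                 unname(point[[tm]] / (-point[[cost_term]])),
               posterior_mean = mean(ratio),
               ci_low = qs[1], ci_high = qs[2],
               n_draws = nrow(d), n_excluded = n_excl,
               group = group, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("wtp_result", "data.frame")
  out
}

#' Full WTP table for a fitted model
#'
#' Convenience wrapper: samples the posterior and summarises WTP for every
#' categorical attribute term plus the status-quo constant.
#'
#' @param fit A converged `rol_fit`.
#' @param encoded The matching [encode()] result.
#' @param config An [mcmc_config()].
#' @param group Group label carried into the table.
#' @return A `wtp_result` data.frame (one row per term).
#' @export
wtp_table <- function(fit, encoded, config = mcmc_config(), group = NA) {
  draws <- mcmc_sample(fit, encoded, config)
  terms <- setdiff(names(fit$estimates), c("cost", "log_sigma"))
  terms <- terms[!grepl(" x ", terms)]
  wtp_credible(draws, terms, point = fit$estimates, group = group)
}

#' Compare WTP between two groups
#'
#' @param wtp_a,wtp_b `wtp_result` tables with matching terms.
#' @return data.frame with per-term WTP of both groups, their difference
#'   (b - a), and whether the 95% intervals overlap.
#' @export
compare_groups <- function(wtp_a, wtp_b) {
  if (!setequal(wtp_a$term, wtp_b$term)) {
    stop("term sets differ: ",
         paste(c(setdiff(wtp_a$term, wtp_b$term),
                 setdiff(wtp_b$term, wtp_a$term)), collapse = ", "),
         call. = FALSE)
  }
  b <- wtp_b[match(wtp_a$term, wtp_b$term), ]
  data.frame(term = wtp_a$term,
             mean_a = wtp_a$posterior_mean, mean_b = b$posterior_mean,
             difference = b$posterior_mean - wtp_a$posterior_mean,
             intervals_overlap = pmax(wtp_a$ci_low, b$ci_low) <=
               pmin(wtp_a$ci_high, b$ci_high),
             stringsAsFactors = FALSE)
}
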