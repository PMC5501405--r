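#' Exploded-logit log-likelihood of ranking data
#'
#' The probability of a record's ranking is the product over explosion stages
#' of multinomial-logit choices among the not-yet-ranked alternatives. With a
#' status-quo random effect, each respondent's product over sets is
#' integrated over `b ~ N(0, sigma^2)` by Gauss-Hermite quadrature; with
#' sigma fixed at 0 (one node) this is exactly the plain exploded logit.
#'
#' @param params Numeric vector: one coefficient per coded column, plus
#'   `log(sigma)` as last element when `spec$random_effect == "status_quo"`.
#' @param encoded An [encode()] result.
#' @param spec The [rol_spec()] used to encode.
#' @param gradient Also return the analytic gradient as attribute `"gradient"`.
#' @return Scalar log-likelihood.
#' @export
ranking_loglik <- function(params, encoded, spec, gradient = FALSE) {
  re <- spec$random_effect == "status_quo"
  p <- ncol(encoded$X)
  if (length(params) != p + as.integer(re)) {
    stop("params has length ", length(params), ", expected ",
         p + as.integer(re), call. = FALSE)
  }
  gh <- if (re) gauss_hermite_rule(spec$quadrature_nodes) else list(z = 0, w = 1)
  out <- rol_loglik_cpp(encoded$X, encoded$resp, encoded$sq, encoded$n_resp,
                        as.numeric(params), gh$z, gh$w, re, gradient)
  ll <- out$loglik
  if (gradient) attr(ll, "gradient") <- out$grad
  ll
}

#' Fit the rank-ordered logit by maximum likelihood
#'
#' Quasi-Newton (BFGS) maximisation with the analytic gradient; the
#' random-effect SD is estimated on the log scale. Standard errors come from
#' the inverse observed information (numerical Jacobian of the analytic
#' gradient) at the optimum.
#'
#' @param data Long-format ranking records (`dce_rankings`).
#' @param cohort Cohort table (needed for interaction terms).
#' @param spec A [rol_spec()].
#' @param start Optional named start vector (defaults: 0 for utilities,
#'   -0.05 for cost terms, sigma start 0.1).
#' @param se Compute the observed-information covariance and standard errors
#'   (skip in simulation loops that only need point estimates).
#' @return Object of class `rol_fit` with elements `estimates`, `std_errors`,
#'   `vcov`, `log_likelihood`, `odds_ratios`, `p_values`, `converged`,
#'   `sigma_re`, `n_respondents`, `n_records`, `spec`, `encoded_terms`.
#' @export
fit_rol <- function(data, cohort = NULL, spec = rol_spec(), start = NULL,
                    se = TRUE) {
  enc <- encode(data, cohort, spec)
  if (enc$n_records < 1L) stop("no complete ranking records", call. = FALSE)
  re <- spec$random_effect == "status_quo"
  p <- ncol(enc$X)
  par_names <- c(enc$terms, if (re) "log_sigma")

  if (is.null(start)) {
    start <- setNames(numeric(p), enc$terms)
    cont <- vapply(spec$schema, function(a) a$kind == "continuous", logical(1))
    cont_names <- vapply(spec$schema[cont], `[[`, character(1), "name")
    start[enc$terms %in% cont_names] <- -0.05
    if (re) start <- c(start, log_sigma = log(0.1))
  }
  stopifnot(length(start) == length(par_names))

  gh <- if (re) gauss_hermite_rule(spec$quadrature_nodes) else list(z = 0, w = 1)
  negll <- function(th) -rol_loglik_cpp(enc$X, enc$resp, enc$sq, enc$n_resp,
                                        th, gh$z, gh$w, re, FALSE)$loglik
  neggr <- function(th) -rol_loglik_cpp(enc$X, enc$resp, enc$sq, enc$n_resp,
                                        th, gh$z, gh$w, re, TRUE)$grad

  opt <- optim(as.numeric(start), negll, neggr, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-9))
  theta <- opt$par
  # Newton polish on the analytic gradient: BFGS line searches stall once
  # objective changes reach the summation noise floor, but the gradient
  # itself is exact; the observed information (recomputed at most twice)
  # drives the remaining steps
  H <- NULL
  g <- neggr(theta)
  for (i in 1:12) {
    if (max(abs(g)) < 1e-7) break
    if (is.null(H) || i %in% c(5L, 9L)) H <- num_hessian(neggr, theta)
    step <- try(solve((H + t(H)) / 2, g), silent = TRUE)
    if (inherits(step, "try-error")) break
    cand <- theta - step
    gc_ <- neggr(cand)
    if (max(abs(gc_)) < max(abs(g))) {
      theta <- cand
      g <- gc_
    } else break
  }
  theta <- setNames(theta, par_names)
  grad <- -g
  converged <- max(abs(grad)) < 1e-5
  # near a flat sigma boundary the log-sigma gradient can stall; accept when
  # all utility-scale gradients are tight and sigma is effectively zero
  if (!converged && re && exp(theta["log_sigma"]) < 1e-3 &&
      max(abs(grad[seq_len(p)])) < 1e-5) converged <- TRUE

  if (se) {
    H <- num_hessian(neggr, theta)
    vc <- try(solve((H + t(H)) / 2), silent = TRUE)
    if (inherits(vc, "try-error") || any(!is.finite(vc)) ||
        any(diag(vc) <= 0)) {
      if (converged) warning("observed information not invertible; SEs withheld")
      vc <- matrix(NA_real_, length(theta), length(theta))
    }
    dimnames(vc) <- list(par_names, par_names)
    ses <- sqrt(diag(vc))
    if (!converged) ses[] <- NA_real_
  } else {
    vc <- matrix(NA_real_, length(theta), length(theta),
                 dimnames = list(par_names, par_names))
    ses <- setNames(rep(NA_real_, length(theta)), par_names)
  }

  big <- abs(theta[seq_len(p)]) > 15
  if (any(big)) {
    warning("possible separation: extreme estimate(s) for ",
            paste(par_names[which(big)], collapse = ", "))
  }

  est <- theta
  fit <- structure(list(
    estimates = est,
    std_errors = ses,
    vcov = vc,
    log_likelihood = -opt$value,
    converged = converged,
    sigma_re = if (re) unname(exp(est["log_sigma"])) else 0,
    n_respondents = enc$n_resp,
    n_records = enc$n_records,
    spec = spec,
    encoded_terms = enc$terms,
    gradient_norm = max(abs(grad))
  ), class = "rol_fit")
  fit$odds_ratios <- odds_ratios(fit)
  fit$p_values <- if (all(is.na(ses))) setNames(rep(NA_real_, length(est)),
                                                names(est)) else wald_tests(fit)
  fit
}

# central-difference Jacobian of a gradient function (observed information)
num_hessian <- function(gr, theta, h = 1e-5) {
  k <- length(theta)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    hj <- h * (1 + abs(theta[j]))
    tp <- tm <- theta
    tp[j] <- tp[j] + hj
    tm[j] <- tm[j] - hj
    H[, j] <- (gr(tp) - gr(tm)) / (2 * hj)
  }
  H
}

#' Odds ratios of utility-scale estimates
#'
#' @param fit A `rol_fit`.
#' @return Named vector `exp(estimate)` for every utility-scale term (the
#'   random-effect SD parameter is excluded).
#' @export
odds_ratios <- function(fit) {
  est <- fit$estimates
  est <- est[setdiff(names(est), "log_sigma")]
  exp(est)
}

#' Two-sided Wald tests
#'
#' @param fit A `rol_fit`.
#' @return Named vector of p-values `2 * pnorm(-|estimate / SE|)` for the
#'   utility-scale terms.
#' @export
wald_tests <- function(fit) {
  est <- fit$estimates[setdiff(names(fit$estimates), "log_sigma")]
  se <- fit$std_errors[names(est)]
  if (any(!is.na(se) & se == 0)) {
    stop("degenerate fit: zero standard error for ",
         paste(names(se)[which(se == 0)], collapse = ", "), call. = FALSE)
  }
  2 * pnorm(-abs(est / se))
}

#' @export
print.rol_fit <- function(x, ...) {
  cat("Rank-ordered (exploded) logit fit\n")
  cat("  respondents: ", x$n_respondents, "   records: ", x$n_records,
      "   logLik: ", format(x$log_likelihood, digits = 8), "\n", sep = "")
  cat("  converged: ", x$converged,
      if (x$spec$random_effect == "status_quo")
        paste0("   sigma_re: ", format(x$sigma_re, digits = 4)), "\n", sep = "")
  print(fit_table(x), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Coefficient table in the study's reporting layout
#'
#' @param fit A `rol_fit`.
#' @return data.frame with columns `term`, `estimate`, `se`, `p_value`,
#'   `odds_ratio`.
#' @export
fit_table <- function(fit) {
  terms <- setdiff(names(fit$estimates), "log_sigma")
  data.frame(term = terms,
             estimate = unname(fit$estimates[terms]),
             se = unname(fit$std_errors[terms]),
             p_value = unname(fit$p_values[terms]),
             odds_ratio = unname(fit$odds_ratios[terms]),
             stringsAsFactors = FALSE)
}

#' @export
coef.rol_fit <- function(object, ...) object$estimates

#' @export
vcov.rol_fit <- function(object, ...) object$vcov

#' @export
logLik.rol_fit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$estimates),
            class = "logLik")
}
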