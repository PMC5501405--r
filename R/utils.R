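#' @useDynLib inhalerdce, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rgamma rbeta optim pnorm qnorm quantile sd
#'   cor dnorm pchisq setNames
#' @importFrom utils write.csv read.csv modifyList
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministically fold a master seed with integer indices into a
# substream seed in [1, 2^31 - 2]. Keeps record-level reproducibility
# independent of the order in which records are simulated.
derive_seed <- function(master, ...) {
  h <- as.double(master) %% 2147483647
  for (x in c(...)) {
    h <- (h * 69069 + as.double(x) + 1) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Gauss-Hermite rule rescaled for E[f(b)], b ~ N(0, sigma^2):
# sum(w * f(sqrt(2) * sigma * z)) with w summing to 1.
gauss_hermite_rule <- function(n_nodes) {
  if (n_nodes == 1L) return(list(z = 0, w = 1))
  gh <- pracma::gaussHermite(n_nodes)
  list(z = gh$x, w = gh$w / sqrt(pi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
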