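#' Construct a choice design object
#'
#' A design is a long-format table of profiles: one row per choice set x
#' alternative, two fictitious alternatives per set. The respondent's current
#' inhaler is appended at simulation/analysis time, not stored in the design.
#'
#' @param profiles data.frame with columns `block_id`, `set_id`, `alt_id` and
#'   one column per schema attribute.
#' @param schema The `dce_schema` the profiles are drawn from.
#' @return An object of class `dce_design`.
#' @export
choice_design <- function(profiles, schema) {
  stopifnot(is.data.frame(profiles),
            all(c("block_id", "set_id", "alt_id") %in% names(profiles)))
  an <- vapply(schema, `[[`, character(1), "name")
  if (!all(an %in% names(profiles))) {
    stop("profiles lack attribute columns: ",
         paste(setdiff(an, names(profiles)), collapse = ", "), call. = FALSE)
  }
  profiles <- profiles[order(profiles$set_id, profiles$alt_id),
                       c("block_id", "set_id", "alt_id", an)]
  rownames(profiles) <- NULL
  counts <- table(profiles$set_id)
  if (any(counts != 2L)) stop("every set needs exactly 2 alternatives", call. = FALSE)
  bs <- table(unique(profiles[c("set_id", "block_id")])$block_id)
  if (length(unique(bs)) > 1L) stop("block sizes must be equal", call. = FALSE)
  structure(list(profiles = profiles, schema = schema,
                 n_sets = length(counts), n_blocks = length(bs)),
            class = "dce_design")
}

#' @export
print.dce_design <- function(x, ...) {
  cat("D-efficient choice design: ", x$n_sets, " sets in ", x$n_blocks,
      " block(s) of ", x$n_sets / x$n_blocks, "\n", sep = "")
  d <- d_efficiency(x, beta = NULL)
  cat("D-efficiency at zero prior: ", format(d, digits = 5), "\n", sep = "")
  invisible(x)
}

# Per-set coded difference vectors and MNL weights at beta.
# With two alternatives the per-set Fisher information is
# p1*p2 * d %*% t(d), d the coded difference of the two rows.
design_contrasts <- function(design, beta = NULL) {
  X <- code_profiles(design$profiles, design$schema, center_continuous = TRUE)
  p <- ncol(X)
  i1 <- seq(1L, nrow(X), by = 2L)
  D <- X[i1, , drop = FALSE] - X[i1 + 1L, , drop = FALSE]
  if (is.null(beta)) beta <- rep(0, p)
  if (length(beta) != p) {
    stop("beta has length ", length(beta), ", expected ", p, call. = FALSE)
  }
  eta <- drop(D %*% beta)                    # u1 - u2
  p1 <- 1 / (1 + exp(-eta))
  list(D = D, w = p1 * (1 - p1), terms = colnames(X))
}

#' Fisher information of the MNL over a design
#'
#' Sums, over choice sets, `X_s' (P_s - p_s p_s') X_s` where `X_s` is the
#' coded two-row alternative matrix of set `s` and `p_s` the multinomial-logit
#' choice probabilities at `beta`. Symmetric positive semidefinite.
#'
#' @param design A `dce_design`.
#' @param beta Prior coefficient vector on the coded columns; `NULL` means the
#'   utility-neutral prior (all zero).
#' @return Symmetric p x p matrix, dimnames = coded column names.
#' @export
mnl_information_matrix <- function(design, beta = NULL) {
  ct <- design_contrasts(design, beta)
  M <- crossprod(ct$D * sqrt(ct$w))
  dimnames(M) <- list(ct$terms, ct$terms)
  M
}

#' D-efficiency of a choice design
#'
#' `det(M)^(1/p) / n_sets` with `M` the MNL Fisher information and `p` the
#' number of coded parameters; 0 when `M` is singular.
#'
#' @inheritParams mnl_information_matrix
#' @return Nonnegative scalar.
#' @export
d_efficiency <- function(design, beta = NULL) {
  M <- mnl_information_matrix(design, beta)
  p <- ncol(M)
  dt <- suppressWarnings(determinant(M, logarithm = TRUE))
  if (dt$sign <= 0 || !is.finite(dt$modulus)) return(0)
  exp(as.numeric(dt$modulus) / p) / design$n_sets
}

# Draw a design uniformly at random: each set is an unordered pair of
# distinct candidate profiles. Used as search start and as the random
# benchmark population.
random_design <- function(schema, n_sets, n_blocks = 1L, seed = NULL,
                          candidates = NULL) {
  with_seed(seed, {
    if (is.null(candidates)) candidates <- enumerate_full_factorial(schema)
    n <- nrow(candidates)
    idx <- matrix(0L, n_sets, 2L)
    for (s in seq_len(n_sets)) idx[s, ] <- sample.int(n, 2L, replace = FALSE)
    profiles <- candidates[as.vector(t(idx)), , drop = FALSE]
    profiles <- cbind(
      data.frame(block_id = rep(rep(seq_len(n_blocks),
                                    each = n_sets / n_blocks), each = 2L),
                 set_id = rep(seq_len(n_sets), each = 2L),
                 alt_id = rep(1:2, n_sets)),
      profiles)
    choice_design(profiles, schema)
  })
}

#' Search for a D-efficient blocked choice design
#'
#' Profile-level coordinate exchange from random starts: every alternative of
#' every set is in turn offered each candidate profile from the full
#' factorial, and an exchange is kept only when it strictly increases the
#' D-efficiency (ties keep the incumbent). Passes repeat until no exchange
#' improves, and the best of `n_restarts` starts is returned, blocked into
#' `n_blocks` balanced blocks.
#'
#' @param schema A `dce_schema`.
#' @param n_sets Number of choice sets (must be divisible by `n_blocks`).
#' @param n_blocks Number of blocks.
#' @param beta Prior coefficients for the information matrix (`NULL` =
#'   utility-neutral zero prior, main-effects coding).
#' @param seed Integer seed; the search is deterministic given the seed.
#' @param n_restarts Random restarts of the exchange search.
#' @param max_passes Safety cap on full exchange passes per restart.
#' @return A `dce_design` with diagnostics attached (`$diagnostics`).
#' @export
search_design <- function(schema, n_sets = 36L, n_blocks = 3L, beta = NULL,
                          seed = 1L, n_restarts = 20L, max_passes = 25L) {
  if (n_sets %% n_blocks != 0L) {
    stop("n_sets (", n_sets, ") not divisible by n_blocks (", n_blocks, ")",
         call. = FALSE)
  }
  candidates <- enumerate_full_factorial(schema)
  C <- code_profiles(candidates, schema, center_continuous = TRUE)
  p <- ncol(C)
  if (is.null(beta)) beta <- rep(0, p)

  best <- NULL
  best_eff <- -Inf
  for (r in seq_len(n_restarts)) {
    des <- random_design(schema, n_sets, 1L, seed = derive_seed(seed, r),
                         candidates = candidates)
    idx <- matrix(match(
      interaction(des$profiles[, names(candidates), drop = FALSE], drop = FALSE),
      interaction(candidates, drop = FALSE)), ncol = 2L, byrow = TRUE)
    res <- exchange_search(idx, C, beta, n_sets, max_passes)
    if (res$eff > best_eff) {
      best_eff <- res$eff
      best <- res$idx
    }
  }

  profiles <- cbind(
    data.frame(block_id = 1L, set_id = rep(seq_len(n_sets), each = 2L),
               alt_id = rep(1:2, n_sets)),
    candidates[as.vector(t(best)), , drop = FALSE])
  des <- choice_design(profiles, schema)
  des <- block_design(des, n_blocks, seed = derive_seed(seed, 0L))
  des$diagnostics <- design_diagnostics(des)
  des
}

# Coordinate-exchange inner loop on candidate indices (n_sets x 2).
# Uses rank-one determinant updates vectorised over all candidates.
exchange_search <- function(idx, C, beta, n_sets, max_passes) {
  p <- ncol(C)
  set_info <- function(i, j) {
    d <- C[i, ] - C[j, ]
    eta <- sum(d * beta)
    pr <- 1 / (1 + exp(-eta))
    list(d = d, w = pr * (1 - pr))
  }
  build_M <- function(idx) {
    M <- matrix(0, p, p)
    for (s in seq_len(n_sets)) {
      si <- set_info(idx[s, 1L], idx[s, 2L])
      M <- M + si$w * tcrossprod(si$d)
    }
    M
  }
  logdet <- function(M) {
    dt <- suppressWarnings(determinant(M, logarithm = TRUE))
    if (dt$sign <= 0 || !is.finite(dt$modulus)) -Inf else as.numeric(dt$modulus)
  }

  M <- build_M(idx)
  ld <- logdet(M)
  nC <- nrow(C)
  eta_all <- drop(C %*% beta)

  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (s in seq_len(n_sets)) {
      for (a in 1:2) {
        partner <- idx[s, 3L - a]
        cur <- set_info(idx[s, a], partner)
        M0 <- M - cur$w * tcrossprod(cur$d)
        ld0 <- logdet(M0)
        # candidate difference vectors and MNL weights against the partner
        D <- sweep(C, 2L, C[partner, ])
        eta <- eta_all - sum(C[partner, ] * beta)
        w <- 1 / (1 + exp(-eta)); w <- w * (1 - w)
        Minv0 <- if (is.finite(ld0)) try(solve(M0), silent = TRUE) else NULL
        if (!is.null(Minv0) && !inherits(Minv0, "try-error")) {
          q <- rowSums((D %*% Minv0) * D)
          ld_cand <- ld0 + log1p(pmax(w * q, -1 + 1e-300))
        } else {
          ld_cand <- vapply(seq_len(nC), function(k)
            logdet(M0 + w[k] * tcrossprod(D[k, ])), numeric(1))
        }
        ld_cand[partner] <- -Inf   # no within-set duplicate profile
        k <- which.max(ld_cand)
        if (ld_cand[k] > ld + 1e-9 && k != idx[s, a]) {
          # verify with an exact determinant before accepting the exchange,
          # so the search is monotone even when the rank-one update is noisy
          si <- set_info(k, partner)
          M_new <- M0 + si$w * tcrossprod(si$d)
          ld_new <- logdet(M_new)
          if (ld_new > ld + 1e-12) {
            idx[s, a] <- k
            M <- M_new
            ld <- ld_new
            improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }
  list(idx = idx, eff = if (is.finite(ld)) exp(ld / p) / n_sets else 0)
}

#' Assign choice sets to balanced blocks
#'
#' Splits the sets into `n_blocks` equal blocks, then greedily swaps sets
#' between blocks to minimise the maximum per-block deviation of attribute
#' level frequencies from perfect balance (ties broken by the sum of squared
#' deviations; the incumbent assignment is kept on exact ties).
#'
#' @param design A `dce_design`.
#' @param n_blocks Number of blocks; must divide the number of sets.
#' @param seed Seed for the initial shuffled assignment.
#' @return The design with `block_id` reassigned.
#' @export
block_design <- function(design, n_blocks, seed = NULL) {
  n_sets <- design$n_sets
  if (n_sets %% n_blocks != 0L) {
    stop("n_sets not divisible by n_blocks", call. = FALSE)
  }
  prof <- design$profiles
  set_ids <- sort(unique(prof$set_id))
  if (n_blocks == 1L) {
    prof$block_id <- 1L
    out <- choice_design(prof, design$schema)
    return(out)
  }
  # per-set level count matrix (levels of every attribute, continuous levels
  # treated as labels for balance purposes)
  lv_cols <- unlist(lapply(design$schema, function(a)
    paste0(a$name, "=", a$levels)))
  counts <- matrix(0L, n_sets, length(lv_cols),
                   dimnames = list(NULL, lv_cols))
  for (a in design$schema) {
    for (lv in a$levels) {
      col <- paste0(a$name, "=", lv)
      hits <- tapply(prof[[a$name]] == lv, prof$set_id, sum)
      counts[, col] <- as.integer(hits[as.character(set_ids)])
    }
  }
  per_block <- n_sets / n_blocks
  ideal <- colSums(counts) / n_blocks

  objective <- function(assign) {
    block_tot <- rowsum(counts, assign)
    dev <- abs(sweep(block_tot, 2L, ideal))
    c(max(dev), sum(dev^2))
  }
  assign <- with_seed(seed, rep(seq_len(n_blocks), per_block)[sample.int(n_sets)])
  obj <- objective(assign)
  repeat {
    improved <- FALSE
    for (i in seq_len(n_sets - 1L)) for (j in seq(i + 1L, n_sets)) {
      if (assign[i] == assign[j]) next
      cand <- assign
      cand[c(i, j)] <- cand[c(j, i)]
      co <- objective(cand)
      if (co[1] < obj[1] - 1e-12 ||
          (abs(co[1] - obj[1]) < 1e-12 && co[2] < obj[2] - 1e-12)) {
        assign <- cand; obj <- co; improved <- TRUE
      }
    }
    if (!improved) break
  }
  prof$block_id <- assign[match(prof$set_id, set_ids)]
  # renumber sets so set_id is nested in block order
  ord <- order(prof$block_id, prof$set_id, prof$alt_id)
  prof <- prof[ord, ]
  out <- choice_design(prof, design$schema)
  out
}

#' Design diagnostics
#'
#' Level frequencies per attribute, pairwise correlations of the coded
#' columns, duplicate-set count, and D-efficiency at the zero prior.
#'
#' @param design A `dce_design`.
#' @return A list of class `dce_diagnostics` with elements `d_efficiency`,
#'   `level_balance`, `pairwise_correlation`, `duplicate_set_count`.
#' @export
design_diagnostics <- function(design) {
  prof <- design$profiles
  balance <- lapply(design$schema, function(a) {
    tab <- table(factor(prof[[a$name]], levels = a$levels))
    as.data.frame(tab, responseName = "freq", stringsAsFactors = FALSE)
  })
  names(balance) <- vapply(design$schema, `[[`, character(1), "name")

  X <- code_profiles(prof, design$schema, center_continuous = TRUE)
  sds <- apply(X, 2L, sd)
  if (any(sds == 0)) {
    warning("constant coded column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "),
            "; correlations reported as NA")
  }
  suppressWarnings(corr <- cor(X))
  corr[sds == 0, ] <- NA_real_
  corr[, sds == 0] <- NA_real_
  diag(corr) <- 1

  key <- vapply(split(prof, prof$set_id), function(s) {
    rows <- apply(s[, names(s) %in% vapply(design$schema, `[[`,
                                           character(1), "name"),
                    drop = FALSE], 1L, paste, collapse = "\r")
    paste(sort(rows), collapse = "\n")
  }, character(1))
  structure(list(
    d_efficiency = d_efficiency(design, beta = NULL),
    level_balance = balance,
    pairwise_correlation = corr,
    duplicate_set_count = as.integer(design$n_sets - length(unique(key)))
  ), class = "dce_diagnostics")
}

#' @export
print.dce_diagnostics <- function(x, ...) {
  cat("D-efficiency (zero prior): ", format(x$d_efficiency, digits = 5), "\n",
      "Duplicate sets: ", x$duplicate_set_count, "\n", sep = "")
  cat("Level balance:\n")
  for (nm in names(x$level_balance)) {
    b <- x$level_balance[[nm]]
    cat("  ", nm, ": ", paste(b$freq, collapse = "/"), "\n", sep = "")
  }
  invisible(x)
}

#' Write / read a design as CSV (+ JSON diagnostics sidecar)
#'
#' @param design A `dce_design`.
#' @param path CSV output path; diagnostics go to `<path>.diag.json`.
#' @export
write_design <- function(design, path) {
  write.csv(design$profiles, path, row.names = FALSE)
  diag <- design$diagnostics %||% design_diagnostics(design)
  side <- list(
    d_efficiency = diag$d_efficiency,
    duplicate_set_count = diag$duplicate_set_count,
    level_balance = diag$level_balance
  )
  jsonlite::write_json(side, paste0(path, ".diag.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_design
#' @param schema Schema the design was built from.
#' @export
read_design <- function(path, schema) {
  prof <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  choice_design(prof, schema)
}
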