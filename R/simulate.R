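#' Simulate one two-step choice task
#'
#' Draws one independent standard Gumbel error per alternative, so the
#' observed two-step outcome (first a choice between the two fictitious
#' inhalers, then between that winner and the current inhaler) coincides with
#' the full descending sort of the three total utilities. Utilities are
#' `U_j = x_j beta + cost_j beta_cost + 1[j = current] (delta_sq + b_i) + e_j`.
#'
#' @param respondent One row of a `dce_cohort`.
#' @param choice_set Two-row data.frame of attribute columns (alternatives A
#'   and B of one design set).
#' @param model A [true_model()].
#' @param seed Integer seed for the three Gumbel draws.
#' @param random_effect The respondent's latent status-quo shift `b_i`.
#' @param profile_map Device profile lookup, as [default_device_profiles()].
#' @return One-row data.frame: `step1_choice` (A|B), `step2_choice`
#'   (winner|current), `rank1`, `rank2`, `rank3` (the descending-utility
#'   ranking over A, B, current).
#' @export
simulate_choice_set <- function(respondent, choice_set, model, seed = NULL,
                                random_effect = 0,
                                profile_map = default_device_profiles()) {
  coefs <- true_model_coef(model)
  Xab <- code_profiles(choice_set, model$schema)
  cur <- current_profile(respondent, profile_map)
  xc <- code_profiles(cur, model$schema)
  u <- c(drop(Xab %*% coefs),
         drop(xc %*% coefs) + model$delta_sq + random_effect)
  g <- with_seed(seed, -log(-log(runif(3))))
  tot <- u + g
  ranking_from_utilities(tot)
}

# descending sort of total utilities over (A, B, current) -> two-step record
ranking_from_utilities <- function(tot) {
  alts <- c("A", "B", "current")
  ord <- order(tot, decreasing = TRUE)
  step1 <- alts[1:2][which.max(tot[1:2])]
  step2 <- if (tot[3] > max(tot[1:2])) "current" else "winner"
  data.frame(step1_choice = step1, step2_choice = step2,
             rank1 = alts[ord[1]], rank2 = alts[ord[2]], rank3 = alts[ord[3]],
             stringsAsFactors = FALSE)
}

#' Simulate a full ranking study
#'
#' Every respondent answers the 12 choice sets of their assigned block; each
#' record gets its own substream seed derived from the master seed and the
#' (respondent, set) pair, so record-level draws are reproducible regardless
#' of simulation order. Latent random effects are drawn per respondent from
#' `N(0, sigma_re^2)` and never exported.
#'
#' @param cohort A `dce_cohort`.
#' @param design A `dce_design`.
#' @param model A [true_model()].
#' @param seed Master integer seed.
#' @param profile_map Device profile lookup.
#' @return Long-format data.frame of class `dce_rankings`: three rows per
#'   respondent x choice set (`alt_id` in A, B, current) with the shown
#'   attribute levels, cost increment, `rank` (1-3) and the step choices.
#'   The latent random effects are attached as `attr(, "random_effects")`
#'   for inspection but are not part of the exported table.
#' @export
simulate_study <- function(cohort, design, model, seed = 1L,
                           profile_map = default_device_profiles()) {
  an <- vapply(model$schema, `[[`, character(1), "name")
  coefs <- true_model_coef(model)
  prof <- design$profiles
  Xd <- code_profiles(prof, model$schema)
  ud <- drop(Xd %*% coefs)

  if (nrow(cohort) == 0L) {
    out <- cbind(data.frame(respondent_id = integer(0), block_id = integer(0),
                            set_id = integer(0), alt_id = character(0)),
                 prof[0, an, drop = FALSE],
                 data.frame(rank = integer(0), step1_choice = character(0),
                            step2_choice = character(0)))
    attr(out, "random_effects") <- numeric(0)
    class(out) <- c("dce_rankings", "data.frame")
    return(out)
  }

  dev_u <- vapply(profile_map, function(p)
    drop(code_profiles(p, model$schema) %*% coefs), numeric(1))
  devs <- names(profile_map)
  bad_dev <- setdiff(unique(cohort$current_inhaler), devs)
  if (length(bad_dev)) {
    stop("no current-inhaler profile configured for device label '",
         bad_dev[1L], "'", call. = FALSE)
  }

  re <- vapply(seq_len(nrow(cohort)), function(i) {
    if (model$sigma_re == 0) 0
    else with_seed(derive_seed(seed, cohort$respondent_id[i], 0L),
                   rnorm(1, 0, model$sigma_re))
  }, numeric(1))

  # record grid: one row per respondent x set in their block
  set_of_block <- split(unique(prof[c("set_id", "block_id")])$set_id,
                        unique(prof[c("set_id", "block_id")])$block_id)
  n_per <- lengths(set_of_block)[as.character(cohort$block_id)]
  ri <- rep(seq_len(nrow(cohort)), n_per)
  si <- unlist(set_of_block[as.character(cohort$block_id)], use.names = FALSE)
  n_rec <- length(ri)

  G <- matrix(0, n_rec, 3L)
  for (r in seq_len(n_rec)) {
    G[r, ] <- with_seed(derive_seed(seed, cohort$respondent_id[ri[r]], si[r]),
                        runif(3))
  }
  G <- -log(-log(G))

  row1 <- match(si, prof$set_id)            # profiles sorted by set, alt
  totA <- ud[row1] + G[, 1L]
  totB <- ud[row1 + 1L] + G[, 2L]
  totC <- dev_u[cohort$current_inhaler[ri]] + model$delta_sq + re[ri] + G[, 3L]

  rankA <- 1L + (totB > totA) + (totC > totA)
  rankB <- 1L + (totA >= totB) + (totC > totB)
  rankC <- 6L - rankA - rankB
  step1 <- ifelse(totA >= totB, "A", "B")
  step2 <- ifelse(totC > pmax(totA, totB), "current", "winner")

  # three output rows per record: A, B, current
  dev_attrs <- do.call(rbind, lapply(profile_map, function(p)
    p[, an, drop = FALSE]))
  idx <- rep(seq_len(n_rec), each = 3L)
  alt <- rep(c("A", "B", "current"), n_rec)
  shown <- prof[1L, an, drop = FALSE][rep(1L, 3L * n_rec), , drop = FALSE]
  a_rows <- seq(1L, 3L * n_rec, by = 3L)
  shown[a_rows, ] <- prof[row1, an, drop = FALSE]
  shown[a_rows + 1L, ] <- prof[row1 + 1L, an, drop = FALSE]
  shown[a_rows + 2L, ] <- dev_attrs[match(cohort$current_inhaler[ri], devs), ,
                                    drop = FALSE]
  out <- cbind(
    data.frame(respondent_id = cohort$respondent_id[ri][idx],
               block_id = cohort$block_id[ri][idx],
               set_id = si[idx],
               alt_id = alt, stringsAsFactors = FALSE),
    shown,
    data.frame(rank = as.integer(rbind(rankA, rankB, rankC)),
               step1_choice = step1[idx], step2_choice = step2[idx],
               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "random_effects") <- setNames(re, cohort$respondent_id)
  class(out) <- c("dce_rankings", "data.frame")
  out
}

#' Write / read study tables as CSV
#'
#' The rankings export strips the latent random effects; identical seeds give
#' byte-identical files.
#'
#' @param x Rankings or cohort data.frame.
#' @param path File path.
#' @export
write_rankings <- function(x, path) {
  df <- as.data.frame(x)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rankings
#' @export
read_rankings <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  class(out) <- c("dce_rankings", "data.frame")
  out
}

#' @rdname write_rankings
#' @export
write_cohort <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rankings
#' @export
read_cohort <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  class(out) <- c("dce_cohort", "data.frame")
  out
}
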