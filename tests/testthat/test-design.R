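test_that("information matrix matches closed forms on tiny designs", {
  sch <- binary_schema()
  on <- data.frame(feature = "on")
  off <- data.frame(feature = "off")

  # identical profiles in a set contribute nothing (no contrast)
  des0 <- manual_design(sch, list(on, on))
  expect_equal(unname(mnl_information_matrix(des0)), matrix(0, 1, 1))

  # one contrasting set at beta = 0: information = 0.25 * d d'
  des1 <- manual_design(sch, list(on, off))
  d <- 1  # coded difference on - off
  expect_equal(unname(mnl_information_matrix(des1, beta = 0)),
               matrix(0.25 * d * d, 1, 1))

  # prior coefficient vector must match the coded dimension
  expect_error(mnl_information_matrix(des1, beta = c(0, 0)), "length")
})

test_that("information matrix equals brute-force probability arithmetic", {
  sch <- toy_schema()
  set.seed(42)
  ff <- enumerate_full_factorial(sch)
  for (rep in 1:5) {
    des <- random_design(sch, n_sets = 6, seed = 100 + rep, candidates = ff)
    for (beta in list(NULL, rnorm(4, 0, 0.5))) {
      M <- mnl_information_matrix(des, beta)
      expect_equal(unname(M), unname(oracle_info_matrix(des, beta)),
                   tolerance = 1e-10)
      expect_true(all(eigen(M, symmetric = TRUE)$values >= -1e-10))
      expect_equal(d_efficiency(des, beta), oracle_d_efficiency(des, beta),
                   tolerance = 1e-10)
    }
  }
})

test_that("d-efficiency is zero for singular designs and per-set normalised", {
  sch <- binary_schema()
  on <- data.frame(feature = "on")
  dup <- manual_design(sch, list(on, on, on, on))
  expect_equal(d_efficiency(dup), 0)

  sch2 <- toy_schema()
  des <- random_design(sch2, n_sets = 4, seed = 3)
  prof2 <- des$profiles
  prof2$set_id <- prof2$set_id + 4L
  doubled <- choice_design(rbind(des$profiles, prof2), sch2)
  expect_equal(d_efficiency(doubled), d_efficiency(des), tolerance = 1e-12)
})

test_that("hand-enumerable two-attribute design matches exhaustive arithmetic", {
  sch <- attribute_schema(
    attribute_spec("a", c("hi", "lo"), reference_level = "lo"),
    attribute_spec("b", c("hi", "lo"), reference_level = "lo"))
  rows <- list(
    data.frame(a = "hi", b = "lo"), data.frame(a = "lo", b = "hi"),
    data.frame(a = "hi", b = "hi"), data.frame(a = "lo", b = "lo"),
    data.frame(a = "hi", b = "lo"), data.frame(a = "lo", b = "lo"),
    data.frame(a = "lo", b = "hi"), data.frame(a = "lo", b = "lo"))
  des <- manual_design(sch, rows)
  # at beta = 0 every set weight is 1/4; the four sets' coded difference
  # vectors, enumerated by hand from the profile pairs above:
  D <- rbind(c(1, -1), c(1, 1), c(1, 0), c(0, 1))
  M <- matrix(0, 2, 2)
  for (i in 1:4) M <- M + 0.25 * D[i, ] %*% t(D[i, ])
  expect_equal(unname(mnl_information_matrix(des)), M)
  expect_equal(d_efficiency(des), det(M)^(1 / 2) / 4)
})

test_that("coordinate-exchange search honours its contracts", {
  sch <- binary_schema()
  # two sets, one binary attribute: only the two-level contrast in both sets
  # is nonsingular (up to relabeling)
  des <- search_design(sch, n_sets = 2, n_blocks = 1, seed = 4,
                       n_restarts = 3)
  for (s in 1:2) {
    lv <- des$profiles$feature[des$profiles$set_id == s]
    expect_setequal(lv, c("on", "off"))
  }

  expect_error(search_design(toy_schema(), n_sets = 7, n_blocks = 3),
               "not divisible")

  # determinism and monotonicity vs the random designs the search starts from
  sch2 <- toy_schema()
  d1 <- search_design(sch2, 12, 3, seed = 9, n_restarts = 3)
  d2 <- search_design(sch2, 12, 3, seed = 9, n_restarts = 3)
  expect_identical(d1$profiles, d2$profiles)
  eff <- d_efficiency(d1)
  for (r in 1:3) {
    start <- random_design(sch2, 12, 1, seed = inhalerdce:::derive_seed(9, r))
    expect_gte(eff, d_efficiency(start))
  }
})

test_that("blocking balances levels and conserves the set list", {
  sch <- binary_schema()
  on <- data.frame(feature = "on")
  off <- data.frame(feature = "off")
  # 4 perfectly balanced sets; either block split puts each level twice per
  # block (all 3 pairings of 4 sets into 2 blocks are balanced here)
  des <- manual_design(sch, list(on, off, on, off, on, off, on, off))
  b <- block_design(des, 2, seed = 1)
  for (blk in 1:2) {
    lv <- b$profiles$feature[b$profiles$block_id == blk]
    expect_equal(sum(lv == "on"), 2L)
    expect_equal(sum(lv == "off"), 2L)
  }
  # conservation: same multiset of sets before and after
  key <- function(d) sort(vapply(split(d$profiles$feature, d$profiles$set_id),
                                 paste, character(1), collapse = "|"))
  expect_equal(key(b), key(des))

  b1 <- block_design(des, 1)
  expect_equal(unique(b1$profiles$block_id), 1L)
  expect_equal(b1$n_sets, des$n_sets)
})

test_that("diagnostics report balance, orthogonality and degeneracies", {
  sch <- attribute_schema(
    attribute_spec("a", c("hi", "lo"), reference_level = "lo"),
    attribute_spec("b", c("hi", "lo"), reference_level = "lo"))
  # orthogonal toy design: coded columns of the 2x2 factorial crossed
  rows <- list(
    data.frame(a = "hi", b = "hi"), data.frame(a = "lo", b = "lo"),
    data.frame(a = "hi", b = "lo"), data.frame(a = "lo", b = "hi"))
  des <- manual_design(sch, rows)
  diag <- design_diagnostics(des)
  expect_equal(unname(diag$pairwise_correlation[1, 2]), 0)
  expect_equal(diag$duplicate_set_count, 0L)
  freqs <- diag$level_balance$a$freq
  expect_equal(sum(freqs), des$n_sets * 2L)

  # constant column: flagged NA with a warning
  rows_const <- list(
    data.frame(a = "hi", b = "hi"), data.frame(a = "hi", b = "lo"),
    data.frame(a = "hi", b = "lo"), data.frame(a = "hi", b = "hi"))
  des_const <- manual_design(sch, rows_const)
  expect_warning(dg <- design_diagnostics(des_const), "constant")
  expect_true(is.na(dg$pairwise_correlation["a:hi", "b:hi"]))

  # duplicate sets are counted (unordered profile pairs)
  rows_dup <- list(
    data.frame(a = "hi", b = "hi"), data.frame(a = "lo", b = "lo"),
    data.frame(a = "lo", b = "lo"), data.frame(a = "hi", b = "hi"))
  expect_equal(design_diagnostics(manual_design(sch, rows_dup))$duplicate_set_count,
               1L)
})

test_that("study-scale search yields near-balanced non-duplicated sets", {
  des <- study_fixture()$design
  expect_equal(des$n_sets, 36L)
  expect_equal(des$n_blocks, 3L)
  expect_equal(as.integer(table(unique(des$profiles[c("set_id", "block_id")])$block_id)),
               rep(12L, 3))
  diag <- des$diagnostics
  expect_equal(diag$duplicate_set_count, 0L)
  for (a in inhaler_schema()) {
    if (a$kind != "categorical") next  # cost is pushed to extreme levels
    L <- length(a$levels)
    expect_true(all(abs(diag$level_balance[[a$name]]$freq - 72 / L) <= 2),
                label = paste("level balance within +/-2 for", a$name))
  }
  # design CSV + diagnostics sidecar round trip
  f <- tempfile(fileext = ".csv")
  write_design(des, f)
  expect_true(file.exists(paste0(f, ".diag.json")))
  des2 <- read_design(f, inhaler_schema())
  expect_equal(des2$profiles$cost, des$profiles$cost)
  expect_equal(d_efficiency(des2), d_efficiency(des))
})
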