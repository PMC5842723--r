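test_that("matrix means reduce diagonal and upper triangle correctly", {
  toy <- toy_matrix(5, -1)
  ms <- matrix_means(toy)
  expect_equal(ms$mean_saa, 5)
  expect_equal(ms$mean_sab, -1)

  # independent recomputation straight from the bundled fixture text,
  # parsed with different code than the package parser
  path <- system.file("extdata", "matrices", "BLOSUM62.txt", package = "msaparam")
  lines <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  header <- scan(text = lines[1], what = "", quiet = TRUE)
  body <- read.table(text = lines[-1], row.names = 1)
  colnames(body) <- header
  core <- as.matrix(body)[AA20, AA20]
  ms62 <- matrix_means(load_blosum("blosum62"))
  expect_equal(ms62$mean_saa, mean(diag(core)))
  expect_equal(ms62$mean_sab, mean(core[upper.tri(core)]))

  for (nm in c("blosum30", "blosum45", "blosum62")) {
    m <- matrix_means(load_blosum(nm))
    expect_gt(m$mean_saa, m$mean_sab)
  }
})

test_that("matrix-rationality test evaluates the printed threshold", {
  w <- msa_weights()
  # no gaps: threshold reduces to mean_sab / beta
  st0 <- family_stats(m = 4, len_max = 50, len_min = 50, iden = 0.5)
  st0$num_gap <- 0
  for (nm in c("blosum30", "blosum45", "blosum62")) {
    ms <- matrix_means(load_blosum(nm))
    chk <- check_matrix(st0, ms, w)
    expect_equal(chk$calc, ms$mean_sab / w$beta)
    expect_true(chk$passed)
  }

  # num_gap/num_match = 1 with the toy matrix, against the oracle
  st1 <- family_stats(m = 4, len_max = 10, len_min = 10, iden = 1 / 30)
  expect_equal(st1$num_gap / st1$num_match, 1)
  ms_toy <- matrix_means(toy_matrix(5, -1))
  chk1 <- check_matrix(st1, ms_toy, w)
  expect_equal(chk1$calc,
               oracle_rationality_calc(4, st1$num_gap, st1$num_match, -1,
                                       w$alpha, w$beta))
  expect_equal(chk1$reference, 5)

  # doubling num_match moves the threshold toward mean_sab / beta
  st2 <- st1; st2$num_match <- 2 * st1$num_match
  chk2 <- check_matrix(st2, ms_toy, w)
  lim <- ms_toy$mean_sab / w$beta
  expect_lt(abs(chk2$calc - lim), abs(chk1$calc - lim))

  st_bad <- family_stats(m = 3, len_max = 20, len_min = 10, iden = 0)
  expect_error(check_matrix(st_bad, ms_toy, w), "identity")
})

test_that("GOP upper bound matches the independent evaluation", {
  w <- msa_weights(lambda = 3, n = 5)
  # identical-sequence toy family (iden = 1)
  st <- family_stats(m = 4, len_max = 30, len_min = 30, iden = 1)
  ms <- matrix_means(toy_matrix(5, -1))
  expect_equal(gop_upper_bound(st, ms, w),
               oracle_gop_bound(4, st$num_gap, st$num_match, 5, -1,
                                3, 5, w$alpha, w$beta))

  # monotone in beta when num_match > 0
  w_hi <- msa_weights(lambda = 3, n = 5, beta = 1.2)
  expect_gt(gop_upper_bound(st, ms, w_hi), gop_upper_bound(st, ms, w))

  # joint scaling of num_gap and num_match preserves the bound's sign
  st_sc <- st
  st_sc$num_gap <- st$num_gap * 7
  st_sc$num_match <- st$num_match * 7
  expect_equal(sign(gop_upper_bound(st_sc, ms, w)),
               sign(gop_upper_bound(st, ms, w)))

  st_eq <- family_stats(m = 4, len_max = 30, len_min = 30, iden = 0.5)
  st_eq$num_gap <- 0
  expect_error(gop_upper_bound(st_eq, ms, w), "num_gap")
})

test_that("bound and rationality test match oracles over random statistics", {
  set.seed(404)
  w_draws <- replicate(20, msa_weights(
    lambda = sample(1:5, 1), n = sample(1:12, 1),
    omega = stats::runif(1, 0.01, 0.5),
    alpha = stats::runif(1, 0.05, 0.95),
    beta = stats::runif(1, 0.5, 1.5)), simplify = FALSE)
  mats <- lapply(c("blosum30", "blosum45", "blosum62"),
                 function(nm) matrix_means(load_blosum(nm)))
  for (i in 1:1000) {
    st <- random_family_stats()
    w <- w_draws[[sample(20, 1)]]
    ms <- mats[[sample(3, 1)]]
    expect_equal(gop_upper_bound(st, ms, w),
                 oracle_gop_bound(st$m, st$num_gap, st$num_match,
                                  ms$mean_saa, ms$mean_sab,
                                  w$lambda, w$n, w$alpha, w$beta))
    expect_equal(check_matrix(st, ms, w)$calc,
                 oracle_rationality_calc(st$m, st$num_gap, st$num_match,
                                         ms$mean_sab, w$alpha, w$beta))
  }
})

test_that("GOP/GEP estimation composes the bound with the weights", {
  w <- msa_weights(omega = 0.05, n = 5)
  st <- family_stats(m = 4, len_max = 120, len_min = 100, iden = 0.4)
  b45 <- load_blosum("blosum45")
  est <- estimate_gop_gep(st, b45, w)
  expect_equal(est$gop, 0.05 * gop_upper_bound(st, matrix_means(b45), w))
  expect_equal(est$gep, est$gop / 5)
  expect_gt(est$gop, 0)
  expect_lte(est$gop, est$upper_bound)

  # linear in omega
  est2 <- estimate_gop_gep(st, b45, msa_weights(omega = 0.10, n = 5))
  expect_equal(est2$gop, 2 * est$gop)
  expect_equal(est2$gep, 2 * est$gep)

  # strictly increasing in omega
  omegas <- c(0.01, 0.05, 0.2, 0.6, 0.95)
  gops <- vapply(omegas, function(o) {
    estimate_gop_gep(st, b45, msa_weights(omega = o, n = 5))$gop
  }, numeric(1))
  expect_true(all(diff(gops) > 0))

  # a matrix with positive mismatch means drives the bound negative
  pos <- toy_matrix(1, 3)
  expect_error(estimate_gop_gep(st, pos, w), "non-positive")
})

test_that("preset table covers the five calibrated sequence classes", {
  p <- select_preset(family_stats(4, 150, 100, 0.3))
  expect_equal(p$weights$omega, 0.05); expect_equal(p$weights$n, 5L)
  expect_equal(p$matrix_name, "BLOSUM45"); expect_false(p$extrapolated)

  p <- select_preset(family_stats(4, 80, 60, 0.3))
  expect_equal(p$weights$omega, 0.03); expect_equal(p$weights$n, 5L)
  expect_equal(p$matrix_name, "BLOSUM45")

  p <- select_preset(family_stats(5, 400, 300, 0.3))
  expect_equal(p$weights$omega, 0.08); expect_equal(p$weights$n, 10L)
  expect_equal(p$matrix_name, "BLOSUM62")

  p <- select_preset(family_stats(15, 200, 100, 0.3))
  expect_equal(p$weights$omega, 0.02); expect_equal(p$weights$n, 10L)
  expect_equal(p$matrix_name, "BLOSUM45")

  p <- select_preset(family_stats(25, 400, 100, 0.3))
  expect_equal(p$weights$omega, 0.02); expect_equal(p$weights$n, 10L)
  expect_equal(p$matrix_name, "BLOSUM45")

  # every preset shares lambda/alpha/beta
  for (m in c(4, 15, 25)) {
    w <- select_preset(family_stats(m, 150, 100, 0.3))$weights
    expect_equal(w$lambda, 3L)
    expect_equal(w$alpha, 0.2)
    expect_equal(w$beta, 0.9)
  }

  # uncalibrated counts map to the small-family rows, flagged
  p <- select_preset(family_stats(8, 150, 100, 0.3))
  expect_true(p$extrapolated)
  expect_equal(p$weights$omega, 0.05)
})
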