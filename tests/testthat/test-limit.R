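test_that("time change closed forms match adaptive quadrature", {
  king_exp <- time_change(size_profile("exponential", rho = 0.5), gamma = 2)
  got <- time_change_G(king_exp, 1)
  expect_equal(got, exp(1) - 1, tolerance = 1e-9)
  quad <- stats::integrate(function(s) exp(-0.5 * s)^(-2), 0, 1,
                           rel.tol = 1e-12)$value
  expect_equal(got, quad, tolerance = 1e-9)

  expect_equal(time_change_G(time_change(size_profile("constant"), 3), 4.2),
               4.2)
  tabp <- size_profile("tabulated", times = c(0, 1, 10),
                       values = c(1, 0.5, 0.5))
  expect_equal(time_change_G(time_change(tabp, 0), 5), 5)  # gamma = 0 case

  # inverse round trip on a profile with no closed form
  tc <- time_change(tabp, 1.5)
  for (t in c(0.3, 1, 4)) {
    expect_equal(time_change_Ginv(tc, time_change_G(tc, t)), t,
                 tolerance = 1e-8)
  }
  # G(t)/t bounded by the profile bounds to the power -gamma
  ts <- seq(0.1, 8, by = 0.5)
  ratio <- time_change_G(tc, ts) / ts
  expect_true(all(ratio >= 1 - 1e-9 & ratio <= 0.5^-1.5 + 1e-9))
})

test_that("the standard coalescent has the exact jump-chain and clock", {
  king <- lambda_measure("point_mass", psi = 0)
  expect_equal(simulate_lambda_coalescent(king, 1)$tmrca, 0)

  set.seed(31)
  # Kingman: only binary mergers; waits at b blocks are Exp(choose(b,2))
  g <- simulate_lambda_coalescent(king, 8)
  expect_true(all(vapply(g$events, function(e) length(e$members), 1L) == 2L))

  reps <- 5000
  pair <- replicate(reps, simulate_lambda_coalescent(king, 2)$tmrca)
  expect_lt(abs(mean(pair) - 1), 3 * stats::sd(pair) / sqrt(reps))

  waits5 <- replicate(2000, simulate_lambda_coalescent(king, 5)$events[[1]]$time)
  expect_lt(abs(mean(waits5) - 1 / choose(5, 2)),
            3 * stats::sd(waits5) / sqrt(2000))

  # first-merger sizes follow C(b,k) lambda_{b,k} / lambda_b
  set.seed(32)
  bs <- lambda_measure("beta", a = 1, b = 1)
  first <- replicate(1e4, length(simulate_lambda_coalescent(bs, 5)$events[[1]]$members))
  probs <- mmcsim:::.merger_size_probs(bs, 5)
  obs <- tabulate(first, 5)[2:5]
  chi <- mmcsim:::.chisq_pooled(obs, probs)
  expect_gt(chi$p_value, 0.01)

  # block counts decrease to 1 in every completed run
  set.seed(33)
  for (i in 1:20) {
    tr <- simulate_lambda_coalescent(bs, 7)
    bc <- events_table(tr)$block_count_after
    expect_true(all(diff(bc) < 0))
    expect_equal(bc[length(bc)], 1L)
  }
})

test_that("time-changed simulation preserves the jump chain exactly", {
  meas <- lambda_measure("beta", a = 1.5, b = 1.5)
  tc <- time_change(size_profile("exponential", rho = 1), gamma = 1.5)
  set.seed(34)
  std <- simulate_lambda_coalescent(meas, 10)
  set.seed(34)
  chg <- simulate_lambda_coalescent(meas, 10, tc)
  sizes_std <- vapply(std$events, function(e) sort(e$members)[1], 1L)
  sizes_chg <- vapply(chg$events, function(e) sort(e$members)[1], 1L)
  expect_identical(vapply(std$events, function(e) length(e$members), 1L),
                   vapply(chg$events, function(e) length(e$members), 1L))
  expect_identical(sizes_std, sizes_chg)
  # external times are the G-inverse of the internal times
  t_int <- cumsum(diff(c(0, vapply(std$events, `[[`, 1, "time"))))
  expect_equal(vapply(chg$events, `[[`, 1, "time"),
               time_change_Ginv(tc, t_int), tolerance = 1e-9)
})

test_that("a constant profile leaves the time-changed law unchanged", {
  set.seed(35)
  meas <- lambda_measure("point_mass", psi = 0.4)
  tc0 <- time_change(size_profile("constant"), gamma = 2)
  a <- replicate(2000, simulate_lambda_coalescent(meas, 2)$tmrca)
  b <- replicate(2000, simulate_lambda_coalescent(meas, 2, tc0)$tmrca)
  expect_gt(stats::ks.test(a, b)$p.value, 0.01)
})

test_that("Gompertz closed form equals the generic time-change path", {
  king <- lambda_measure("point_mass", psi = 0)
  expect_equal(gompertz_waiting_cdf(4, 0.3, 1, 2, king, 0), 0)
  expect_equal(gompertz_waiting_cdf(4, 0.3, 1, 2, king, 1e6), 1)
  tc <- time_change(size_profile("exponential", rho = 1), gamma = 2)
  lam <- total_rate(king, 4)
  t0 <- 0.3
  t <- 0.5
  want <- 1 - exp(-lam * (time_change_G(tc, t0 + t) - time_change_G(tc, t0)))
  expect_equal(gompertz_waiting_cdf(4, t0, 1, 2, king, t), want,
               tolerance = 1e-9)
})

test_that("mutations fall as a Poisson process on branch length", {
  set.seed(36)
  bs <- lambda_measure("beta", a = 1, b = 1)
  tr <- simulate_lambda_coalescent(bs, 6)
  expect_equal(nrow(scatter_mutations(tr, 0)), 0L)
  L <- tr$total_length
  counts <- replicate(5000, nrow(scatter_mutations(tr, 2)))
  expect_lt(abs(mean(counts) - 2 * L), 3 * stats::sd(counts) / sqrt(5000))
  # all mutation times lie inside the tree's span
  mut <- scatter_mutations(tr, 5)
  expect_true(all(mut$time >= 0 & mut$time <= tr$tmrca))
  # discrete counterpart: binomial thinning at mu = theta * c_ref
  set.seed(37)
  m <- moran_model(60, "standard")
  g <- simulate_genealogy(m, 4)
  Lg <- g$total_length
  cnt <- replicate(2000, nrow(scatter_mutations(g, 1)))
  expect_lt(abs(mean(cnt) - 1 * Lg * m$c_ref),
            4 * stats::sd(cnt) / sqrt(2000) + 1e-9)
})
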