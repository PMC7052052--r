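test_that("uprime pmf degenerates correctly and matches quadrature", {
  king <- uprime_law(lambda_measure("point_mass", psi = 0), 50)
  expect_equal(king$support[king$pmf > 1e-12], 2L)
  expect_equal(sum(king$pmf), 1, tolerance = 1e-12)
  star <- uprime_law(lambda_measure("point_mass", psi = 1), 10)
  expect_equal(star$support[star$pmf > 1e-12], 10L)

  m <- lambda_measure("beta", a = 0.5, b = 1.5)
  law <- uprime_law(m, 20)
  lam <- quad_total_rate(m, 20)
  want <- vapply(2:20, function(j)
    choose(20, j) * quad_moment(m, 20, j) / lam * m$rate_multiplier,
    numeric(1))
  expect_equal(law$pmf, want, tolerance = 1e-9)
})

test_that("uprime pmfs stay normalized up to N = 500", {
  for (m in list(lambda_measure("point_mass", psi = 0.3),
                 lambda_measure("beta", a = 1, b = 1),
                 lambda_measure("beta", a = 1.5, b = 0.5))) {
    for (N in c(2, 17, 100, 500)) {
      law <- uprime_law(m, N)
      expect_equal(sum(law$pmf), 1, tolerance = 1e-12)
      expect_true(all(law$support >= 2 & law$support <= N))
    }
  }
})

test_that("factorial moments: closed form, direct sum, and edge cases agree", {
  star8 <- uprime_law(lambda_measure("point_mass", psi = 1), 8)
  expect_equal(factorial_moment(star8, 3), 336)   # (8)_3, U' = N, lambda_N = 1
  expect_equal(factorial_moment(standard_law(40), 2), 2)
  expect_equal(factorial_moment(standard_law(40), 3), 0)
  bs6 <- uprime_law(lambda_measure("beta", a = 1, b = 1), 6)
  expect_equal(factorial_moment(bs6, 3, method = "closed_form"),
               sum(ff(bs6$support, 3) * bs6$pmf), tolerance = 1e-10)
  expect_equal(factorial_moment(bs6, 99), 0)      # k > N vanishes
})

test_that("Moehle-Sagitov ratios are exact for uprime laws at finite N", {
  # c_N^-1 E((U'_N)_a)/(N)_a = E(X^{a-2}), an algebraic identity checked
  # entirely through the pmf (direct summation, no closed forms)
  measures <- list(lambda_measure("beta", a = 0.5, b = 1.5),
                   lambda_measure("beta", a = 1, b = 1),
                   lambda_measure("point_mass", psi = 0.3),
                   lambda_measure("point_mass", psi = 1))
  for (m in measures) {
    for (N in c(10L, 100L)) {
      law <- uprime_law(m, N)
      cN <- factorial_moment(law, 2, method = "direct") / (N * (N - 1))
      for (a in 2:4) {
        lhs <- factorial_moment(law, a, method = "direct") / ff(N, a) / cN
        expect_equal(lhs, measure_moment(m, a - 2), tolerance = 1e-10)
      }
    }
  }
})

test_that("coalescence probabilities take their closed-form values", {
  for (N in c(2, 10, 333)) {
    expect_equal(coalescence_prob(standard_law(N)), 2 / (N * (N - 1)))
  }
  expect_equal(coalescence_prob(uprime_law(
    lambda_measure("point_mass", psi = 1), 25)), 1)
  # uprime: c_N = 1/lambda_N (probability-measure total rate)
  m <- lambda_measure("beta", a = 1.2, b = 0.8)
  expect_equal(coalescence_prob(uprime_law(m, 60)), 1 / total_rate(m, 60),
               tolerance = 1e-12)
})

test_that("rarefaction calibrates the coalescence probability to N^-gamma", {
  star <- lambda_measure("point_mass", psi = 1)
  rl <- rarefy(star, 100, 1.5)
  expect_equal(rl$p_activation, 100^-1.5)
  expect_equal(rarefy(star, 2, 1.99)$p_activation, 2^-1.99)
  d5 <- lambda_measure("point_mass", psi = 0.5)
  rl2 <- rarefy(d5, 100, 1.5)
  lam <- sum(choose(100, 2:100) * 0.5^(2:100 - 2) * 0.5^(100 - 2:100))
  expect_equal(rl2$p_activation, 100^-1.5 * lam, tolerance = 1e-10)
  # exact decomposition c_N = N^-gamma + (1 - P(A_N)) 2/(N)_2, via pmf
  pe <- mmcsim:::.effective_pmf(rl2)
  cN_direct <- sum(ff(pe$support, 2) * pe$pmf) / (100 * 99)
  expect_equal(coalescence_prob(rl2), cN_direct, tolerance = 1e-12)
  expect_equal(coalescence_prob(rl2),
               100^-1.5 + (1 - rl2$p_activation) * 2 / (100 * 99),
               tolerance = 1e-14)
  # infeasible rarefaction names the minimal admissible size (Dirac(0.05):
  # lambda_N ~ 400, so N^-1.5 lambda_N > 1 below N ~ 50)
  err <- tryCatch(rarefy(lambda_measure("point_mass", psi = 0.05), 20, 1.5),
                  error = function(e) conditionMessage(e))
  expect_match(err, "smallest admissible N is")
  Nmin <- as.integer(sub(".*admissible N is (\\d+).*", "\\1", err))
  lam_at <- function(N) total_rate(lambda_measure("point_mass", psi = 0.05), N)
  expect_lte(Nmin^-1.5 * lam_at(Nmin), 1)
  expect_gt((Nmin - 1)^-1.5 * lam_at(Nmin - 1L), 1)
  # Kingman-like measures admit no rarefied size at all
  expect_error(rarefy(lambda_measure("point_mass", psi = 0), 100, 1.5),
               "no admissible size")
  # regime heuristic: Beta(0.5, 1.5) has E((U'_N)_2)/(N-1) -> 0
  expect_warning(rarefy(lambda_measure("beta", a = 0.5, b = 1.5), 200, 1.9),
                 "bounded away")
})

test_that("offspring sampling reproduces the exact pmf", {
  expect_equal(unique(sample_U(standard_law(30), 50)), 2L)
  expect_equal(unique(sample_U(uprime_law(
    lambda_measure("point_mass", psi = 1), 9), 50)), 9L)
  set.seed(101)
  law <- uprime_law(lambda_measure("beta", a = 1, b = 1), 30)
  draws <- sample_U(law, 1e5)
  emp <- tabulate(draws, 30)[law$support] / 1e5
  se <- sqrt(law$pmf * (1 - law$pmf) / 1e5)
  expect_true(all(abs(emp - law$pmf) <= 4 * se + 1e-12))
  # rarefied sampling: activation frequency matches p_activation
  set.seed(102)
  rl <- rarefy(lambda_measure("point_mass", psi = 1), 20, 1.1)
  d <- sample_U(rl, 2e4)
  expect_true(all(d %in% c(2L, 20L)))
  p <- rl$p_activation
  expect_lt(abs(mean(d == 20L) - p), 4 * sqrt(p * (1 - p) / 2e4))
})

test_that("custom laws validate and feed the generic moment machinery", {
  ew <- custom_law(100, support = c(2L, 30L), pmf = c(0.95, 0.05))
  expect_equal(factorial_moment(ew, 2), 0.95 * 2 + 0.05 * 30 * 29)
  expect_error(custom_law(10, support = c(1L, 3L), pmf = c(0.5, 0.5)),
               "support")
  expect_error(custom_law(10, support = c(2L, 3L), pmf = c(0.6, 0.6)),
               "sum")
})
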