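test_that("merger-pattern estimates agree with exact expectations", {
  set.seed(41)
  meas <- lambda_measure("point_mass", psi = 0.5)
  m <- moran_model(30, "uprime", measure = meas)
  # l = 1, a = 2 is the pairwise coalescence probability
  ph2 <- estimate_phi(m, 1, 2L, reps = 3e4)
  cmc <- pairwise_coalescence_mc(m, reps = 3e4)
  expect_lt(abs(ph2$estimate - cmc$estimate),
            4 * sqrt(ph2$se^2 + cmc$se^2))
  # l = 1, a = 3 matches E((U_N)_3)/(N)_3 exactly in expectation
  law <- m$law_at(30)
  want <- factorial_moment(law, 3) / ff(30, 3)
  ph3 <- estimate_phi(m, 1, 3L, reps = 3e4)
  expect_lt(abs(ph3$estimate - want), 4 * ph3$se)
  # simultaneous mergers are impossible with a single multiplying parent
  ph22 <- estimate_phi(m, 1, c(2L, 2L), reps = 2000)
  expect_equal(ph22$estimate, 0)
  expect_error(estimate_phi(m, 1, c(20L, 20L)), "exceeds")
})

test_that("Moehle-Sagitov ratios hit their limits", {
  meas <- lambda_measure("beta", a = 1, b = 1)
  tab <- moehle_sagitov_check(
    function(N) moran_model(N, "uprime", measure = meas),
    N_grid = c(50, 200), patterns = list(3L, c(2L, 2L)), measure = meas)
  r3 <- tab[tab$pattern == "3", ]
  expect_equal(r3$ratio, rep(0.5, 2), tolerance = 1e-10)  # E(X) for Beta(1,1)
  expect_equal(r3$phi, rep(merger_rate(meas, 3, 3), 2))
  expect_equal(tab[tab$pattern == "2,2", ]$ratio, c(0, 0))
  # Kingman standard Moran: triple-merger ratio is exactly 0
  king <- lambda_measure("point_mass", psi = 0)
  tab2 <- moehle_sagitov_check(function(N) moran_model(N, "standard"),
                               N_grid = 200, patterns = list(3L),
                               measure = king)
  expect_equal(tab2$ratio, 0)
  expect_equal(tab2$phi, 0)   # lambda_{3,3} of the Kingman measure
})

test_that("the discrete time scale matches its continuum inverse", {
  # constant size: F_N(s) = [s] c_N and Ginv(t) = ceil(t/c_N) - 1 (+- grid)
  m <- moran_model(40, "standard", horizon_t = 2)
  ts <- empirical_time_scale(m, horizon_t = 1)
  cN <- m$c_ref
  expect_equal(ts$table$c_Nr, rep(cN, nrow(ts$table)))
  expect_equal(ts$table$F, seq_len(nrow(ts$table)) * cN, tolerance = 1e-12)
  for (t in c(0.1, 0.5, 0.9)) {
    expect_lt(abs(ts$Ginv(t) - (ceiling(t / cN) - 1)), 1.5)
  }
  # exponential growth: c_N G_N^-1(t) within 2% of the gamma = 2 inverse
  m2 <- moran_model(500, "standard",
                    profile = size_profile("exponential", rho = 1),
                    horizon_t = 1.2)
  ts2 <- empirical_time_scale(m2, horizon_t = 1.2)
  tc <- time_change(size_profile("exponential", rho = 1), gamma = 2)
  for (t in c(0.1, 0.3, 0.6, 1)) {
    got <- m2$c_ref * ts2$Ginv(t)
    want <- time_change_Ginv(tc, t)
    expect_lt(abs(got / want - 1), 0.02)
  }
})

test_that("exact per-generation rates respect decline neutrality and growth", {
  meas <- lambda_measure("point_mass", psi = 0.5)
  m <- moran_model(20, "uprime", measure = meas)
  law <- m$law_at(20)
  # equal sizes: the fixed-N value
  expect_equal(mmcsim:::.moran_cNr_exact(m, 20L, 20L),
               coalescence_prob(law), tolerance = 1e-12)
  # decline: unchanged numerator over the smaller denominator base (Phi
  # preservation means c equals the fixed-N_r value)
  expect_equal(mmcsim:::.moran_cNr_exact(m, 20L, 12L),
               factorial_moment(law, 2) / (20 * 19), tolerance = 1e-12)
  # growth, all to the multiplier: E((U + d)_2)/(N_prev)_2
  m_mult <- moran_model(20, "uprime", measure = meas,
                        scheme = "to_multiplier")
  d <- 3L
  pe <- mmcsim:::.effective_pmf(law)
  want <- sum(pe$pmf * (pe$support + d) * (pe$support + d - 1)) / (23 * 22)
  expect_equal(mmcsim:::.moran_cNr_exact(m_mult, 20L, 23L), want,
               tolerance = 1e-12)
  # MC agrees with the exact path on a growth generation
  set.seed(42)
  grow <- size_profile("tabulated", times = c(0, 0.5, 2), values = c(1, 0.5, 0.5))
  m3 <- moran_model(40, "standard", profile = grow, horizon_t = 1,
                    scheme = "to_multiplier")
  r_grow <- which(diff(trajectory_sizes(m3$trajectory, 0:50)) < 0)[1]
  exact <- mmcsim:::.moran_cNr_exact(
    m3, trajectory_sizes(m3$trajectory, r_grow),
    trajectory_sizes(m3$trajectory, r_grow - 1L))
  mc <- pairwise_coalescence_mc(m3, r = r_grow, reps = 1e5)
  expect_lt(abs(mc$estimate - exact), 4 * mc$se + 1e-9)
})

test_that("the convergence test discriminates correct from wrong limits", {
  set.seed(43)
  d5 <- lambda_measure("point_mass", psi = 0.5)
  king <- lambda_measure("point_mass", psi = 0)
  # rarefied Dirac at sizes where the Kingman background has died away
  m <- moran_model(1000, "rarefied", measure = d5, gamma = 1.2)
  rep_ok <- genealogy_convergence_test(m, d5, n = 6, reps = 500)
  expect_gt(rep_ok$first_merger_chisq$p_value, 0.01)
  # the same draws against the Kingman jump chain must fail
  wrong <- mmcsim:::.chisq_pooled(
    tabulate(rep_ok$draws$discrete_first, 6)[2:6],
    mmcsim:::.merger_size_probs(king, 6))
  expect_lt(wrong$p_value, 0.01)
})

test_that("standard Moran pairwise times look exponential in the limit", {
  set.seed(44)
  m <- moran_model(300, "standard")
  rep2 <- genealogy_convergence_test(m, lambda_measure("point_mass", psi = 0),
                                     n = 2, reps = 1000)
  expect_gt(rep2$pairwise_ks$p_value, 0.01)
})

test_that("an abrupt expansion keeps coalescence bounded below", {
  set.seed(45)
  out <- abrupt_expansion_demo(100, 0.5, reps = 1e5)
  expect_equal(out$bound, 49^2 / (150 * 149), tolerance = 1e-12)
  expect_gte(out$estimate, out$bound - 4 * out$se)
  for (N in c(50, 200)) {
    o <- abrupt_expansion_demo(N, 0.5, reps = 2e4)
    expect_gte(o$estimate, o$bound - 4 * o$se)
  }
  # m = 0 (no jump) reduces to the ordinary pairwise probability
  o0 <- abrupt_expansion_demo(80, 0, reps = 2e4)
  c80 <- 2 / (80 * 79)
  expect_lt(abs(o0$estimate - c80), 4 * sqrt(c80 * (1 - c80) / 2e4) + 1e-9)
})
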