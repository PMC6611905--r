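test_that("scenario presets encode the studied contexts", {
  co <- scenario_preset("CO")
  expect_equal(c(co$delta, co$tau, co$gamma), c(0, 0, 0.5))
  expect_equal(c(co$N, co$Z, co$c_C, co$c_W, co$r_C, co$r_W),
               c(10, 50, 1, 1, 1, 1))
  expect_equal(co$mu, 1e-6)
  tn <- scenario_preset("TN-baseline")
  expect_equal(c(tn$beta_C, tn$delta, tn$tau), c(0, 0, 0))
  expect_equal(scenario_preset("TN-propaganda")$delta, 0.5)
  expect_equal(scenario_preset("TN-propaganda")$tau, 0)
  expect_equal(scenario_preset("TN-transfer")$tau, 0.5)
  expect_equal(scenario_preset("TN-transfer")$delta, 0)
  expect_equal(scenario_preset("CO", beta_S = 7)$beta_S, 7)
  expect_error(scenario_preset("XX"), "TN-propaganda")
})

test_that("analytic thresholds reproduce the closed-form boundaries", {
  p <- model_params(N = 10, Z = 10, beta_S = 150)
  rp <- analytic_thresholds(p, group_composition(5, 0, 5))
  expect_equal(rp$beta_prime_HW, 100)
  expect_true(rp$honest_beats_wolf)
  rp <- analytic_thresholds(model_params(N = 10, Z = 10),
                            group_composition(5, 5, 0))
  expect_equal(rp$g, 0.5 * 0.1 + 0.5 * 0.5)
  expect_equal(rp$beta_prime_HC, 1 / (0.3 * 0.5), tolerance = 1e-12)
  # unsupported regimes are refused
  expect_error(analytic_thresholds(model_params(N = 10, Z = 50),
                                   group_composition(5, 0, 5)), "N = Z")
  expect_error(analytic_thresholds(model_params(N = 10, Z = 10, tau = 0.5),
                                   group_composition(5, 0, 5)),
               "unsupported")
  expect_error(analytic_thresholds(p, group_composition(4, 3, 3)),
               "two roles")
})

test_that("payoff-difference signs flip exactly at the analytic boundaries", {
  for (N in c(4, 6, 10)) for (gamma in c(0, 0.3, 0.7, 1)) {
    # honest vs wolf: boundary at beta' = N^2, composition independent
    for (nw in c(1, N %/% 2, N - 1)) {
      comp <- group_composition(N - nw, 0, nw)
      lo <- pairwise_sign_test("H", "W", comp,
                               model_params(N = N, Z = N, gamma = gamma,
                                            beta_S = N^2 * 0.99))
      hi <- pairwise_sign_test("H", "W", comp,
                               model_params(N = N, Z = N, gamma = gamma,
                                            beta_S = N^2 * 1.01))
      expect_equal(lo$sign, -1)
      expect_equal(hi$sign, 1)
    }
    # honest vs criminal: boundary at beta' = 1/(g p_C)
    for (nc in c(1, N %/% 2, N - 1)) {
      comp <- group_composition(N - nc, nc, 0)
      pC <- nc / N
      g <- (1 - gamma) / N + gamma * pC
      b <- 1 / (g * pC)
      lo <- pairwise_sign_test("H", "C", comp,
                               model_params(N = N, Z = N, gamma = gamma,
                                            beta_S = b * 0.99))
      hi <- pairwise_sign_test("H", "C", comp,
                               model_params(N = N, Z = N, gamma = gamma,
                                            beta_S = b * 1.01))
      expect_equal(lo$sign, -1)
      expect_equal(hi$sign, 1)
    }
  }
})

test_that("the criminal-wolf boundary from payoffs carries the 1/p_C factor", {
  # brute-force the sign change in beta_C and compare both reported
  # boundary forms
  for (nc in c(2, 5, 8)) {
    comp <- group_composition(0, nc, 10 - nc)
    pC <- nc / 10
    bS <- 10
    rp <- analytic_thresholds(model_params(N = 10, Z = 10, beta_S = bS),
                              comp)
    grid <- seq(0, 4000, by = 0.5)
    sg <- vapply(grid, function(bc)
      pairwise_sign_test("C", "W", comp,
                         model_params(N = 10, Z = 10, beta_S = bS,
                                      beta_C = bc))$sign, 0)
    bf <- grid[which(sg > 0)[1]]
    expect_equal(bf, rp$beta_C_boundary, tolerance = 1e-2)
    expect_equal(rp$beta_C_boundary / rp$beta_C_boundary_compact, 1 / pC,
                 tolerance = 1e-12)
  }
  # at n_C = n_W = 5, gamma = 0.5 the payoff boundary is 28 beta_S,
  # twice the compact form's 14 beta_S
  rp <- analytic_thresholds(model_params(N = 10, Z = 10, beta_S = 10),
                            group_composition(0, 5, 5))
  expect_equal(rp$beta_C_boundary, 280)
  expect_equal(rp$beta_C_boundary_compact, 140)
})

test_that("threshold detection scans the grid in order", {
  sweep <- data.frame(beta_S = c(0, 50, 100, 150),
                      E_x_H = c(0.1, 0.2, 0.95, 0.97))
  hit <- detect_threshold(sweep, function(c) c$E_x_H >= 0.9, "beta_S")
  expect_equal(hit$value, 100)
  expect_equal(hit$resolution, 50)
  all_true <- detect_threshold(sweep, function(c) TRUE, "beta_S")
  expect_equal(all_true$value, 0)
  none <- detect_threshold(sweep, function(c) FALSE, "beta_S")
  expect_true(is.na(none$value))
})

test_that("a 1x1 sweep equals a single stationary summary", {
  p <- model_params(Z = 20, N = 10, beta_S = 150)
  sw <- sweep_phase_diagram(p, list(param = "beta_S", values = 150))
  d <- summarize_distribution(
    stationary_distribution(build_transition_matrix(p)))
  expect_equal(sw$E_x_H, unname(d$expected_x[1]), tolerance = 1e-12)
  expect_equal(as.character(sw$label), d$label)
  expect_equal(sw$E_x_H + sw$E_x_C + sw$E_x_W, 1, tolerance = 1e-9)
  expect_error(sweep_phase_diagram(p, list(param = "nope", values = 1)),
               "unknown")
})

test_that("organised-crime sweeps show criminal coexistence but no stable honest-wolf pair", {
  sw <- sweep_phase_diagram(scenario_preset("CO", beta_H = 0),
                            list(param = "beta_S", values = c(0, 10)),
                            list(param = "beta_C", values = c(0, 400)))
  expect_equal(nrow(sw), 4)
  expect_true(all(abs(sw$E_x_H + sw$E_x_C + sw$E_x_W - 1) < 1e-9))
  # criminals coexist with honests somewhere, and with wolves somewhere
  expect_true(any(sw$E_x_C >= 0.2 & sw$E_x_H >= 0.2))
  expect_true(any(sw$E_x_C >= 0.2 & sw$E_x_W >= 0.2))
  # but honests and wolves never coexist without criminals
  expect_false(any(sw$E_x_C <= 0.05 & sw$E_x_H >= 0.2 & sw$E_x_W >= 0.2))
})
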