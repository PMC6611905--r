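test_that("state enumeration is complete, ordered, and invertible", {
  expect_equal(enumerate_states(1)$size, 3)
  expect_equal(enumerate_states(50)$size, 1326)
  sp <- enumerate_states(17)
  expect_equal(sp$size, 18 * 19 / 2)
  expect_true(all(rowSums(sp$states) == 17))
  for (i in c(1, 2, 50, sp$size))
    expect_equal(state_index(sp, sp$states[i, ]), i)
  # lexicographic in (z_C, z_W): first state is all-honest
  expect_equal(unname(sp$states[1, ]), c(17, 0, 0))
})

test_that("successor states follow the discretised replicator flow", {
  p <- model_params()
  # vertices are fixed points
  s <- successor_state(c(50, 0, 0), p)
  expect_equal(unname(unlist(s[1, 1:3])), c(50, 0, 0))
  expect_equal(s$weight, 1)
  # unpunished wolves gain one individual from honests
  s <- successor_state(c(25, 0, 25), p)
  expect_equal(nrow(s), 1)
  expect_equal(unname(unlist(s[1, 1:3])), c(24, 0, 26))
  # extinct roles are never re-introduced by the deterministic step
  p2 <- model_params(beta_S = 40, beta_C = 150, beta_H = 25, delta = 0.3)
  sp <- enumerate_states(50)
  bnd <- sp$states[rowSums(sp$states == 0) >= 1, ]
  for (i in seq_len(nrow(bnd))) {
    z <- bnd[i, ]
    s <- successor_state(z, p2)
    for (k in 1:3)
      if (z[k] == 0) expect_true(all(s[[k]] == 0))
  }
  expect_true(all(vapply(seq_len(nrow(bnd)), function(i)
    sum(successor_state(bnd[i, ], p2)$weight), 0) == 1))
})

test_that("transition matrix rows are stochastic and fully regularised", {
  p <- model_params(Z = 20, N = 10, beta_S = 10, mu = 1e-6)
  tm <- build_transition_matrix(p)
  S <- tm$space$size
  expect_equal(unname(rowSums(tm$P)), rep(1, S), tolerance = 1e-9)
  expect_true(all(tm$P >= p$mu / (1 + S * p$mu) - 1e-15))
  # a vertex is a fixed point: its self-transition is the largest entry
  i <- state_index(tm$space, c(20, 0, 0))
  expect_equal(which.max(tm$P[i, ]), i)
  # neighbour-restricted regularisation keeps some entries at zero
  tn <- build_transition_matrix(p, mu_mode = "neighbour")
  expect_true(any(tn$P == 0))
  expect_equal(unname(rowSums(tn$P)), rep(1, S), tolerance = 1e-9)
})

test_that("stationary solver recovers known chains", {
  # uniform chain -> uniform distribution
  S <- 6
  d <- stationary_distribution(matrix(1 / S, S, S))
  expect_equal(d$pi, rep(1 / S, S), tolerance = 1e-9)
  # symmetric 2-state chain -> (1/2, 1/2)
  P2 <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2, byrow = TRUE)
  expect_equal(stationary_distribution(P2)$pi, c(0.5, 0.5), tolerance = 1e-10)
  # single absorbing self-loop + mu leak concentrates there as mu shrinks
  toy <- function(mu) {
    P <- matrix(0, 3, 3)
    P[1, 1] <- 1; P[2, 1] <- 1; P[3, 2] <- 1  # all paths end in state 1
    P <- P + mu
    P / rowSums(P)
  }
  brute <- function(P) {
    v <- rep(1 / 3, 3)
    for (i in 1:20000) v <- as.vector(v %*% P)
    v / sum(v)
  }
  for (mu in c(1e-2, 1e-4, 1e-6)) {
    d <- stationary_distribution(toy(mu))
    expect_equal(d$pi, brute(toy(mu)), tolerance = 1e-8)
  }
  expect_gt(stationary_distribution(toy(1e-6))$pi[1], 0.999)
  expect_error(stationary_distribution(matrix(c(1, 1, 0, 1), 2, 2)),
               "row-stochastic")
})

test_that("stationary mass concentrates on attractors as mu decreases", {
  maxpi <- sapply(c(1e-2, 1e-4, 1e-6), function(mu) {
    p <- model_params(Z = 20, N = 10, r_W = 1.1, mu = mu)
    max(stationary_distribution(build_transition_matrix(p))$pi)
  })
  expect_true(all(diff(maxpi) > 0))
})

test_that("a globally attracting vertex captures the stationary distribution", {
  # r_W > r_C and no punishment: wolves outearn both other roles wherever
  # they are present, so the wolf vertex is the unique attractor reachable
  # along the deterministic flow
  p <- model_params(r_W = 1.1, mu = 1e-6)
  ff <- flow_field(p)
  inwolf <- ff$z_W > 0 & ff$z_W < 50
  expect_true(all(ff$xdot_W[inwolf] > 0))
  d <- stationary_distribution(build_transition_matrix(p, mu_mode = "neighbour"))
  near <- d$space$states[, "z_W"] >= 49
  expect_gte(sum(d$pi[near]), 0.99)
})

test_that("stationary pipeline is deterministic and regime labels are sane", {
  p <- model_params(Z = 20, N = 10, beta_S = 150)
  d1 <- stationary_distribution(build_transition_matrix(p))
  d2 <- stationary_distribution(build_transition_matrix(p))
  expect_identical(d1$pi, d2$pi)
  expect_equal(sum(d1$pi), 1, tolerance = 1e-9)
  expect_equal(sum(d1$expected_x), 1, tolerance = 1e-9)
  sm <- summarize_distribution(d1)
  expect_match(sm$label, "honest dominance")
  # fully concentrated distribution on the all-honest state
  dd <- d1
  dd$pi <- c(1, rep(0, length(d1$pi) - 1))
  dd$expected_x <- c(x_H = 1, x_C = 0, x_W = 0)
  sm <- summarize_distribution(dd)
  expect_equal(sm$label, "honest dominance / crime eradicated")
  expect_equal(nrow(sm$top_states), 1)
})

test_that("uniform occupancy over the Z = 2 state space gives equal fractions", {
  sp <- enumerate_states(2)
  d <- structure(list(pi = rep(1 / sp$size, sp$size),
                      expected_x = as.vector(
                        crossprod(rep(1 / sp$size, sp$size),
                                  sp$states / 2)),
                      space = sp, residual = 0, params = NULL),
                 class = "crime_stationary")
  names(d$expected_x) <- c("x_H", "x_C", "x_W")
  expect_equal(unname(d$expected_x), rep(1 / 3, 3), tolerance = 1e-12)
  expect_match(summarize_distribution(d)$label, "coexistence")
})
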