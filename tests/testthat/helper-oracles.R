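# Independent brute-force oracles used across tests.

# Mean payoff of each role present in `state` by explicit enumeration of
# every (N-1)-subset of the other individuals, all equally likely —
# independent of the hypergeometric-weight code path.
brute_mean_payoffs <- function(state, params) {
  z <- if (inherits(state, "crime_state")) state$counts else as.integer(state)
  pop <- rep.int(1:3, z)
  out <- c(H = NA_real_, C = NA_real_, W = NA_real_)
  for (k in 1:3) {
    if (z[k] < 1L) next
    focal <- which(pop == k)[1]
    others <- pop[-focal]
    sets <- utils::combn(length(others), params$N - 1L)
    vals <- apply(sets, 2, function(idx) {
      cnt <- tabulate(others[idx], nbins = 3L)
      cnt[k] <- cnt[k] + 1L
      stage_payoffs(cnt, params, role = c("H", "C", "W")[k])
    })
    out[k] <- mean(vals)
  }
  out
}

# All group compositions (n_H, n_C, n_W) summing to N.
all_compositions <- function(N) {
  out <- NULL
  for (nc in 0:N) for (nw in 0:(N - nc))
    out <- rbind(out, c(N - nc - nw, nc, nw))
  out
}

expect_payoffs_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a, b, tolerance = tol)
}
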