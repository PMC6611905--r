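#' Population state
#'
#' Counts of the three roles across the whole population, with fractions
#' `x_k = z_k / Z`.
#'
#' @param z_H,z_C,z_W Non-negative integer role counts.
#' @return An object of class `crime_state` with `counts` and `x`.
#' @examples
#' population_state(25, 0, 25)
#' @export
population_state <- function(z_H, z_C, z_W) {
  z <- c(z_H = z_H, z_C = z_C, z_W = z_W)
  if (any(!is.finite(z)) || any(z < 0) || any(z != round(z)))
    stop("population counts must be non-negative integers", call. = FALSE)
  z <- as.integer(z)
  structure(list(counts = z, x = z / sum(z)), class = "crime_state")
}

check_state <- function(state, params) {
  z <- if (inherits(state, "crime_state")) state$counts
       else if (is.numeric(state) && length(state) == 3L) state
       else stop("state must be a crime_state or a length-3 count vector",
                 call. = FALSE)
  if (any(z < 0) || any(z != round(z)))
    stop("population counts must be non-negative integers", call. = FALSE)
  if (sum(z) != params$Z)
    stop("invalid state: counts sum to ", sum(z), ", expected Z = ",
         params$Z, call. = FALSE)
  as.integer(z)
}

# All compositions (h, c, w) of `total` into the three roles, one per row,
# ordered lexicographically in (c, w). Shared by subgroup sums and the
# Markov state space.
compositions3 <- function(total) {
  cc <- unlist(lapply(0:total, function(k) rep.int(k, total - k + 1L)),
               use.names = FALSE)
  ww <- unlist(lapply(0:total, function(k) 0:(total - k)), use.names = FALSE)
  cbind(h = total - cc - ww, c = cc, w = ww)
}

#' Multivariate hypergeometric subgroup weight
#'
#' Probability that a focal individual of role `focal_role` finds herself
#' in a group whose other `N - 1` members have composition `subgroup`,
#' when those members are drawn without replacement from the population
#' with the focal removed:
#' \deqn{H[\langle N'_H, N'_C, N'_W\rangle] =
#'   \binom{Z'_H}{N'_H}\binom{Z'_C}{N'_C}\binom{Z'_W}{N'_W} /
#'   \binom{Z-1}{N-1},}
#' and 0 whenever any `N'_j > Z'_j`. Weights over all subgroups of size
#' `N - 1` sum to 1.
#'
#' @param subgroup Length-3 count vector `c(n_H, n_C, n_W)` of the other
#'   group members (must sum to `N - 1`).
#' @param state A [population_state()] (or length-3 count vector) summing
#'   to `Z`; the focal role must be present in it.
#' @param focal_role One of `"H"`, `"C"`, `"W"`.
#' @param params A [model_params()] object.
#' @return A single probability.
#' @examples
#' subgroup_weight(c(9, 0, 0), population_state(50, 0, 0), "H",
#'                 model_params())
#' @export
subgroup_weight <- function(subgroup, state, focal_role, params) {
  z <- check_state(state, params)
  s <- as.integer(subgroup)
  if (length(s) != 3L || any(s < 0) || sum(s) != params$N - 1L)
    stop("subgroup must hold N - 1 members", call. = FALSE)
  k <- match(match.arg(focal_role, c("H", "C", "W")), c("H", "C", "W"))
  if (z[k] < 1L)
    stop("invalid focal: role ", focal_role, " is absent from the state",
         call. = FALSE)
  zp <- z
  zp[k] <- zp[k] - 1L
  if (any(s > zp)) return(0)
  exp(sum(lchoose(zp, s)) - lchoose(sum(zp), params$N - 1L))
}

# Focal total payoff (acting + investigation) for each subgroup row of
# `sub` (n x 3 matrix of the N-1 co-members), per role. Vectorised rewrite
# of stage_payoffs(); kept in exact agreement by tests.
payoff_by_subgroup <- function(sub, params) {
  N <- params$N
  out <- matrix(NA_real_, nrow(sub), 3L, dimnames = list(NULL, c("H", "C", "W")))
  for (k in 1:3) {
    n <- sub
    n[, k] <- n[, k] + 1L
    p_H <- n[, 1] / N; p_C <- n[, 2] / N
    ppW <- 1 - params$delta * (1 - p_C)
    b_C <- params$r_C * params$c_C * (1 - p_C)
    d_C <- params$c_C * p_C
    b_W <- params$r_W * params$c_W * (N - 1) / N * ppW
    base <- params$beta_S + params$beta_H * p_H
    wA <- switch(k,
      -d_C - params$c_W * ppW * n[, 3] / N,
      b_C + params$tau * b_W - params$c_W * ppW * n[, 3] / N,
      (1 - params$tau) * b_W - d_C - params$c_W * ppW * (n[, 3] - 1L) / N)
    wI <- switch(k,
      rep(0, nrow(sub)),
      -base * p_C * (params$gamma * p_C + (1 - params$gamma) / N),
      -(base + params$beta_C * p_C) * ppW / N^2)
    out[, k] <- wA + wI
  }
  out
}

# Mean payoffs omega_k for every state row of `states` (n x 3), via the
# hypergeometric average over all subgroups. Absent roles use the
# hypothetical-focal convention: the subgroup is drawn from the unchanged
# population of Z, so invasion payoffs are defined at the boundary.
omega_matrix <- function(states, params) {
  N <- params$N
  sub <- compositions3(N - 1L)
  w <- payoff_by_subgroup(sub, params)
  m <- nrow(sub); n <- nrow(states)
  omega <- matrix(NA_real_, n, 3L, dimnames = list(NULL, c("H", "C", "W")))
  for (k in 1:3) {
    zp <- states
    present <- states[, k] >= 1L
    zp[present, k] <- zp[present, k] - 1L
    logh <- matrix(0, n, m)
    for (j in 1:3)
      logh <- logh + lchoose(matrix(zp[, j], n, m),
                             matrix(sub[, j], n, m, byrow = TRUE))
    logh <- logh - lchoose(rowSums(zp), N - 1L)
    omega[, k] <- exp(logh) %*% w[, k]
  }
  omega
}

#' Mean-field payoffs in a population state
#'
#' Average payoff `omega_k` obtained by an individual of each role, over
#' all groups of `N` she can be drawn into from the population (subgroup
#' weights from [subgroup_weight()]), plus the population average
#' `omega_bar = sum_k x_k omega_k`. For a role absent from the state,
#' `omega_k` is the invasion payoff of one hypothetical focal of that role
#' placed in the otherwise-unchanged population; it carries zero weight in
#' `omega_bar`.
#'
#' @param state A [population_state()] (or length-3 count vector).
#' @param params A [model_params()] object.
#' @return A list with `omega_H`, `omega_C`, `omega_W` and `omega_bar`.
#' @examples
#' mean_payoffs(population_state(25, 0, 25), model_params())
#' @export
mean_payoffs <- function(state, params) {
  z <- check_state(state, params)
  om <- omega_matrix(matrix(z, 1L), params)
  x <- z / params$Z
  list(omega_H = unname(om[1, 1]), omega_C = unname(om[1, 2]),
       omega_W = unname(om[1, 3]), omega_bar = unname(sum(x * om[1, ])))
}

#' Replicator flow at a population state
#'
#' The replicator dynamics `xdot_k = x_k * (omega_k - omega_bar)`
#' evaluated at the (finite-population) state. Components sum to zero, so
#' the flow stays on the simplex; absent roles have zero flow, and the
#' three monomorphic vertices are fixed points.
#'
#' @inheritParams mean_payoffs
#' @return A named numeric vector `c(xdot_H, xdot_C, xdot_W)`.
#' @examples
#' replicator_flow(population_state(25, 0, 25), model_params())
#' @export
replicator_flow <- function(state, params) {
  z <- check_state(state, params)
  om <- omega_matrix(matrix(z, 1L), params)[1, ]
  x <- z / params$Z
  xdot <- x * (om - sum(x * om))
  names(xdot) <- c("xdot_H", "xdot_C", "xdot_W")
  xdot
}

#' Replicator flow field over all population states
#'
#' Evaluates mean payoffs and the replicator flow at every population
#' state for the given `Z`, as a numeric backing table of simplex flow
#' diagrams.
#'
#' @param params A [model_params()] object.
#' @return A data frame with one row per state and columns `z_H`, `z_C`,
#'   `z_W`, `x_H`, `x_C`, `x_W`, `omega_H`, `omega_C`, `omega_W`,
#'   `omega_bar`, `xdot_H`, `xdot_C`, `xdot_W`, `speed` (Euclidean flow
#'   magnitude).
#' @examples
#' ff <- flow_field(model_params(Z = 20))
#' nrow(ff)  # (Z+1)(Z+2)/2 states
#' @export
flow_field <- function(params) {
  sp <- enumerate_states(params$Z)
  st <- sp$states
  om <- omega_matrix(st, params)
  x <- st / params$Z
  obar <- rowSums(x * om)
  xdot <- x * (om - obar)
  data.frame(z_H = st[, 1], z_C = st[, 2], z_W = st[, 3],
             x_H = x[, 1], x_C = x[, 2], x_W = x[, 3],
             omega_H = om[, 1], omega_C = om[, 2], omega_W = om[, 3],
             omega_bar = obar,
             xdot_H = xdot[, 1], xdot_C = xdot[, 2], xdot_W = xdot[, 3],
             speed = sqrt(rowSums(xdot^2)))
}
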