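#' Enumerate all population states
#'
#' All `(Z+1)(Z+2)/2` configurations `<z_H, z_C, z_W>` of a population of
#' `Z`, ordered lexicographically in `(z_C, z_W)` (so the all-honest state
#' comes first). The ordering is fixed so transition matrices are
#' reproducible.
#'
#' @param Z Population size (integer >= 1).
#' @return An object of class `crime_statespace` with `Z`, the `states`
#'   count matrix (one row per state) and `size`.
#' @examples
#' enumerate_states(2)$states
#' @export
enumerate_states <- function(Z) {
  if (!is.numeric(Z) || length(Z) != 1L || Z < 1 || Z != round(Z))
    stop("Z must be a positive integer", call. = FALSE)
  Z <- as.integer(Z)
  st <- compositions3(Z)
  colnames(st) <- c("z_H", "z_C", "z_W")
  structure(list(Z = Z, states = st, size = nrow(st)),
            class = "crime_statespace")
}

#' Index of a population state in the canonical enumeration
#'
#' @param space An [enumerate_states()] object.
#' @param state Length-3 count vector (or [population_state()]).
#' @return The 1-based row index of `state` in `space$states`.
#' @export
state_index <- function(space, state) {
  z <- if (inherits(state, "crime_state")) state$counts else as.integer(state)
  Z <- space$Z
  if (length(z) != 3L || any(z < 0) || sum(z) != Z)
    stop("state must be 3 non-negative counts summing to Z", call. = FALSE)
  zc <- z[2]; zw <- z[3]
  as.integer(zc * (Z + 1L) - zc * (zc - 1L) / 2L + zw + 1L)
}

#' Deterministic successor(s) of a population state
#'
#' One evolutionary time step moves at most one individual between roles.
#' The replicator flow `xdot` is evaluated at the state and scaled by a
#' step `h` such that its largest component has magnitude `1/Z`; the
#' successor is whichever candidate state — the state itself or any
#' neighbour obtained by moving one individual between two roles — lies
#' closest (Euclidean, in fractions) to `x + h * xdot`. When the flow is
#' numerically zero (max |xdot_k| <= 1e-12, e.g. at the monomorphic
#' vertices) the state is its own successor; exact distance ties split the
#' weight equally.
#'
#' @inheritParams mean_payoffs
#' @param xdot Optionally, a precomputed flow vector for `state` (used
#'   internally to avoid recomputation).
#' @return A data frame with columns `z_H`, `z_C`, `z_W`, `weight`
#'   (weights sum to 1).
#' @examples
#' successor_state(population_state(25, 0, 25), model_params())
#' @export
successor_state <- function(state, params, xdot = NULL) {
  z <- check_state(state, params)
  Z <- params$Z
  if (is.null(xdot)) xdot <- unname(replicator_flow(z, params))
  if (max(abs(xdot)) <= 1e-12)
    return(data.frame(z_H = z[1], z_C = z[2], z_W = z[3], weight = 1))
  target <- z / Z + (1 / Z) * xdot / max(abs(xdot))
  cand <- matrix(z, 1L, 3L, byrow = TRUE)
  for (i in 1:3) for (j in 1:3) {
    if (i == j || z[i] < 1L) next
    nb <- z
    nb[i] <- nb[i] - 1L
    nb[j] <- nb[j] + 1L
    cand <- rbind(cand, nb)
  }
  d2 <- rowSums((cand / Z - matrix(target, nrow(cand), 3L, byrow = TRUE))^2)
  best <- d2 <= min(d2) + 1e-15
  data.frame(z_H = cand[best, 1], z_C = cand[best, 2], z_W = cand[best, 3],
             weight = rep(1 / sum(best), sum(best)))
}

#' Build the regularised transition matrix over all population states
#'
#' Places the deterministic successor weights of [successor_state()] on
#' each row of the state space, then regularises: a small probability `mu`
#' is added to every transition and rows are renormalised, making the
#' chain ergodic. With `mu_mode = "all"` (default) `mu` is added to every
#' entry of the row; `"neighbour"` restricts the leak to the state itself
#' and its one-individual neighbours, for sensitivity checks.
#'
#' @param params A [model_params()] object (`mu` supplies the
#'   regularisation).
#' @param mu_mode `"all"` or `"neighbour"`.
#' @return An object of class `crime_markov`: list with the row-stochastic
#'   matrix `P`, the `space`, and the `params`/`mu_mode` provenance.
#' @examples
#' tm <- build_transition_matrix(model_params(Z = 12, N = 4))
#' range(rowSums(tm$P))
#' @export
build_transition_matrix <- function(params, mu_mode = c("all", "neighbour")) {
  mu_mode <- match.arg(mu_mode)
  space <- enumerate_states(params$Z)
  st <- space$states
  S <- space$size
  Z <- params$Z
  om <- omega_matrix(st, params)
  x <- st / Z
  xdot <- x * (om - rowSums(x * om))
  P <- matrix(0, S, S)
  for (i in seq_len(S)) {
    succ <- successor_state(st[i, ], params, xdot = xdot[i, ])
    for (r in seq_len(nrow(succ)))
      P[i, state_index(space, c(succ$z_H[r], succ$z_C[r], succ$z_W[r]))] <-
        P[i, state_index(space, c(succ$z_H[r], succ$z_C[r], succ$z_W[r]))] +
        succ$weight[r]
  }
  mu <- params$mu
  if (mu_mode == "all") {
    P <- P + mu
  } else {
    for (i in seq_len(S)) {
      z <- st[i, ]
      idx <- i
      for (a in 1:3) for (b in 1:3) {
        if (a == b || z[a] < 1L) next
        nb <- z; nb[a] <- nb[a] - 1L; nb[b] <- nb[b] + 1L
        idx <- c(idx, state_index(space, nb))
      }
      P[i, unique(idx)] <- P[i, unique(idx)] + mu
    }
  }
  P <- P / rowSums(P)
  structure(list(P = P, space = space, params = params, mu_mode = mu_mode),
            class = "crime_markov")
}

#' Stationary distribution of the population Markov chain
#'
#' Solves `pi %*% P = pi` with `sum(pi) = 1` via the linear system
#' `(t(P) - I) pi = 0` (one equation replaced by the normalisation),
#' refined by power iteration if needed. The occupancy `pi` measures the
#' time the evolving population spends in each configuration.
#'
#' @param tm A `crime_markov` object from [build_transition_matrix()], or
#'   a bare row-stochastic matrix.
#' @param tol Residual tolerance on `max |pi P - pi|` (default 1e-10).
#' @return An object of class `crime_stationary`: list with `pi`, the
#'   expected fractions `expected_x`, the `space` (when available),
#'   `residual`, and the generating `params`.
#' @examples
#' tm <- build_transition_matrix(model_params(Z = 12, N = 4))
#' stationary_distribution(tm)$expected_x
#' @export
stationary_distribution <- function(tm, tol = 1e-10) {
  if (inherits(tm, "crime_markov")) {
    P <- tm$P; space <- tm$space; params <- tm$params
  } else {
    P <- as.matrix(tm); space <- NULL; params <- NULL
  }
  S <- nrow(P)
  if (ncol(P) != S || any(P < 0) || max(abs(rowSums(P) - 1)) > 1e-9)
    stop("transition matrix must be square and row-stochastic", call. = FALSE)
  A <- t(P) - diag(S)
  A[S, ] <- 1
  b <- c(rep(0, S - 1L), 1)
  resid <- function(v) max(abs(as.vector(v %*% P) - v))
  clean <- function(v) {
    v[v < 0] <- 0
    v / sum(v)
  }
  pvec <- tryCatch({
    lu <- A
    v <- solve(lu, b)
    # iterative refinement: near-reducible chains are ill-conditioned
    for (i in 1:5) {
      rr <- b - as.vector(lu %*% v)
      if (max(abs(rr)) < 1e-14) break
      v <- v + solve(lu, rr)
    }
    clean(v)
  }, error = function(e) rep(1 / S, S))
  if (resid(pvec) > tol) {
    # fallback: leading left eigenvector
    ev <- eigen(t(P))
    i <- which.min(abs(ev$values - 1))
    cand <- clean(abs(Re(ev$vectors[, i])))
    if (resid(cand) < resid(pvec)) pvec <- cand
  }
  it <- 0L
  while (resid(pvec) > tol && it < 20000L) {
    pvec <- as.vector(pvec %*% P)
    pvec <- pvec / sum(pvec)
    it <- it + 1L
  }
  r <- resid(pvec)
  if (r > tol)
    stop(sprintf("stationary solver did not converge: residual %.3e > %.1e",
                 r, tol), call. = FALSE)
  expected_x <- if (!is.null(space))
    as.vector(crossprod(pvec, space$states / space$Z)) else NULL
  if (!is.null(expected_x)) names(expected_x) <- c("x_H", "x_C", "x_W")
  structure(list(pi = pvec, expected_x = expected_x, space = space,
                 residual = r, params = params),
            class = "crime_stationary")
}

#' Summarise a stationary distribution into a regime label
#'
#' Reports the expected role fractions `E[x_k]`, the most-visited states
#' (those whose probability is at least `top_floor` of the maximum,
#' mirroring the usual rendering convention of occupancy diagrams), and a
#' regime label: role dominance when some `E[x_k] >= dominance`, "crime
#' eradicated" when `E[x_C] + E[x_W] <= eradication`, otherwise
#' coexistence of the roles with `E[x_k] >= eradication`.
#'
#' @param dist A `crime_stationary` object with a state space.
#' @param dominance Dominance threshold on an expected fraction
#'   (default 0.8).
#' @param eradication Eradication threshold on `E[x_C] + E[x_W]`
#'   (default 0.05).
#' @param top_floor Relative-probability floor for the most-visited list
#'   (default 0.1).
#' @return A list of class `crime_regime` with `expected_x`, `label`, and
#'   `top_states` (data frame of states and probabilities).
#' @export
summarize_distribution <- function(dist, dominance = 0.8, eradication = 0.05,
                                   top_floor = 0.1) {
  if (!inherits(dist, "crime_stationary") || is.null(dist$space))
    stop("need a crime_stationary with its state space", call. = FALSE)
  ex <- dist$expected_x
  roles <- c("honest", "criminal", "wolf")
  parts <- character(0)
  if (max(ex) >= dominance)
    parts <- paste(roles[which.max(ex)], "dominance")
  if (ex[2] + ex[3] <= eradication)
    parts <- c(parts, "crime eradicated")
  if (!length(parts))
    parts <- paste0("coexistence (",
                    paste(roles[ex >= eradication], collapse = ", "), ")")
  keep <- dist$pi >= top_floor * max(dist$pi)
  top <- data.frame(dist$space$states[keep, , drop = FALSE],
                    pi = dist$pi[keep])
  top <- top[order(-top$pi), ]
  rownames(top) <- NULL
  structure(list(expected_x = ex, label = paste(parts, collapse = " / "),
                 top_states = top),
            class = "crime_regime")
}

#' @export
print.crime_regime <- function(x, ...) {
  cat("regime:", x$label, "\n")
  cat(sprintf("  E[x_H] = %.4f, E[x_C] = %.4f, E[x_W] = %.4f\n",
              x$expected_x[1], x$expected_x[2], x$expected_x[3]))
  cat("  most visited states:\n")
  print(utils::head(x$top_states, 5))
  invisible(x)
}
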