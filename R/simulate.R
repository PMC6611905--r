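#' Fermi imitation probability
#'
#' Probability that an individual with payoff `omega_i` adopts the role of
#' an individual with payoff `omega_j`:
#' \deqn{P(i \leftarrow j) = \frac{1}{e^{-(\omega_j - \omega_i)/T} + 1}.}
#' Overflow-safe for arbitrarily large payoff differences;
#' `P(i<-j) + P(j<-i) = 1`.
#'
#' @param omega_i,omega_j Payoffs (vectorised).
#' @param T Fermi temperature (> 0): the smaller, the closer to a strict
#'   better-payoff-wins rule.
#' @return Probabilities in (0, 1).
#' @examples
#' fermi_probability(0, 0, 1)            # 0.5
#' fermi_probability(0, log(3), 1)       # 0.75
#' @export
fermi_probability <- function(omega_i, omega_j, T = 1) {
  if (any(T <= 0)) stop("T must be positive", call. = FALSE)
  stats::plogis((omega_j - omega_i) / T)
}

roles_from_state <- function(state, params) {
  z <- check_state(state, params)
  rep.int(1:3, z)
}

role_counts <- function(roles) tabulate(roles, nbins = 3L)

#' Play one game: stochastic acting and investigation stages
#'
#' The population is shuffled and partitioned into `Z/N` groups. In each
#' group one member is drawn uniformly to act: an honest does nothing, a
#' criminal always acts, a wolf acts with probability
#' `1 - delta*(1 - p_C)`. A criminal act costs every non-criminal `c_C`
#' and pays every group criminal `r_C*c_C*(N - n_C)/n_C`; a wolf act costs
#' every other member `c_W`, pays the wolf `(1-tau)*r_W*c_W*(N-1)` and
#' pays every group criminal `tau*r_W*c_W*(N-1)/n_W`. After an act one
#' member is drawn uniformly for investigation: if the act was criminal
#' and the drawn member is a criminal, she loses `beta_S + beta_H*p_H` and
#' every other group criminal loses `gamma` times that; if the act was a
#' wolf's and the drawn member is that wolf, she loses
#' `beta_S + beta_H*p_H + beta_C*p_C`. Realised per-role payoffs equal the
#' analytic stage payoffs in expectation.
#'
#' @param roles Integer vector of length `Z` with roles coded 1 = honest,
#'   2 = criminal, 3 = wolf (see [agent_population()]).
#' @param params A [model_params()] object; `Z` must be divisible by `N`.
#' @return Numeric vector of per-agent payoffs for this game.
#' @examples
#' set.seed(1)
#' p <- model_params(Z = 50, N = 10)
#' play_game(roles_from_state(c(25, 20, 5), p), p)
#' @export
play_game <- function(roles, params) {
  as.vector(play_games(roles, params, games = 1L))
}

# Vectorised core: total per-agent payoffs over `games` independent games
# (each with its own shuffle/partition), divided by `games`.
play_games <- function(roles, params, games) {
  Z <- params$Z; N <- params$N
  if (length(roles) != Z) stop("roles must have length Z", call. = FALSE)
  if (Z %% N != 0L)
    stop("cannot partition: Z = ", Z, " is not a multiple of N = ", N,
         call. = FALSE)
  ngpg <- Z %/% N
  acc <- numeric(Z)
  done <- 0L
  chunk_max <- max(1L, 200000L %/% Z)
  while (done < games) {
    g <- min(chunk_max, games - done)
    ng <- ngpg * g
    # one permutation per game; slot layout is column-major, N per group
    perms <- vapply(seq_len(g), function(i) sample.int(Z), integer(Z))
    roles_flat <- roles[as.vector(perms)]
    nH <- colSums(matrix(roles_flat == 1L, N, ng))
    nC <- colSums(matrix(roles_flat == 2L, N, ng))
    nW <- colSums(matrix(roles_flat == 3L, N, ng))
    base <- (seq_len(ng) - 1L) * N
    actor_idx <- base + sample.int(N, ng, replace = TRUE)
    actor_role <- roles_flat[actor_idx]
    ppW <- 1 - params$delta * (1 - nC / N)
    act_u <- stats::runif(ng)
    crim_act <- actor_role == 2L
    wolf_act <- actor_role == 3L & act_u < ppW
    drawn_idx <- base + sample.int(N, ng, replace = TRUE)
    pay <- numeric(Z * g)
    is_C <- roles_flat == 2L
    punish <- params$beta_S + params$beta_H * nH / N
    # acting stage, criminal acts
    if (any(crim_act)) {
      gain <- ifelse(crim_act, params$r_C * params$c_C * (N - nC) / pmax(nC, 1L), 0)
      gsl <- rep(gain, each = N)
      csl <- rep(crim_act, each = N)
      pay <- pay + ifelse(csl, ifelse(is_C, gsl, -params$c_C), 0)
      # investigation: any drawn criminal is punished, co-offenders reduced
      inv <- crim_act & roles_flat[drawn_idx] == 2L
      psl <- rep(ifelse(inv, punish, 0), each = N)
      pay <- pay - ifelse(is_C, params$gamma * psl, 0)
      hit <- drawn_idx[inv]
      pay[hit] <- pay[hit] - (1 - params$gamma) * punish[inv]
    }
    # acting stage, wolf acts
    if (any(wolf_act)) {
      tshare <- ifelse(wolf_act & nW > 0L,
                       params$tau * params$r_W * params$c_W * (N - 1) / pmax(nW, 1L),
                       0)
      wsl <- rep(wolf_act, each = N)
      pay <- pay + ifelse(wsl, ifelse(is_C, rep(tshare, each = N), 0) - params$c_W, 0)
      wa <- actor_idx[wolf_act]
      pay[wa] <- pay[wa] + params$c_W +
        (1 - params$tau) * params$r_W * params$c_W * (N - 1)
      # investigation succeeds only if the acting wolf herself is drawn
      inv <- wolf_act & drawn_idx == actor_idx
      hit <- actor_idx[inv]
      pay[hit] <- pay[hit] - (punish[inv] + params$beta_C * nC[inv] / N)
    }
    acc <- acc + unname(rowsum(pay, group = as.vector(perms), reorder = TRUE)[, 1])
    done <- done + g
  }
  acc / games
}

#' Average per-agent payoffs over G games
#'
#' Plays `params$G` independent games (the population is reshuffled and
#' re-partitioned before each) and returns each agent's payoff averaged
#' over them — the payoff estimate used by the imitation step.
#'
#' @inheritParams play_game
#' @return Numeric vector of per-agent average payoffs.
#' @export
accumulate_payoffs <- function(roles, params) {
  play_games(roles, params, games = params$G)
}

#' One asynchronous evolutionary update
#'
#' With probability `mu` a mutation occurs: one uniformly chosen agent
#' adopts one of the three roles with equal probability. Otherwise two
#' distinct agents `i`, `j` are drawn uniformly and `i` adopts `j`'s role
#' with probability [fermi_probability()]`(omega_i, omega_j, T)`.
#'
#' @inheritParams play_game
#' @param payoffs Per-agent payoffs for the current population (from
#'   [accumulate_payoffs()]).
#' @return The updated roles vector.
#' @export
evolution_step <- function(roles, payoffs, params) {
  Z <- params$Z
  if (stats::runif(1) < params$mu) {
    a <- sample.int(Z, 1L)
    roles[a] <- sample.int(3L, 1L)
  } else {
    ij <- sample.int(Z, 2L)
    if (stats::runif(1) < fermi_probability(payoffs[ij[1]], payoffs[ij[2]],
                                            params$T))
      roles[ij[1]] <- roles[ij[2]]
  }
  roles
}

#' Create an agent population from a population state
#'
#' @param state A [population_state()] (or length-3 count vector).
#' @param params A [model_params()] object.
#' @return Integer role vector of length `Z` (1 = honest, 2 = criminal,
#'   3 = wolf).
#' @export
agent_population <- function(state, params) roles_from_state(state, params)

#' Run the Monte Carlo multi-agent simulation
#'
#' Per replicate: starting from `init`, each iteration estimates per-agent
#' payoffs over `G` games ([accumulate_payoffs()]) and applies one
#' [evolution_step()]; the role fractions are recorded after every
#' iteration. Replicates use seeds derived deterministically from `seed`,
#' so identical inputs give bit-identical trajectories.
#'
#' @param params A [model_params()] object (`Z` divisible by `N`).
#' @param init Initial [population_state()] (or length-3 count vector).
#' @param iterations Number of evolutionary steps per replicate.
#' @param replicates Number of independent runs averaged.
#' @param seed Integer seed governing all randomness.
#' @return An object of class `crime_trajectory`: list with `fractions`
#'   (array `[iterations + 1, 3, replicates]`, iteration 0 first), `mean`
#'   (matrix of across-replicate averages), `sd` (per-point dispersion),
#'   and the run manifest (`params`, `init`, `seed`, sizes).
#' @examples
#' tr <- run_simulation(model_params(Z = 20, N = 10, G = 5),
#'                      c(10, 5, 5), iterations = 10, replicates = 2,
#'                      seed = 1)
#' tail(tr$mean, 2)
#' @export
run_simulation <- function(params, init, iterations, replicates = 1L,
                           seed = 1L) {
  z0 <- check_state(init, params)
  stopifnot(iterations >= 1, replicates >= 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, replicates)
  traj <- array(NA_real_, dim = c(iterations + 1L, 3L, replicates),
                dimnames = list(NULL, c("x_H", "x_C", "x_W"), NULL))
  for (r in seq_len(replicates)) {
    set.seed(rep_seeds[r])
    roles <- roles_from_state(z0, params)
    traj[1L, , r] <- role_counts(roles) / params$Z
    for (it in seq_len(iterations)) {
      pay <- accumulate_payoffs(roles, params)
      roles <- evolution_step(roles, pay, params)
      traj[it + 1L, , r] <- role_counts(roles) / params$Z
    }
  }
  mean_traj <- apply(traj, c(1, 2), mean)
  sd_traj <- if (replicates > 1L) apply(traj, c(1, 2), stats::sd)
             else matrix(0, iterations + 1L, 3L,
                         dimnames = dimnames(mean_traj))
  structure(list(fractions = traj, mean = mean_traj, sd = sd_traj,
                 params = params, init = z0, seed = seed,
                 iterations = as.integer(iterations),
                 replicates = as.integer(replicates)),
            class = "crime_trajectory")
}

#' @export
print.crime_trajectory <- function(x, ...) {
  cat(sprintf("Monte Carlo trajectory: %d iterations x %d replicates, Z = %d\n",
              x$iterations, x$replicates, x$params$Z))
  cat("final averaged fractions:\n")
  print(round(x$mean[nrow(x$mean), ], 4))
  invisible(x)
}

#' @export
as.data.frame.crime_trajectory <- function(x, ...) {
  reps <- lapply(seq_len(x$replicates), function(r)
    data.frame(iteration = 0:x$iterations, replicate = as.character(r),
               x_H = x$fractions[, 1, r], x_C = x$fractions[, 2, r],
               x_W = x$fractions[, 3, r]))
  avg <- data.frame(iteration = 0:x$iterations, replicate = "mean",
                    x_H = x$mean[, 1], x_C = x$mean[, 2], x_W = x$mean[, 3])
  do.call(rbind, c(reps, list(avg)))
}
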