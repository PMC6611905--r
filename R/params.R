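#' Model parameters for the three-role adversarial game
#'
#' Constructs and validates the full parameter vector of the game and its
#' dynamics. Roles are honest citizens (H), members of the criminal
#' organisation (C), and lone wolves (W).
#'
#' @param N Group size: number of players per game group (integer, >= 2).
#' @param Z Population size (integer, >= N). For agent-based simulation,
#'   `Z` must be a multiple of `N` (the population is partitioned into
#'   `Z/N` groups each game).
#' @param c_C,c_W Damage inflicted on each victim by a criminal / wolf act
#'   (payoff units, >= 0).
#' @param r_C,r_W Reward multiplier on damage for criminals / wolves
#'   (dimensionless, >= 0).
#' @param delta Propaganda coupling in `[0, 1]`: a wolf acts with
#'   probability `1 - delta * (1 - p_C)`, linking wolf activity to the
#'   presence of criminals in the group.
#' @param tau Benefit-transfer fraction in `[0, 1]`: the share of wolf loot
#'   credited to the organisation.
#' @param gamma Co-offender punishment reduction in `[0, 1]`: a caught
#'   criminal's group co-members receive `gamma` times her punishment.
#' @param beta_S,beta_H,beta_C Punishment intensities from the state, the
#'   civil society (scaled by the honest fraction), and the criminal
#'   organisation (scaled by the criminal fraction, hits wolves only); all
#'   in payoff units, >= 0.
#' @param mu Regularisation/mutation probability, in (0, 1). Used both to
#'   regularise the finite-population transition matrix and as the mutation
#'   rate of the agent simulation.
#' @param T Fermi temperature (payoff units, > 0) of the imitation rule.
#' @param G Number of games played per payoff estimate in the agent
#'   simulation (integer, >= 1).
#'
#' @return An object of class `crime_params`: a named list of the
#'   validated parameters.
#' @examples
#' p <- model_params(N = 10, Z = 50, beta_S = 100)
#' p$beta_S
#' @export
model_params <- function(N = 10, Z = 50,
                         c_C = 1, c_W = 1, r_C = 1, r_W = 1,
                         delta = 0, tau = 0, gamma = 0.5,
                         beta_S = 0, beta_H = 0, beta_C = 0,
                         mu = 1e-6, T = 1, G = 100) {
  p <- list(N = N, Z = Z, c_C = c_C, c_W = c_W, r_C = r_C, r_W = r_W,
            delta = delta, tau = tau, gamma = gamma,
            beta_S = beta_S, beta_H = beta_H, beta_C = beta_C,
            mu = mu, T = T, G = G)
  validate_params(p)
}

validate_params <- function(p) {
  chk <- function(cond, field, msg) {
    if (!isTRUE(cond)) stop("invalid parameter '", field, "': ", msg, call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in names(p)) chk(num1(p[[f]]), f, "must be a single finite number")
  chk(p$N >= 2 && p$N == round(p$N), "N", "group size must be an integer >= 2")
  chk(p$Z >= p$N && p$Z == round(p$Z), "Z", "population size must be an integer >= N")
  for (f in c("c_C", "c_W", "r_C", "r_W", "beta_S", "beta_H", "beta_C"))
    chk(p[[f]] >= 0, f, "must be non-negative")
  for (f in c("delta", "tau", "gamma"))
    chk(p[[f]] >= 0 && p[[f]] <= 1, f, "must lie in [0, 1]")
  chk(p$mu > 0 && p$mu < 1, "mu", "must lie in (0, 1)")
  chk(p$T > 0, "T", "temperature must be positive")
  chk(p$G >= 1 && p$G == round(p$G), "G", "games per estimate must be an integer >= 1")
  p$N <- as.integer(p$N); p$Z <- as.integer(p$Z); p$G <- as.integer(p$G)
  structure(p, class = "crime_params")
}

#' @export
print.crime_params <- function(x, ...) {
  cat("Three-role adversarial game parameters\n")
  cat(sprintf("  group size N = %d, population Z = %d\n", x$N, x$Z))
  cat(sprintf("  damages  c_C = %g, c_W = %g; rewards r_C = %g, r_W = %g\n",
              x$c_C, x$c_W, x$r_C, x$r_W))
  cat(sprintf("  delta = %g, tau = %g, gamma = %g\n", x$delta, x$tau, x$gamma))
  cat(sprintf("  punishment beta_S = %g, beta_H = %g, beta_C = %g\n",
              x$beta_S, x$beta_H, x$beta_C))
  cat(sprintf("  mu = %g, T = %g, G = %d\n", x$mu, x$T, x$G))
  invisible(x)
}

#' Scenario presets for organised-crime and terrorist-network settings
#'
#' Named parameterisations of the two studied contexts. `"CO"` is the
#' organised-crime scenario: criminals and wolves compete, with no
#' propaganda (`delta = 0`) and no benefit transfer (`tau = 0`).
#' `"TN-baseline"` models a terrorist network whose interests are aligned
#' with lone wolves, so the organisation never punishes them
#' (`beta_C = 0`); `"TN-propaganda"` adds propaganda only
#' (`delta = 0.5, tau = 0`) and `"TN-transfer"` benefit transfer only
#' (`delta = 0, tau = 0.5`). All presets share `gamma = 0.5`, `N = 10`,
#' `Z = 50`, `c_C = c_W = r_C = r_W = 1` and `mu = 1e-6`; punishment
#' intensities default to 0 and are meant to be swept or overridden.
#'
#' @param name One of `"CO"`, `"TN-baseline"`, `"TN-propaganda"`,
#'   `"TN-transfer"`.
#' @param ... Overrides passed on to [model_params()] (e.g. `beta_S = 100`).
#' @return A `crime_params` object.
#' @examples
#' scenario_preset("CO", beta_S = 50, beta_C = 400)
#' @export
scenario_preset <- function(name, ...) {
  presets <- list(
    "CO"            = list(delta = 0,   tau = 0),
    "TN-baseline"   = list(delta = 0,   tau = 0,   beta_C = 0),
    "TN-propaganda" = list(delta = 0.5, tau = 0,   beta_C = 0),
    "TN-transfer"   = list(delta = 0,   tau = 0.5, beta_C = 0)
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets))
    stop("unknown scenario preset; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  base <- c(presets[[name]],
            list(gamma = 0.5, N = 10, Z = 50,
                 c_C = 1, c_W = 1, r_C = 1, r_W = 1, mu = 1e-6))
  over <- list(...)
  base[names(over)] <- over
  do.call(model_params, base)
}
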