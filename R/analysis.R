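#' Analytic two-type invasion thresholds
#'
#' In the single-group limit `N = Z`, with `delta = tau = 0`,
#' `c_C = c_W = c` and `r_C = r_W = 1`, the pairwise competition between
#' any two roles reduces to closed-form conditions on the rescaled
#' punishment `beta' = (beta_S + beta_H * p_H)/c` and the criminal
#' traceability `g = (1 - gamma) * p1 + gamma * p_C`:
#'
#' * no criminals (`x_C = 0`): honests defeat wolves iff `beta' > N^2`;
#' * no wolves (`x_W = 0`): honests defeat criminals iff
#'   `beta' > 1/(g * p_C)`;
#' * no honests (`x_H = 0`): the organisation defeats wolves iff the
#'   payoff difference `omega_C - omega_W =
#'   (beta_S + beta_C p_C)/N^2 - beta_S p_C g` is positive, i.e.
#'   `beta_C > (N^2 g p_C - 1) beta_S / p_C`.
#'
#' For the third case the commonly quoted compact form
#' `beta_C > (N^2 g p_C - 1) beta_S` is also reported
#' (`beta_C_boundary_compact`); it differs from the payoff-derived
#' boundary by the factor `1/p_C`, and [pairwise_sign_test()] confirms
#' the payoff-derived one. All boundaries returned are the values at
#' which the relevant payoff difference changes sign.
#'
#' @param params A [model_params()] with `N = Z`, `delta = tau = 0`,
#'   `c_C = c_W` and `r_C = r_W = 1`.
#' @param comp A two-type [group_composition()] (exactly one role count
#'   is zero).
#' @return A list of class `threshold_report` with `beta_prime`, `g`, the
#'   three boundary values (`beta_prime_HW = N^2`,
#'   `beta_prime_HC = 1/(g p_C)`, `beta_C_boundary` and
#'   `beta_C_boundary_compact`), and logical conditions `honest_beats_wolf`,
#'   `honest_beats_criminal`, `criminal_beats_wolf` evaluated at `params`.
#' @examples
#' analytic_thresholds(model_params(N = 10, Z = 10, beta_S = 150),
#'                     group_composition(5, 0, 5))
#' @export
analytic_thresholds <- function(params, comp) {
  n <- check_comp(comp, params)
  if (params$N != params$Z || params$delta != 0 || params$tau != 0 ||
      params$c_C != params$c_W || params$r_C != 1 || params$r_W != 1)
    stop("unsupported regime: thresholds require N = Z, delta = tau = 0, ",
         "c_C = c_W, r_C = r_W = 1", call. = FALSE)
  if (sum(n == 0L) != 1L)
    stop("unsupported regime: composition must contain exactly two roles",
         call. = FALSE)
  N <- params$N; cc <- params$c_C
  p1 <- 1 / N
  p_H <- n[1] / N; p_C <- n[2] / N
  g <- (1 - params$gamma) * p1 + params$gamma * p_C
  beta_prime <- (params$beta_S + params$beta_H * p_H) / cc
  rep_ <- list(
    beta_prime = beta_prime,
    g = g,
    beta_prime_HW = N^2,
    beta_prime_HC = if (p_C > 0) 1 / (g * p_C) else Inf,
    beta_C_boundary = if (p_C > 0) (N^2 * g * p_C - 1) * params$beta_S / p_C
                      else Inf,
    beta_C_boundary_compact = (N^2 * g * p_C - 1) * params$beta_S,
    honest_beats_wolf = beta_prime > N^2,
    honest_beats_criminal = p_C > 0 && beta_prime > 1 / (g * p_C),
    criminal_beats_wolf = p_C > 0 &&
      params$beta_C > (N^2 * g * p_C - 1) * params$beta_S / p_C
  )
  structure(rep_, class = "threshold_report")
}

#' Numeric sign of a pairwise payoff difference
#'
#' Ground-truth check for [analytic_thresholds()]: computes the total
#' focal payoffs (acting + investigation) of two roles directly from the
#' stage-payoff formulas in the single-group limit `N = Z` and returns the
#' sign of their difference.
#'
#' @param roleA,roleB Roles `"H"`, `"C"`, `"W"`; both must be present in
#'   `comp`.
#' @param comp A two-type [group_composition()].
#' @param params A [model_params()] with `N = Z`.
#' @return A list with `diff` (`omega_A - omega_B`) and `sign`
#'   (-1, 0 or 1).
#' @examples
#' pairwise_sign_test("H", "W", group_composition(5, 0, 5),
#'                    model_params(N = 10, Z = 10, beta_S = 101))
#' @export
pairwise_sign_test <- function(roleA, roleB, comp, params) {
  if (params$N != params$Z)
    stop("pairwise sign test is defined in the single-group limit N = Z",
         call. = FALSE)
  wA <- stage_payoffs(comp, params, role = roleA)
  wB <- stage_payoffs(comp, params, role = roleB)
  d <- wA - wB
  list(diff = d, sign = sign(d))
}

#' Sweep a phase diagram over one or two punishment axes
#'
#' For every grid cell the parameter(s) are set, the regularised Markov
#' chain over all population states is built, its stationary distribution
#' is computed and summarised. Deterministic.
#'
#' @param params Base [model_params()] (typically a [scenario_preset()]).
#' @param axis1 A list `list(param = <name>, values = <numeric grid>)`;
#'   the name must be a numeric field of the parameter vector.
#' @param axis2 Optional second axis in the same form; omit for a 1-D
#'   sweep.
#' @param dominance,eradication Passed to [summarize_distribution()].
#' @param mu_mode Passed to [build_transition_matrix()].
#' @return A data frame of class `crime_phase` with one row per cell:
#'   the axis values, `E_x_H`, `E_x_C`, `E_x_W`, and `label`.
#' @examples
#' \donttest{
#' sweep_phase_diagram(scenario_preset("CO"),
#'                     list(param = "beta_S", values = c(0, 100)))
#' }
#' @export
sweep_phase_diagram <- function(params, axis1, axis2 = NULL,
                                dominance = 0.8, eradication = 0.05,
                                mu_mode = "all") {
  chk_axis <- function(ax) {
    if (!is.list(ax) || !all(c("param", "values") %in% names(ax)))
      stop("axis must be list(param = , values = )", call. = FALSE)
    if (!ax$param %in% names(params) || !is.numeric(params[[ax$param]]))
      stop("unknown or non-numeric parameter '", ax$param, "'", call. = FALSE)
    ax
  }
  axis1 <- chk_axis(axis1)
  grid <- if (is.null(axis2)) {
    stats::setNames(data.frame(v1 = axis1$values), axis1$param)
  } else {
    axis2 <- chk_axis(axis2)
    stats::setNames(expand.grid(v1 = axis1$values, v2 = axis2$values),
                    c(axis1$param, axis2$param))
  }
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    for (nm in names(grid)) p[[nm]] <- grid[[nm]][i]
    p <- validate_params(unclass(p))
    dist <- stationary_distribution(build_transition_matrix(p, mu_mode))
    sm <- summarize_distribution(dist, dominance = dominance,
                                 eradication = eradication)
    data.frame(E_x_H = sm$expected_x[1], E_x_C = sm$expected_x[2],
               E_x_W = sm$expected_x[3], label = sm$label)
  })
  out <- cbind(grid, do.call(rbind, res))
  rownames(out) <- NULL
  class(out) <- c("crime_phase", "data.frame")
  out
}

#' Detect the first grid value satisfying a regime predicate
#'
#' Scans a 1-D phase-diagram slice in increasing axis order and returns
#' the smallest grid value whose cell satisfies `predicate`, together
#' with the local grid step as the resolution of the estimate.
#'
#' @param sweep A data frame from [sweep_phase_diagram()] (1-D).
#' @param predicate A function of one row (as a list) returning TRUE or
#'   FALSE, e.g. `function(cell) cell$E_x_H >= 0.9`.
#' @param param Name of the swept axis column (default: first column).
#' @return A list with `value` (the threshold, or `NA` if the predicate
#'   is never satisfied), `resolution` (grid step at the threshold) and
#'   `satisfied` (logical vector over the grid).
#' @export
detect_threshold <- function(sweep, predicate, param = names(sweep)[1]) {
  ord <- order(sweep[[param]])
  vals <- sweep[[param]][ord]
  sat <- vapply(ord, function(i) isTRUE(predicate(as.list(sweep[i, ]))),
                logical(1))
  hit <- which(sat)[1]
  if (is.na(hit))
    return(list(value = NA_real_, resolution = NA_real_, satisfied = sat))
  res <- if (hit > 1L) vals[hit] - vals[hit - 1L]
         else if (length(vals) > 1L) vals[2L] - vals[1L] else NA_real_
  list(value = vals[hit], resolution = res, satisfied = sat)
}
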