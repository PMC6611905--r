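#' Group composition
#'
#' A playing group of `N` individuals holding `n_H` honest citizens, `n_C`
#' criminals and `n_W` lone wolves, with `n_H + n_C + n_W = N`.
#'
#' @param n_H,n_C,n_W Non-negative integer role counts.
#' @return An object of class `crime_group` (named integer vector).
#' @examples
#' group_composition(8, 1, 1)
#' @export
group_composition <- function(n_H, n_C, n_W) {
  n <- c(n_H = n_H, n_C = n_C, n_W = n_W)
  if (any(!is.finite(n)) || any(n < 0) || any(n != round(n)))
    stop("group counts must be non-negative integers", call. = FALSE)
  structure(as.integer(n), names = names(n), class = "crime_group")
}

check_comp <- function(comp, params) {
  if (inherits(comp, "crime_group")) n <- unclass(comp)
  else if (is.numeric(comp) && length(comp) == 3L) n <- comp
  else stop("composition must be a crime_group or a length-3 count vector",
            call. = FALSE)
  if (any(n < 0) || any(n != round(n)))
    stop("group counts must be non-negative integers", call. = FALSE)
  if (sum(n) != params$N)
    stop("invalid composition: counts sum to ", sum(n),
         ", expected N = ", params$N, call. = FALSE)
  as.integer(n)
}

#' Within-group acting probabilities
#'
#' The probability that any particular member is drawn to act is
#' `p1 = 1/N`; the probability that the drawn member has role k is
#' `p_k = n_k/N`. A drawn wolf then acts with probability
#' `pprime_W = 1 - delta * (1 - p_C)`: with full propaganda coupling
#' (`delta = 1`) wolves are quiescent unless criminals are present.
#'
#' @param comp A [group_composition()] (or length-3 count vector
#'   `c(n_H, n_C, n_W)`).
#' @param params A [model_params()] object.
#' @return A list with `p1`, `p_H`, `p_C`, `p_W` and `pprime_W`.
#' @examples
#' group_probabilities(group_composition(5, 4, 1),
#'                     model_params(delta = 0.5))
#' @export
group_probabilities <- function(comp, params) {
  n <- check_comp(comp, params)
  N <- params$N
  p_C <- n[2] / N
  list(p1 = 1 / N, p_H = n[1] / N, p_C = p_C, p_W = n[3] / N,
       pprime_W = 1 - params$delta * (1 - p_C))
}

#' Acting-stage expected payoffs
#'
#' Expected payoff of a focal individual of each role in a group of
#' composition `comp`, from the acting stage of one game. One member is
#' drawn uniformly; a drawn criminal always acts, a drawn wolf acts with
#' probability `pprime_W`, a drawn honest does nothing. A criminal act
#' damages every non-criminal by `c_C` and the resulting benefit
#' `r_C * c_C` per victim is shared among the group's criminals; a wolf
#' act damages every other member by `c_W` and the wolf keeps a fraction
#' `1 - tau` of the benefit `r_W * c_W` per victim, the remaining `tau`
#' share being credited to the organisation. In expectation:
#' \deqn{b_C = r_C c_C (1 - p_C), \quad d_C = c_C p_C,}
#' \deqn{b_W = r_W c_W (N-1) p_1 p'_W, \quad d_{W|N'} = c_W p'_W N'/N,}
#' where `N'` counts the *other* wolves threatening the focal individual
#' (`n_W` for honests and criminals, `n_W - 1` for a wolf). Then
#' `w_H = -d_C - d_W|n_W`, `w_C = b_C + tau*b_W - d_W|n_W`,
#' `w_W = (1-tau)*b_W - d_C - d_W|n_W-1`. The `tau*b_W` credit to a
#' criminal is taken literally and does not scale with the number of
#' wolves present. Honests are only harmed in this stage, so `w_H <= 0`;
#' an all-honest group yields all zeros.
#'
#' `w_C` is only defined when the group contains a criminal (the benefit
#' share divides by `n_C`); for `n_C = 0` it is returned as `NA` and
#' requesting it via `role = "C"` is an error.
#'
#' @inheritParams group_probabilities
#' @param role Optionally, one of `"H"`, `"C"`, `"W"` to return a single
#'   focal payoff instead of the full stage record.
#' @return A list of class `stage_payoffs` with focal payoffs `w_H`,
#'   `w_C`, `w_W` and the intermediates `b_C`, `b_W`, `d_C`, `d_W`
#'   (damage from all `n_W` wolves), or a single number when `role` is
#'   given.
#' @examples
#' acting_payoffs(group_composition(8, 1, 1), model_params())
#' @export
acting_payoffs <- function(comp, params, role = NULL) {
  n <- check_comp(comp, params)
  pr <- group_probabilities(n, params)
  b_C <- params$r_C * params$c_C * (1 - pr$p_C)
  d_C <- params$c_C * pr$p_C
  b_W <- params$r_W * params$c_W * (params$N - 1) * pr$p1 * pr$pprime_W
  d_W <- function(n_other) params$c_W * pr$pprime_W * n_other / params$N
  w_H <- -d_C - d_W(n[3])
  w_C <- if (n[2] >= 1) b_C + params$tau * b_W - d_W(n[3]) else NA_real_
  w_W <- (1 - params$tau) * b_W - d_C - d_W(max(n[3] - 1L, 0L))
  out <- structure(list(w_H = w_H, w_C = w_C, w_W = w_W,
                        b_C = b_C, b_W = b_W, d_C = d_C, d_W = d_W(n[3])),
                   class = "stage_payoffs")
  pick_role(out, role, n)
}

#' Investigation-stage expected payoffs
#'
#' Expected payoff reduction of a focal individual of each role from the
#' investigation following a criminal act. A victimiser must first act
#' (probability `p_C` for a criminal, `p1 * pprime_W` for a wolf) and is
#' then caught with probability `gamma*p_C + (1-gamma)*p1` (criminals: a
#' caught co-offender drags the others down, reduced by `gamma`) or `p1`
#' (wolves). Punishment combines the state (`beta_S`), the civil society
#' (`beta_H`, scaled by the honest fraction `p_H`) and, against wolves
#' only, the criminal organisation (`beta_C`, scaled by `p_C`):
#' \deqn{w^I_H = 0}
#' \deqn{w^I_C = -(\beta_S + \beta_H p_H) p_C [\gamma p_C + (1-\gamma) p_1]}
#' \deqn{w^I_W = -(\beta_S + \beta_H p_H + \beta_C p_C) p_1^2 p'_W}
#' All values are non-positive.
#'
#' @inheritParams acting_payoffs
#' @return As [acting_payoffs()], with intermediates absent.
#' @examples
#' investigation_payoffs(group_composition(8, 2, 0),
#'                       model_params(beta_S = 100))
#' @export
investigation_payoffs <- function(comp, params, role = NULL) {
  n <- check_comp(comp, params)
  pr <- group_probabilities(n, params)
  base <- params$beta_S + params$beta_H * pr$p_H
  w_C <- -base * pr$p_C * (params$gamma * pr$p_C + (1 - params$gamma) * pr$p1)
  w_W <- -(base + params$beta_C * pr$p_C) * pr$p1^2 * pr$pprime_W
  out <- structure(list(w_H = 0, w_C = w_C, w_W = w_W),
                   class = "stage_payoffs")
  pick_role(out, role, n)
}

#' Total (acting + investigation) focal payoffs in a group
#'
#' @inheritParams acting_payoffs
#' @return A list with `w_H`, `w_C`, `w_W` (total expected payoff per
#'   focal role), or a single number when `role` is given.
#' @export
stage_payoffs <- function(comp, params, role = NULL) {
  a <- acting_payoffs(comp, params)
  i <- investigation_payoffs(comp, params)
  out <- structure(list(w_H = a$w_H + i$w_H, w_C = a$w_C + i$w_C,
                        w_W = a$w_W + i$w_W), class = "stage_payoffs")
  pick_role(out, role, check_comp(comp, params))
}

pick_role <- function(payoffs, role, n) {
  if (is.null(role)) return(payoffs)
  role <- match.arg(role, c("H", "C", "W"))
  if (role == "C" && n[2] == 0L)
    stop("undefined focal: criminal payoff requested in a group with no criminals",
         call. = FALSE)
  payoffs[[paste0("w_", role)]]
}

#' @export
print.stage_payoffs <- function(x, ...) {
  cat(sprintf("focal payoffs: w_H = %g, w_C = %g, w_W = %g\n",
              x$w_H, x$w_C, x$w_W))
  if (!is.null(x$b_C))
    cat(sprintf("  (b_C = %g, b_W = %g, d_C = %g, d_W = %g)\n",
                x$b_C, x$b_W, x$d_C, x$d_W))
  invisible(x)
}
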