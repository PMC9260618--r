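#' Task utility families
#'
#' A utility family maps the number of performers of a task to the utility
#' (net work done or saved, in energy units per time step) that the colony
#' derives from the task. All shipped families satisfy the law of
#' diminishing marginal utility past their threshold: the second derivative
#' of `U` with respect to the task fraction `eps` is negative there, and the
#' marginal utility of the work component vanishes as performers saturate
#' the available resource.
#'
#' Let `x = n * eps` be the number of ants performing the task. The
#' families are parameterised by the task's importance constant `k_tau`
#' (dimensionless, in (0, 1]), work capacity `R` (energy units), saturation
#' rate `a` (per worker) and per-performer energy rate `c`:
#'
#' * `"saturating"` (default): `U = k*R*(1 - exp(-a*x)) - c*x`. Work
#'   saturates exponentially; task energy is linear in performers. Strictly
#'   concave in `eps` wherever `R > 0`.
#' * `"saturating_satcost"`: `U = (k*R - c/a) * (1 - exp(-a*x))`. Both the
#'   work and the energy component saturate, so the total marginal utility
#'   tends to zero as `eps -> 1` for large `a*n`. Concave iff
#'   `k*R*a >= c`.
#' * `"logistic"`: work term `k*R` times a logistic ramp in `x` centred at
#'   the concavity threshold `threshold_n0`, normalised to 0 at `x = 0`,
#'   minus `c*x`. Concave only for `x > threshold_n0` (accelerating
#'   returns below it), so the equilibrium solver accepts it only when
#'   `threshold_n0 = 0`.
#' * `"linear"`: `U = (k*R - c)*x`. Constant marginal utility; used for
#'   degenerate checks and for the per-capita-utility reading that
#'   underlies the biomass proxy.
#'
#' @name utility-families
#' @keywords internal
NULL

.family_names <- c("saturating", "saturating_satcost", "logistic", "linear")

.check_family <- function(family) {
  if (!is.character(family) || length(family) != 1L || !family %in% .family_names) {
    stop("unknown utility family '", paste(family, collapse = ","),
         "'; available: ", paste(.family_names, collapse = ", "),
         call. = FALSE)
  }
  family
}

# logistic helper, numerically safe for large |z|
.sigm <- function(z) 1 / (1 + exp(-z))

#' Evaluate a task utility function
#'
#' Computes `U_j(n, eps)` for a task under its configured utility family.
#' Vectorised over `eps`.
#'
#' @param task a [task_spec()].
#' @param n colony size (non-negative scalar).
#' @param eps fraction of the colony performing the task, in `[0, 1]`
#'   (vectorised).
#' @return utility value(s), energy units per time step. `eps = 0` always
#'   yields 0: with no performers there is neither work nor task cost.
#' @examples
#' tsk <- task_spec("forage", k_tau = 1, R = 10, a = 0.1, c = 0.02)
#' evaluate_utility(tsk, n = 100, eps = 0.5)   # 10*(1 - exp(-5)) - 1
#' @export
evaluate_utility <- function(task, n, eps) {
  stopifnot(inherits(task, "task_spec"))
  if (length(n) != 1L || is.na(n) || n < 0) {
    stop("colony size 'n' must be a single non-negative number", call. = FALSE)
  }
  if (any(is.na(eps)) || any(eps < 0) || any(eps > 1)) {
    stop("'eps' must lie in [0, 1]", call. = FALSE)
  }
  x <- n * eps
  k <- task$k_tau; R <- task$R; a <- task$a; cc <- task$c
  switch(task$family,
    saturating = k * R * (1 - exp(-a * x)) - cc * x,
    saturating_satcost = (k * R - cc / a) * (1 - exp(-a * x)),
    logistic = {
      x0 <- task$threshold_n0
      s0 <- .sigm(-a * x0)
      k * R * (.sigm(a * (x - x0)) - s0) / (1 - s0) - cc * x
    },
    linear = (k * R - cc) * x
  )
}

#' Marginal utility of a task
#'
#' Returns the fractional marginal utility
#' `nu = (U(n*(eps + delta_eps)) - U(n*eps)) / delta_eps` and its
#' infinitesimal limit `mu = dU/d(eps)`, the analytic derivative of the
#' configured family. `nu` converges to `mu` as `delta_eps -> 0`.
#'
#' @inheritParams evaluate_utility
#' @param delta_eps finite increment for `nu`; must satisfy
#'   `eps + delta_eps <= 1` and `delta_eps > 0`. `NULL` (default) skips the
#'   finite-difference value.
#' @return a list with components `nu` (or `NULL`) and `mu`.
#' @export
marginal_utility <- function(task, n, eps, delta_eps = NULL) {
  stopifnot(inherits(task, "task_spec"))
  mu <- marginal_utility_mu(task, n, eps)
  nu <- NULL
  if (!is.null(delta_eps)) {
    if (any(delta_eps <= 0)) {
      stop("'delta_eps' must be positive for the fractional marginal utility",
           call. = FALSE)
    }
    if (any(eps + delta_eps > 1 + 1e-12)) {
      stop("'eps + delta_eps' must not exceed 1", call. = FALSE)
    }
    nu <- (evaluate_utility(task, n, pmin(eps + delta_eps, 1)) -
             evaluate_utility(task, n, eps)) / delta_eps
  }
  list(nu = nu, mu = mu)
}

# analytic dU/d(eps); vectorised over eps
marginal_utility_mu <- function(task, n, eps) {
  x <- n * eps
  k <- task$k_tau; R <- task$R; a <- task$a; cc <- task$c
  switch(task$family,
    saturating = n * (k * R * a * exp(-a * x) - cc),
    saturating_satcost = n * a * (k * R - cc / a) * exp(-a * x),
    logistic = {
      x0 <- task$threshold_n0
      s0 <- .sigm(-a * x0)
      s <- .sigm(a * (x - x0))
      n * (k * R * a * s * (1 - s) / (1 - s0) - cc)
    },
    linear = rep.int(n * (k * R - cc), length(eps))
  )
}

# TRUE if the family is concave in eps over the whole domain [0, 1],
# which the equilibrium solver requires for a global-optimum guarantee
family_is_concave <- function(task) {
  switch(task$family,
    saturating = TRUE,
    saturating_satcost = task$k_tau * task$R * task$a >= task$c,
    logistic = task$threshold_n0 <= 0,
    linear = TRUE
  )
}

# TRUE if mu is strictly decreasing in eps (strict concavity);
# linear families are only weakly concave
family_is_strictly_concave <- function(task) {
  switch(task$family,
    saturating = task$R > 0 && task$k_tau > 0,
    saturating_satcost = task$k_tau * task$R * task$a > task$c,
    logistic = task$threshold_n0 <= 0 && task$R > 0,
    linear = FALSE
  )
}

# Solve mu(eps) = lambda for eps in [0, 1]; mu must be non-increasing.
# Returns 0 when even the first performer is not worth lambda, 1 when the
# marginal utility still exceeds lambda at full allocation.
mu_inverse <- function(task, n, lambda) {
  mu0 <- marginal_utility_mu(task, n, 0)
  if (mu0 <= lambda) return(0)
  mu1 <- marginal_utility_mu(task, n, 1)
  if (mu1 >= lambda) return(1)
  k <- task$k_tau; R <- task$R; a <- task$a; cc <- task$c
  if (task$family == "saturating") {
    # n*(kRa e^{-a n eps} - c) = lambda
    return(-log((lambda / n + cc) / (k * R * a)) / (a * n))
  }
  if (task$family == "saturating_satcost") {
    return(-log(lambda / (n * a * (k * R - cc / a))) / (a * n))
  }
  stats::uniroot(function(e) marginal_utility_mu(task, n, e) - lambda,
                 interval = c(0, 1), tol = 1e-14)$root
}
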