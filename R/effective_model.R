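#' Parameters of the three-junction effective model
#'
#' One-dimensional reduction of the excitable tissue: a central junction of
#' length \eqn{l_1} flanked by two mirror-symmetric outer junctions of length
#' \eqn{l_2}, between fixed walls, so \eqn{l_1 + 2 l_2 = 3L} at all times.
#' Each junction combines a spring (constant `k`, natural length `L`), a
#' dashpot (`mu`), a constant line tension (`Lambda1` center, `Lambda2`
#' outer) and a length-proportional active tension (`Gamma0` when active).
#' Units are nondimensionalized by `k`, `L` and `mu` (all 1 by default).
#'
#' @param k spring constant.
#' @param L natural length.
#' @param mu friction coefficient.
#' @param Lambda1,Lambda2 line tension of the central / outer junctions.
#' @param Gamma0 active contractility.
#' @param eps_on activation strain threshold.
#' @param kL rest-length remodeling rate.
#' @param tau_act,tau_ref active / refractory durations (the analysis of the
#'   model takes them equal, `tau`).
#' @param dt forward-Euler integration step.
#' @return An object of class `eff_params`.
#' @export
eff_params <- function(k = 1, L = 1, mu = 1, Lambda1 = 0.1, Lambda2 = 0.1,
                       Gamma0 = 1, eps_on = 0.1, kL = 0,
                       tau_act = 0.1, tau_ref = tau_act, dt = 1e-3) {
  p <- list(k = k, L = L, mu = mu, Lambda1 = Lambda1, Lambda2 = Lambda2,
            Gamma0 = Gamma0, eps_on = eps_on, kL = kL,
            tau_act = tau_act, tau_ref = tau_ref, dt = dt)
  for (nm in c("k", "L", "mu", "dt", "tau_act"))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop(sprintf("'%s' must be a positive number", nm))
  for (nm in c("Lambda1", "Lambda2", "Gamma0", "eps_on", "kL", "tau_ref"))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) || p[[nm]] < 0)
      stop(sprintf("'%s' must be a non-negative number", nm))
  structure(p, class = "eff_params")
}

#' Passive equilibrium of the three-junction model
#'
#' With all contractilities zero, tension balance at the internal nodes gives
#' \eqn{k(l_1 - L) + \Lambda_1 = k(l_2 - L) + \Lambda_2} under the constraint
#' \eqn{l_1 + 2 l_2 = 3L}, i.e. \eqn{l_1 = L + 2(\Lambda_2 - \Lambda_1)/(3k)}.
#' A central tension lower than the outer one therefore yields a long central
#' junction flanked by short ones, and vice versa.
#'
#' @param params an `eff_params` object.
#' @return Named numeric vector `c(l1, l2)`.
#' @export
eff_equilibrium <- function(params) {
  l1 <- params$L + 2 * (params$Lambda2 - params$Lambda1) / (3 * params$k)
  c(l1 = l1, l2 = (3 * params$L - l1) / 2)
}

#' Simulate the effective three-junction model
#'
#' Starts from the passive equilibrium with zero strain, activates the
#' central junction at t = 0 with a full `tau_act` timer, and integrates the
#' single constrained degree of freedom (the internal node position
#' \eqn{x = l_2}, with \eqn{l_1 = 3L - 2x}) by forward Euler, together with
#' rest-length remodeling of both lengths and the three-state rules applied
#' to the central and (jointly, by symmetry) the outer junctions. The run
#' spans t = 0 to `2 * tau_act` (plus the step on which the central
#' refractory period expires, so reactivation at that instant is observed).
#'
#' Outcomes: `"no_propagation"` if the outer junctions never activate,
#' `"pulse"` if they activate but the central junction never re-activates,
#' `"reactivation"` otherwise.
#'
#' @param params an `eff_params` object.
#' @param tau optional activation period overriding `tau_act` (and `tau_ref`).
#' @param kL optional remodeling rate overriding `params$kL`.
#' @param record keep full trajectories (set FALSE inside root finding).
#' @return A list of class `eff_outcome` with `label` and (when recorded) a
#'   `trajectory` data frame with columns time, l1, l2, l1_rest, l2_rest,
#'   eps1, eps2, state1, state2.
#' @export
simulate_effective <- function(params, tau = NULL, kL = NULL, record = TRUE) {
  p <- params
  if (!is.null(tau)) { p$tau_act <- tau; p$tau_ref <- tau }
  if (!is.null(kL)) p$kL <- kL
  eq <- eff_equilibrium(p)
  x <- eq[["l2"]]
  l10 <- eq[["l1"]]; l20 <- eq[["l2"]]
  st1 <- 1L; tm1 <- p$tau_act
  st2 <- 0L; tm2 <- 0
  outer_ever <- FALSE; react <- FALSE
  dt <- p$dt
  n_steps <- ceiling((p$tau_act + p$tau_ref) / dt) + 2L
  L <- p$L; k <- p$k; mu <- p$mu
  dLam <- 2 * (p$Lambda1 - p$Lambda2)
  traj <- if (record) matrix(NA_real_, n_steps + 1L, 9L) else NULL
  rec <- function(row, t) {
    l2c <- x; l1c <- 3 * L - 2 * x
    traj[row, ] <<- c(t, l1c, l2c, l10, l20,
                      (l1c - l10) / l10, (l2c - l20) / l20, st1, st2)
  }
  if (record) rec(1L, 0)
  for (s in seq_len(n_steps)) {
    l2c <- x; l1c <- 3 * L - 2 * x
    G1 <- if (st1 == 1L) p$Gamma0 else 0
    G2 <- if (st2 == 1L) p$Gamma0 else 0
    Fx <- 2 * k * (l1c - L) - 2 * k * (l2c - L) + dLam + 2 * G1 * l1c - 2 * G2 * l2c
    if (!is.finite(Fx)) stop("non-finite state in effective-model integration")
    x <- x + dt * Fx / mu
    l10 <- l10 - dt * p$kL * (l10 - l1c)
    l20 <- l20 - dt * p$kL * (l20 - l2c)
    l2c <- x; l1c <- 3 * L - 2 * x
    e1 <- (l1c - l10) / l10
    e2 <- (l2c - l20) / l20
    # state updates from the pre-step state, as in the tissue model
    if (st1 == 1L) { tm1 <- tm1 - dt; if (tm1 <= 0) { st1 <- 2L; tm1 <- p$tau_ref } }
    else if (st1 == 2L) { tm1 <- tm1 - dt; if (tm1 <= 0) st1 <- 0L }
    else if (e1 >= p$eps_on) { st1 <- 1L; tm1 <- p$tau_act; react <- TRUE }
    if (st2 == 1L) { tm2 <- tm2 - dt; if (tm2 <= 0) { st2 <- 2L; tm2 <- p$tau_ref } }
    else if (st2 == 2L) { tm2 <- tm2 - dt; if (tm2 <= 0) st2 <- 0L }
    else if (e2 >= p$eps_on) { st2 <- 1L; tm2 <- p$tau_act; outer_ever <- TRUE }
    if (record) rec(s + 1L, s * dt)
  }
  label <- if (!outer_ever) "no_propagation" else if (react) "reactivation" else "pulse"
  out <- list(label = label)
  if (record) {
    colnames(traj) <- c("time", "l1", "l2", "l1_rest", "l2_rest",
                        "eps1", "eps2", "state1", "state2")
    out$trajectory <- as.data.frame(traj)
  }
  structure(out, class = "eff_outcome")
}

#' Closed-form propagation threshold
#'
#' Without rest-length remodeling, a centrally activated junction propagates
#' activity to its neighbors only if the activation period exceeds
#' \deqn{\tau_p = \frac{1}{2(3 + 2\Gamma_0)}
#'   \ln\frac{\Gamma_0}{\Gamma_0 - (3 + 2\Gamma_0)\,\varepsilon_{on}},}
#' the time at which the outer-junction strain
#' \eqn{[\Gamma_0/(3+2\Gamma_0)](1 - e^{-2(3+2\Gamma_0)t})} first reaches the
#' threshold. Returns `Inf` when
#' \eqn{\varepsilon_{on} \ge \Gamma_0/(3+2\Gamma_0)} (no propagation at any
#' activation period) and 0 when `eps_on` is 0 (activity always propagates).
#'
#' @param Gamma0 active contractility (> 0).
#' @param eps_on activation strain threshold (>= 0).
#' @return The threshold activation period (possibly `Inf`).
#' @export
tau_p <- function(Gamma0, eps_on) {
  if (any(Gamma0 <= 0) || any(eps_on < 0)) stop("Gamma0 must be > 0 and eps_on >= 0")
  c0 <- 3 + 2 * Gamma0
  ifelse(eps_on >= Gamma0 / c0, Inf, log(Gamma0 / (Gamma0 - c0 * eps_on)) / (2 * c0))
}

#' Coefficients of the reactivation inequality
#'
#' For `kL = 0` the central junction re-activates at the end of its
#' refractory period iff \eqn{A e^{-6\tau} - B e^{-6(2+\Gamma_0)\tau} >
#' \varepsilon_{on}}, with
#' \deqn{A = \frac{2\Gamma_0}{3+\Gamma_0}\left(1 - e^{-2(3+\Gamma_0)\tau_p}\right) e^{6\tau_p},\qquad
#'       B = \frac{2\Gamma_0}{3+2\Gamma_0}\left(1 - e^{-2(3+2\Gamma_0)\tau_p}\right) e^{2(3+2\Gamma_0)\tau_p}.}
#' Both vanish when `eps_on = 0` (so only pulse propagation remains) and are
#' undefined when propagation is impossible (`tau_p` infinite).
#'
#' @inheritParams tau_p
#' @return A list with components `A` and `B`.
#' @export
reactivation_coefficients <- function(Gamma0, eps_on) {
  tp <- tau_p(Gamma0, eps_on)
  if (any(!is.finite(tp)))
    stop("tau_p is infinite: no propagation, reactivation coefficients undefined")
  A <- 2 * Gamma0 / (3 + Gamma0) * (1 - exp(-2 * (3 + Gamma0) * tp)) * exp(6 * tp)
  B <- 2 * Gamma0 / (3 + 2 * Gamma0) * (1 - exp(-2 * (3 + 2 * Gamma0) * tp)) *
    exp(2 * (3 + 2 * Gamma0) * tp)
  list(A = A, B = B)
}

#' Reactivation window of activation periods
#'
#' Solves \eqn{A e^{-6\tau} - B e^{-6(2+\Gamma_0)\tau} - \varepsilon_{on} > 0}
#' for \eqn{\tau > \tau_p} (for \eqn{\Gamma_0 = 1} the left-hand side is the
#' cubic \eqn{A y - B y^3 - \varepsilon_{on}} in \eqn{y = e^{-6\tau}}).
#'
#' @inheritParams tau_p
#' @return Named numeric vector `c(tau1, tau2)`, or `NULL` when no
#'   reactivation window exists (including the no-propagation regime).
#' @export
reactivation_range <- function(Gamma0, eps_on) {
  tp <- tau_p(Gamma0, eps_on)
  if (!is.finite(tp)) return(NULL)
  if (tp == 0) return(NULL)  # eps_on = 0: A = B = 0, inequality never holds
  ab <- reactivation_coefficients(Gamma0, eps_on)
  f <- function(tau) ab$A * exp(-6 * tau) - ab$B * exp(-6 * (2 + Gamma0) * tau) - eps_on
  taus <- seq(tp, tp + 5, by = 1e-4)
  v <- f(taus)
  pos <- which(v > 0)
  if (!length(pos)) return(NULL)
  i1 <- pos[1L]; i2 <- pos[length(pos)]
  tau1 <- if (i1 == 1L) tp else
    stats::uniroot(f, c(taus[i1 - 1L], taus[i1]), tol = 1e-10)$root
  tau2 <- stats::uniroot(f, c(taus[i2], taus[i2] + 1e-4), tol = 1e-10)$root
  c(tau1 = tau1, tau2 = tau2)
}

#' Numeric thresholds of the effective model by bisection
#'
#' Smallest activation period for which the simulated model propagates
#' (`what = "propagation"`: outer junctions activate) or re-activates the
#' central junction (`what = "reactivation"`), at a given remodeling rate.
#' Propagation is bisected directly (the outcome is monotone in `tau`);
#' reactivation occurs on a window, so a coarse upward scan brackets its
#' onset first. Resolution is limited by the integration step through the
#' timer quantization.
#'
#' @param params an `eff_params` object.
#' @param kL remodeling rate.
#' @param what threshold to locate.
#' @param tau_max largest activation period scanned.
#' @param tol bisection tolerance (defaults to the integration step).
#' @return The critical activation period, or `NA` if the outcome never
#'   occurs below `tau_max`.
#' @export
eff_critical_tau <- function(params, kL = 0,
                             what = c("propagation", "reactivation"),
                             tau_max = 1, tol = params$dt) {
  what <- match.arg(what)
  hit <- function(tau) {
    lab <- simulate_effective(params, tau = tau, kL = kL, record = FALSE)$label
    if (what == "propagation") lab != "no_propagation" else lab == "reactivation"
  }
  lo <- tol
  hi <- NA_real_
  for (tau in seq(tol, tau_max, by = max(tol, tau_max / 200))) {
    if (hit(tau)) { hi <- tau; break }
    lo <- tau
  }
  if (is.na(hi)) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (hit(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Phase diagram of the effective model
#'
#' Classifies the outcome of [simulate_effective()] on a grid of activation
#' periods and remodeling rates.
#'
#' @param params an `eff_params` object.
#' @param tau_grid,kL_grid numeric grids.
#' @return A data frame with columns `tau`, `kL`, `label`.
#' @export
effective_phase_diagram <- function(params, tau_grid, kL_grid) {
  g <- expand.grid(tau = tau_grid, kL = kL_grid)
  g$label <- vapply(seq_len(nrow(g)), function(i)
    simulate_effective(params, tau = g$tau[i], kL = g$kL[i], record = FALSE)$label,
    character(1L))
  g
}
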