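#' Excitability parameters
#'
#' Parameters of the three-state junction automaton. A junction is inactive
#' (\eqn{\Gamma = 0}), active (\eqn{\Gamma = \Gamma_0}), or refractory
#' (\eqn{\Gamma = 0}, cannot activate). Inactive junctions activate when
#' their strain reaches `eps_on`; active junctions turn refractory after
#' `tau_act`; refractory junctions turn inactive after `tau_ref`. Durations
#' are in units of the simulation time \eqn{t_0}.
#'
#' @param eps_on activation strain threshold (dimensionless).
#' @param tau_act active-state duration.
#' @param tau_ref refractory duration; defaults to `tau_act`, the case in
#'   which both are referred to jointly as the activation period.
#' @param Gamma0 contractility of an active junction.
#' @return An object of class `excit_params`; `Delta` is the derived ratio
#'   `tau_ref / tau_act`.
#' @export
excit_params <- function(eps_on = 0.1, tau_act = 1, tau_ref = tau_act,
                         Gamma0 = 0.5) {
  if (!is.numeric(eps_on) || length(eps_on) != 1L || !is.finite(eps_on) || eps_on < 0)
    stop("'eps_on' must be a non-negative number")
  if (!is.numeric(tau_act) || length(tau_act) != 1L || !is.finite(tau_act) || tau_act <= 0)
    stop("'tau_act' must be a positive number")
  if (!is.numeric(tau_ref) || length(tau_ref) != 1L || !is.finite(tau_ref) || tau_ref < 0)
    stop("'tau_ref' must be a non-negative number")
  if (!is.numeric(Gamma0) || length(Gamma0) != 1L || !is.finite(Gamma0) || Gamma0 < 0)
    stop("'Gamma0' must be a non-negative number")
  structure(list(eps_on = eps_on, tau_act = tau_act, tau_ref = tau_ref,
                 Gamma0 = Gamma0, Delta = tau_ref / tau_act),
            class = "excit_params")
}

#' Junction strain
#'
#' \eqn{\varepsilon_{ij} = (l_{ij} - l^0_{ij}) / l^0_{ij}}.
#'
#' @param tissue a `tissue` object.
#' @param junction optional junction index; all junctions when omitted.
#' @return Numeric strain(s).
#' @export
junction_strain <- function(tissue, junction = NULL) {
  if (any(tissue$l0 <= 0)) stop("invalid state: non-positive rest length")
  if (is.null(junction)) {
    l <- junction_lengths(tissue)
    return((l - tissue$l0) / tissue$l0)
  }
  g <- junction_geometry(tissue, junction)
  (g$length - tissue$l0[junction]) / tissue$l0[junction]
}

#' Update all junction states by one time step
#'
#' Timers of timed states are decremented by `dt`; active junctions with an
#' expired timer become refractory (timer reset to `tau_ref`, contractility
#' dropped to zero); refractory junctions with an expired timer become
#' inactive; inactive junctions whose strain reaches `eps_on` become active
#' (timer `tau_act`, contractility `Gamma0`). All transitions are computed
#' from the pre-step state and applied simultaneously, so there is no
#' junction-ordering bias, and realized durations are quantized to multiples
#' of `dt`.
#'
#' @param tissue a `tissue` object.
#' @param params an `excit_params` object.
#' @param dt time step.
#' @return The updated `tissue`.
#' @export
update_states <- function(tissue, params, dt) {
  st <- tissue$state
  tm <- tissue$timer
  eps <- junction_strain(tissue)
  timed <- st != 0L
  tm[timed] <- tm[timed] - dt
  to_ref <- st == 1L & tm <= 0
  to_ina <- st == 2L & tm <= 0
  to_act <- st == 0L & eps >= params$eps_on
  st[to_ref] <- 2L; tm[to_ref] <- params$tau_ref
  st[to_ina] <- 0L; tm[to_ina] <- 0
  st[to_act] <- 1L; tm[to_act] <- params$tau_act
  tissue$state <- st
  tissue$timer <- tm
  tissue$gamma <- ifelse(st == 1L, params$Gamma0, 0)
  tissue
}

#' Seed an initial activation pattern
#'
#' Starting from an equilibrated, fully inactive tissue, activates either a
#' single junction, a partial row of junctions, or a partial row with the
#' adjacent junction layer underneath set refractory (the initial condition
#' that breaks circular symmetry and can nucleate spiral pairs).
#'
#' @param tissue an equilibrated `tissue` with all junctions inactive.
#' @param mode one of `"single"`, `"row"`, `"row_plus_refractory"`.
#' @param selector for `"single"`: a junction index, or `NULL` to pick the
#'   junction nearest the box center. For the row modes: either a list with
#'   `y` (band center) and `xlim` (length-2 x-range for junction midpoints),
#'   or a list with `junctions` giving explicit indices.
#' @param params an `excit_params` object (supplies `Gamma0` and the timers).
#' @return The seeded `tissue`.
#' @export
seed_activation <- function(tissue, mode = c("single", "row", "row_plus_refractory"),
                            selector = NULL, params = excit_params()) {
  mode <- match.arg(mode)
  if (any(tissue$state != 0L))
    stop("seed_activation expects a fully inactive tissue")
  mids <- junction_midpoints(tissue)
  if (mode == "single") {
    j <- if (is.null(selector)) {
      ctr <- tissue$box / 2
      d <- min_image(sweep(mids, 2L, ctr), tissue$box)
      which.min(d[, 1L]^2 + d[, 2L]^2)
    } else as.integer(selector)
    if (length(j) != 1L || is.na(j) || j < 1L || j > n_junctions(tissue))
      stop("selector names a nonexistent junction")
    tissue$state[j] <- 1L
    tissue$timer[j] <- params$tau_act
    tissue$gamma[j] <- params$Gamma0
    return(tissue)
  }
  row_j <- row_junctions(tissue, selector, mids)
  tissue$state[row_j] <- 1L
  tissue$timer[row_j] <- params$tau_act
  tissue$gamma[row_j] <- params$Gamma0
  if (mode == "row_plus_refractory") {
    rv <- unique(c(tissue$ja[row_j], tissue$jb[row_j]))
    touch <- which((tissue$ja %in% rv | tissue$jb %in% rv) &
                     !(seq_len(n_junctions(tissue)) %in% row_j))
    y0 <- mean(band_rel_y(mids[row_j, 2L, drop = TRUE], tissue$box))
    below <- touch[band_rel_y(mids[touch, 2L], tissue$box, ref = y0) < 0]
    tissue$state[below] <- 2L
    tissue$timer[below] <- params$tau_ref
  }
  tissue
}

junction_midpoints <- function(tissue) {
  d <- junction_vectors(tissue)
  wrap_positions(tissue$pos[tissue$ja, , drop = FALSE] + d / 2, tissue$box)
}

# signed y-offset on the periodic axis (minimum image about ref)
band_rel_y <- function(y, box, ref = NULL) {
  if (is.null(ref)) return(y)
  dy <- y - ref
  dy - box[[2L]] * round(dy / box[[2L]])
}

# junctions forming a quasi-horizontal row: non-vertical junctions whose
# midpoints fall in the band selector$y +/- half an edge length, restricted
# to selector$xlim
row_junctions <- function(tissue, selector, mids) {
  if (is.list(selector) && !is.null(selector$junctions)) {
    j <- as.integer(selector$junctions)
    if (any(is.na(j)) || any(j < 1L) || any(j > n_junctions(tissue)))
      stop("selector names a nonexistent junction")
    return(j)
  }
  if (!is.list(selector) || is.null(selector$y))
    stop("row selector must be a list with 'y' (and optionally 'xlim') or 'junctions'")
  d <- junction_vectors(tissue)
  l <- sqrt(d[, 1L]^2 + d[, 2L]^2)
  a <- stats::median(l)
  nonvert <- abs(d[, 1L]) > 0.2 * l
  dy <- band_rel_y(mids[, 2L], tissue$box, ref = selector$y)
  inband <- abs(dy) <= 0.45 * a
  inx <- if (is.null(selector$xlim)) TRUE else
    mids[, 1L] >= selector$xlim[[1L]] & mids[, 1L] <= selector$xlim[[2L]]
  j <- which(nonvert & inband & inx)
  if (!length(j)) stop("row selector matches no junctions")
  j
}
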