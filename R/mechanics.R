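#' Mechanical parameters
#'
#' Constants of the vertex-model energy and dynamics, in simulation units
#' (force scale \eqn{K A_0^{3/2}}, length scale \eqn{\sqrt{A_0}}, time scale
#' \eqn{t_0 = \mu / (0.636 K \sqrt{A_0}) = 1} with the defaults). Defaults are
#' the model's standard parameter set.
#'
#' @param K area elastic modulus.
#' @param A0 preferred cell area.
#' @param Lambda line tension along junctions.
#' @param mu vertex friction coefficient (0.636 makes the time unit 1).
#' @param kL rest-length remodeling rate (units \eqn{1/t_0}).
#' @param lT1 junction length threshold below which a T1 swap is performed.
#' @param dt forward-Euler integration time step.
#' @param t_end default total simulated time.
#' @return An object of class `mech_params`.
#' @export
mech_params <- function(K = 1, A0 = 1, Lambda = 0.1, mu = 0.636,
                        kL = 1, lT1 = 0.01, dt = 0.01, t_end = 20) {
  p <- list(K = K, A0 = A0, Lambda = Lambda, mu = mu,
            kL = kL, lT1 = lT1, dt = dt, t_end = t_end)
  for (nm in c("K", "A0", "mu", "lT1", "dt", "t_end"))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop(sprintf("'%s' must be a positive number", nm))
  for (nm in c("Lambda", "kL"))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) || p[[nm]] < 0)
      stop(sprintf("'%s' must be a non-negative number", nm))
  structure(p, class = "mech_params")
}

#' Total mechanical energy
#'
#' \deqn{H = \frac{K}{2}\sum_\alpha (A_\alpha - A_0)^2 + \Lambda \sum_{\langle i,j\rangle} l_{ij}.}
#' The active contractile term enters the dynamics as a force, not as part of
#' the energy.
#'
#' @param tissue a `tissue` object.
#' @param params a `mech_params` object.
#' @return Scalar energy.
#' @export
total_energy <- function(tissue, params) {
  ar <- cell_areas(tissue)
  params$K / 2 * sum((ar - params$A0)^2) +
    params$Lambda * sum(junction_lengths(tissue))
}

# scatter-add 2-column values into an n x 2 matrix by index
acc2 <- function(idx, vals, n) {
  out <- matrix(0, n, 2L)
  r <- rowsum(vals, idx, reorder = TRUE)
  out[as.integer(rownames(r)), ] <- r
  out
}

# force kernel; returns per-vertex forces plus the junction lengths and cell
# areas used (so callers avoid recomputation)
.forces <- function(tissue, params) {
  pos <- tissue$pos
  box <- tissue$box
  ca <- tissue$cache
  # per-loop-entry minimum-image displacement v -> next vertex
  dx <- pos[ca$vn, 1L] - pos[ca$v, 1L]
  dy <- pos[ca$vn, 2L] - pos[ca$v, 2L]
  dx <- dx - box[[1L]] * round(dx / box[[1L]])
  dy <- dy - box[[2L]] * round(dy / box[[2L]])
  # unwrapped relative loop coordinates -> shoelace areas
  csx <- cumsum(dx); csy <- cumsum(dy)
  n <- length(dx)
  sx <- c(0, csx[-n]); sy <- c(0, csy[-n])
  rx <- sx - rep.int(sx[ca$starts], ca$lens)
  ry <- sy - rep.int(sy[ca$starts], ca$lens)
  cross <- rx * (ry + dy) - (rx + dx) * ry
  areas <- as.vector(rowsum(cross, ca$cid, reorder = TRUE)) / 2
  # area elasticity: -K (A - A0) dA/dr with dA/dx_v = (y_next - y_prev)/2
  coefA <- -params$K * (areas[ca$cid] - params$A0)
  fax <- coefA * 0.5 * (dy + dy[ca$pe])
  fay <- coefA * -0.5 * (dx + dx[ca$pe])
  # junction tension (Lambda) and active contractility (Gamma l), per junction
  djx <- pos[tissue$jb, 1L] - pos[tissue$ja, 1L]
  djy <- pos[tissue$jb, 2L] - pos[tissue$ja, 2L]
  djx <- djx - box[[1L]] * round(djx / box[[1L]])
  djy <- djy - box[[2L]] * round(djy / box[[2L]])
  l <- sqrt(djx^2 + djy^2)
  coefJ <- params$Lambda / l + tissue$gamma
  fjx <- coefJ * djx
  fjy <- coefJ * djy
  F <- acc2(c(ca$v, tissue$ja, tissue$jb),
            cbind(c(fax, fjx, -fjx), c(fay, fjy, -fjy)),
            nrow(pos))
  list(F = F, lengths = l, areas = areas)
}

#' Net force on every vertex
#'
#' Sum of the energy gradient \eqn{-\partial H/\partial r_i} and the active
#' force \eqn{F^{act}_i = -\sum_{\langle i,j\rangle} \Gamma_{ij} l_{ij}
#' (\partial l_{ij}/\partial r_i)}; the active contribution of a junction on
#' each endpoint has magnitude \eqn{\Gamma_{ij} l_{ij}} pulling the endpoints
#' together.
#'
#' @param tissue a `tissue` object.
#' @param params a `mech_params` object.
#' @return A vertices x 2 matrix of forces.
#' @export
net_vertex_forces <- function(tissue, params) {
  .forces(tissue, params)$F
}

#' Advance the tissue by one or more Euler steps
#'
#' Each step performs, in fixed order: force evaluation; forward-Euler update
#' of all vertex positions \eqn{r_i \leftarrow r_i + (\Delta t/\mu) F_i};
#' forward-Euler rest-length remodeling
#' \eqn{l^0_{ij} \leftarrow l^0_{ij} - \Delta t\, k_L (l^0_{ij} - l_{ij})};
#' junction state updates and strain-triggered activations (when `excit` is
#' supplied); T1 checks. Positions are re-reduced into the box.
#'
#' @param tissue a `tissue` object.
#' @param params a `mech_params` object.
#' @param excit optional `excit_params`; omit to integrate passive mechanics
#'   only.
#' @param steps number of steps.
#' @param t1 perform T1 transitions (default TRUE).
#' @return The advanced `tissue`.
#' @export
step_tissue <- function(tissue, params, excit = NULL, steps = 1L, t1 = TRUE) {
  h <- params$dt / params$mu
  for (s in seq_len(steps)) {
    fr <- .forces(tissue, params)
    if (!all(is.finite(fr$F)))
      stop("non-finite force encountered; the integration has become unstable")
    tissue$pos <- wrap_positions(tissue$pos + h * fr$F, tissue$box)
    tissue$l0 <- tissue$l0 - params$dt * params$kL * (tissue$l0 - fr$lengths)
    if (!is.null(excit)) tissue <- update_states(tissue, excit, params$dt)
    if (t1) tissue <- t1_transitions(tissue, params)
  }
  tissue
}

#' Perform all pending T1 transitions
#'
#' Every junction shorter than `lT1` undergoes a neighbor exchange: the edge
#' collapses to a transient 4-fold vertex which is instantly resolved into
#' the transverse connectivity. The new junction is placed perpendicular to
#' the old one, centered at its midpoint, with length and rest length
#' `1.5 * lT1`, in the inactive state with zero contractility. A swap that
#' would create a 2-sided cell is skipped (counted in `tissue$stats`).
#'
#' @param tissue a `tissue` object.
#' @param params a `mech_params` object.
#' @return The updated `tissue`; `tissue$stats$t1_count` accumulates swaps.
#' @export
t1_transitions <- function(tissue, params) {
  l <- junction_lengths(tissue)
  shorts <- which(l < params$lT1)
  if (!length(shorts)) return(tissue)
  for (j in shorts) {
    if (junction_geometry(tissue, j)$length >= params$lT1) next
    tissue <- t1_swap(tissue, j, params)
  }
  tissue
}

# one T1 edge swap on junction j = (a, b)
t1_swap <- function(tissue, j, params) {
  a <- tissue$ja[j]; b <- tissue$jb[j]
  ca <- tissue$cache
  cells_a <- unique(ca$cid[ca$v == a])
  cells_b <- unique(ca$cid[ca$v == b])
  PQ <- intersect(cells_a, cells_b)
  R <- setdiff(cells_a, PQ)
  S <- setdiff(cells_b, PQ)
  if (length(PQ) != 2L || length(R) != 1L || length(S) != 1L || R == S) {
    tissue$stats$t1_skipped <- tissue$stats$t1_skipped + 1L
    return(tissue)
  }
  P <- PQ[1L]; Q <- PQ[2L]
  if (length(tissue$cells[[P]]) <= 3L || length(tissue$cells[[Q]]) <= 3L) {
    tissue$stats$t1_skipped <- tissue$stats$t1_skipped + 1L
    return(tissue)
  }
  loop_nbrs <- function(cell, v) {
    lp <- tissue$cells[[cell]]
    i <- match(v, lp)
    m <- length(lp)
    c(lp[if (i == 1L) m else i - 1L], lp[if (i == m) 1L else i + 1L])
  }
  u  <- setdiff(loop_nbrs(P, a), b)   # a's P-side neighbor (edge stays on a)
  w1 <- setdiff(loop_nbrs(P, b), a)   # b's P-side neighbor (edge moves to a)
  u2 <- setdiff(loop_nbrs(Q, a), b)   # a's Q-side neighbor (edge moves to b)
  w2 <- setdiff(loop_nbrs(Q, b), a)
  if (length(u) != 1L || length(w1) != 1L || length(u2) != 1L || length(w2) != 1L) {
    tissue$stats$t1_skipped <- tissue$stats$t1_skipped + 1L
    return(tissue)
  }
  # geometry: rotate the edge 90 degrees about its midpoint; a stays on P's side
  pa <- tissue$pos[a, ]
  d <- as.numeric(min_image(rbind(tissue$pos[b, ] - pa), tissue$box))
  m <- pa + d / 2
  nrm <- c(-d[2L], d[1L])
  nrm <- nrm / sqrt(sum(nrm^2))
  lpP <- tissue$cells[[P]]
  relP <- loop_rel_coords(tissue, P)                       # rel to first loop vertex
  centP <- colMeans(relP) - relP[match(a, lpP), ] - d / 2  # P centroid rel to midpoint
  s <- if (sum(centP * nrm) >= 0) 1 else -1
  half <- 0.75 * params$lT1
  tissue$pos[a, ] <- (m + s * half * nrm)
  tissue$pos[b, ] <- (m - s * half * nrm)
  tissue$pos <- wrap_positions(tissue$pos, tissue$box)
  # rewire junction endpoints: (a,u2) -> (b,u2), (b,w1) -> (a,w1)
  swap_end <- function(v1, v2, vnew) {
    hit <- which((tissue$ja == v1 & tissue$jb == v2) | (tissue$ja == v2 & tissue$jb == v1))
    stopifnot(length(hit) == 1L)
    if (tissue$ja[hit] == v1) tissue$ja[hit] <<- vnew else tissue$jb[hit] <<- vnew
  }
  swap_end(a, u2, b)
  swap_end(b, w1, a)
  # loops: P drops b, Q drops a, R gains b next to a (u2 side), S gains a (w1 side)
  drop_v <- function(cell, v) {
    lp <- tissue$cells[[cell]]
    tissue$cells[[cell]] <<- lp[lp != v]
  }
  insert_between <- function(cell, v1, v2, vnew) {
    lp <- tissue$cells[[cell]]
    m <- length(lp)
    i <- match(v1, lp)
    ip <- if (i == 1L) m else i - 1L
    inx <- if (i == m) 1L else i + 1L
    pos_after <- if (lp[inx] == v2) i else if (lp[ip] == v2) ip else stop("T1: loop inconsistency")
    tissue$cells[[cell]] <<- append(lp, vnew, after = pos_after)
  }
  drop_v(P, b)
  drop_v(Q, a)
  insert_between(R, a, u2, b)
  insert_between(S, b, w1, a)
  # the swapped junction: fresh, inactive, strain-free
  tissue$l0[j] <- 1.5 * params$lT1
  tissue$state[j] <- 0L
  tissue$timer[j] <- 0
  tissue$gamma[j] <- 0
  tissue$stats$t1_count <- tissue$stats$t1_count + 1L
  tissue$cache <- build_cell_cache(tissue$cells)
  tissue
}

# unwrapped coordinates of one cell's loop, relative to its first vertex
loop_rel_coords <- function(tissue, cell) {
  lp <- tissue$cells[[cell]]
  p <- tissue$pos[lp, , drop = FALSE]
  d <- min_image(p[c(2:nrow(p), 1L), , drop = FALSE] - p, tissue$box)
  rbind(c(0, 0), apply(d[-nrow(d), , drop = FALSE], 2L, cumsum))
}

#' Relax a tissue to mechanical equilibrium
#'
#' Gradient-flow relaxation (no excitability, contractilities forced to zero)
#' until the maximum vertex force falls below `tol`; rest lengths are then
#' reset to the current lengths so every junction is strain-free, and all
#' junctions are set inactive.
#'
#' @param tissue a `tissue` object.
#' @param params a `mech_params` object; `dt_relax` overrides its time step
#'   during relaxation.
#' @param tol maximum residual force allowed.
#' @param max_steps step budget.
#' @param dt_relax relaxation time step (larger than the dynamical default is
#'   safe for pure gradient flow).
#' @return The equilibrated `tissue`.
#' @export
equilibrate <- function(tissue, params, tol = 1e-6, max_steps = 200000L,
                        dt_relax = 0.05) {
  p <- params
  p$dt <- dt_relax
  p$kL <- 0
  tissue$gamma[] <- 0
  check_every <- 100L
  fmax <- max(abs(net_vertex_forces(tissue, p)))
  done <- fmax < tol
  while (!done) {
    tissue <- step_tissue(tissue, p, excit = NULL, steps = check_every, t1 = TRUE)
    fmax <- max(abs(net_vertex_forces(tissue, p)))
    done <- fmax < tol
    max_steps <- max_steps - check_every
    if (max_steps <= 0L) break
  }
  if (!done)
    stop(sprintf("equilibration did not converge: residual max force %.3g after %d steps",
                 fmax, max_steps))
  tissue$l0 <- junction_lengths(tissue)
  tissue$state[] <- 0L
  tissue$timer[] <- 0
  tissue$gamma[] <- 0
  tissue
}
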