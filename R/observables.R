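#' Junction state fractions
#'
#' @param tissue a `tissue` object.
#' @return Named numeric vector `c(inactive, active, refractory)` summing to 1.
#' @export
state_fractions <- function(tissue) {
  n <- n_junctions(tissue)
  c(inactive = sum(tissue$state == 0L),
    active = sum(tissue$state == 1L),
    refractory = sum(tissue$state == 2L)) / n
}

#' Total junction strain
#'
#' \eqn{\sum_{\langle i,j\rangle} \varepsilon_{ij}} over all junctions. Zero
#' in an equilibrated tissue; a traveling pulse produces a positive peak,
#' then a negative peak, and a return to zero, whereas a sustained wave
#' settles to a fluctuating plateau.
#'
#' @param tissue a `tissue` object.
#' @return Scalar strain sum.
#' @export
total_strain <- function(tissue) sum(junction_strain(tissue))

#' Run a tissue simulation and record observables
#'
#' Steps the tissue with [step_tissue()] from t = 0 to `t_end`, sampling
#' state fractions and total strain every `record_interval`, and optionally
#' storing tissue snapshots at given times. The resulting record is
#' classified with [classify_outcome()].
#'
#' @param tissue a seeded `tissue`.
#' @param mech a `mech_params` object (supplies `dt`; `t_end` defaults from
#'   it).
#' @param excit an `excit_params` object.
#' @param t_end total simulated time.
#' @param record_interval sampling interval for the time series.
#' @param snapshot_times times (rounded to whole steps) at which deep copies
#'   of the tissue are stored in the result.
#' @param theta_prop propagation threshold passed to [classify_outcome()].
#' @return An `outcome_record`: list with `times`, `f_inactive`, `f_active`,
#'   `f_refractory`, `total_strain`, `max_active_fraction`,
#'   `final_active_fraction`, `label`, `snapshots`, `final_tissue`.
#' @export
run_simulation <- function(tissue, mech, excit, t_end = mech$t_end,
                           record_interval = 0.1, snapshot_times = NULL,
                           theta_prop = 0.1) {
  dt <- mech$dt
  n_steps <- ceiling(t_end / dt)
  every <- max(1L, round(record_interval / dt))
  snap_steps <- if (is.null(snapshot_times)) integer(0) else
    pmin(pmax(round(snapshot_times / dt), 0L), n_steps)
  n_rec <- length(seq(0L, n_steps, by = every))
  times <- numeric(n_rec)
  fr <- matrix(NA_real_, n_rec, 3L)
  ts <- numeric(n_rec)
  snapshots <- list()
  r <- 1L
  record_now <- function(s) {
    times[r] <<- s * dt
    fr[r, ] <<- state_fractions(tissue)
    ts[r] <<- total_strain(tissue)
    r <<- r + 1L
  }
  record_now(0L)
  if (0L %in% snap_steps) snapshots[["0"]] <- tissue
  for (s in seq_len(n_steps)) {
    tissue <- step_tissue(tissue, mech, excit, steps = 1L)
    if (s %% every == 0L) record_now(s)
    if (s %in% snap_steps) snapshots[[as.character(s)]] <- tissue
  }
  rec <- structure(list(
    times = times[seq_len(r - 1L)],
    f_inactive = fr[seq_len(r - 1L), 1L],
    f_active = fr[seq_len(r - 1L), 2L],
    f_refractory = fr[seq_len(r - 1L), 3L],
    total_strain = ts[seq_len(r - 1L)],
    snapshots = snapshots,
    final_tissue = tissue
  ), class = "outcome_record")
  rec$max_active_fraction <- max(rec$f_active)
  rec$final_active_fraction <- final_active_fraction(rec)
  rec$label <- classify_outcome(rec, theta_prop)
  rec
}

# mean active fraction over the last 10% of the run (robust to wave phase)
final_active_fraction <- function(record) {
  t1 <- max(record$times)
  mean(record$f_active[record$times >= 0.9 * t1])
}

#' Classify a simulation outcome
#'
#' `"quiescent"` if the maximum active junction fraction never exceeds
#' `theta_prop`; otherwise `"wave"` if activity persists (mean active
#' fraction over the last 10% of the run is positive), else `"pulse"`.
#'
#' @param record an `outcome_record`.
#' @param theta_prop active-fraction threshold separating propagation from
#'   quiescence (default 0.1).
#' @return One of `"quiescent"`, `"pulse"`, `"wave"`.
#' @export
classify_outcome <- function(record, theta_prop = 0.1) {
  ma <- if (!is.null(record$max_active_fraction)) record$max_active_fraction
        else max(record$f_active)
  if (ma <= theta_prop) return("quiescent")
  fin <- if (!is.null(record$final_active_fraction)) record$final_active_fraction
         else final_active_fraction(record)
  if (fin > 0) "wave" else "pulse"
}

#' Sweep the (tau, kL) phase diagram
#'
#' Runs a fresh simulation at every grid point: the factory builds (or
#' returns a copy of) the equilibrated tissue, the same seeding is applied,
#' and the outcome is recorded. A run that fails is recorded as label
#' `"failed"` and the sweep continues.
#'
#' @param tissue_factory function of no arguments returning an equilibrated,
#'   inactive `tissue` (called once per grid point).
#' @param tau_grid,kL_grid numeric grids of activation periods and
#'   remodeling rates.
#' @param mech a `mech_params` object (its `kL` is overridden per point).
#' @param excit an `excit_params` object (its timers are overridden per
#'   point, with `tau_ref = tau_act = tau`).
#' @param seed_mode,seed_selector passed to [seed_activation()].
#' @param t_end,theta_prop passed to [run_simulation()].
#' @return Data frame with columns `tau`, `kL`, `max_active_fraction`,
#'   `final_active_fraction`, `label`.
#' @export
sweep_phase_diagram <- function(tissue_factory, tau_grid, kL_grid, mech, excit,
                                seed_mode = "single", seed_selector = NULL,
                                t_end = mech$t_end, theta_prop = 0.1) {
  g <- expand.grid(tau = tau_grid, kL = kL_grid)
  g$max_active_fraction <- NA_real_
  g$final_active_fraction <- NA_real_
  g$label <- NA_character_
  for (i in seq_len(nrow(g))) {
    res <- try({
      m <- mech; m$kL <- g$kL[i]
      e <- excit; e$tau_act <- g$tau[i]; e$tau_ref <- g$tau[i]; e$Delta <- 1
      tis <- seed_activation(tissue_factory(), seed_mode, seed_selector, e)
      run_simulation(tis, m, e, t_end = t_end, theta_prop = theta_prop)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      g$label[i] <- "failed"
    } else {
      g$max_active_fraction[i] <- res$max_active_fraction
      g$final_active_fraction[i] <- res$final_active_fraction
      g$label[i] <- res$label
    }
  }
  g
}

#' Critical remodeling rate for propagation
#'
#' Bisects `kL` for the boundary at which the maximum active junction
#' fraction crosses `theta_prop`, for a fixed activation period and a fixed
#' seeded junction. Deterministic given the tissue and junction.
#'
#' @param tissue an equilibrated, inactive `tissue`.
#' @param seed_junction index of the junction to activate.
#' @param tau activation period (`tau_act = tau_ref = tau`).
#' @param mech,excit parameter objects.
#' @param kL_range search interval.
#' @param iters bisection iterations.
#' @param t_end run horizon per evaluation.
#' @param theta_prop propagation threshold.
#' @return The critical rate, `0` if there is no propagation even at the
#'   lower end of `kL_range`, or `kL_range[2]` if propagation persists at the
#'   upper end.
#' @export
critical_kL <- function(tissue, seed_junction, tau, mech, excit,
                        kL_range = c(0, 1.5), iters = 5L, t_end = mech$t_end,
                        theta_prop = 0.1) {
  e <- excit; e$tau_act <- tau; e$tau_ref <- tau; e$Delta <- 1
  propagates <- function(kL) {
    m <- mech; m$kL <- kL
    tis <- seed_activation(tissue, "single", seed_junction, e)
    run_simulation(tis, m, e, t_end = t_end, theta_prop = theta_prop)$max_active_fraction >
      theta_prop
  }
  lo <- kL_range[[1L]]; hi <- kL_range[[2L]]
  if (!propagates(lo)) return(0)
  if (propagates(hi)) return(hi)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (propagates(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Measure the wavelength of a radial wave pattern
#'
#' For each snapshot, computes the radial activity profile -- the mean
#' active-junction indicator binned by minimum-image distance of junction
#' midpoints from `origin` (bin width defaulting to the median junction
#' length) -- segments it into rings (contiguous runs of bins whose active
#' fraction reaches `ring_threshold`, which separates the broad active bands
#' from the low-activity dips between them), and takes the mean spacing
#' between consecutive ring centers; the result is averaged over snapshots.
#' Radii beyond half the smaller box side are discarded to avoid wrap
#' artifacts, so snapshots should be taken while the pattern still expands.
#'
#' @param snapshots list of `tissue` objects from a wave run.
#' @param origin length-2 point the wave emanates from.
#' @param bin_width radial bin width; default the median junction length.
#' @param ring_threshold active fraction above which a bin belongs to a ring.
#' @return Mean ring spacing, or `NA` (with a diagnostic attribute) when
#'   fewer than two rings are found in every snapshot.
#' @export
measure_wavelength <- function(snapshots, origin, bin_width = NULL,
                               ring_threshold = 0.5) {
  if (inherits(snapshots, "tissue")) snapshots <- list(snapshots)
  if (!length(snapshots)) stop("no snapshots supplied")
  if (is.null(bin_width)) bin_width <- stats::median(junction_lengths(snapshots[[1L]]))
  per_snap <- vapply(snapshots, function(tis) {
    rmax <- min(tis$box) / 2
    mids <- junction_midpoints(tis)
    d <- min_image(sweep(mids, 2L, origin), tis$box)
    r <- sqrt(d[, 1L]^2 + d[, 2L]^2)
    keep <- r <= rmax
    act <- tis$state[keep] == 1L
    bins <- floor(r[keep] / bin_width)
    nb <- max(bins) + 1L
    frac <- tabulate(bins[act] + 1L, nb) / pmax(tabulate(bins + 1L, nb), 1L)
    in_ring <- frac >= ring_threshold
    runs <- rle(in_ring)
    ends <- cumsum(runs$lengths)
    on <- which(runs$values)
    if (length(on) < 2L) return(NA_real_)
    centers <- (ends[on] - runs$lengths[on] / 2) * bin_width
    mean(diff(centers))
  }, numeric(1L))
  ok <- is.finite(per_snap)
  if (!any(ok)) {
    out <- NA_real_
    attr(out, "diagnostic") <- "fewer than 2 activity rings detected in every snapshot"
    return(out)
  }
  mean(per_snap[ok])
}

#' @export
print.outcome_record <- function(x, ...) {
  cat(sprintf("Simulation record: %d samples to t = %.2f, label '%s'\n",
              length(x$times), max(x$times), x$label))
  cat(sprintf("max active fraction %.4f, final active fraction %.4f\n",
              x$max_active_fraction, x$final_active_fraction))
  invisible(x)
}

#' Coerce a simulation record to a data frame
#'
#' @param x an `outcome_record`.
#' @param ... unused.
#' @return Data frame with columns time, f_inactive, f_active, f_refractory,
#'   total_strain.
#' @export
as.data.frame.outcome_record <- function(x, ...) {
  data.frame(time = x$times, f_inactive = x$f_inactive, f_active = x$f_active,
             f_refractory = x$f_refractory, total_strain = x$total_strain)
}
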