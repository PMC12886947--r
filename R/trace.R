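# Particle pathline advection through the time-resolved velocity field, for
# vortex visualization support.

# Velocity (mm/s) at world points `pts` (n x 3, mm) and time `t` (s), with
# trilinear interpolation in space and linear interpolation in time, cyclic
# over the cardiac cycle.
velocity_at <- function(ds, pts, t) {
  N <- ds$n_phases
  dt <- ds$cycle_duration / N
  tm <- t %% ds$cycle_duration
  k0 <- floor(tm / dt)
  f <- (tm - k0 * dt) / dt
  k0 <- (as.integer(k0) %% N) + 1L
  k1 <- (k0 %% N) + 1L
  out <- matrix(0, nrow(pts), 3)
  for (c in 1:3) {
    v0 <- interp_trilinear(ds$velocity[k0, , , , c], ds$spacing, ds$origin, pts)
    v1 <- interp_trilinear(ds$velocity[k1, , , , c], ds$spacing, ds$origin, pts)
    out[, c] <- (1 - f) * v0 + f * v1
  }
  out * 1e3    # m/s -> mm/s
}

#' Advect particle pathlines through the time-resolved field
#'
#' Classical 4th-order Runge-Kutta integration with trilinear spatial and
#' linear temporal interpolation, cyclic in time. Particles are emitted at
#' `t0` from the given world positions and integrated for
#' `n_steps = trail * steps_per_phase` steps of `dt = cycle_duration /
#' (n_phases * steps_per_phase)`; a particle terminates (and is flagged) when
#' it leaves the labeled region.
#'
#' @param ds a masked `flow_dataset`.
#' @param emitters n x 3 matrix of world emission points (mm), e.g. the lumen
#'   points of a [extract_cross_section()].
#' @param mask optional `mask3d` bounding the flow domain; particles leaving
#'   it terminate.
#' @param label mask label.
#' @param t0 emission time, s.
#' @param steps_per_phase integration substeps per cardiac phase (default 4).
#' @param trail trail length in phases retained per particle (default 6).
#' @return a `pathline_set`: list of `particles`, each with `times`,
#'   `positions` (k x 3 mm), `speed` (m/s per point), `terminated` flag.
#' @export
advect <- function(ds, emitters, mask = NULL, label = "LA", t0 = 0,
                   steps_per_phase = 4L, trail = 6L) {
  emitters <- rbind(emitters)
  inmask <- if (is.null(mask)) NULL else label_array(mask, label) * 1
  in_domain <- function(p) {
    if (is.null(inmask)) return(rep(TRUE, nrow(p)))
    interp_trilinear(inmask, ds$spacing, ds$origin, p) >= 0.5
  }
  v0 <- velocity_at(ds, emitters, t0)
  if (all(rowSums(v0^2) == 0))
    warning("zero velocity at all emitters; empty pathline set")
  dt <- ds$cycle_duration / (ds$n_phases * steps_per_phase)
  n_steps <- trail * steps_per_phase
  n <- nrow(emitters)
  alive <- in_domain(emitters) & rowSums(v0^2) > 0
  pos <- emitters
  traj <- vector("list", n)
  for (i in seq_len(n))
    traj[[i]] <- list(times = t0, positions = emitters[i, , drop = FALSE],
                      speed = sqrt(sum(v0[i, ]^2)) / 1e3, terminated = !alive[i])
  t <- t0
  for (s in seq_len(n_steps)) {
    if (!any(alive)) break
    idx <- which(alive)
    p <- pos[idx, , drop = FALSE]
    k1 <- velocity_at(ds, p, t)
    k2 <- velocity_at(ds, p + dt / 2 * k1, t + dt / 2)
    k3 <- velocity_at(ds, p + dt / 2 * k2, t + dt / 2)
    k4 <- velocity_at(ds, p + dt * k3, t + dt)
    pnew <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    ok <- in_domain(pnew)
    t <- t + dt
    vnew <- velocity_at(ds, pnew, t)
    for (m in seq_along(idx)) {
      i <- idx[m]
      if (!ok[m]) {
        traj[[i]]$terminated <- TRUE
        alive[i] <- FALSE
        next
      }
      traj[[i]]$times <- c(traj[[i]]$times, t)
      traj[[i]]$positions <- rbind(traj[[i]]$positions, pnew[m, ])
      traj[[i]]$speed <- c(traj[[i]]$speed, sqrt(sum(vnew[m, ]^2)) / 1e3)
      pos[i, ] <- pnew[m, ]
    }
  }
  # retain at most the trailing `trail * steps_per_phase + 1` samples
  keep <- trail * steps_per_phase + 1L
  for (i in seq_len(n)) {
    k <- nrow(traj[[i]]$positions)
    if (k > keep) {
      sel <- (k - keep + 1L):k
      traj[[i]]$times <- traj[[i]]$times[sel]
      traj[[i]]$positions <- traj[[i]]$positions[sel, , drop = FALSE]
      traj[[i]]$speed <- traj[[i]]$speed[sel]
    }
  }
  structure(list(particles = traj, trail = trail, t0 = t0), class = "pathline_set")
}

#' @export
print.pathline_set <- function(x, ...) {
  term <- sum(vapply(x$particles, `[[`, TRUE, "terminated"))
  cat(sprintf("pathline_set: %d particles (%d terminated), trail %d phases, emitted at t = %.3g s\n",
              length(x$particles), term, x$trail, x$t0))
  invisible(x)
}
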