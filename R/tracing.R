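#' Stokes drag force on a microparticle
#'
#' \deqn{F_f = -6\pi\eta R_p (v_p - v_f)}
#' valid at the low particle Reynolds numbers of micrometer carriers in air.
#'
#' @param v_p particle velocity \[m/s\]: 2-vector or n-by-2 matrix.
#' @param v_f fluid velocity at the particle position \[m/s\], same shape.
#' @param props a [particle_props()].
#' @param viscosity fluid dynamic viscosity \[Pa s\].
#' @return drag force \[N\], same shape as `v_p`.
#' @export
drag_force <- function(v_p, v_f, props, viscosity) {
  -6 * pi * viscosity * props$radius * (v_p - v_f)
}

#' Particle momentum relaxation time
#'
#' The time scale \eqn{\tau = m_p/(6\pi\eta R_p) = 2\rho_p R_p^2/(9\eta)}
#' on which the particle velocity equilibrates to the local flow; about
#' 3.4 ms for 7.5 um magnetite in air, far below the nasal transit time,
#' so the motion is overdamped.  Used for step-size control.
#'
#' @param props a [particle_props()].
#' @param viscosity fluid dynamic viscosity \[Pa s\].
#' @return \eqn{\tau} \[s\].
#' @export
relaxation_time <- function(props, viscosity) {
  2 * props$density * props$radius^2 / (9 * viscosity)
}

# classical RK4 update of (pos, vel) under d(pos)/dt = vel,
# d(vel)/dt = accel(pos, vel); pos/vel are n x 2 matrices
rk4_core <- function(pos, vel, accel, dt) {
  k1x <- vel
  k1v <- accel(pos, vel)
  k2x <- vel + dt / 2 * k1v
  k2v <- accel(pos + dt / 2 * k1x, vel + dt / 2 * k1v)
  k3x <- vel + dt / 2 * k2v
  k3v <- accel(pos + dt / 2 * k2x, vel + dt / 2 * k2v)
  k4x <- vel + dt * k3v
  k4v <- accel(pos + dt * k3x, vel + dt * k3v)
  list(pos = pos + dt / 6 * (k1x + 2 * k2x + 2 * k3x + k4x),
       vel = vel + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v))
}

#' One Runge-Kutta step of the particle equation of motion
#'
#' Fourth-order update of position and velocity under
#' \eqn{m_p \, dv_p/dt = F(x, v_p)}, \eqn{dx/dt = v_p}, with constant
#' particle mass.  Only IN_FLIGHT particles are advanced.
#'
#' @param state a `particle_states` data frame (see [release_line()]).
#' @param force_eval function `(pos, vel, time)` returning the total force
#'   \[N\] as an n-by-2 matrix for n-by-2 position/velocity inputs.
#' @param dt time step \[s\].
#' @param props a [particle_props()] (supplies the mass).
#' @return the updated `particle_states`.
#' @export
step_rk4 <- function(state, force_eval, dt, props) {
  act <- state$status == "IN_FLIGHT"
  if (!any(act)) return(state)
  pos <- cbind(state$y[act], state$z[act])
  vel <- cbind(state$vy[act], state$vz[act])
  t0 <- state$time[act]
  accel <- function(p, v) force_eval(p, v, t0) / props$mass
  st <- rk4_core(pos, vel, accel, dt)
  state$y[act] <- st$pos[, 1]; state$z[act] <- st$pos[, 2]
  state$vy[act] <- st$vel[, 1]; state$vz[act] <- st$vel[, 2]
  state$time[act] <- t0 + dt
  state
}

#' Release specification for a line of particles
#'
#' Particles are released at rest across a horizontal line in the sagittal
#' plane.  When `start`/`end` are not given, the line is anchored to the
#' inlet centerline: centered on the inlet segment's midpoint at height
#' `dz` above it, with nominal length `dy` clipped to the fluid channel
#' (one grid cell of wall clearance); the nostril of the surrogate is
#' narrower than the anatomical nostril length the nominal 1.5 cm refers
#' to, so the clip is normally active.
#'
#' @param count number of particles N.
#' @param dz release height above the inlet \[m\].
#' @param dx sagittal offset of the release/tracing plane from the septum
#'   reference plane \[m\]; the 3-D magnet field is evaluated at x = `dx`.
#' @param dy nominal release-line length \[m\].
#' @param start,end optional explicit 2-vectors (y, z) \[m\] overriding the
#'   anchored construction.
#' @param jitter_seed optional integer; when given, positions get uniform
#'   jitter of up to half the inter-particle spacing (otherwise the release
#'   is deterministic and equally spaced, endpoints included).
#' @return object of class `release_spec`.
#' @export
release_spec <- function(count = 100, dz = 0.005, dx = 0.005, dy = 0.015,
                         start = NULL, end = NULL, jitter_seed = NULL) {
  stopifnot(count >= 1, dx >= 0, dy > 0)
  structure(list(count = as.integer(count), dz = dz, dx = dx, dy = dy,
                 start = start, end = end, jitter_seed = jitter_seed),
            class = "release_spec")
}

#' Per-protocol release positions
#'
#' Release offsets identified per protocol by trial and error in the
#' delivery study: height dz above the inlet of 0.71 cm (Protocols 1 and 2)
#' or 0.31 cm (Protocol 3), and sagittal offsets dx of 0.25 cm
#' (Protocol 1) or 0.3 cm (Protocols 2 and 3).
#'
#' @param protocol 1, 2 or 3.
#' @param count number of particles (default 100).
#' @return a [release_spec()].
#' @export
protocol_release <- function(protocol, count = 100) {
  if (!length(protocol) == 1 || !protocol %in% c(1, 2, 3)) {
    stop("protocol_release: protocol must be 1, 2 or 3")
  }
  dz <- c(0.0071, 0.0071, 0.0031)[protocol]
  dx <- c(0.0025, 0.0030, 0.0030)[protocol]
  release_spec(count = count, dz = dz, dx = dx)
}

#' Create the initial particle states on the release line
#'
#' @param spec a [release_spec()].
#' @param domain a `nasal_domain` (used to anchor the line and to verify
#'   that every release point lies in the fluid).
#' @return a `particle_states` data frame with columns `id`, `y`, `z`
#'   \[m\], `vy`, `vz` \[m/s\] (zero), `status` (`IN_FLIGHT`), `label`
#'   (NA until terminal) and `time` \[s\].
#' @export
release_line <- function(spec, domain) {
  n <- spec$count
  if (is.null(spec$start)) {
    segs <- domain$segments
    inlet <- segs[segs$label == "INLET", ]
    cy <- (inlet$y1 + inlet$y2) / 2
    cz <- (inlet$z1 + inlet$z2) / 2 + spec$dz
    half <- spec$dy / 2
    # clip to the duct with one grid cell of wall clearance
    lim <- inlet$length / 2 - domain$grid$h
    half <- min(half, lim)
    start <- c(cy - half, cz); end <- c(cy + half, cz)
  } else {
    start <- spec$start; end <- spec$end
  }
  if (sqrt(sum((end - start)^2)) <= 0) stop("release_line: line length must be > 0")
  t <- if (n == 1L) 0.5 else seq(0, 1, length.out = n)
  y <- start[1] + t * (end[1] - start[1])
  z <- start[2] + t * (end[2] - start[2])
  if (!is.null(spec$jitter_seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$jitter_seed)
    if (n > 1L) {
      spacing <- sqrt((y[2] - y[1])^2 + (z[2] - z[1])^2)
      jit <- stats::runif(n, -spacing / 2, spacing / 2)
      dirv <- (end - start) / sqrt(sum((end - start)^2))
      y <- y + jit * dirv[1]; z <- z + jit * dirv[2]
    }
  }
  sd <- signed_distance(domain, cbind(y, z))
  bad <- which(sd$distance >= 0)
  if (length(bad)) {
    stop("release_line: release points outside the fluid region at indices ",
         paste(bad, collapse = ", "))
  }
  structure(data.frame(id = seq_len(n), y = y, z = z, vy = 0, vz = 0,
                       status = "IN_FLIGHT", label = NA_character_,
                       time = 0, stringsAsFactors = FALSE),
            class = c("particle_states", "data.frame"),
            x_plane = spec$dx)
}

#' Integration settings for particle tracing
#'
#' @param dt_factor the fixed step is `dt = tau / dt_factor` where `tau` is
#'   the particle relaxation time; the default 20 resolves the velocity
#'   relaxation well.  A guard rejects steps coarser than `tau / 10`.
#' @param dt optional explicit step \[s\] (still subject to the guard).
#' @param t_max maximum simulated time per particle \[s\].
#' @param store_trajectories keep decimated trajectory polylines.
#' @param stride decimation stride for stored trajectories (steps).
#' @param force_mode `"high_chi"` (default) or `"exact"` magnetophoretic
#'   force law, see [magnetophoretic_force()].
#' @param force_interp tabulate the (static) magnetophoretic force on a
#'   refined copy of the domain grid once and interpolate it bilinearly
#'   during stepping (default), instead of evaluating the closed-form field
#'   at every Runge-Kutta stage.  This mirrors the standard
#'   solve-fields-then-trace workflow and is two orders of magnitude
#'   faster; set to `FALSE` for exact per-stage evaluation.
#' @return object of class `trace_config`.
#' @export
trace_config <- function(dt_factor = 20, dt = NULL, t_max = 10,
                         store_trajectories = FALSE, stride = 20,
                         force_mode = c("high_chi", "exact"),
                         force_interp = TRUE) {
  stopifnot(dt_factor > 0, t_max > 0, stride >= 1)
  structure(list(dt_factor = dt_factor, dt = dt, t_max = t_max,
                 store_trajectories = store_trajectories,
                 stride = as.integer(stride),
                 force_mode = match.arg(force_mode),
                 force_interp = isTRUE(force_interp)),
            class = "trace_config")
}

#' Trace microparticles through the flow under magnetophoretic guidance
#'
#' Lagrangian integration of non-interacting particles under Stokes drag
#' and the magnetophoretic force (one-way coupling: the flow field is never
#' modified; gravity and Brownian motion are neglected at this particle
#' size).  Forces use the full 3-D field formulas evaluated in the sagittal
#' plane `x = x_plane`; the lateral component of motion is dropped.  Each
#' particle is advanced with fixed-step RK4 until it
#' deposits (first wall contact within one particle radius sticks, no
#' rebound), escapes through the outlet, or reaches `t_max` (SUSPENDED).
#' Deposited positions are projected onto the nearest boundary segment.
#'
#' @param particles a `particle_states` data frame from [release_line()].
#' @param flow a `flow_field` on `domain`.
#' @param magnets magnet layout (list of [magnet()]), or `NULL` for a
#'   magnet-free control run.
#' @param domain the `nasal_domain` shared by all inputs.
#' @param props a [particle_props()].
#' @param config a [trace_config()].
#' @param x_plane sagittal evaluation offset \[m\]; defaults to the
#'   release spec's `dx` carried by `particles`, else 0.005.
#' @return terminal `particle_states` (statuses `DEPOSITED`, `ESCAPED` or
#'   `SUSPENDED`; `label` holds the nearest boundary region).  When
#'   trajectories are stored, they are attached as attribute
#'   `"trajectories"` (list of matrices, one per particle).
#' @export
trace_particles <- function(particles, flow, magnets, domain, props,
                            config = trace_config(), x_plane = NULL) {
  eta <- flow$params$viscosity
  tau <- relaxation_time(props, eta)
  dt <- if (!is.null(config$dt)) config$dt else tau / config$dt_factor
  if (dt > tau / 10 + 1e-15) {
    stop(sprintf("trace_particles: dt = %.3g s exceeds the stiffness guard tau/10 = %.3g s",
                 dt, tau / 10))
  }
  if (is.null(x_plane)) {
    x_plane <- attr(particles, "x_plane")
    if (is.null(x_plane)) x_plane <- 0.005
  }
  has_mag <- !is.null(magnets) && length(magnets) > 0
  if (has_mag && inherits(magnets, "magnet")) magnets <- list(magnets)
  cdrag <- 6 * pi * eta * props$radius
  mp <- props$mass
  bb <- domain$grid$bbox
  clamp <- function(p) {
    cbind(pmin(pmax(p[, 1], bb[1]), bb[2]), pmin(pmax(p[, 2], bb[3]), bb[4]))
  }
  g <- domain$grid
  eval_force_yz <- function(pts_yz) {
    fs <- total_field(cbind(x_plane, pts_yz), magnets)
    Fm <- magnetophoretic_force(fs, props, mode = config$force_mode)
    if (!is.matrix(Fm)) Fm <- matrix(Fm, 1)
    Fm[, 2:3, drop = FALSE]
  }
  if (has_mag && config$force_interp) {
    # the magnetostatic field is time-independent: tabulate the in-plane
    # force once on a 2x-refined copy of the domain grid (the field is
    # defined everywhere, so no masking) and interpolate during stepping
    hf <- g$h / 2
    nyf <- 2L * g$ny; nzf <- 2L * g$nz
    ycf <- (seq_len(nyf) - 0.5) * hf
    zcf <- (seq_len(nzf) - 0.5) * hf
    Ftab <- eval_force_yz(cbind(rep(ycf, times = nzf), rep(zcf, each = nyf)))
    Fy_tab <- matrix(Ftab[, 1], nyf, nzf)
    Fz_tab <- matrix(Ftab[, 2], nyf, nzf)
    mag_force <- function(pc) {
      s <- bilinear_setup(pc, hf, nyf, nzf)
      cbind(bilinear_apply(Fy_tab, s), bilinear_apply(Fz_tab, s))
    }
  } else if (has_mag) {
    mag_force <- eval_force_yz
  }
  accel <- function(pos, vel) {
    pc <- clamp(pos)
    vf <- sample_velocity(flow, pc, strict = FALSE)
    F <- cdrag * (vf - vel)
    if (has_mag) F <- F + mag_force(pc)
    F / mp
  }

  # lean per-step boundary test: unsigned distance + inside flag only;
  # label and wall projection are resolved via signed_distance() on the few
  # particles that actually make contact
  segs <- domain$segments
  sg <- list(y1 = segs$y1, z1 = segs$z1, dy = segs$y2 - segs$y1,
             dz = segs$z2 - segs$z1)
  sg$L2 <- sg$dy^2 + sg$dz^2
  boundary_probe <- function(pts) {
    y <- pts[, 1]; z <- pts[, 2]
    dmin2 <- rep(Inf, length(y))
    inside <- logical(length(y))
    for (k in seq_along(sg$y1)) {
      t <- ((y - sg$y1[k]) * sg$dy[k] + (z - sg$z1[k]) * sg$dz[k]) / sg$L2[k]
      t[t < 0] <- 0; t[t > 1] <- 1
      d2 <- (y - (sg$y1[k] + t * sg$dy[k]))^2 + (z - (sg$z1[k] + t * sg$dz[k]))^2
      upd <- d2 < dmin2
      dmin2[upd] <- d2[upd]
      z2k <- sg$z1[k] + sg$dz[k]
      crosses <- (sg$z1[k] > z) != (z2k > z)
      if (any(crosses)) {
        yint <- sg$y1[k] + (z[crosses] - sg$z1[k]) / sg$dz[k] * sg$dy[k]
        idx <- which(crosses)[yint > y[crosses]]
        inside[idx] <- !inside[idx]
      }
    }
    list(dmin = sqrt(dmin2), inside = inside)
  }

  st <- particles
  n <- nrow(st)
  pos <- cbind(st$y, st$z)
  vel <- cbind(st$vy, st$vz)
  time <- st$time
  status <- st$status
  label <- st$label
  active <- which(status == "IN_FLIGHT")
  n_steps <- ceiling(config$t_max / dt)
  traj <- if (isTRUE(config$store_trajectories)) {
    lapply(seq_len(n), function(i) pos[i, , drop = FALSE])
  } else NULL

  for (step in seq_len(n_steps)) {
    if (length(active) == 0) break
    upd <- rk4_core(pos[active, , drop = FALSE], vel[active, , drop = FALSE],
                    accel, dt)
    if (!all(is.finite(upd$pos)) || !all(is.finite(upd$vel))) {
      bad <- active[!is.finite(rowSums(upd$pos) + rowSums(upd$vel))][1]
      stop(sprintf(paste0("trace_particles: non-finite state for particle %d ",
                          "at t = %.4g s (last position %.4g, %.4g)"),
                   st$id[bad], time[bad], pos[bad, 1], pos[bad, 2]))
    }
    pos[active, ] <- upd$pos
    vel[active, ] <- upd$vel
    time[active] <- time[active] + dt
    pc <- clamp(pos[active, , drop = FALSE])
    bp <- boundary_probe(pc)
    hit <- !bp$inside | bp$dmin <= props$radius
    if (any(hit)) {
      ids <- active[hit]
      sd <- signed_distance(domain, pc[hit, , drop = FALSE], .projection = TRUE)
      lab <- sd$label
      # stick at the wall: project onto the nearest boundary segment
      pos[ids, 1] <- sd$proj_y
      pos[ids, 2] <- sd$proj_z
      status[ids] <- ifelse(lab %in% c("OUTLET", "INLET"), "ESCAPED", "DEPOSITED")
      label[ids] <- lab
      active <- active[!hit]
    }
    if (!is.null(traj) && step %% config$stride == 0) {
      for (i in active) traj[[i]] <- rbind(traj[[i]], pos[i, ])
    }
  }
  if (length(active)) {
    status[active] <- "SUSPENDED"
    pcl <- clamp(pos[active, , drop = FALSE])
    label[active] <- NA_character_
    pos[active, ] <- pcl
  }
  st$y <- pos[, 1]; st$z <- pos[, 2]
  st$vy <- vel[, 1]; st$vz <- vel[, 2]
  st$time <- time
  st$status <- status
  st$label <- label
  if (!is.null(traj)) attr(st, "trajectories") <- traj
  attr(st, "dt") <- dt
  st
}

#' @export
print.particle_states <- function(x, ...) {
  cat("<particle_states>", nrow(x), "particles\n")
  print(table(status = x$status, label = factor(x$label, levels = REGION_LABELS),
              useNA = "ifany"))
  invisible(x)
}
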