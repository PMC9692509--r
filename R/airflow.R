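#' Air and solver parameters for the steady laminar flow problem
#'
#' Defaults are the inhalation conditions of the delivery study: air at
#' body temperature (density 1.14 kg/m^3, dynamic viscosity 1.9e-5 Pa s),
#' a steady uniform normal inflow of 0.5 m/s at the nostril, zero gauge
#' pressure at the nasopharynx outlet, and no-slip mucosa walls.
#'
#' @param density air density \[kg/m^3\].
#' @param viscosity dynamic viscosity \[Pa s\].
#' @param u_in inlet normal speed \[m/s\].
#' @param p_out outlet gauge pressure \[Pa\] (the projection solver works in
#'   gauge pressure, so only 0 is meaningful; recorded for provenance).
#' @param tol convergence tolerance on the pseudo-time momentum residual,
#'   relative to the residual of the first pseudo-time step.
#' @param max_iter maximum pseudo-time steps.
#' @param cfl Courant number used to pick the pseudo-time step.
#' @param dt optional explicit pseudo-time step \[s\] (overrides `cfl`).
#' @return object of class `flow_params`.
#' @export
flow_params <- function(density = 1.14, viscosity = 1.9e-5, u_in = 0.5,
                        p_out = 0, tol = 1e-6, max_iter = 60000,
                        cfl = 0.4, dt = NULL) {
  stopifnot(density > 0, viscosity > 0, u_in >= 0, tol > 0, max_iter >= 1)
  structure(list(density = density, viscosity = viscosity, u_in = u_in,
                 p_out = p_out, tol = tol, max_iter = max_iter,
                 cfl = cfl, dt = dt),
            class = "flow_params")
}

# face classification codes
FACE_DEAD <- 0L; FACE_INT <- 1L; FACE_FIXED <- 2L; FACE_OUTLET <- 3L

# classify staggered faces against the labeled boundary.  `horiz = TRUE`
# classifies u-faces (normal along y), else w-faces (normal along z).
classify_faces <- function(dom, horiz) {
  g <- dom$grid; ny <- g$ny; nz <- g$nz; h <- g$h
  mask <- dom$mask
  segs <- dom$segments
  open_segs <- segs[segs$label %in% c("INLET", "OUTLET"), , drop = FALSE]
  if (horiz) {
    nf1 <- ny + 1L; nf2 <- nz
    fy <- (seq_len(nf1) - 1) * h
    fz <- (seq_len(nf2) - 0.5) * h
    Lm <- rbind(FALSE, mask) # cell (i-1, j)
    Rm <- rbind(mask, FALSE) # cell (i, j)
  } else {
    nf1 <- ny; nf2 <- nz + 1L
    fy <- (seq_len(nf1) - 0.5) * h
    fz <- (seq_len(nf2) - 1) * h
    Lm <- cbind(FALSE, mask); Rm <- cbind(mask, FALSE)
  }
  type <- matrix(FACE_DEAD, nf1, nf2)
  type[Lm & Rm] <- FACE_INT
  bnd <- xor(Lm, Rm)
  value <- matrix(0, nf1, nf2)
  # inward orientation sign of a boundary face: +1 when fluid on the + side
  orient <- matrix(0, nf1, nf2)
  orient[bnd & Rm] <- 1
  orient[bnd & Lm] <- -1
  if (any(bnd)) {
    idx <- which(bnd, arr.ind = TRUE)
    pts <- cbind(fy[idx[, 1]], fz[idx[, 2]])
    lab <- rep("WALLISH", nrow(pts))
    for (k in seq_len(nrow(open_segs))) {
      s <- open_segs[k, ]
      d <- point_segment_distance(pts, s$y1, s$z1, s$y2, s$z2)
      on <- d$dist < h / 4
      lab[on] <- s$label
    }
    type[idx] <- FACE_FIXED
    type[idx[lab == "OUTLET", , drop = FALSE]] <- FACE_OUTLET
  }
  list(type = type, orient = orient, value = value)
}

# sparse SPD Helmholtz operator (1/dt - nu Laplacian) over interior faces
build_helmholtz <- function(type, dt, nu, h) {
  nf1 <- nrow(type); nf2 <- ncol(type)
  unk <- which(type == FACE_INT)
  id <- matrix(0L, nf1, nf2); id[unk] <- seq_along(unk)
  n <- length(unk)
  ii <- jj <- integer(0); xx <- numeric(0)
  diagv <- rep(1 / dt + 4 * nu / h^2, n)
  ij <- arrayInd(unk, c(nf1, nf2))
  # neighbor bookkeeping: for each direction, interior neighbors give
  # off-diagonal links, valued neighbors go to the per-step RHS, dead
  # tangential neighbors act as mirror (no-slip) ghosts on the diagonal
  nb_rhs_idx <- list(); nb_rhs_row <- list()
  dirs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  for (d in seq_along(dirs)) {
    di <- dirs[[d]][1]; dj <- dirs[[d]][2]
    ni <- ij[, 1] + di; nj <- ij[, 2] + dj
    inb <- ni >= 1 & ni <= nf1 & nj >= 1 & nj <= nf2
    ntype <- rep(FACE_DEAD, n)
    nidx <- rep(NA_integer_, n)
    nidx[inb] <- (nj[inb] - 1L) * nf1 + ni[inb]
    ntype[inb] <- type[nidx[inb]]
    is_int <- ntype == FACE_INT
    ii <- c(ii, which(is_int)); jj <- c(jj, id[nidx[is_int]])
    xx <- c(xx, rep(-nu / h^2, sum(is_int)))
    is_val <- ntype == FACE_FIXED | ntype == FACE_OUTLET
    nb_rhs_idx[[d]] <- nidx[is_val]
    nb_rhs_row[[d]] <- which(is_val)
    is_dead <- !is_int & !is_val
    diagv[is_dead] <- diagv[is_dead] + nu / h^2 # ghost = -u mirror
  }
  A <- Matrix::sparseMatrix(i = c(seq_len(n), ii), j = c(seq_len(n), jj),
                            x = c(diagv, xx), dims = c(n, n), symmetric = FALSE)
  A <- Matrix::forceSymmetric(A)
  list(chol = Matrix::Cholesky(A, LDL = FALSE), unk = unk, id = id,
       rhs_idx = nb_rhs_idx, rhs_row = nb_rhs_row, n = n)
}

# sparse SPD pressure-Poisson operator over fluid cells
build_poisson <- function(mask, utype, wtype, h) {
  ny <- nrow(mask); nz <- ncol(mask)
  unk <- which(mask)
  id <- matrix(0L, ny, nz); id[unk] <- seq_along(unk)
  n <- length(unk)
  ij <- arrayInd(unk, c(ny, nz))
  diagv <- numeric(n)
  ii <- jj <- integer(0); xx <- numeric(0)
  # faces of cell (i, j): u(i, j) (west), u(i+1, j) (east),
  #                       w(i, j) (south), w(i, j+1) (north)
  face_of <- function(d, i, j) {
    switch(d,
      cbind(i, j, 1L),     # west  u-face
      cbind(i + 1L, j, 1L), # east u-face
      cbind(i, j, 2L),     # south w-face
      cbind(i, j + 1L, 2L)) # north w-face
  }
  nb_of <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  for (d in 1:4) {
    f <- face_of(d, ij[, 1], ij[, 2])
    ftyp <- ifelse(f[, 3] == 1L, utype[f[, 1:2, drop = FALSE]],
                   wtype[f[, 1:2, drop = FALSE]])
    ni <- ij[, 1] + nb_of[[d]][1]; nj <- ij[, 2] + nb_of[[d]][2]
    is_int <- ftyp == FACE_INT
    diagv[is_int] <- diagv[is_int] + 1 / h^2
    nidx <- (pmin(pmax(nj, 1L), nz) - 1L) * ny + pmin(pmax(ni, 1L), ny)
    ii <- c(ii, which(is_int)); jj <- c(jj, id[nidx[is_int]])
    xx <- c(xx, rep(-1 / h^2, sum(is_int)))
    is_out <- ftyp == FACE_OUTLET
    diagv[is_out] <- diagv[is_out] + 1 / h^2 # p = 0 ghost beyond the outlet
  }
  A <- Matrix::sparseMatrix(i = c(seq_len(n), ii), j = c(seq_len(n), jj),
                            x = c(diagv, xx), dims = c(n, n))
  A <- Matrix::forceSymmetric(A)
  list(chol = Matrix::Cholesky(A, LDL = FALSE), unk = unk, id = id, n = n)
}

#' Solve the steady incompressible laminar airflow
#'
#' Solves the steady incompressible Navier-Stokes equations on the domain's
#' regular grid with the three boundary conditions of the inhalation
#' problem: uniform normal inflow at the INLET, fixed (zero gauge) pressure
#' at the OUTLET, and no-slip on all walls.  The discretization is a
#' staggered (MAC) finite-volume grid with first-order upwind convection,
#' implicit backward-Euler diffusion and a pressure-projection step, marched
#' in pseudo-time to the stationary state.  Walls that do not align with the
#' grid are represented by first-order stair-step masking.
#'
#' @param domain a `nasal_domain` (from [build_surrogate()] or
#'   [channel_domain()]).
#' @param params a [flow_params()].
#' @return object of class `flow_field`: staggered `u`, `w` \[m/s\],
#'   cell-centered `uc`, `wc`, pressure `p` \[Pa\], `residuals` history,
#'   inflow/outflow fluxes, and the grid/mask needed for sampling.
#' @export
solve_flow <- function(domain, params = flow_params()) {
  g <- domain$grid; h <- g$h; ny <- g$ny; nz <- g$nz
  mask <- domain$mask
  rho <- params$density; eta <- params$viscosity; nu <- eta / rho
  u_in <- params$u_in
  w_open <- domain$wall_lengths[["INLET"]]
  Re <- rho * u_in * w_open / eta
  if (Re >= 2000) {
    stop(sprintf("solve_flow: inlet Reynolds number %.0f is outside the laminar regime", Re))
  }

  fu <- classify_faces(domain, horiz = TRUE)
  fw <- classify_faces(domain, horiz = FALSE)
  # fixed (inlet) values: u_in along the inward normal
  set_inlet <- function(fc, horiz) {
    segs <- domain$segments
    inlet <- segs[segs$label == "INLET", ]
    idx <- which(fc$type == FACE_FIXED, arr.ind = TRUE)
    if (nrow(idx) == 0) return(fc)
    if (horiz) { fy <- (idx[, 1] - 1) * h; fz <- (idx[, 2] - 0.5) * h }
    else { fy <- (idx[, 1] - 0.5) * h; fz <- (idx[, 2] - 1) * h }
    d <- point_segment_distance(cbind(fy, fz), inlet$y1, inlet$z1,
                                inlet$y2, inlet$z2)
    on <- d$dist < h / 4
    fc$value[idx[on, , drop = FALSE]] <-
      u_in * fc$orient[idx[on, , drop = FALSE]]
    fc
  }
  fu <- set_inlet(fu, TRUE)
  fw <- set_inlet(fw, FALSE)

  # pseudo-time step from a CFL estimate of the peak speed
  narrow <- min(domain$wall_lengths[["INLET"]], domain$wall_lengths[["OUTLET"]])
  # diffusive velocity scale nu/h floors the estimate (and covers u_in = 0)
  u_ref <- max(u_in, 1.7 * u_in * w_open / narrow, nu / h)
  dt <- if (!is.null(params$dt)) params$dt else params$cfl * h / u_ref

  Hu <- build_helmholtz(fu$type, dt, nu, h)
  Hw <- build_helmholtz(fw$type, dt, nu, h)
  Pp <- build_poisson(mask, fu$type, fw$type, h)

  # per-face neighbor setup for the convection kernel
  conv_setup <- function(type) {
    unk <- which(type == FACE_INT)
    nf1 <- nrow(type); nf2 <- ncol(type)
    ij <- arrayInd(unk, c(nf1, nf2))
    dirs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
    nb_idx <- nb_ok <- nb_dead <- vector("list", 4)
    for (d in 1:4) {
      ni <- ij[, 1] + dirs[[d]][1]; nj <- ij[, 2] + dirs[[d]][2]
      inb <- ni >= 1 & ni <= nf1 & nj >= 1 & nj <= nf2
      nidx <- (pmin(pmax(nj, 1L), nf2) - 1L) * nf1 + pmin(pmax(ni, 1L), nf1)
      ntyp <- rep(FACE_DEAD, length(unk))
      ntyp[inb] <- type[nidx[inb]]
      nb_idx[[d]] <- nidx
      nb_ok[[d]] <- inb & ntyp != FACE_DEAD
      nb_dead[[d]] <- !(inb & ntyp != FACE_DEAD)
    }
    list(lin = unk, ij = ij, nb_idx = nb_idx, nb_ok = nb_ok, nb_dead = nb_dead)
  }
  su <- conv_setup(fu$type)
  sw <- conv_setup(fw$type)

  U <- fu$value # current u array (fixed faces pre-filled, rest 0)
  W <- fw$value
  u_out_faces <- which(fu$type == FACE_OUTLET)
  w_out_faces <- which(fw$type == FACE_OUTLET)
  # zero-gradient source for outlet faces: the neighboring interior face
  # along the face normal, on the fluid side
  out_nb <- function(type, faces, horiz) {
    if (length(faces) == 0) return(integer(0))
    nf1 <- nrow(type)
    ij <- arrayInd(faces, dim(type))
    d1 <- if (horiz) c(-1, 0) else c(0, -1)
    nb <- integer(length(faces))
    for (k in seq_along(faces)) {
      for (s in list(d1, -d1)) {
        ni <- ij[k, 1] + s[1]; nj <- ij[k, 2] + s[2]
        if (ni >= 1 && ni <= nf1 && nj >= 1 && nj <= ncol(type) &&
            type[ni, nj] == FACE_INT) nb[k] <- (nj - 1L) * nf1 + ni
      }
    }
    nb
  }
  u_out_nb <- out_nb(fu$type, u_out_faces, TRUE)
  w_out_nb <- out_nb(fw$type, w_out_faces, FALSE)

  # cell-face averages of the transverse component at interior faces
  other_at_u <- function(W) {
    ij <- su$ij
    0.25 * (W[cbind(ij[, 1] - 1L, ij[, 2])] + W[cbind(ij[, 1] - 1L, ij[, 2] + 1L)] +
            W[cbind(ij[, 1], ij[, 2])] + W[cbind(ij[, 1], ij[, 2] + 1L)])
  }
  other_at_w <- function(U) {
    ij <- sw$ij
    0.25 * (U[cbind(ij[, 1], ij[, 2] - 1L)] + U[cbind(ij[, 1] + 1L, ij[, 2] - 1L)] +
            U[cbind(ij[, 1], ij[, 2])] + U[cbind(ij[, 1] + 1L, ij[, 2])])
  }

  cell_idx <- Pp$unk
  cij <- arrayInd(cell_idx, c(ny, nz))
  uW <- cbind(cij[, 1], cij[, 2]); uE <- cbind(cij[, 1] + 1L, cij[, 2])
  wS <- cbind(cij[, 1], cij[, 2]); wN <- cbind(cij[, 1], cij[, 2] + 1L)

  residuals <- numeric(0)
  res0 <- NA_real_
  upw <- function(vc, aN, aT, vW, vE, vS, vN) {
    dVn <- ifelse(aN > 0, (vc - vW) / h, (vE - vc) / h)
    dVt <- ifelse(aT > 0, (vc - vS) / h, (vN - vc) / h)
    aN * dVn + aT * dVt
  }
  nbval <- function(V, s, d) {
    vc <- V[s$lin]
    out <- -vc
    ok <- s$nb_ok[[d]]
    out[ok] <- V[s$nb_idx[[d]][ok]]
    out
  }

  for (it in seq_len(params$max_iter)) {
    Uo <- U; Wo <- W
    # predictor for u
    vc <- U[su$lin]
    conv_u <- upw(vc, vc, other_at_u(W),
                  nbval(U, su, 1), nbval(U, su, 2),
                  nbval(U, su, 3), nbval(U, su, 4))
    rhs_u <- vc / dt - conv_u
    for (d in 1:4) {
      r <- Hu$rhs_row[[d]]
      if (length(r)) rhs_u[r] <- rhs_u[r] + nu / h^2 * U[Hu$rhs_idx[[d]]]
    }
    ustar <- as.numeric(Matrix::solve(Hu$chol, rhs_u))
    # predictor for w
    vcw <- W[sw$lin]
    conv_w <- upw(vcw, other_at_w(U), vcw,
                  nbval(W, sw, 1), nbval(W, sw, 2),
                  nbval(W, sw, 3), nbval(W, sw, 4))
    rhs_w <- vcw / dt - conv_w
    for (d in 1:4) {
      r <- Hw$rhs_row[[d]]
      if (length(r)) rhs_w[r] <- rhs_w[r] + nu / h^2 * W[Hw$rhs_idx[[d]]]
    }
    wstar <- as.numeric(Matrix::solve(Hw$chol, rhs_w))

    U[su$lin] <- ustar
    W[sw$lin] <- wstar
    if (length(u_out_faces)) U[u_out_faces] <- U[u_out_nb]
    if (length(w_out_faces)) W[w_out_faces] <- W[w_out_nb]

    # projection
    div <- (U[uE] - U[uW] + W[wN] - W[wS]) / h
    p <- as.numeric(Matrix::solve(Pp$chol, -rho / dt * div))
    P <- matrix(0, ny, nz); P[cell_idx] <- p
    # correct interior faces
    ij <- su$ij
    U[su$lin] <- U[su$lin] -
      dt / rho * (P[cbind(ij[, 1], ij[, 2])] - P[cbind(ij[, 1] - 1L, ij[, 2])]) / h
    ij <- sw$ij
    W[sw$lin] <- W[sw$lin] -
      dt / rho * (P[cbind(ij[, 1], ij[, 2])] - P[cbind(ij[, 1], ij[, 2] - 1L)]) / h
    # correct outlet faces against the p = 0 ghost
    if (length(u_out_faces)) {
      ijo <- arrayInd(u_out_faces, dim(U))
      pL <- ifelse(ijo[, 1] - 1L >= 1, P[cbind(pmax(ijo[, 1] - 1L, 1L), ijo[, 2])], 0)
      pL[ijo[, 1] - 1L >= 1 & !mask[cbind(pmax(ijo[, 1] - 1L, 1L), ijo[, 2])]] <- 0
      pR <- ifelse(ijo[, 1] <= ny, P[cbind(pmin(ijo[, 1], ny), ijo[, 2])], 0)
      pR[ijo[, 1] <= ny & !mask[cbind(pmin(ijo[, 1], ny), ijo[, 2])]] <- 0
      U[u_out_faces] <- U[u_out_faces] - dt / rho * (pR - pL) / h
    }
    if (length(w_out_faces)) {
      ijo <- arrayInd(w_out_faces, dim(W))
      pS <- ifelse(ijo[, 2] - 1L >= 1, P[cbind(ijo[, 1], pmax(ijo[, 2] - 1L, 1L))], 0)
      pS[ijo[, 2] - 1L >= 1 & !mask[cbind(ijo[, 1], pmax(ijo[, 2] - 1L, 1L))]] <- 0
      pN <- ifelse(ijo[, 2] <= nz, P[cbind(ijo[, 1], pmin(ijo[, 2], nz))], 0)
      pN[ijo[, 2] <= nz & !mask[cbind(ijo[, 1], pmin(ijo[, 2], nz))]] <- 0
      W[w_out_faces] <- W[w_out_faces] - dt / rho * (pN - pS) / h
    }

    delta <- max(max(abs(U - Uo)), max(abs(W - Wo))) / dt
    if (!is.finite(delta)) {
      stop("solve_flow: solution diverged (non-finite velocity) at step ", it)
    }
    if (it == 1L) res0 <- max(delta, .Machine$double.eps)
    res <- delta / res0
    if (it %% 10 == 0 || it == 1L) residuals <- c(residuals, res)
    if (res < params$tol || delta * dt < 1e-15 * max(u_in, 1)) break
  }
  if (res >= params$tol && delta * dt >= 1e-15 * max(u_in, 1)) {
    stop(sprintf(paste0("solve_flow: no convergence within %d steps ",
                        "(relative residual %.3g); residual history attached"),
                 params$max_iter, res),
         call. = FALSE)
  }

  # cell-centered velocities (zero in solid cells)
  uc <- 0.5 * (U[seq_len(ny), , drop = FALSE] + U[seq_len(ny) + 1L, , drop = FALSE])
  wc <- 0.5 * (W[, seq_len(nz), drop = FALSE] + W[, seq_len(nz) + 1L, drop = FALSE])
  uc[!mask] <- 0; wc[!mask] <- 0

  influx <- sum(abs(fu$value[fu$type == FACE_FIXED])) * h +
    sum(abs(fw$value[fw$type == FACE_FIXED])) * h
  outflux <- sum(abs(U[u_out_faces])) * h + sum(abs(W[w_out_faces])) * h
  div_final <- (U[uE] - U[uW] + W[wN] - W[wS]) / h

  structure(list(u = U, w = W, p = P, uc = uc, wc = wc,
                 grid = g, mask = mask, params = params,
                 residuals = residuals, iterations = it,
                 influx = influx, outflux = outflux,
                 max_divergence = max(abs(div_final))),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat("<flow_field> steady laminar solution\n")
  cat(sprintf("  grid %d x %d, %d pseudo-time steps, final residual %.3g\n",
              x$grid$ny, x$grid$nz, x$iterations, tail_or_na(x$residuals)))
  cat(sprintf("  peak speed %.3g m/s; influx %.4g, outflux %.4g m^2/s; max |div| %.3g\n",
              max(sqrt(x$uc^2 + x$wc^2)), x$influx, x$outflux, x$max_divergence))
  invisible(x)
}
tail_or_na <- function(v) if (length(v)) v[length(v)] else NA_real_

#' Straight-channel validation domain
#'
#' A rectangular channel with inlet at y = 0, outlet at y = `length`, and
#' no-slip walls at z = 0 and z = `width`.  Used to validate the flow
#' solver against the plane-Poiseuille closed form and as a controlled
#' stage for particle-tracing fixtures.  A short wall strip on the upper
#' wall is labeled OLFACTORY so that deposition bookkeeping has a target
#' region; its extent is `olfactory_fraction` of the wall length.
#'
#' @param length,width channel dimensions \[m\].
#' @param grid_spacing lattice spacing \[m\].
#' @param olfactory_fraction wall fraction labeled OLFACTORY (upper wall,
#'   centered).
#' @return a `nasal_domain`.
#' @export
channel_domain <- function(length = 4, width = 1, grid_spacing = 1 / 64,
                           olfactory_fraction = 0.08) {
  p <- list(inlet_width = width, passage_height = width,
            passage_length = length, olfactory_fraction = olfactory_fraction,
            bend_radius = 0, grid_spacing = grid_spacing,
            outlet_width = width, septum_offset = 0.005)
  class(p) <- "surrogate_params"
  v <- rbind(c(0, 0), c(0, width), c(length, width), c(length, 0))
  segs <- data.frame(
    y1 = c(0, 0, length, length), z1 = c(0, width, width, 0),
    y2 = c(0, length, length, 0), z2 = c(width, width, 0, 0),
    label = c("INLET", "WALL", "OUTLET", "WALL"), stringsAsFactors = FALSE
  )
  segs$length <- seg_lengths(segs)
  # carve the olfactory strip out of the upper wall
  wall_tot <- sum(segs$length[segs$label == "WALL"])
  olf <- olfactory_fraction * wall_tot
  lo <- length / 2 - olf / 2; hi <- length / 2 + olf / 2
  top <- data.frame(y1 = c(0, lo, hi), z1 = width, y2 = c(lo, hi, length),
                    z2 = width, label = c("WALL", "OLFACTORY", "WALL"),
                    stringsAsFactors = FALSE)
  top$length <- seg_lengths(top)
  segs <- rbind(segs[1, ], top, segs[3:4, ])
  rownames(segs) <- NULL
  h <- grid_spacing
  ny <- round(length / h); nz <- round(width / h)
  dom <- structure(
    list(params = p, segments = segs,
         mask = matrix(TRUE, ny, nz),
         grid = list(h = h, ny = ny, nz = nz,
                     yc = (seq_len(ny) - 0.5) * h, zc = (seq_len(nz) - 0.5) * h,
                     bbox = c(0, length, 0, width)),
         wall_lengths = vapply(REGION_LABELS,
                               function(l) sum(segs$length[segs$label == l]),
                               numeric(1))),
    class = "nasal_domain"
  )
  dom
}

#' Sample the flow velocity at arbitrary points
#'
#' Bilinear interpolation of the cell-centered velocity field.  Cells
#' outside the fluid hold zero velocity (the no-slip wall value), so
#' samples adjacent to walls blend toward zero.
#'
#' @param flow a `flow_field`.
#' @param point 2-vector `(y, z)` \[m\] or n-by-2 matrix.
#' @param strict error when the containing cell is not fluid (default);
#'   with `strict = FALSE` the sample is taken anyway (clamped to the grid),
#'   which is what the particle tracer uses during the final partial step
#'   before wall contact.
#' @return 2-column matrix (or 2-vector) of velocity \[m/s\].
#' @export
sample_velocity <- function(flow, point, strict = TRUE) {
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  g <- flow$grid; h <- g$h; ny <- g$ny; nz <- g$nz
  if (strict) {
    ci <- pmin(pmax(ceiling(pts[, 1] / h), 1L), ny)
    cj <- pmin(pmax(ceiling(pts[, 2] / h), 1L), nz)
    inside <- pts[, 1] >= 0 & pts[, 1] <= g$bbox[2] &
      pts[, 2] >= 0 & pts[, 2] <= g$bbox[4] & flow$mask[cbind(ci, cj)]
    if (!all(inside)) {
      stop("sample_velocity: point outside the fluid region")
    }
  }
  s <- bilinear_setup(pts, h, ny, nz)
  out <- cbind(bilinear_apply(flow$uc, s), bilinear_apply(flow$wc, s))
  if (!is.matrix(point)) as.vector(out) else out
}

# shared bilinear-interpolation kernel on a cell-center lattice with
# spacing h and origin at (h/2, h/2)
bilinear_setup <- function(pts, h, ny, nz) {
  gx <- pts[, 1] / h - 0.5
  gy <- pts[, 2] / h - 0.5
  i0 <- pmin(pmax(floor(gx) + 1L, 1L), ny - 1L)
  j0 <- pmin(pmax(floor(gy) + 1L, 1L), nz - 1L)
  fx <- pmin(pmax(gx - (i0 - 1L), 0), 1)
  fy <- pmin(pmax(gy - (j0 - 1L), 0), 1)
  list(i00 = cbind(i0, j0), i10 = cbind(i0 + 1L, j0),
       i01 = cbind(i0, j0 + 1L), i11 = cbind(i0 + 1L, j0 + 1L),
       w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy),
       w01 = (1 - fx) * fy, w11 = fx * fy)
}

bilinear_apply <- function(A, s) {
  A[s$i00] * s$w00 + A[s$i10] * s$w10 + A[s$i01] * s$w01 + A[s$i11] * s$w11
}
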