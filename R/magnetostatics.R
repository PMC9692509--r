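#' Define a uniformly magnetized cuboid permanent magnet
#'
#' The magnet is described by its center, half edge lengths along the body
#' axes, a body-to-world rotation, and a remanence vector \eqn{B_r} given in
#' the world frame.  The field is computed from the Coulombian (magnetic
#' surface charge) model with magnetization \eqn{M = B_r/\mu_0}; the stated
#' relative permeability `mu_r` is recorded for provenance but the interior
#' is modeled with \eqn{\mu_r = 1} (the closed form), which perturbs the
#' exterior field of NdFeB magnets by a few percent at most.
#'
#' @param center world coordinates of the magnet center \[m\] (3-vector).
#' @param half_lengths half edge lengths along the body axes \[m\] (3-vector).
#' @param rotation 3x3 orthonormal body-to-world rotation matrix.
#' @param remanence remanence vector \eqn{B_r} in the world frame \[T\].
#'   Defaults to the NdFeB value used throughout: magnitude 1.2 T with
#'   components (0, 0.771, 0.919) T, i.e. tilted in the sagittal yz-plane.
#' @param mu_r relative permeability, informational (default 1.05).
#' @return an object of class `magnet`.
#' @export
magnet <- function(center, half_lengths, rotation = diag(3),
                   remanence = c(0, 0.771, 0.919), mu_r = 1.05) {
  center <- as.numeric(center); half_lengths <- as.numeric(half_lengths)
  remanence <- as.numeric(remanence)
  stopifnot(length(center) == 3, length(half_lengths) == 3,
            length(remanence) == 3, all(half_lengths > 0))
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-12) {
    stop("magnet: rotation must be orthonormal (R'R = I within 1e-12)")
  }
  if (sqrt(sum(remanence^2)) <= 0) stop("magnet: |remanence| must be > 0")
  structure(list(center = center, half_lengths = half_lengths,
                 rotation = rotation, remanence = remanence, mu_r = mu_r),
            class = "magnet")
}

#' @export
print.magnet <- function(x, ...) {
  cat("<magnet> cuboid, edges", paste(signif(2 * x$half_lengths, 3), collapse = " x "),
      "m\n  center:", paste(signif(x$center, 3), collapse = ", "),
      "\n  |B_r| =", signif(sqrt(sum(x$remanence^2)), 4), "T\n")
  invisible(x)
}

#' Magnetite microparticle properties
#'
#' @param radius particle radius \[m\] (default 7.5e-6, a 15 um carrier).
#' @param density particle density \[kg/m^3\] (default 5200, magnetite).
#' @param susceptibility dimensionless magnetic susceptibility; only needed
#'   for the exact force mode, `NULL` otherwise (magnetite microparticles
#'   have a high, sample-dependent susceptibility).
#' @return an object of class `particle_props` with the derived volume
#'   `V_p = 4/3 pi R_p^3` \[m^3\] and mass `m_p` \[kg\] cached.
#' @export
particle_props <- function(radius = 7.5e-6, density = 5200,
                           susceptibility = NULL) {
  stopifnot(is.numeric(radius), radius > 0, is.numeric(density), density > 0)
  V <- 4 / 3 * pi * radius^3
  structure(list(radius = radius, density = density,
                 susceptibility = susceptibility,
                 volume = V, mass = density * V),
            class = "particle_props")
}

# field of a uniformly charged rectangle lying in the plane w = 0,
# spanning [-au, au] x [-av, av]; (u, v, w) are evaluation coordinates
# relative to the plate center. Returns H components along (u, v, w) and,
# when `jac`, the 3x3 Jacobian d H_i / d (u, v, w) as an n x 3 x 3 array.
plate_field <- function(u, v, w, au, av, sigma, jac = TRUE) {
  n <- length(u)
  Hu <- Hv <- Hw <- numeric(n)
  J <- if (jac) array(0, c(n, 3, 3)) else NULL
  cu <- c(1, 1, -1, -1) # corner offsets: u_i = u + cu*au
  cv <- c(1, -1, 1, -1)
  cs <- c(1, -1, -1, 1) # corner signs of the double antiderivative
  for (k in 1:4) {
    uu <- u + cu[k] * au
    vv <- v + cv[k] * av
    R <- sqrt(uu * uu + vv * vv + w * w)
    s <- cs[k]
    # v + R >= 0 analytically; clamp rounding undershoot near the edge
    # lines so log() stays silent (the eps-offset fallback handles zeros)
    Hu <- Hu - s * log(pmax(vv + R, .Machine$double.xmin))
    Hv <- Hv - s * log(pmax(uu + R, .Machine$double.xmin))
    # plain atan (not atan2): the principal branch gives the correct
    # solid-angle continuation on both sides of the charged plate
    Hw <- Hw + s * atan(uu * vv / (w * R))
    if (jac) {
      uw2 <- uu * uu + w * w
      vw2 <- vv * vv + w * w
      J[, 1, 1] <- J[, 1, 1] - s * uu / (R * (vv + R))
      J[, 1, 2] <- J[, 1, 2] - s / R
      J[, 1, 3] <- J[, 1, 3] - s * w / (R * (vv + R))
      J[, 2, 1] <- J[, 2, 1] - s / R
      J[, 2, 2] <- J[, 2, 2] - s * vv / (R * (uu + R))
      J[, 2, 3] <- J[, 2, 3] - s * w / (R * (uu + R))
      J[, 3, 1] <- J[, 3, 1] + s * vv * w / (R * uw2)
      J[, 3, 2] <- J[, 3, 2] + s * uu * w / (R * vw2)
      J[, 3, 3] <- J[, 3, 3] - s * uu * vv * (R * R + w * w) / (R * uw2 * vw2)
    }
  }
  f <- sigma / (4 * pi)
  if (jac) J <- J * f
  list(Hu = f * Hu, Hv = f * Hv, Hw = f * Hw, J = J)
}

# H (and optionally Jacobian) of one cuboid magnet at world points (n x 3).
# Points within ~1e-9 m of a face-edge singularity of the closed form are
# nudged by eps and flagged via the "singular_offset" attribute.
field_eval <- function(pts, mag, jac = TRUE, eps = 1e-9, .depth = 0) {
  pts <- if (is.matrix(pts)) pts else matrix(pts, ncol = 3)
  n <- nrow(pts)
  Rm <- mag$rotation
  prel <- sweep(pts, 2, mag$center) %*% Rm # body-frame coordinates
  Mb <- as.vector(crossprod(Rm, mag$remanence)) / MU0
  hl <- mag$half_lengths
  Hb <- matrix(0, n, 3)
  Jb <- if (jac) array(0, c(n, 3, 3)) else NULL
  axmap <- list(c(2, 3), c(3, 1), c(1, 2)) # in-plane axes for each normal
  for (k in 1:3) {
    if (Mb[k] == 0) next
    iu <- axmap[[k]][1]; iv <- axmap[[k]][2]
    ax <- c(iu, iv, k)
    for (sgn in c(1, -1)) {
      pf <- plate_field(prel[, iu], prel[, iv], prel[, k] - sgn * hl[k],
                        hl[iu], hl[iv], sgn * Mb[k], jac = jac)
      Hb[, iu] <- Hb[, iu] + pf$Hu
      Hb[, iv] <- Hb[, iv] + pf$Hv
      Hb[, k] <- Hb[, k] + pf$Hw
      if (jac) {
        for (a in 1:3) for (b in 1:3) {
          Jb[, ax[a], ax[b]] <- Jb[, ax[a], ax[b]] + pf$J[, a, b]
        }
      }
    }
  }
  H <- Hb %*% t(Rm)
  J <- NULL
  if (jac) {
    J <- array(0, c(n, 3, 3))
    for (i in 1:3) for (j in 1:3) {
      acc <- numeric(n)
      for (a in 1:3) for (b in 1:3) {
        acc <- acc + Rm[i, a] * Rm[j, b] * Jb[, a, b]
      }
      J[, i, j] <- acc
    }
  }
  bad <- !is.finite(rowSums(H))
  if (jac) bad <- bad | !is.finite(rowSums(J, dims = 1))
  flagged <- logical(n)
  if (any(bad) && .depth < 3) {
    off <- eps * (.depth + 1) / sqrt(3)
    sub <- field_eval(pts[bad, , drop = FALSE] + off, mag, jac = jac,
                      eps = eps, .depth = .depth + 1)
    H[bad, ] <- sub$H
    if (jac) J[bad, , ] <- sub$J
    flagged[bad] <- TRUE
  }
  list(H = H, J = J, singular_offset = flagged)
}

#' Magnetic field intensity of a cuboid magnet
#'
#' Closed-form H of a uniformly magnetized cuboid via the Coulombian
#' surface-charge model: each magnetization component charges the pair of
#' faces it crosses, and the field of a uniformly charged rectangle is the
#' classical corner sum of logarithm (in-plane) and arctangent (normal)
#' terms.  The expression is valid inside and outside the magnet; inside,
#' the flux density is \eqn{B = \mu_0 (H + M)}, outside \eqn{B = \mu_0 H}.
#'
#' Points falling on an edge singularity of the logarithm terms are
#' evaluated at a 1 nm offset and flagged in the `"singular_offset"`
#' attribute rather than raising an error, so particle tracing cannot crash
#' at a grazing point.
#'
#' @param point world point \[m\]: 3-vector or n-by-3 matrix.
#' @param magnet a [magnet()].
#' @return H \[A/m\]: 3-vector, or n-by-3 matrix for matrix input, with
#'   attribute `singular_offset`.
#' @export
cuboid_H <- function(point, magnet) {
  fe <- field_eval(point, magnet, jac = FALSE)
  out <- if (is.matrix(point)) fe$H else as.vector(fe$H)
  attr(out, "singular_offset") <- fe$singular_offset
  out
}

#' Spatial Jacobian of the cuboid magnet field
#'
#' Analytic differentiation of the closed form of [cuboid_H()].  At
#' exterior points the Jacobian is symmetric (curl-free) and traceless
#' (divergence-free).
#'
#' @inheritParams cuboid_H
#' @return the 3x3 matrix \eqn{\partial H_i/\partial x_j} \[A/m^2\], or an
#'   n-by-3-by-3 array for matrix input, with attribute `singular_offset`.
#' @export
grad_H <- function(point, magnet) {
  fe <- field_eval(point, magnet, jac = TRUE)
  out <- if (is.matrix(point)) fe$J else fe$J[1, , ]
  attr(out, "singular_offset") <- fe$singular_offset
  out
}

#' Superposed field sample of a magnet layout
#'
#' @param point world point \[m\]: 3-vector or n-by-3 matrix.
#' @param magnets non-empty list of [magnet()] objects.
#' @return an object of class `field_sample`: list with `H` (n-by-3,
#'   \[A/m\]), `B` (n-by-3, \[T\], \eqn{\mu_0 H}, valid at exterior points)
#'   and `J` (n-by-3-by-3, \[A/m^2\]).
#' @export
total_field <- function(point, magnets) {
  if (inherits(magnets, "magnet")) magnets <- list(magnets)
  if (!is.list(magnets) || length(magnets) == 0) {
    stop("total_field: 'magnets' must be a non-empty list of magnet objects")
  }
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  n <- nrow(pts)
  H <- matrix(0, n, 3)
  J <- array(0, c(n, 3, 3))
  flagged <- logical(n)
  for (m in magnets) {
    fe <- field_eval(pts, m, jac = TRUE)
    H <- H + fe$H
    J <- J + fe$J
    flagged <- flagged | fe$singular_offset
  }
  structure(list(H = H, B = MU0 * H, J = J, singular_offset = flagged),
            class = "field_sample")
}

#' Magnetophoretic force on a magnetizable microparticle
#'
#' The force on a small magnetizable sphere in a field gradient is
#' \deqn{F_m = \mu_0 V_p \frac{3\chi_p}{\chi_p + 3} (H\cdot\nabla)H,}
#' which for the high susceptibilities of magnetite microparticles
#' saturates at \deqn{F_m = 3 \mu_0 V_p (H\cdot\nabla)H.}
#' Here \eqn{((H\cdot\nabla)H)_i = \sum_j H_j \partial H_i/\partial x_j}.
#'
#' @param sample a `field_sample` from [total_field()] (n points).
#' @param props a [particle_props()].
#' @param mode `"high_chi"` (default, the saturated limit) or `"exact"`
#'   (requires `props$susceptibility`).
#' @return force \[N\]: n-by-3 matrix (a 3-vector for a single point).
#' @export
magnetophoretic_force <- function(sample, props, mode = c("high_chi", "exact")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sample, "field_sample"), inherits(props, "particle_props"))
  if (mode == "exact") {
    chi <- props$susceptibility
    if (is.null(chi)) stop("magnetophoretic_force: exact mode requires susceptibility")
    if (chi <= -3) stop("magnetophoretic_force: susceptibility must exceed -3 (pole)")
    fac <- 3 * chi / (chi + 3)
  } else {
    fac <- 3
  }
  H <- sample$H; J <- sample$J
  n <- nrow(H)
  JH <- matrix(0, n, 3)
  for (i in 1:3) {
    JH[, i] <- J[, i, 1] * H[, 1] + J[, i, 2] * H[, 2] + J[, i, 3] * H[, 3]
  }
  F <- MU0 * props$volume * fac * JH
  if (n == 1L) as.vector(F) else F
}

#' Magnet layouts of the three delivery protocols
#'
#' Two laboratory NdFeB magnets placed against the nasal septum:
#' magnet 1 is a 1 cm x 1 cm x 4 cm bar, magnet 2 a 5 cm x 3 cm x 0.2 cm
#' flat plate.  Protocol 1 places the bar with its long axis parallel to
#' the septum along the anterior-posterior (y) direction; Protocol 2 is the
#' same bar rotated by 90 degrees about the septum normal (long axis
#' superior-inferior); Protocol 3 places the flat magnet horizontally flat
#' against the septum.  All magnet centers sit at distance `d` from the
#' sagittal reference plane (x = 0), on the negative-x side, and all share
#' the remanence vector (0, 0.771, 0.919) T in the world frame.
#'
#' Default in-plane centers position the bar beside the vestibule/nasal
#' valve and the plate across the main passage of the default surrogate;
#' both can be overridden for other geometries.
#'
#' @param protocol 1, 2 or 3.
#' @param d distance of the magnet center from the sagittal plane \[m\]
#'   (default 0.005, the septum-to-nose-surface distance).
#' @param center_yz optional length-2 override of the magnet center's
#'   (y, z) position \[m\].
#' @return a list with a single [magnet()] (layouts are lists so that
#'   superposed arrangements can be passed anywhere a layout is accepted).
#' @export
protocol_layout <- function(protocol, d = 0.005, center_yz = NULL) {
  if (!length(protocol) == 1 || !protocol %in% c(1, 2, 3)) {
    stop("protocol_layout: protocol must be 1, 2 or 3")
  }
  rot90x <- rbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0)) # +90 deg about x
  if (protocol == 1) {
    yz <- if (is.null(center_yz)) c(0.010, 0.025) else center_yz
    m <- magnet(center = c(-d, yz[1], yz[2]),
                half_lengths = c(0.005, 0.020, 0.005), rotation = diag(3))
  } else if (protocol == 2) {
    yz <- if (is.null(center_yz)) c(0.010, 0.025) else center_yz
    m <- magnet(center = c(-d, yz[1], yz[2]),
                half_lengths = c(0.005, 0.020, 0.005), rotation = rot90x)
  } else {
    yz <- if (is.null(center_yz)) c(0.035, 0.025) else center_yz
    m <- magnet(center = c(-d, yz[1], yz[2]),
                half_lengths = c(0.001, 0.025, 0.015), rotation = diag(3))
  }
  list(m)
}

#' Map of the magnetic flux-density gradient magnitude
#'
#' Evaluates \eqn{|\nabla |B||} on the domain grid (or a supplied grid) in
#' the sagittal plane `x = x_plane`, using the analytic identity
#' \eqn{\nabla|B| = J_B^T B / |B|}.  These maps locate the regions of
#' strong magnetophoretic force; for a bar magnet the maximum sits adjacent
#' to a magnet edge/pole face.
#'
#' @param domain a `nasal_domain` (supplies the default grid).
#' @param magnets magnet layout (list of [magnet()]).
#' @param grid optional list with numeric vectors `y`, `z` \[m\]; defaults
#'   to the domain cell centers.  Must lie within the domain bounding box.
#' @param x_plane sagittal evaluation offset \[m\].
#' @return matrix `length(y)` x `length(z)` of \eqn{|\nabla|B||} \[T/m\],
#'   class `gradB_map`, with the grid attached as attributes.
#' @export
gradB_map <- function(domain, magnets, grid = NULL, x_plane = 0.005) {
  if (is.null(grid)) grid <- list(y = domain$grid$yc, z = domain$grid$zc)
  bb <- domain$grid$bbox
  if (min(grid$y) < bb[1] - 1e-9 || max(grid$y) > bb[2] + 1e-9 ||
      min(grid$z) < bb[3] - 1e-9 || max(grid$z) > bb[4] + 1e-9) {
    stop("gradB_map: grid extends outside the domain bounding box")
  }
  pts <- cbind(x_plane, rep(grid$y, times = length(grid$z)),
               rep(grid$z, each = length(grid$y)))
  fs <- total_field(pts, magnets)
  B <- fs$B
  JB <- MU0 * fs$J
  Bn <- sqrt(rowSums(B^2))
  Bn[Bn == 0] <- Inf # |B| = 0: |grad|B|| of an identically null field is 0
  g2 <- numeric(nrow(pts))
  for (j in 1:3) {
    gj <- B[, 1] * JB[, 1, j] + B[, 2] * JB[, 2, j] + B[, 3] * JB[, 3, j]
    g2 <- g2 + (gj / Bn)^2
  }
  out <- matrix(sqrt(g2), nrow = length(grid$y))
  structure(out, y = grid$y, z = grid$z, x_plane = x_plane,
            class = c("gradB_map", "matrix"))
}
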