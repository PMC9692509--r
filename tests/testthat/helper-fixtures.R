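# shared fixtures, computed once per test run and cached
.fix <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fix)) assign(name, force(expr), envir = .fix)
  get(name, envir = .fix)
}

default_domain <- function() memo("dom", build_surrogate(surrogate_params()))

default_flow <- function() memo("flow", solve_flow(default_domain(), flow_params()))

# Stokes-regime straight channel for the plane-Poiseuille oracle
poiseuille_flow <- function() {
  memo("pois", {
    dom <- channel_domain(length = 2, width = 1, grid_spacing = 1 / 64)
    list(dom = dom,
         flow = solve_flow(dom, flow_params(density = 1, viscosity = 1, u_in = 1)))
  })
}

# physical-scale straight channel for magnet-free escape runs
fast_channel <- function() {
  memo("fastch", {
    dom <- channel_domain(length = 0.08, width = 0.01, grid_spacing = 0.01 / 16)
    list(dom = dom, flow = solve_flow(dom, flow_params(u_in = 0.5)))
  })
}

# slow channel with a bar magnet under the lower wall: the magnetophoretic
# drift (~0.017 m/s toward z = 0) dominates the weak axial flow near the
# release line, so every particle deposits on the magnet-side wall
magnet_fixture <- function() {
  memo("magfix", {
    dom <- channel_domain(length = 0.03, width = 0.01, grid_spacing = 0.01 / 16)
    flow <- solve_flow(dom, flow_params(u_in = 0.05))
    mag <- list(magnet(center = c(0, 0.015, -0.012),
                       half_lengths = c(0.005, 0.005, 0.005),
                       remanence = c(0, 0, 0.3)))
    rel <- release_line(release_spec(count = 12, start = c(0.002, 0.002),
                                     end = c(0.002, 0.0035)), dom)
    list(dom = dom, flow = flow, mag = mag, rel = rel)
  })
}

magnet_fixture_traced <- function(dt_factor = 20) {
  nm <- paste0("magfix_ts", dt_factor)
  memo(nm, {
    fx <- magnet_fixture()
    trace_particles(fx$rel, fx$flow, fx$mag, fx$dom, particle_props(),
                    trace_config(dt_factor = dt_factor))
  })
}

protocol_comparison_default <- function() {
  memo("cmp_default", {
    compare_protocols(domain = default_domain(), flow = default_flow())
  })
}

# independent brute-force surface-integration oracle for the cuboid field:
# Gauss-Legendre quadrature of the magnetic surface-charge (Coulombian)
# integral over each charged face
oracle_cuboid_H <- function(p, m, ngl = 144) {
  gl <- pracma::gaussLegendre(ngl, -1, 1)
  Rm <- m$rotation
  prel <- as.vector(crossprod(Rm, p - m$center))
  Mb <- as.vector(crossprod(Rm, m$remanence)) / (4e-7 * pi)
  hl <- m$half_lengths
  H <- c(0, 0, 0)
  axmap <- list(c(2, 3), c(3, 1), c(1, 2))
  for (k in 1:3) {
    if (Mb[k] == 0) next
    iu <- axmap[[k]][1]; iv <- axmap[[k]][2]
    for (sgn in c(1, -1)) {
      sigma <- sgn * Mb[k]
      up <- gl$x * hl[iu]; wu <- gl$w * hl[iu]
      vp <- gl$x * hl[iv]; wv <- gl$w * hl[iv]
      UU <- outer(up, rep(1, ngl)); VV <- outer(rep(1, ngl), vp)
      WW <- outer(wu, wv)
      du <- prel[iu] - UU; dv <- prel[iv] - VV; dw <- prel[k] - sgn * hl[k]
      R3 <- (du^2 + dv^2 + dw^2)^1.5
      H[iu] <- H[iu] + sigma / (4 * pi) * sum(WW * du / R3)
      H[iv] <- H[iv] + sigma / (4 * pi) * sum(WW * dv / R3)
      H[k] <- H[k] + sigma / (4 * pi) * sum(WW * dw / R3)
    }
  }
  as.vector(Rm %*% H)
}

fd_jacobian <- function(p, m, h = 1e-6) {
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    e <- rep(0, 3); e[j] <- h
    J[, j] <- (cuboid_H(p + e, m) - cuboid_H(p - e, m)) / (2 * h)
  }
  J
}

random_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3)))
}

# programmatic 12-facet unit cube surface
cube_stl <- function() {
  tri <- list()
  add <- function(a, b, c) tri[[length(tri) + 1]] <<- rbind(a, b, c)
  v <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  q <- function(i1, i2, i3, i4) {
    a <- as.numeric(v[i1, ]); b <- as.numeric(v[i2, ])
    cc <- as.numeric(v[i3, ]); d <- as.numeric(v[i4, ])
    add(a, b, cc); add(a, cc, d)
  }
  q(1, 2, 4, 3); q(5, 7, 8, 6) # z faces
  q(1, 5, 6, 2); q(3, 4, 8, 7) # y faces
  q(1, 3, 7, 5); q(2, 6, 8, 4) # x faces
  facets <- array(0, c(12, 3, 3))
  for (i in 1:12) facets[i, , ] <- tri[[i]]
  structure(list(facets = facets, normals = matrix(0, 12, 3), n_facets = 12L),
            class = "stl_surface")
}
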