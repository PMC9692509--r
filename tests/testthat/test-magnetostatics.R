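MU0 <- 4e-7 * pi

test_that("cube center field equals the -M/3 demagnetizing value", {
  m <- magnet(center = c(0, 0, 0), half_lengths = c(0.01, 0.01, 0.01),
              remanence = c(0, 0, 1.2))
  M <- 1.2 / MU0
  H <- cuboid_H(c(0, 0, 0), m)
  expect_lt(abs(H[3] + M / 3) / (M / 3), 1e-6)
  expect_lt(max(abs(H[1:2])), 1e-6 * M)
})

test_that("cuboid field matches the surface-integration oracle at exterior points", {
  skip_if_not_installed("pracma")
  set.seed(7)
  m1 <- magnet(center = c(0, 0, 0), half_lengths = c(0.005, 0.02, 0.005),
               remanence = c(0, 0.771, 0.919))
  m2 <- magnet(center = c(0.01, -0.02, 0.005),
               half_lengths = c(0.001, 0.025, 0.015),
               rotation = random_rotation(), remanence = c(0, 0.771, 0.919))
  for (m in list(m1, m2)) {
    for (rep in 1:4) {
      # exterior point at least ~1 mm beyond every face
      dirn <- stats::rnorm(3); dirn <- dirn / sqrt(sum(dirn^2))
      p <- m$center + dirn * (max(m$half_lengths) + stats::runif(1, 0.002, 0.02))
      Ha <- cuboid_H(p, m)
      Ho <- oracle_cuboid_H(p, m)
      expect_lt(max(abs(Ha - Ho)) / max(abs(Ho)), 1e-6)
    }
  }
})

test_that("mirror symmetry of the field through a magnet symmetry plane", {
  m <- magnet(center = c(0, 0, 0), half_lengths = c(0.005, 0.02, 0.005),
              remanence = c(0, 0, 1.2))
  p <- c(0.013, 0.007, 0.011)
  pm <- c(-p[1], p[2], p[3]) # mirror through the x = 0 plane (M along z)
  H <- cuboid_H(p, m); Hm <- cuboid_H(pm, m)
  expect_equal(as.numeric(Hm), c(-H[1], H[2], H[3]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("far field approaches the point dipole within 1% at 10 edge lengths", {
  m <- magnet(center = c(0, 0, 0), half_lengths = c(0.005, 0.02, 0.005),
              remanence = c(0, 0, 1.2))
  L <- 2 * max(m$half_lengths)
  mom <- (1.2 / MU0) * prod(2 * m$half_lengths)
  for (rhat in list(c(0, 0, 1), c(1, 0, 0), c(0, 1, 1) / sqrt(2))) {
    r <- 10 * L
    p <- rhat * r
    Hd <- mom / (4 * pi * r^3) * (3 * sum(rhat * c(0, 0, 1)) * rhat - c(0, 0, 1))
    H <- cuboid_H(p, m)
    expect_lt(max(abs(H - Hd)) / max(abs(Hd)), 0.01)
  }
})

test_that("analytic Jacobian matches central finite differences", {
  set.seed(11)
  m <- magnet(center = c(0.002, -0.004, 0.001),
              half_lengths = c(0.005, 0.02, 0.005),
              rotation = random_rotation(), remanence = c(0, 0.771, 0.919))
  for (rep in 1:4) {
    dirn <- stats::rnorm(3); dirn <- dirn / sqrt(sum(dirn^2))
    p <- m$center + dirn * (max(m$half_lengths) + stats::runif(1, 0.003, 0.02))
    Ja <- grad_H(p, m)
    Jf <- fd_jacobian(p, m)
    expect_lt(max(abs(Ja - Jf)) / max(abs(Jf)), 1e-4)
  }
})

test_that("exterior field is curl- and divergence-free at 100 random points", {
  set.seed(3)
  m <- magnet(center = c(0, 0, 0), half_lengths = c(0.005, 0.02, 0.005),
              remanence = c(0, 0.771, 0.919), rotation = random_rotation())
  n <- 0
  while (n < 100) {
    p <- stats::runif(3, -0.08, 0.08)
    pb <- abs(as.vector(crossprod(m$rotation, p - m$center)))
    if (all(pb < m$half_lengths + 5e-4)) next # skip interior/near-face points
    J <- grad_H(p, m)
    s <- max(abs(J))
    expect_lt(max(abs(J - t(J))) / s, 1e-6)
    expect_lt(abs(sum(diag(J))) / s, 1e-6)
    n <- n + 1
  }
})

test_that("Jacobian magnitude decays with the dipole r^-4 law", {
  m <- magnet(center = c(0, 0, 0), half_lengths = c(0.005, 0.02, 0.005),
              remanence = c(0, 0, 1.2))
  L <- 2 * max(m$half_lengths)
  r <- exp(seq(log(10 * L), log(100 * L), length.out = 12))
  Jn <- vapply(r, function(ri) max(abs(grad_H(c(0.3, 0.5, 0.8) / sqrt(1.38) * ri, m))),
               numeric(1))
  slope <- stats::coef(stats::lm(log(Jn) ~ log(r)))[2]
  expect_lt(abs(slope + 4), 0.05)
})

test_that("total_field superposes magnets linearly", {
  m1 <- magnet(center = c(0, 0, 0), half_lengths = c(0.005, 0.02, 0.005))
  m2 <- magnet(center = c(0.03, 0.01, -0.02), half_lengths = c(0.001, 0.025, 0.015))
  p <- c(0.02, 0.04, 0.03)
  fs <- total_field(p, list(m1, m2))
  expect_equal(as.vector(fs$H), cuboid_H(p, m1) + cuboid_H(p, m2),
               tolerance = 1e-12, ignore_attr = TRUE)
  f1 <- total_field(p, list(m1))
  expect_equal(as.vector(f1$H), as.vector(cuboid_H(p, m1)),
               tolerance = 1e-14, ignore_attr = TRUE)
  expect_error(total_field(p, list()), "non-empty")
})

test_that("opposite coincident magnets cancel", {
  m1 <- magnet(center = c(0, 0, 0), half_lengths = c(0.005, 0.02, 0.005),
               remanence = c(0, 0.771, 0.919))
  m2 <- magnet(center = c(0, 0, 0), half_lengths = c(0.005, 0.02, 0.005),
               remanence = -c(0, 0.771, 0.919))
  p <- c(0.02, 0.01, 0.015)
  fs <- total_field(p, list(m1, m2))
  scale <- max(abs(cuboid_H(p, m1)))
  expect_lt(max(abs(fs$H)) / scale, 1e-10)
})

test_that("doubling the remanence doubles H and quadruples the force", {
  m1 <- magnet(center = c(0, 0, -0.02), half_lengths = c(0.005, 0.005, 0.005),
               remanence = c(0, 0, 0.6))
  m2 <- magnet(center = c(0, 0, -0.02), half_lengths = c(0.005, 0.005, 0.005),
               remanence = c(0, 0, 1.2))
  p <- c(0.004, 0.003, 0.002)
  f1 <- total_field(p, list(m1)); f2 <- total_field(p, list(m2))
  expect_equal(2 * f1$H, f2$H, tolerance = 1e-12)
  pr <- particle_props()
  F1 <- magnetophoretic_force(f1, pr); F2 <- magnetophoretic_force(f2, pr)
  expect_equal(4 * F1, F2, tolerance = 1e-12)
})

test_that("edge-grazing points are evaluated at an offset and flagged, not fatal", {
  m <- magnet(center = c(0, 0, 0), half_lengths = c(0.01, 0.01, 0.01),
              remanence = c(0, 0, 1.2))
  p <- c(0.01, 0, 0.01) # exactly on an edge of the charged face
  H <- cuboid_H(p, m)
  expect_true(all(is.finite(H)))
  expect_true(any(attr(H, "singular_offset")))
})

test_that("protocol layouts reproduce the two lab magnets and their placement", {
  l1 <- protocol_layout(1); l2 <- protocol_layout(2); l3 <- protocol_layout(3)
  expect_length(l1, 1)
  expect_equal(sort(2 * l1[[1]]$half_lengths), c(0.01, 0.01, 0.04)) # 1x1x4 cm
  expect_equal(sort(2 * l3[[1]]$half_lengths), c(0.002, 0.03, 0.05)) # 5x3x0.2 cm
  # protocol 2 = protocol 1 rotated by 90 degrees about the septum normal
  rot90x <- rbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0))
  expect_equal(l2[[1]]$rotation, rot90x %*% l1[[1]]$rotation, tolerance = 1e-12)
  expect_equal(l2[[1]]$half_lengths, l1[[1]]$half_lengths)
  for (l in list(l1, l2, l3)) {
    expect_equal(l[[1]]$center[1], -0.005) # d = 5 mm from the sagittal plane
    expect_equal(l[[1]]$remanence, c(0, 0.771, 0.919))
  }
  expect_error(protocol_layout(4), "protocol")
})

test_that("|grad B| map vanishes in a null field and peaks at the magnet edge", {
  dom <- default_domain()
  # cancelling pair -> uniform (zero) field -> zero gradient map
  m1 <- magnet(center = c(-0.005, 0.01, 0.025), half_lengths = c(0.005, 0.02, 0.005))
  m2 <- magnet(center = c(-0.005, 0.01, 0.025), half_lengths = c(0.005, 0.02, 0.005),
               remanence = -c(0, 0.771, 0.919))
  g0 <- gradB_map(dom, list(m1, m2),
                  grid = list(y = seq(0.03, 0.05, 0.005), z = seq(0.02, 0.04, 0.005)))
  g1 <- gradB_map(dom, list(m1),
                  grid = list(y = seq(0.03, 0.05, 0.005), z = seq(0.02, 0.04, 0.005)))
  expect_lt(max(g0) / max(g1), 1e-8)
  # full-domain map: maximum adjacent to the bar-magnet edge projection
  gm <- gradB_map(dom, protocol_layout(1), x_plane = 0.0025)
  idx <- which(gm == max(gm), arr.ind = TRUE)[1, ]
  ymax <- attr(gm, "y")[idx[1]]; zmax <- attr(gm, "z")[idx[2]]
  # bar projection: y in [-0.01, 0.03], z in [0.02, 0.03]
  d_edge <- min(abs(ymax - 0.03), abs(zmax - 0.02), abs(zmax - 0.03))
  expect_lt(d_edge, 3 * dom$grid$h)
})

test_that("|grad B| map matches finite differences of |B| on a finer grid", {
  dom <- default_domain()
  mag <- protocol_layout(1)
  ys <- seq(0.025, 0.045, 0.002); zs <- seq(0.015, 0.035, 0.002)
  gm <- gradB_map(dom, mag, grid = list(y = ys, z = zs), x_plane = 0.0025)
  hh <- 0.001 # 2x finer sampling step for the oracle
  for (i in c(2, 5, 9)) {
    for (j in c(3, 7)) {
      p0 <- c(0.0025, ys[i], zs[j])
      Babs <- function(p) sqrt(sum(total_field(p, mag)$B^2))
      gy <- (Babs(p0 + c(0, hh, 0)) - Babs(p0 - c(0, hh, 0))) / (2 * hh)
      gz <- (Babs(p0 + c(0, 0, hh)) - Babs(p0 - c(0, 0, hh))) / (2 * hh)
      gx <- (Babs(p0 + c(hh, 0, 0)) - Babs(p0 - c(hh, 0, 0))) / (2 * hh)
      expect_lt(abs(gm[i, j] - sqrt(gx^2 + gy^2 + gz^2)) /
                  sqrt(gx^2 + gy^2 + gz^2), 0.05)
    }
  }
})
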