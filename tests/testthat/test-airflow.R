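test_that("straight channel recovers the plane-Poiseuille profile", {
  px <- poiseuille_flow()
  dom <- px$dom; fl <- px$flow
  zc <- dom$grid$zc
  prof <- sample_velocity(fl, cbind(1.75, zc))[, 1]
  exact <- 6 * 1 * zc * (1 - zc) # mean speed 1 -> parabola, peak 1.5
  expect_lt(abs(max(prof) - 1.5) / 1.5, 0.02)
  expect_lt(sqrt(sum((prof - exact)^2) / sum(exact^2)), 0.02)
})

test_that("global mass balance closes within 1%", {
  px <- poiseuille_flow()
  expect_lt(abs(px$flow$influx - px$flow$outflux) / px$flow$influx, 0.01)
  fl <- default_flow()
  expect_lt(abs(fl$influx - fl$outflux) / fl$influx, 0.01)
})

test_that("zero inflow yields the null solution", {
  dom <- channel_domain(length = 1, width = 1, grid_spacing = 1 / 16)
  fl <- solve_flow(dom, flow_params(density = 1, viscosity = 1, u_in = 0))
  expect_lt(max(abs(fl$uc)), 1e-12)
  expect_lt(max(abs(fl$wc)), 1e-12)
  expect_lt(max(fl$p) - min(fl$p), 1e-9)
})

test_that("no-slip and discrete incompressibility hold on the surrogate", {
  fl <- default_flow()
  dom <- default_domain()
  # sample just inside wall-adjacent cells along the olfactory roof
  olf <- dom$segments[dom$segments$label == "OLFACTORY", ]
  ymid <- (olf$y1 + olf$y2) / 2
  v_wall <- sample_velocity(fl, c(ymid, dom$params$passage_height - dom$grid$h / 2))
  v_mid <- sample_velocity(fl, c(ymid, dom$params$passage_height - dom$params$inlet_width / 2))
  expect_lt(sqrt(sum(v_wall^2)), 0.3 * sqrt(sum(v_mid^2))) # strong damping at the wall
  # sampling in the solid region blends to the zero wall value
  expect_lt(max(abs(sample_velocity(fl, c(ymid, 0.02), strict = FALSE))), 1e-12)
  expect_lt(fl$max_divergence, fl$params$tol * fl$params$u_in / dom$grid$h)
})

test_that("turbulent-regime inputs are rejected", {
  dom <- default_domain()
  expect_error(solve_flow(dom, flow_params(u_in = 5)), "laminar")
})

test_that("velocity sampling is bilinear: node identity, midpoint mean, linear exactness", {
  fl0 <- default_flow()
  g <- fl0$grid
  # synthetic flow field with a linear velocity profile on the same grid
  lin <- fl0
  yc <- matrix(g$yc, g$ny, g$nz); zc <- matrix(g$zc, g$ny, g$nz, byrow = TRUE)
  lin$uc <- 0.3 + 2 * yc - zc
  lin$wc <- -0.1 + yc + 4 * zc
  lin$mask <- matrix(TRUE, g$ny, g$nz)
  p_node <- c(g$yc[10], g$zc[20])
  expect_equal(sample_velocity(lin, p_node),
               c(lin$uc[10, 20], lin$wc[10, 20]), tolerance = 1e-14)
  p_mid <- c((g$yc[10] + g$yc[11]) / 2, g$zc[20])
  expect_equal(sample_velocity(lin, p_mid)[1],
               (lin$uc[10, 20] + lin$uc[11, 20]) / 2, tolerance = 1e-14)
  set.seed(9)
  pts <- cbind(runif(20, g$yc[2], g$yc[g$ny - 1]),
               runif(20, g$zc[2], g$zc[g$nz - 1]))
  got <- sample_velocity(lin, pts)
  expect_equal(got[, 1], 0.3 + 2 * pts[, 1] - pts[, 2], tolerance = 1e-12)
  expect_equal(got[, 2], -0.1 + pts[, 1] + 4 * pts[, 2], tolerance = 1e-12)
  # strict sampling refuses points outside the fluid
  expect_error(sample_velocity(fl0, c(0.05, 0.005)), "outside")
})

test_that("flow speed ordering: olfactory roof < mid-passage < nasopharynx outlet", {
  dom <- default_domain(); fl <- default_flow()
  p <- dom$params
  olf <- dom$segments[dom$segments$label == "OLFACTORY", ]
  ymid <- (olf$y1 + olf$y2) / 2
  v_roof <- sqrt(sum(sample_velocity(fl, c(ymid, p$passage_height - 2 * p$grid_spacing))^2))
  v_mid <- sqrt(sum(sample_velocity(fl, c(p$passage_length / 2,
                                          p$passage_height - p$inlet_width / 2))^2))
  v_out <- sqrt(sum(sample_velocity(fl, c(p$passage_length - p$outlet_width / 2,
                                          3 * p$grid_spacing))^2))
  expect_lt(v_roof, v_mid)
  expect_lt(v_mid, v_out)
})

test_that("grid refinement changes the peak passage speed by less than 5%", {
  pars_c <- surrogate_params(passage_length = 0.04, passage_height = 0.03,
                             inlet_width = 0.008, outlet_width = 0.005,
                             bend_radius = 0.004, grid_spacing = 0.0008)
  pars_f <- surrogate_params(passage_length = 0.04, passage_height = 0.03,
                             inlet_width = 0.008, outlet_width = 0.005,
                             bend_radius = 0.004, grid_spacing = 0.0004)
  fc <- solve_flow(build_surrogate(pars_c), flow_params())
  ff <- solve_flow(build_surrogate(pars_f), flow_params())
  pk <- function(f) max(sqrt(f$uc^2 + f$wc^2))
  expect_lt(abs(pk(fc) - pk(ff)) / pk(ff), 0.05)
})
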