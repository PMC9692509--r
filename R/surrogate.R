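#' Parameters of the synthetic sagittal nasal-passage geometry
#'
#' The surrogate emulates, in the sagittal (yz) plane, the gross features of
#' a segmented adult nasal airway: a nostril inlet at the bottom of an
#' anterior vestibule, a bend into the main passage running under the
#' olfactory roof, and a nasopharynx duct descending to the outlet.  It is an
#' idealized channel, not an anatomical replica; the olfactory segment sits
#' on the superior roof and occupies a prescribed fraction of the total wall
#' length (8% by default, matching the areal fraction of the olfactory
#' epithelium in the nasal cavity).
#'
#' @param inlet_width nostril (inlet) opening width \[m\].  The default
#'   0.01 m is of the order of a single nostril dimension and preserves the
#'   0.5 m/s mean inlet speed used for the airflow problem.
#' @param passage_height inferior-to-superior extent of the geometry \[m\].
#' @param passage_length anterior-to-posterior extent \[m\].
#' @param olfactory_fraction fraction of the total wall length (inlet and
#'   outlet openings excluded) labeled OLFACTORY.
#' @param bend_radius chamfer length rounding the two inner corners of the
#'   channel \[m\] (a 45-degree chamfer stands in for the curved vestibule).
#' @param grid_spacing lattice spacing of the regular yz grid \[m\]; must
#'   resolve `inlet_width` by at least 8 cells.
#' @param outlet_width nasopharynx (outlet) duct width \[m\].  Narrower than
#'   the inlet so that, by mass conservation, the flow accelerates toward
#'   the nasopharynx as observed in airway simulations.
#' @param septum_offset distance from the sagittal reference (septum) plane
#'   at which magnet centers are placed \[m\].
#'
#' @return an object of class `surrogate_params` (a validated list).
#' @seealso [build_surrogate()]
#' @export
surrogate_params <- function(inlet_width = 0.01,
                             passage_height = 0.05,
                             passage_length = 0.07,
                             olfactory_fraction = 0.08,
                             bend_radius = 0.005,
                             grid_spacing = 0.001,
                             outlet_width = 0.006,
                             septum_offset = 0.005) {
  p <- list(
    inlet_width = inlet_width, passage_height = passage_height,
    passage_length = passage_length, olfactory_fraction = olfactory_fraction,
    bend_radius = bend_radius, grid_spacing = grid_spacing,
    outlet_width = outlet_width, septum_offset = septum_offset
  )
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]])) {
      stop("surrogate_params: field '", nm, "' must be a finite numeric scalar")
    }
  }
  if (p$olfactory_fraction <= 0 || p$olfactory_fraction >= 1) {
    stop("surrogate_params: olfactory_fraction must lie strictly in (0, 1)")
  }
  if (p$inlet_width / p$grid_spacing < 8) {
    stop("surrogate_params: grid_spacing too coarse; inlet_width must span >= 8 cells")
  }
  if (any(unlist(p[c("inlet_width", "passage_height", "passage_length",
                     "grid_spacing", "outlet_width")]) <= 0)) {
    stop("surrogate_params: lengths must be positive")
  }
  if (p$bend_radius < 0) stop("surrogate_params: bend_radius must be >= 0")
  if (p$inlet_width + p$outlet_width + 2 * p$bend_radius >= p$passage_length) {
    stop("surrogate_params: ducts and chamfers do not fit in passage_length")
  }
  if (p$inlet_width + p$bend_radius >= p$passage_height) {
    stop("surrogate_params: passage duct does not fit in passage_height")
  }
  structure(p, class = "surrogate_params")
}

REGION_LABELS <- c("OLFACTORY", "WALL", "INLET", "OUTLET")

# ordered closed polygon of the channel: inlet duct up the anterior wall,
# horizontal passage under the roof, nasopharynx duct down to the outlet.
surrogate_polygon <- function(p) {
  w <- p$inlet_width; W <- p$outlet_width
  Ly <- p$passage_length; Lz <- p$passage_height
  r <- p$bend_radius
  # boundary walk; labels apply to the segment *leaving* each vertex
  v <- rbind(
    c(0, 0),               # inlet left corner -> up anterior wall
    c(0, Lz),              # roof start
    c(Ly, Lz),             # roof end -> down posterior wall
    c(Ly, 0),              # outlet right corner -> OUTLET
    c(Ly - W, 0),          # up inner posterior wall
    c(Ly - W, Lz - w - r), # chamfer
    c(Ly - W - r, Lz - w), # inner passage floor
    c(w + r, Lz - w),      # chamfer
    c(w, Lz - w - r),      # down inner anterior wall
    c(w, 0)                # -> INLET back to start
  )
  labels <- c("WALL", "WALL", "WALL", "OUTLET", "WALL", "WALL", "WALL",
              "WALL", "WALL", "INLET")
  list(vertices = v, labels = labels)
}

seg_lengths <- function(segs) {
  sqrt((segs$y2 - segs$y1)^2 + (segs$z2 - segs$z1)^2)
}

# split the roof segment (z = Lz) into WALL | OLFACTORY | WALL
place_olfactory <- function(segs, p) {
  wall_idx <- segs$label %in% c("WALL", "OLFACTORY")
  total_wall <- sum(segs$length[wall_idx])
  # relabeling roof wall as olfactory keeps the total wall length fixed,
  # so the target olfactory length is simply fraction * total wall length
  olf_len <- p$olfactory_fraction * total_wall
  roof <- which(segs$z1 == p$passage_height & segs$z2 == p$passage_height)
  stopifnot(length(roof) == 1L)
  roof_len <- segs$length[roof]
  margin <- p$grid_spacing
  if (olf_len > roof_len - 2 * margin) {
    stop("build_surrogate: olfactory_fraction too large for the roof segment")
  }
  # centered slightly posterior (the olfactory cleft is posterior-superior)
  ctr <- 0.6 * p$passage_length
  lo <- ctr - olf_len / 2
  hi <- ctr + olf_len / 2
  lo <- max(lo, segs$y1[roof] + margin)
  hi <- lo + olf_len
  if (hi > segs$y2[roof] - margin) {
    hi <- segs$y2[roof] - margin
    lo <- hi - olf_len
  }
  Lz <- p$passage_height
  pieces <- data.frame(
    y1 = c(segs$y1[roof], lo, hi), z1 = Lz,
    y2 = c(lo, hi, segs$y2[roof]), z2 = Lz,
    label = c("WALL", "OLFACTORY", "WALL"),
    stringsAsFactors = FALSE
  )
  pieces$length <- seg_lengths(pieces)
  out <- rbind(segs[seq_len(roof - 1L), ], pieces,
               segs[seq(roof + 1L, nrow(segs)), ])
  out$length <- seg_lengths(out)
  rownames(out) <- NULL
  out
}

#' Build the surrogate nasal-passage domain
#'
#' Constructs the labeled 2-D channel geometry and its regular grid mask.
#' The result is deterministic for fixed parameters.
#'
#' @param params a [surrogate_params()] object.
#' @return an object of class `nasal_domain` with components
#'   `params`, `segments` (closed boundary polyline with one
#'   `RegionLabel` in `OLFACTORY`, `WALL`, `INLET`, `OUTLET` per segment),
#'   `grid` (cell size `h`, cell counts `ny`, `nz`, center coordinates
#'   `yc`, `zc`), `mask` (logical ny-by-nz matrix of fluid cells) and
#'   `wall_lengths` (total boundary length per label \[m\]).
#' @examples
#' dom <- build_surrogate(surrogate_params())
#' dom$wall_lengths["OLFACTORY"] / sum(dom$wall_lengths[c("OLFACTORY", "WALL")])
#' @export
build_surrogate <- function(params) {
  if (!inherits(params, "surrogate_params")) params <- do.call(surrogate_params, params)
  p <- params
  poly <- surrogate_polygon(p)
  v <- poly$vertices
  n <- nrow(v)
  nxt <- c(seq(2, n), 1L)
  segs <- data.frame(
    y1 = v[, 1], z1 = v[, 2], y2 = v[nxt, 1], z2 = v[nxt, 2],
    label = poly$labels, stringsAsFactors = FALSE
  )
  segs$length <- seg_lengths(segs)
  segs <- place_olfactory(segs, p)

  h <- p$grid_spacing
  ny <- round(p$passage_length / h)
  nz <- round(p$passage_height / h)
  yc <- (seq_len(ny) - 0.5) * h
  zc <- (seq_len(nz) - 0.5) * h
  pts <- cbind(rep(yc, times = nz), rep(zc, each = ny))
  inside <- point_in_polygon(pts, segs)
  mask <- matrix(inside, nrow = ny, ncol = nz)

  wl <- vapply(REGION_LABELS, function(l) sum(segs$length[segs$label == l]),
               numeric(1))
  dom <- structure(
    list(params = p, segments = segs, mask = mask,
         grid = list(h = h, ny = ny, nz = nz, yc = yc, zc = zc,
                     bbox = c(0, p$passage_length, 0, p$passage_height)),
         wall_lengths = wl),
    class = "nasal_domain"
  )
  validate_domain(dom)
  dom
}

validate_domain <- function(dom) {
  segs <- dom$segments
  # closed curve: each segment's end is the next segment's start
  n <- nrow(segs)
  nxt <- c(seq(2, n), 1L)
  gap <- max(abs(segs$y2 - segs$y1[nxt]), abs(segs$z2 - segs$z1[nxt]))
  if (gap > 1e-12) stop("domain boundary is not a closed curve")
  if (sum(segs$label == "INLET") != 1L) stop("domain must have exactly one inlet segment")
  if (sum(segs$label == "OUTLET") != 1L) stop("domain must have exactly one outlet segment")
  wl <- dom$wall_lengths
  frac <- wl[["OLFACTORY"]] / (wl[["OLFACTORY"]] + wl[["WALL"]])
  tol <- dom$grid$h / sum(wl[c("OLFACTORY", "WALL")]) # one cell of wall length
  if (abs(frac - dom$params$olfactory_fraction) > tol) {
    stop("realized olfactory fraction deviates from request by more than one cell")
  }
  invisible(dom)
}

#' @export
print.nasal_domain <- function(x, ...) {
  p <- x$params
  cat("<nasal_domain> sagittal nasal-passage surrogate\n")
  cat(sprintf("  extent: %.3f m (y) x %.3f m (z), grid %d x %d (h = %.2g m)\n",
              p$passage_length, p$passage_height, x$grid$ny, x$grid$nz, x$grid$h))
  cat(sprintf("  fluid cells: %d; boundary segments: %d\n",
              sum(x$mask), nrow(x$segments)))
  wl <- x$wall_lengths
  cat(sprintf("  olfactory wall fraction: %.4f (requested %.4f)\n",
              wl[["OLFACTORY"]] / (wl[["OLFACTORY"]] + wl[["WALL"]]),
              p$olfactory_fraction))
  invisible(x)
}

# even-odd ray casting, vectorized over points (n x 2 matrix)
point_in_polygon <- function(pts, segs) {
  y <- pts[, 1]; z <- pts[, 2]
  inside <- logical(length(y))
  for (k in seq_len(nrow(segs))) {
    z1 <- segs$z1[k]; z2 <- segs$z2[k]
    y1 <- segs$y1[k]; y2 <- segs$y2[k]
    crosses <- (z1 > z) != (z2 > z)
    if (any(crosses)) {
      yint <- y1 + (z[crosses] - z1) / (z2 - z1) * (y2 - y1)
      flip <- yint > y[crosses]
      idx <- which(crosses)[flip]
      inside[idx] <- !inside[idx]
    }
  }
  inside
}

# distance from points (n x 2) to one segment
point_segment_distance <- function(pts, y1, z1, y2, z2) {
  dy <- y2 - y1; dz <- z2 - z1
  L2 <- dy * dy + dz * dz
  t <- ((pts[, 1] - y1) * dy + (pts[, 2] - z1) * dz) / L2
  t <- pmin(pmax(t, 0), 1)
  py <- y1 + t * dy
  pz <- z1 + t * dz
  list(dist = sqrt((pts[, 1] - py)^2 + (pts[, 2] - pz)^2),
       proj_y = py, proj_z = pz)
}

#' Signed distance to the domain boundary
#'
#' Distance from a point (or rows of a matrix of points) to the nearest
#' boundary segment, negative inside the fluid channel and positive outside.
#' Ties between equidistant segments are broken by the fixed label priority
#' OLFACTORY > WALL > INLET > OUTLET.
#'
#' @param domain a `nasal_domain`.
#' @param point numeric 2-vector `(y, z)` \[m\] or an n-by-2 matrix.
#' @param .projection also return the boundary projection point(s).
#' @return a data.frame with columns `distance` \[m\] and `label`, plus
#'   `proj_y`, `proj_z` when `.projection = TRUE`; one row per input point.
#' @export
signed_distance <- function(domain, point, .projection = FALSE) {
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  bb <- domain$grid$bbox
  tol <- 1e-9
  if (any(pts[, 1] < bb[1] - tol | pts[, 1] > bb[2] + tol |
          pts[, 2] < bb[3] - tol | pts[, 2] > bb[4] + tol)) {
    stop("signed_distance: point outside the domain bounding box")
  }
  segs <- domain$segments
  n <- nrow(pts)
  best <- rep(Inf, n)
  best_lab <- rep(NA_character_, n)
  best_py <- best_pz <- rep(NA_real_, n)
  prio <- match(segs$label, REGION_LABELS) # smaller = higher priority
  best_prio <- rep(Inf, n)
  for (k in seq_len(nrow(segs))) {
    d <- point_segment_distance(pts, segs$y1[k], segs$z1[k], segs$y2[k], segs$z2[k])
    closer <- d$dist < best - 1e-12
    tie <- abs(d$dist - best) <= 1e-12 & prio[k] < best_prio
    upd <- closer | tie
    if (any(upd)) {
      best[upd] <- d$dist[upd]
      best_lab[upd] <- segs$label[k]
      best_prio[upd] <- prio[k]
      best_py[upd] <- d$proj_y[upd]
      best_pz[upd] <- d$proj_z[upd]
    }
  }
  inside <- point_in_polygon(pts, segs)
  sgn <- ifelse(inside, -1, 1)
  out <- data.frame(distance = sgn * best, label = best_lab,
                    stringsAsFactors = FALSE)
  if (.projection) {
    out$proj_y <- best_py
    out$proj_z <- best_pz
  }
  out
}

#' Plot a domain with labeled boundary regions
#'
#' @param x a `nasal_domain`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.nasal_domain <- function(x, ...) {
  bb <- x$grid$bbox
  graphics::plot(NA, xlim = bb[1:2], ylim = bb[3:4], asp = 1,
                 xlab = "y [m] (anterior → posterior)",
                 ylab = "z [m] (inferior → superior)", ...)
  cols <- c(OLFACTORY = "red", WALL = "black", INLET = "blue", OUTLET = "darkgreen")
  segs <- x$segments
  graphics::segments(segs$y1, segs$z1, segs$y2, segs$z2,
                     col = cols[segs$label], lwd = 2)
  graphics::legend("bottomright", legend = names(cols), col = cols, lwd = 2,
                   cex = 0.7, bg = "white")
  invisible(x)
}
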