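#' Assemble and validate a run configuration
#'
#' A run configuration bundles every parameter of the pipeline: geometry,
#' air and solver settings, particle properties, tracing settings, the
#' protocols to run, and output options.  It round-trips losslessly
#' through YAML ([write_run_config()] / [read_run_config()]).
#'
#' @param geometry list of [surrogate_params()] arguments.
#' @param flow list of [flow_params()] arguments.
#' @param particle list of [particle_props()] arguments.
#' @param tracing list of [trace_config()] arguments.
#' @param protocols integer vector out of 1:3.
#' @param magnet_distance distance d of magnet centers from the sagittal
#'   plane \[m\].
#' @param count particles per protocol.
#' @param include_control also run the magnet-free baseline.
#' @param seed integer seed used for any optional release jitter.
#' @param write_figures write PNG figures (trajectory overlay, |grad B|
#'   maps) alongside the tables.
#' @return object of class `run_config`.
#' @export
run_config <- function(geometry = list(), flow = list(), particle = list(),
                       tracing = list(), protocols = 1:3,
                       magnet_distance = 0.005, count = 100,
                       include_control = FALSE, seed = NULL,
                       write_figures = FALSE) {
  cfg <- list(geometry = geometry, flow = flow, particle = particle,
              tracing = tracing, protocols = as.integer(protocols),
              magnet_distance = magnet_distance, count = as.integer(count),
              include_control = isTRUE(include_control), seed = seed,
              write_figures = isTRUE(write_figures))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  check_args <- function(args, fn, section) {
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad)) {
      stop("run_config: unknown field(s) in '", section, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    tryCatch(do.call(fn, args),
             error = function(e) stop("run_config: invalid '", section, "': ",
                                      conditionMessage(e), call. = FALSE))
  }
  check_args(cfg$geometry, surrogate_params, "geometry")
  check_args(cfg$flow, flow_params, "flow")
  check_args(cfg$particle, particle_props, "particle")
  check_args(cfg$tracing, trace_config, "tracing")
  if (!all(cfg$protocols %in% 1:3)) {
    stop("run_config: field 'protocols' must be a subset of 1:3", call. = FALSE)
  }
  if (cfg$count < 1) stop("run_config: field 'count' must be >= 1", call. = FALSE)
  if (!is.numeric(cfg$magnet_distance) || cfg$magnet_distance <= 0) {
    stop("run_config: field 'magnet_distance' must be a positive number",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("read_run_config: unknown top-level field(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  }
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Execute the full delivery pipeline
#'
#' Geometry, flow, per-protocol magnet fields, particle tracing and
#' deposition summary, with every artifact written to `out_dir`:
#' the domain (JSON + mask CSV), the flow field (CSV and VTK), per-protocol
#' terminal particle states and |grad B| maps (CSV), the comparison table
#' (CSV), summaries (JSON) and a provenance record (config, package
#' version, wall times, config hash).  Re-running the same configuration
#' into a fresh directory reproduces the same tables.
#'
#' @param cfg a [run_config()] (or path to a YAML file).
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages (written to `stderr`).
#' @return the `protocol_comparison`, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  validate_run_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  t_all <- Sys.time()

  say("building surrogate geometry")
  dom <- build_surrogate(do.call(surrogate_params, cfg$geometry))
  write_domain(dom, file.path(out_dir, "domain"))

  say("solving steady airflow")
  t0 <- Sys.time()
  fparams <- do.call(flow_params, cfg$flow)
  flow <- solve_flow(dom, fparams)
  t_flow <- as.numeric(Sys.time() - t0, units = "secs")
  write_flow(flow, file.path(out_dir, "flow"))

  props <- do.call(particle_props, cfg$particle)
  tconf <- do.call(trace_config, cfg$tracing)

  say("tracing protocols ", paste(cfg$protocols, collapse = ", "))
  t0 <- Sys.time()
  cmp <- compare_protocols(domain = dom, protocols = cfg$protocols,
                           props = props, config = tconf,
                           d = cfg$magnet_distance, count = cfg$count,
                           include_control = cfg$include_control, flow = flow)
  t_trace <- as.numeric(Sys.time() - t0, units = "secs")

  utils::write.csv(cmp$table, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  for (nm in names(cmp$states)) {
    utils::write.csv(cmp$states[[nm]],
                     file.path(out_dir, paste0("states_", nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    lapply(cmp$summaries, function(s) {
      list(n_released = s$n_released,
           status_counts = as.list(s$status_counts),
           region_counts = as.list(s$region_counts),
           delivery_efficiency_pct = s$delivery_efficiency)
    }),
    file.path(out_dir, "summaries.json"), auto_unbox = TRUE, digits = NA)

  for (p in cfg$protocols) {
    gm <- gradB_map(dom, protocol_layout(p, d = cfg$magnet_distance),
                    x_plane = protocol_release(p)$dx)
    utils::write.csv(as.data.frame(as.matrix(gm)),
                     file.path(out_dir, sprintf("gradB_protocol%d.csv", p)),
                     row.names = FALSE)
  }

  if (cfg$write_figures) {
    say("writing figures")
    write_figures(cmp, cfg, out_dir)
  }

  prov <- list(
    package = "magnasal",
    version = as.character(utils::packageVersion("magnasal")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(cfg),
    config_hash = config_hash(cfg),
    wall_times_s = list(flow = t_flow, tracing = t_trace,
                        total = as.numeric(Sys.time() - t_all, units = "secs"))
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("done")
  invisible(cmp)
}

# deterministic hash of the configuration (FNV-1a over its serialized form)
config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass(cfg), digits.d = 15)),
             collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_domain <- function(dom, stem) {
  jsonlite::write_json(
    list(params = unclass(dom$params),
         segments = dom$segments,
         wall_lengths = as.list(dom$wall_lengths),
         grid = dom$grid[c("h", "ny", "nz", "bbox")]),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(dom$mask * 1L), paste0(stem, "_mask.csv"),
                   row.names = FALSE)
  invisible(stem)
}

write_flow <- function(flow, stem) {
  g <- flow$grid
  df <- data.frame(y = rep(g$yc, times = g$nz), z = rep(g$zc, each = g$ny),
                   u = as.vector(flow$uc), w = as.vector(flow$wc),
                   p = as.vector(flow$p), fluid = as.vector(flow$mask) * 1L)
  utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  write_vtk_grid(paste0(stem, ".vtk"), g$yc, g$zc,
                 list(u = flow$uc, w = flow$wc, p = flow$p))
  invisible(stem)
}

#' Write scalar fields on a regular 2-D grid as legacy-ASCII VTK
#'
#' Minimal structured-points writer for visualization in ParaView and
#' friends; fields are written as point data on the yz grid (a single x
#' slab).
#'
#' @param path output file.
#' @param y,z grid coordinates \[m\].
#' @param fields named list of `length(y)` x `length(z)` matrices.
#' @return `path`, invisibly.
#' @export
write_vtk_grid <- function(path, y, z, fields) {
  con <- file(path, "w")
  on.exit(close(con))
  ny <- length(y); nz <- length(z)
  writeLines(c("# vtk DataFile Version 3.0",
               "magnasal field export", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", ny, nz),
               sprintf("ORIGIN %g %g 0", y[1], z[1]),
               sprintf("SPACING %g %g 1", if (ny > 1) y[2] - y[1] else 1,
                       if (nz > 1) z[2] - z[1] else 1),
               sprintf("POINT_DATA %d", ny * nz)), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(format(as.vector(fields[[nm]]), digits = 10, trim = TRUE,
                      scientific = TRUE), con)
  }
  invisible(path)
}

write_figures <- function(cmp, cfg, out_dir) {
  dom <- cmp$domain
  for (nm in names(cmp$states)) {
    grDevices::png(file.path(out_dir, paste0("trajectories_", nm, ".png")),
                   width = 900, height = 700)
    plot(dom, main = paste("terminal particle positions:", nm))
    st <- cmp$states[[nm]]
    cols <- c(DEPOSITED = "red", ESCAPED = "darkgreen", SUSPENDED = "orange")
    graphics::points(st$y, st$z, col = cols[st$status], pch = 16, cex = 0.6)
    grDevices::dev.off()
  }
  for (p in cfg$protocols) {
    gm <- gradB_map(dom, protocol_layout(p, d = cfg$magnet_distance),
                    x_plane = protocol_release(p)$dx)
    grDevices::png(file.path(out_dir, sprintf("gradB_protocol%d.png", p)),
                   width = 900, height = 700)
    graphics::image(attr(gm, "y"), attr(gm, "z"), as.matrix(gm),
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "y [m]", ylab = "z [m]", asp = 1,
                    main = sprintf("|grad B| [T/m], protocol %d", p))
    grDevices::dev.off()
  }
  invisible(out_dir)
}
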