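#' Olfactory delivery efficiency
#'
#' The percentage of released particles that deposit on the target region,
#' out of the total number released.  Particles still suspended at the
#' time cap count in the denominator but never the numerator (conservative
#' accounting).
#'
#' @param states terminal `particle_states` from [trace_particles()].
#' @param region target region label (default `"OLFACTORY"`).
#' @return efficiency in percent (0-100).
#' @export
delivery_efficiency <- function(states, region = "OLFACTORY") {
  if (any(states$status == "IN_FLIGHT")) {
    stop("delivery_efficiency: run incomplete, IN_FLIGHT particles present")
  }
  n <- nrow(states)
  if (n == 0) stop("delivery_efficiency: no particles")
  100 * sum(states$status == "DEPOSITED" & states$label == region,
            na.rm = TRUE) / n
}

#' Regional deposition summary
#'
#' Histogram of terminal particle fates: counts per status and, for
#' deposited particles, per boundary region (mapped through the domain's
#' nearest-label signed distance).  Enforces conservation
#' (DEPOSITED + ESCAPED + SUSPENDED = N).
#'
#' @param states terminal `particle_states`.
#' @param domain the `nasal_domain` the particles were traced in.
#' @return object of class `deposition_summary`: list with `n_released`,
#'   `status_counts`, `region_counts` (deposition counts per label),
#'   `delivery_efficiency` (percent; `NA` with a flag for an empty run).
#' @export
deposition_summary <- function(states, domain) {
  if (any(states$status == "IN_FLIGHT")) {
    stop("deposition_summary: run incomplete, IN_FLIGHT particles present")
  }
  n <- nrow(states)
  status_counts <- c(DEPOSITED = sum(states$status == "DEPOSITED"),
                     ESCAPED = sum(states$status == "ESCAPED"),
                     SUSPENDED = sum(states$status == "SUSPENDED"))
  if (sum(status_counts) != n) {
    stop("deposition_summary: status counts do not sum to the released count")
  }
  dep <- states[states$status == "DEPOSITED", , drop = FALSE]
  if (nrow(dep)) {
    # verify every deposited particle maps to a boundary segment
    sd <- signed_distance(domain, cbind(dep$y, dep$z))
    tol <- domain$grid$h + 1e-9
    off <- which(abs(sd$distance) > tol)
    if (length(off)) {
      stop("deposition_summary: deposited particles further than one cell from ",
           "any boundary at ids ", paste(dep$id[off], collapse = ", "))
    }
    region_counts <- vapply(REGION_LABELS, function(l) sum(dep$label == l),
                            numeric(1))
  } else {
    region_counts <- stats::setNames(numeric(length(REGION_LABELS)), REGION_LABELS)
  }
  eff <- if (n > 0) 100 * region_counts[["OLFACTORY"]] / n else NA_real_
  structure(list(n_released = n, status_counts = status_counts,
                 region_counts = region_counts,
                 delivery_efficiency = eff,
                 empty = n == 0),
            class = "deposition_summary")
}

#' @export
print.deposition_summary <- function(x, ...) {
  cat("<deposition_summary>", x$n_released, "particles released\n")
  print(x$status_counts)
  cat("deposited per region:\n")
  print(x$region_counts)
  cat(sprintf("olfactory delivery efficiency: %s\n",
              if (is.na(x$delivery_efficiency)) "undefined (no particles)"
              else sprintf("%.1f%%", x$delivery_efficiency)))
  invisible(x)
}

#' Run and compare the three magnet protocols
#'
#' Full pipeline on one shared domain and flow field (the airflow is
#' magnet-independent, so it is solved once): for each requested protocol,
#' build the magnet layout and release line, trace the particles, and
#' summarize the deposition.  An optional magnet-free control row gives the
#' purely aerodynamic baseline.
#'
#' @param domain a `nasal_domain` (default: [build_surrogate()] of the
#'   default [surrogate_params()]).
#' @param protocols integer vector out of 1:3.
#' @param fparams a [flow_params()].
#' @param props a [particle_props()].
#' @param config a [trace_config()].
#' @param d magnet distance from the sagittal plane \[m\].
#' @param count particles per protocol.
#' @param include_control also run a magnet-free release (Protocol 3 line).
#' @param flow optional precomputed `flow_field` for `domain`.
#' @return object of class `protocol_comparison`: list with `table` (one
#'   row per protocol: efficiency plus status and per-region counts),
#'   `summaries`, `states`, `flow` and `domain`.
#' @export
compare_protocols <- function(domain = build_surrogate(surrogate_params()),
                              protocols = 1:3,
                              fparams = flow_params(),
                              props = particle_props(),
                              config = trace_config(),
                              d = 0.005, count = 100,
                              include_control = FALSE, flow = NULL) {
  stopifnot(all(protocols %in% 1:3))
  if (is.null(flow)) flow <- solve_flow(domain, fparams)
  runs <- lapply(protocols, function(p) {
    list(name = paste0("protocol", p),
         magnets = protocol_layout(p, d = d),
         spec = protocol_release(p, count = count))
  })
  if (include_control) {
    runs <- c(runs, list(list(name = "control",
                              magnets = NULL,
                              spec = protocol_release(3, count = count))))
  }
  states <- list(); summaries <- list()
  rows <- list()
  for (r in runs) {
    rel <- release_line(r$spec, domain)
    ts <- tryCatch(
      trace_particles(rel, flow, r$magnets, domain, props, config),
      error = function(e) stop("compare_protocols: stage failure in ", r$name,
                               ": ", conditionMessage(e), call. = FALSE)
    )
    sm <- deposition_summary(ts, domain)
    states[[r$name]] <- ts
    summaries[[r$name]] <- sm
    rows[[r$name]] <- data.frame(
      protocol = r$name,
      n = sm$n_released,
      efficiency_pct = sm$delivery_efficiency,
      deposited = sm$status_counts[["DEPOSITED"]],
      escaped = sm$status_counts[["ESCAPED"]],
      suspended = sm$status_counts[["SUSPENDED"]],
      dep_olfactory = sm$region_counts[["OLFACTORY"]],
      dep_wall = sm$region_counts[["WALL"]],
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, summaries = summaries, states = states,
                 flow = flow, domain = domain),
            class = "protocol_comparison")
}

#' @export
print.protocol_comparison <- function(x, ...) {
  cat("<protocol_comparison>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
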