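#' Detect a binding-site escape in a trajectory
#'
#' The escape time is the first frame at which the particle's distance from
#' the site center exceeds the escape radius continuously for at least
#' `persistence` picoseconds; shorter excursions are treated as recrossings
#' and ignored.  Trajectories without such an excursion are censored at
#' their final frame.
#'
#' @param traj a `toy_trajectory`.
#' @param site a [site_model()] (defaults to the trajectory's own site).
#' @param persistence minimum time outside the escape radius, ps.
#' @param molecule_id label carried into the event.
#' @return An `escape_event`: list with `molecule_id`, `escaped` and `time`
#'   in nanoseconds (escape time, or the censoring span).
#' @export
detect_escape <- function(traj, site = traj$site, persistence = 5,
                          molecule_id = "mol1") {
  stopifnot(inherits(traj, "toy_trajectory"), inherits(site, "toy_site"))
  n <- length(traj$times)
  if (n == 0) stop("empty trajectory")
  d <- sqrt(colSums((t(traj$positions) - site$site_center)^2))
  outside <- d > site$escape_radius
  spacing <- if (n > 1) traj$times[2] - traj$times[1] else traj$times[1]
  need <- max(1L, ceiling(persistence / spacing))
  r <- rle(outside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (length(hit) > 0) {
    k <- starts[hit[1]]
    structure(list(molecule_id = molecule_id, escaped = TRUE,
                   time = traj$times[k] / 1000), class = "escape_event")
  } else {
    structure(list(molecule_id = molecule_id, escaped = FALSE,
                   time = traj$times[n] / 1000), class = "escape_event")
  }
}

#' Pool escape events into survival data
#'
#' Every monitored molecule contributes exactly one event (escape or
#' censoring), so the pooled table has one row per molecule and the summed
#' event count equals the number of trajectories.
#'
#' @param events list of `escape_event`s from [detect_escape()].
#' @return A [survival_data()] object.
#' @export
events_to_survival <- function(events) {
  stopifnot(length(events) > 0,
            all(vapply(events, inherits, logical(1), "escape_event")))
  as_survival_data(data.frame(
    molecule_id = vapply(events, `[[`, character(1), "molecule_id"),
    span = vapply(events, `[[`, numeric(1), "time"),
    escaped = vapply(events, `[[`, logical(1), "escaped"),
    time = vapply(events, `[[`, numeric(1), "time")))
}

#' Root mean squared fluctuation about the mean position
#'
#' \deqn{RMSF = \sqrt{\langle |x - \bar{x}|^2 \rangle}} over the retained
#' frames, with the retained-frame mean position as reference.  A proxy for
#' the crystallographic disorder of a bound molecule: localized occupants
#' give small RMSF, loosely caged ones large RMSF.
#'
#' @param traj a `toy_trajectory`.
#' @param equilibration leading span to discard, ps.
#' @return list of class `rmsf_result` with `rmsf` (nm), `n_frames` and
#'   `reference = "mean-position"`.
#' @export
rmsf <- function(traj, equilibration = 0) {
  stopifnot(inherits(traj, "toy_trajectory"))
  keep <- traj$times > equilibration
  if (sum(keep) < 2) stop("need at least 2 retained frames for an RMSF")
  p <- traj$positions[keep, , drop = FALSE]
  ctr <- colMeans(p)
  val <- sqrt(mean(rowSums(sweep(p, 2, ctr)^2)))
  structure(list(rmsf = val, n_frames = nrow(p), reference = "mean-position"),
            class = "rmsf_result")
}

#' Project a trajectory onto an axis
#'
#' Returns the scalar projections of the positions onto the (normalized)
#' axis, for displacement-trace inspection (e.g. along a membrane normal).
#'
#' @param traj a `toy_trajectory`.
#' @param axis direction 3-vector; normalized internally, must be non-zero.
#' @return list with `times` (ps) and `projections` (nm).
#' @export
axis_trace <- function(traj, axis = c(0, 0, 1)) {
  stopifnot(inherits(traj, "toy_trajectory"))
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (!is.finite(nrm) || nrm == 0) stop("axis must be a non-zero vector")
  list(times = traj$times,
       projections = as.numeric(traj$positions %*% (axis / nrm)))
}

#' Write escape events as a survival-compatible CSV
#' @param events list of `escape_event`s.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  write_survival_csv(events_to_survival(events), path)
}
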