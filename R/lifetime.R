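#' Censored escape-time data
#'
#' Records `M` monitored molecules, their observation spans and the escape
#' times of those that left within their span.  Spans may differ per
#' molecule (replicas of different lengths are pooled); `T_s` may be a
#' scalar common span or a length-`M` vector.  With a vector span the escape
#' times are matched to the first `m` molecules unless a full event table is
#' supplied via [as_survival_data()].
#'
#' @param M number of monitored molecules (>= 1).
#' @param T_s observation span(s), ns.
#' @param escape_times times of observed escapes, ns; each must be positive
#'   and no larger than its molecule's span.
#' @return An object of class `survival_data` holding an event table with
#'   one row per molecule (`molecule_id`, `span`, `escaped`, `time`).
#' @export
survival_data <- function(M, T_s, escape_times = numeric(0)) {
  M <- as.integer(M)
  if (M < 1) stop("M must be >= 1")
  if (!length(T_s) %in% c(1L, M)) stop("T_s must be scalar or length M")
  if (any(T_s <= 0)) stop("observation spans must be > 0")
  spans <- rep_len(as.numeric(T_s), M)
  m <- length(escape_times)
  if (m > M) stop("more escapes than monitored molecules (m > M)")
  if (any(escape_times <= 0)) stop("escape times must be > 0")
  if (m > 0 && any(escape_times > spans[seq_len(m)]))
    stop("every escape time must be <= its molecule's observation span")
  events <- data.frame(
    molecule_id = paste0("mol", seq_len(M)),
    span = spans,
    escaped = seq_len(M) <= m,
    time = c(as.numeric(escape_times), spans[seq_len(M - m) + m]))
  structure(list(events = events, M = M), class = "survival_data")
}

#' Build survival data from an event table
#'
#' @param events data frame with columns `molecule_id`, `span` (ns),
#'   `escaped` (logical) and `time` (escape time for escaped molecules,
#'   otherwise the censoring time, which must equal the span).
#' @return A `survival_data` object.
#' @export
as_survival_data <- function(events) {
  events <- as.data.frame(events)
  needed <- c("molecule_id", "span", "escaped", "time")
  if (!all(needed %in% names(events)))
    stop("events must have columns ", paste(needed, collapse = ", "))
  if (any(events$time <= 0) || any(events$span <= 0))
    stop("times and spans must be > 0")
  if (any(events$escaped & events$time > events$span))
    stop("escape times must be <= the observation span")
  events$time[!events$escaped] <- events$span[!events$escaped]
  structure(list(events = events, M = nrow(events)), class = "survival_data")
}

#' @export
print.survival_data <- function(x, ...) {
  cat(sprintf("survival_data: M = %d molecules, m = %d escapes, total time at risk %.1f ns\n",
              x$M, sum(x$events$escaped),
              sum(ifelse(x$events$escaped, x$events$time, x$events$span))))
  invisible(x)
}

#' Maximum-likelihood residence lifetime under fixed-duration censoring
#'
#' For exponentially distributed residence times observed over fixed spans,
#' the maximum-likelihood estimate is total time at risk over event count:
#' \deqn{\tau_{ml} = m^{-1}\left[(M - m) T_s + \sum_{i=1}^m t_i\right],}
#' generalized to per-molecule spans by summing `min(t_i, T_s,i)` over all
#' molecules.  With no escape events (`m = 0`) the likelihood has no
#' interior maximum and the total observation time is reported as a lower
#' bound on the lifetime, flagged as such (the "greater-than-about" entries
#' of residence-time tables).
#'
#' @param data a [survival_data()].
#' @return list of class `lifetime_estimate` with `tau` (ns) and
#'   `is_lower_bound`.
#' @export
tau_ml <- function(data) {
  stopifnot(inherits(data, "survival_data"))
  ev <- data$events
  m <- sum(ev$escaped)
  at_risk <- sum(ifelse(ev$escaped, ev$time, ev$span))
  if (m == 0)
    return(lifetime_estimate(at_risk, lower_bound = TRUE))
  lifetime_estimate(at_risk / m, lower_bound = FALSE)
}

#' Wrap a lifetime value with its lower-bound flag
#' @param tau lifetime, ns (> 0).
#' @param lower_bound TRUE when `tau` is only a lower bound (no events).
#' @return An object of class `lifetime_estimate`.
#' @export
lifetime_estimate <- function(tau, lower_bound = FALSE) {
  if (tau <= 0) stop("tau must be > 0")
  structure(list(tau = tau, is_lower_bound = isTRUE(lower_bound)),
            class = "lifetime_estimate")
}

#' @export
print.lifetime_estimate <- function(x, ...) {
  cat(sprintf("tau_ml %s %.3g ns\n", if (x$is_lower_bound) ">~" else "=",
              x$tau))
  invisible(x)
}

#' Parametric bootstrap confidence interval for the lifetime
#'
#' Resamples whole escape experiments from an exponential with mean
#' `tau_ml(data)` under the same per-molecule censoring spans and returns
#' the percentile interval of the re-estimated lifetimes.  Bootstrap
#' replicates without any event contribute their lower bound.
#'
#' @param data a [survival_data()] with at least one escape event.
#' @param level interval coverage, e.g. 0.95.
#' @param n_boot number of bootstrap replicates (> 0).
#' @param seed integer seed.
#' @return list with `lo` and `hi`, ns.  With `m = 0` returns
#'   `(total observation time, Inf)` without resampling.
#' @export
tau_confidence <- function(data, level = 0.95, n_boot = 1000, seed = 1) {
  stopifnot(inherits(data, "survival_data"))
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  est <- tau_ml(data)
  if (est$is_lower_bound)
    return(list(lo = est$tau, hi = Inf))
  spans <- data$events$span
  boots <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      t_all <- rexp(length(spans), rate = 1 / est$tau)
      esc <- t_all <= spans
      if (!any(esc)) sum(spans)
      else (sum(t_all[esc]) + sum(spans[!esc])) / sum(esc)
    }, numeric(1))
  })
  a <- (1 - level) / 2
  q <- stats::quantile(boots, c(a, 1 - a), names = FALSE)
  list(lo = q[1], hi = q[2])
}

#' Read an escape-event table from CSV
#'
#' Expected columns: `molecule_id`, `observed_ns`, `escaped_bool`,
#' `escape_ns` (NA for censored molecules).
#'
#' @param path CSV file.
#' @return A [survival_data()] object.
#' @export
read_survival_csv <- function(path) {
  df <- read.csv(path)
  needed <- c("molecule_id", "observed_ns", "escaped_bool", "escape_ns")
  if (!all(needed %in% names(df)))
    stop("survival CSV must have columns ", paste(needed, collapse = ", "))
  as_survival_data(data.frame(
    molecule_id = df$molecule_id, span = df$observed_ns,
    escaped = as.logical(df$escaped_bool),
    time = ifelse(as.logical(df$escaped_bool), df$escape_ns, df$observed_ns)))
}

#' Write an escape-event table to CSV
#' @param data a [survival_data()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(data, path) {
  stopifnot(inherits(data, "survival_data"))
  ev <- data$events
  write.csv(data.frame(molecule_id = ev$molecule_id, observed_ns = ev$span,
                       escaped_bool = ev$escaped,
                       escape_ns = ifelse(ev$escaped, ev$time, NA)),
            path, row.names = FALSE)
  invisible(path)
}
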