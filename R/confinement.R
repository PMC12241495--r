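#' Recurrence-based confinement states
#'
#' For every pair of consecutive localisations a circle is drawn centred at
#' their midpoint with diameter equal to the step length (radius floored at
#' `min_radius`, the localisation precision, so zero-length steps still define
#' an area). The number of localisations of the whole track falling inside
#' the circle is counted; if it exceeds `v_th` the particle is considered to
#' revisit that area and both endpoints of the step are marked confined. A
#' localisation is confined if any of the circles it belongs to exceeds the
#' threshold.
#'
#' @param track data.frame with `x`, `y` columns; needs >= 3 localisations.
#' @param v_th visit threshold (default 33; the historical preset 11 tends to
#'   over-call confinement at MINFLUX sampling rates).
#' @param min_radius radius floor in nm (default 7, the localisation
#'   precision).
#' @return logical vector, `TRUE` = confined, of class-free length
#'   `nrow(track)`; visit counts per circle in attribute `"visits"`.
#' @export
recurrence_states <- function(track, v_th = 33, min_radius = 7) {
  n <- nrow(track)
  stopifnot(n >= 3)
  x <- track$x; y <- track$y
  mx <- (x[-n] + x[-1]) / 2
  my <- (y[-n] + y[-1]) / 2
  r <- pmax(sqrt((x[-1] - x[-n])^2 + (y[-1] - y[-n])^2) / 2, min_radius)
  # visits[i]: localisations strictly inside circle i (endpoints of the whole
  # track included in the count)
  visits <- integer(n - 1L)
  for (i in seq_len(n - 1L)) {
    visits[i] <- sum((x - mx[i])^2 + (y - my[i])^2 < r[i]^2)
  }
  conf_circle <- visits > v_th
  states <- logical(n)
  states[-n] <- conf_circle
  states[-1] <- states[-1] | conf_circle
  attr(states, "visits") <- visits
  states
}

#' Majority smoothing of a confinement state sequence
#'
#' The sequence is divided into non-overlapping windows of `window` steps and
#' every step is reassigned to the state occurring most frequently in its
#' window. A trailing partial window takes its own majority; on a tie it
#' inherits the previous window's (smoothed) state.
#'
#' @param states logical vector (`TRUE` = confined).
#' @param window window length (default 3).
#' @return smoothed logical vector of the same length.
#' @export
smooth_states <- function(states, window = 3L) {
  n <- length(states)
  if (n == 0L) return(states)
  out <- logical(n)
  prev <- states[1]
  for (s in seq(1L, n, by = window)) {
    e <- min(s + window - 1L, n)
    k <- sum(states[s:e])
    len <- e - s + 1L
    maj <- if (2L * k > len) TRUE else if (2L * k < len) FALSE else prev
    out[s:e] <- maj
    prev <- maj
  }
  attributes(out) <- NULL
  out
}

# Covariance (second-moment) ellipse of a point cloud at 2 SD.
# Returns c(major, minor, eccentricity) or NAs for degenerate clouds.
moment_ellipse <- function(x, y) {
  if (length(unique(paste(x, y))) < 3) {
    return(c(major = NA_real_, minor = NA_real_, eccentricity = NA_real_))
  }
  ev <- eigen(stats::cov(cbind(x, y)), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  a <- 2 * sqrt(ev[1]); b <- 2 * sqrt(ev[2])
  ecc <- if (a > 0) sqrt(max(0, 1 - (b / a)^2)) else NA_real_
  c(major = a, minor = b, eccentricity = ecc)
}

#' Segment a track into confinement sojourns
#'
#' Maximal runs of the (smoothed) state sequence become sojourns. A sojourn's
#' time interval runs from its first localisation to the first localisation
#' of the next sojourn (the track end for the last one), so that confined and
#' free residence times partition the track duration exactly. Confined
#' sojourns get a convex-hull area and a second-moment ellipse
#' (semi-axes at 2 SD, eccentricity from the axis ratio).
#'
#' @param track data.frame with `t`, `x`, `y`.
#' @param states logical state sequence (after [smooth_states]).
#' @return list with `sojourns` (data.frame: `kind`, `start_index`,
#'   `end_index`, `start_t`, `end_t`, `duration`, `n_locs`, `hull_area`,
#'   `major`, `minor`, `eccentricity`) and `summary` (data.frame:
#'   `confined_ratio_r`, `transition_rate` (state changes per second),
#'   `mean_confined_duration`, `mean_free_duration`, `n_sojourns`).
#' @export
segment_sojourns <- function(track, states) {
  n <- nrow(track)
  stopifnot(length(states) == n, n >= 1)
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  t_total <- track$t[n] - track$t[1]
  start_t <- track$t[starts]
  end_t <- c(track$t[starts[-1]], track$t[n])
  rows <- data.frame(
    kind = ifelse(r$values, "confined", "free"),
    start_index = starts, end_index = ends,
    start_t = start_t, end_t = end_t, duration = end_t - start_t,
    n_locs = r$lengths, hull_area = NA_real_, major = NA_real_,
    minor = NA_real_, eccentricity = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    if (!r$values[i]) next
    xs <- track$x[starts[i]:ends[i]]
    ys <- track$y[starts[i]:ends[i]]
    uq <- unique(cbind(xs, ys))
    if (nrow(uq) < 3) {
      rows$hull_area[i] <- 0
    } else {
      h <- grDevices::chull(uq)
      rows$hull_area[i] <- polygon_area(uq[h, , drop = FALSE])
      el <- moment_ellipse(xs, ys)
      rows$major[i] <- el[1]; rows$minor[i] <- el[2]
      rows$eccentricity[i] <- el[3]
    }
  }
  conf_t <- sum(rows$duration[rows$kind == "confined"])
  free_t <- sum(rows$duration[rows$kind == "free"])
  summary <- data.frame(
    confined_ratio_r = if (t_total > 0) conf_t / t_total else 0,
    free_ratio = if (t_total > 0) free_t / t_total else 0,
    transition_rate = if (t_total > 0) (k - 1) / t_total else 0,
    mean_confined_duration = if (any(rows$kind == "confined"))
      mean(rows$duration[rows$kind == "confined"]) else NA_real_,
    mean_free_duration = if (any(rows$kind == "free"))
      mean(rows$duration[rows$kind == "free"]) else NA_real_,
    n_sojourns = k)
  list(sojourns = rows, summary = summary)
}

#' Kinetic fits of individual sojourns
#'
#' TA-MSD and anomalous-diffusion fit restricted to each sojourn, with the
#' shorter segment-level fit range (default 25 ms). Sojourns with fewer than
#' `min_locs` localisations are skipped.
#'
#' @param track data.frame with `t`, `x`, `y`.
#' @param sojourns data.frame from [segment_sojourns].
#' @param fit_max_lag fit range (s), default 25 ms.
#' @param min_locs minimum sojourn length (default 10).
#' @param ... passed to [ta_msd] / [fit_anomalous].
#' @return `sojourns` with added columns `beta`, `k_beta`, `sigma_fit`,
#'   `fit_valid`, `regime` (NA for skipped sojourns).
#' @export
sojourn_kinetics <- function(track, sojourns, fit_max_lag = 0.025,
                             min_locs = 10L, ...) {
  sj <- sojourns
  sj$beta <- NA_real_; sj$k_beta <- NA_real_; sj$sigma_fit <- NA_real_
  sj$fit_valid <- NA; sj$regime <- NA_character_
  n_skipped <- 0L
  for (i in seq_len(nrow(sj))) {
    if (sj$n_locs[i] < min_locs) { n_skipped <- n_skipped + 1L; next }
    sub <- track[sj$start_index[i]:sj$end_index[i], , drop = FALSE]
    cu <- ta_msd(sub, max_lag = fit_max_lag)
    if (nrow(cu) < 4) { n_skipped <- n_skipped + 1L; next }
    f <- fit_anomalous(cu, fit_max_lag = fit_max_lag, ...)
    sj$beta[i] <- f$beta; sj$k_beta[i] <- f$k_beta
    sj$sigma_fit[i] <- f$sigma; sj$fit_valid[i] <- f$valid
    sj$regime[i] <- f$regime
  }
  attr(sj, "n_skipped") <- n_skipped
  sj
}

#' Confinement analysis of a whole dataset
#'
#' Runs [recurrence_states], [smooth_states] and [segment_sojourns] on every
#' track with at least 3 localisations.
#'
#' @param ds an [mfx_dataset].
#' @param v_th visit threshold.
#' @param window smoothing window.
#' @param min_radius circle radius floor (nm).
#' @return list with `states` (named list of logical vectors), `sojourns`
#'   (data.frame with `track_id` column), `summaries` (per-track data.frame).
#' @export
confinement_analysis <- function(ds, v_th = 33, window = 3L, min_radius = 7) {
  trs <- split_tracks(ds)
  states <- list(); sjs <- list(); sums <- list()
  for (id in names(trs)) {
    tr <- trs[[id]]
    if (nrow(tr) < 3) next
    st <- smooth_states(recurrence_states(tr, v_th = v_th,
                                          min_radius = min_radius),
                        window = window)
    seg <- segment_sojourns(tr, st)
    states[[id]] <- st
    s <- seg$sojourns; s$track_id <- id
    sjs[[id]] <- s
    sm <- seg$summary; sm$track_id <- id
    sums[[id]] <- sm
  }
  list(states = states,
       sojourns = if (length(sjs)) do.call(rbind, c(sjs, list(make.row.names = FALSE))) else NULL,
       summaries = if (length(sums)) do.call(rbind, c(sums, list(make.row.names = FALSE))) else NULL)
}
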