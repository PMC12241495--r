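#' Turning angles of a track at a given step lag
#'
#' The displacement vector at step lag Delta is `V(i; Delta) = r_{i+Delta} -
#' r_i`; the turning angle is the angle between `V(i; Delta)` and
#' `V(i + Delta; Delta)`, in degrees in \[0, 180\]. Step lags (not time lags)
#' are used because MINFLUX sampling intervals are irregular. Pairs involving
#' a zero-length displacement are skipped (the angle is undefined); their
#' count is attached as attribute `"n_skipped"`.
#'
#' @param track data.frame with `x`, `y`.
#' @param step_lag integer step lag Delta >= 1.
#' @return numeric vector of angles (degrees).
#' @export
turning_angles <- function(track, step_lag = 1L) {
  n <- nrow(track)
  d <- as.integer(step_lag)
  stopifnot(d >= 1)
  if (n < 2L * d + 1L) {
    out <- numeric(0)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  vx <- track$x[(1L + d):n] - track$x[1L:(n - d)]
  vy <- track$y[(1L + d):n] - track$y[1L:(n - d)]
  nv <- length(vx)
  i1 <- 1L:(nv - d)
  i2 <- (1L + d):nv
  dot <- vx[i1] * vx[i2] + vy[i1] * vy[i2]
  nrm <- sqrt(vx[i1]^2 + vy[i1]^2) * sqrt(vx[i2]^2 + vy[i2]^2)
  ok <- nrm > 0
  ang <- acos(pmin(pmax(dot[ok] / nrm[ok], -1), 1)) * 180 / pi
  attr(ang, "n_skipped") <- sum(!ok)
  ang
}

#' Probability density function of turning angles
#'
#' Histogram density over \[0, 180\] degrees with fixed-width bins (10
#' degrees by default); the density integrates to 1.
#'
#' @param angles numeric vector of angles in degrees.
#' @param bin_width bin width in degrees (default 10; must divide 180).
#' @return data.frame of class `mfx_angle_pdf`: `bin_lo`, `bin_hi`,
#'   `bin_mid`, `density` (per degree), `count`; attribute `n_angles`.
#' @export
angle_pdf <- function(angles, bin_width = 10) {
  if (length(angles) == 0) stop("no angles supplied")
  stopifnot(180 %% bin_width == 0)
  edges <- seq(0, 180, by = bin_width)
  idx <- pmin(pmax(floor(angles / bin_width) + 1L, 1L), length(edges) - 1L)
  cnt <- tabulate(idx, nbins = length(edges) - 1L)
  dens <- cnt / (sum(cnt) * bin_width)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    bin_mid = edges[-length(edges)] + bin_width / 2,
                    density = dens, count = cnt)
  structure(out, class = c("mfx_angle_pdf", "data.frame"),
            n_angles = length(angles), bin_width = bin_width)
}

#' Turning-angle PDFs stratified by confinement state and step lag
#'
#' Angles are computed within sojourns only (displacement vectors never
#' straddle a confined/free boundary) and pooled across tracks per stratum.
#' Strata with fewer than `min_angles` angles are flagged low-confidence.
#'
#' @param ds an [mfx_dataset].
#' @param states named list of smoothed logical state sequences (from
#'   [confinement_analysis]), one per track.
#' @param step_lags integer step lags (default `c(1, 4, 8)`).
#' @param bin_width histogram bin width (degrees).
#' @param min_angles low-confidence limit (default 50).
#' @return data.frame: `state`, `step_lag`, `bin_lo`, `bin_hi`, `bin_mid`,
#'   `density`, `count`, `n_angles`, `low_confidence`.
#' @export
stratified_angle_pdfs <- function(ds, states, step_lags = c(1L, 4L, 8L),
                                  bin_width = 10, min_angles = 50L) {
  trs <- split_tracks(ds)
  pool <- list()
  for (id in names(states)) {
    tr <- trs[[id]]
    st <- states[[id]]
    r <- rle(st)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      seg <- tr[starts[i]:ends[i], , drop = FALSE]
      key <- if (r$values[i]) "confined" else "free"
      for (d in step_lags) {
        a <- turning_angles(seg, d)
        if (length(a) > 0) {
          k <- paste(key, d, sep = ".")
          pool[[k]] <- c(pool[[k]], as.numeric(a))
        }
      }
    }
  }
  out <- list()
  for (state in c("confined", "free")) {
    for (d in step_lags) {
      a <- pool[[paste(state, d, sep = ".")]]
      if (is.null(a) || length(a) == 0) next
      p <- angle_pdf(a, bin_width = bin_width)
      p$state <- state
      p$step_lag <- d
      p$n_angles <- length(a)
      p$low_confidence <- length(a) < min_angles
      out[[length(out) + 1L]] <- as.data.frame(p)
    }
  }
  if (length(out) == 0) stop("no angles in any stratum")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("state", "step_lag", "bin_lo", "bin_hi", "bin_mid", "density",
          "count", "n_angles", "low_confidence")]
}
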