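#' Binned time-averaged MSD for irregularly sampled tracks
#'
#' Because MINFLUX sampling intervals are irregular, displacement pairs are
#' binned by their time separation: the pair (t_i, t_i') contributes to bin m
#' when `delta0 + (m-1)*dt_bin <= t_i' - t_i < delta0 + m*dt_bin`. The bin's
#' nominal lag is `m * dt_bin`. Empty bins are dropped; bins are computed up
#' to `max_lag`.
#'
#' @param track data.frame with `t`, `x`, `y` columns.
#' @param dt_bin bin width (s); default 132 us.
#' @param delta0 offset of the first bin (s); default 84 us.
#' @param max_lag largest lag considered (s); default 50 ms.
#' @return data.frame of class `mfx_msd` with columns `m` (bin index),
#'   `lag` (= m * dt_bin, s, the nominal bin lag), `msd` (nm^2), `n_pairs`,
#'   and `tau_mean` (mean pair separation actually falling in the bin, s;
#'   under irregular sampling this can deviate from the nominal lag at small
#'   m, and model fits evaluate the models there); attributes `dt_bin`,
#'   `delta0`, `n_locs`.
#' @export
ta_msd <- function(track, dt_bin = 132e-6, delta0 = 84e-6, max_lag = 0.05) {
  n <- nrow(track)
  stopifnot(n >= 2)
  t <- track$t; x <- track$x; y <- track$y
  m_max <- max(1L, floor(max_lag / dt_bin))
  hi <- delta0 + m_max * dt_bin
  ms <- vector("list", n - 1L)
  d2s <- vector("list", n - 1L)
  taus <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    i2 <- (1L + k):n
    i1 <- 1L:(n - k)
    tau <- t[i2] - t[i1]
    if (min(tau) >= hi) break
    sel <- tau > delta0 & tau < hi
    if (!any(sel)) next
    ms[[k]] <- floor((tau[sel] - delta0) / dt_bin) + 1L
    d2s[[k]] <- (x[i2][sel] - x[i1][sel])^2 + (y[i2][sel] - y[i1][sel])^2
    taus[[k]] <- tau[sel]
  }
  m_all <- unlist(ms)
  sums <- numeric(m_max)
  tsum <- numeric(m_max)
  cnts <- integer(m_max)
  if (length(m_all) > 0) {
    d2_all <- unlist(d2s)
    agg <- rowsum(d2_all, m_all, reorder = TRUE)
    sums[as.integer(rownames(agg))] <- agg[, 1]
    tagg <- rowsum(unlist(taus), m_all, reorder = TRUE)
    tsum[as.integer(rownames(tagg))] <- tagg[, 1]
    cnts <- tabulate(m_all, nbins = m_max)
  }
  keep <- cnts > 0L
  out <- data.frame(m = which(keep), lag = which(keep) * dt_bin,
                    msd = sums[keep] / cnts[keep], n_pairs = cnts[keep],
                    tau_mean = tsum[keep] / cnts[keep])
  structure(out, class = c("mfx_msd", "data.frame"),
            dt_bin = dt_bin, delta0 = delta0, n_locs = n, m_max = m_max,
            duration = t[n] - t[1])
}

#' Ensemble average of TA-MSD curves
#'
#' Per-bin average across tracks, weighted by each curve's displacement-pair
#' count. Bins present in fewer than `min_frac` of the tracks are dropped.
#'
#' @param curves list of `mfx_msd` curves (same `dt_bin`/`delta0`).
#' @param min_frac minimum fraction of curves a bin must appear in (0.10).
#' @return an `mfx_msd` data.frame (columns `m`, `lag`, `msd`, `n_pairs`,
#'   plus `n_curves`).
#' @export
ea_ta_msd <- function(curves, min_frac = 0.10) {
  stopifnot(length(curves) >= 1)
  dt_bin <- attr(curves[[1]], "dt_bin")
  all_m <- unlist(lapply(curves, `[[`, "m"))
  w <- unlist(lapply(curves, `[[`, "n_pairs"))
  v <- unlist(lapply(curves, `[[`, "msd"))
  tm <- unlist(lapply(curves, function(cu)
    if (is.null(cu$tau_mean)) cu$m * dt_bin else cu$tau_mean))
  mm <- sort(unique(all_m))
  sw <- vapply(split(w, all_m), sum, numeric(1))[as.character(mm)]
  swv <- vapply(split(w * v, all_m), sum, numeric(1))[as.character(mm)]
  swt <- vapply(split(w * tm, all_m), sum, numeric(1))[as.character(mm)]
  ncur <- vapply(split(all_m, all_m), length, integer(1))[as.character(mm)]
  keep <- ncur >= min_frac * length(curves)
  out <- data.frame(m = mm[keep], lag = mm[keep] * dt_bin,
                    msd = (swv / sw)[keep], n_pairs = sw[keep],
                    n_curves = ncur[keep], tau_mean = (swt / sw)[keep])
  rownames(out) <- NULL
  structure(out, class = c("mfx_msd", "data.frame"),
            dt_bin = dt_bin, delta0 = attr(curves[[1]], "delta0"),
            m_max = max(vapply(curves, function(cu) attr(cu, "m_max"), numeric(1))),
            duration = sum(vapply(curves, function(cu)
              attr(cu, "duration") %||% 0, numeric(1))))
}

# Anomalous-diffusion MSD model with motion-blur and noise terms:
# msd(m) = Gamma * (m dt)^(beta-1) * 2 n_d dt m * (1 - 2R/m) + 2 n_d sigma^2
anomalous_model <- function(m, dt_bin, gamma, beta, sigma, r_blur = 1 / 6.2,
                            n_d = 2) {
  gamma * (m * dt_bin)^(beta - 1) * 2 * n_d * dt_bin * m *
    (1 - 2 * r_blur / m) + 2 * n_d * sigma^2
}

#' Fit the anomalous-diffusion model to a TA-MSD curve
#'
#' Weighted bounded nonlinear least squares of
#' `msd(m) = Gamma (m dt)^(beta-1) 2 n_d dt m (1 - 2R/m) + 2 n_d sigma^2`
#' for the transport coefficient Gamma (nm^2 s^-beta), anomalous exponent
#' beta, and dynamic localisation uncertainty sigma (nm). The blur factor R
#' (default 1/6.2) accounts for motion blur under homogeneous illumination.
#' The generalised diffusion coefficient is `K_beta = Gamma * 2 * n_d`
#' (= 4 Gamma in 2D).
#'
#' Bins are weighted by an inverse-variance model of the time-averaged MSD,
#' `Var(msd_m) ~ mu_m^2 * (2 / n_pairs + m dt / T)` (T = track duration):
#' the pair-count term governs sparsely populated bins under irregular
#' sampling, while the `m dt / T` term captures the correlated single-track
#' fluctuations that dominate long lags. The fit is solved by bounded
#' multistart least squares followed by two iteratively reweighted passes
#' with weights evaluated at the current model curve. Fits with residual
#' standard deviation above 1000 nm^2, or on curves with at most 50% of the
#' available bins populated, are flagged invalid.
#'
#' @param curve an `mfx_msd` curve.
#' @param fit_max_lag fit range upper limit (s); 50 ms for whole tracks,
#'   25 ms for confinement sojourns.
#' @param r_blur blur factor R (1/6.2).
#' @param n_d dimensionality (2).
#' @param n_starts multistart count (bounded log-uniform draws).
#' @param seed sub-seed for the multistarts.
#' @param resid_sd_max validity limit on the residual SD (nm^2).
#' @return list of class `mfx_kinetic_fit`: `gamma`, `beta`, `sigma`,
#'   `k_beta`, `r_blur`, `n_d`, `resid_sd`, `n_bins`, `frac_bins`, `regime`,
#'   `valid`, `reason`.
#' @export
fit_anomalous <- function(curve, fit_max_lag = 0.05, r_blur = 1 / 6.2,
                          n_d = 2, n_starts = 10L, seed = 7L,
                          resid_sd_max = 1000) {
  dt_bin <- attr(curve, "dt_bin")
  cv <- curve[curve$lag <= fit_max_lag, , drop = FALSE]
  m_avail <- min(attr(curve, "m_max"), floor(fit_max_lag / dt_bin))
  frac <- nrow(cv) / m_avail
  if (nrow(cv) < 4) {
    return(invalid_fit(r_blur, n_d, frac, "fewer than 4 bins in fit range"))
  }
  m <- cv$m; y <- cv$msd; np <- cv$n_pairs
  dur <- attr(curve, "duration")
  if (is.null(dur) || !is.finite(dur) || dur <= 0) dur <- max(m) * dt_bin * 10
  lo <- c(lgamma = -6, beta = 0.1, sigma = 0)
  hi <- c(lgamma = 9, beta = 2, sigma = 100)
  solve_wls <- function(w, p0) {
    resid_fn <- function(p) {
      sqrt(w) * (anomalous_model(m, dt_bin, 10^p[1], p[2], p[3], r_blur, n_d) - y)
    }
    tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lo, upper = hi, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
  }
  # data-driven start: log-log slope and intercept
  pos <- y > 0
  b0 <- if (sum(pos) >= 2) {
    cf <- stats::coef(stats::lm(log(y[pos]) ~ log(m[pos] * dt_bin)))
    max(min(cf[2], hi["beta"]), lo["beta"])
  } else 1
  g0 <- max(min(log10(max(y[1], 1e-6) / (2 * n_d * dt_bin * m[1] *
                                           (m[1] * dt_bin)^(b0 - 1))),
                hi["lgamma"]), lo["lgamma"])
  starts <- list(c(g0, b0, 7))
  if (n_starts > 1) {
    rand <- with_seed(seed, {
      lapply(seq_len(n_starts - 1L), function(i)
        stats::runif(3, lo, hi))
    })
    starts <- c(starts, rand)
  }
  w0 <- np / pmax(y, 1)^2
  best <- NULL
  for (p0 in starts) {
    fit <- solve_wls(w0, p0)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) {
    return(invalid_fit(r_blur, n_d, frac, "optimizer failed to converge"))
  }
  p <- best$fit$par
  # iteratively reweighted passes with model-based inverse-variance weights
  for (pass in 1:2) {
    mu <- anomalous_model(m, dt_bin, 10^p[1], p[2], p[3], r_blur, n_d)
    w <- 1 / (pmax(mu, 1)^2 * (2 / np + m * dt_bin / dur))
    fit <- solve_wls(w, p)
    if (!is.null(fit)) p <- fit$par
  }
  gamma <- 10^p[1]; beta <- p[2]; sigma <- p[3]
  res <- anomalous_model(m, dt_bin, gamma, beta, sigma, r_blur, n_d) - y
  resid_sd <- sqrt(sum(res^2) / max(1, length(res) - 3))
  valid <- resid_sd <= resid_sd_max && frac > 0.5
  reason <- if (valid) "" else if (frac <= 0.5) {
    "<= 50% of available MSD bins populated"
  } else "residual SD above limit"
  structure(list(gamma = gamma, beta = beta, sigma = sigma,
                 k_beta = gamma * 2 * n_d, r_blur = r_blur, n_d = n_d,
                 resid_sd = resid_sd, n_bins = length(m), frac_bins = frac,
                 regime = classify_regime(beta), valid = valid,
                 reason = reason),
            class = "mfx_kinetic_fit")
}

invalid_fit <- function(r_blur, n_d, frac, reason) {
  structure(list(gamma = NA_real_, beta = NA_real_, sigma = NA_real_,
                 k_beta = NA_real_, r_blur = r_blur, n_d = n_d,
                 resid_sd = NA_real_, n_bins = NA_integer_, frac_bins = frac,
                 regime = NA_character_, valid = FALSE, reason = reason),
            class = "mfx_kinetic_fit")
}

#' @export
print.mfx_kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<mfx_kinetic_fit> beta = %.3f, K_beta = %.3g nm^2 s^-beta, sigma = %.2f nm (%s%s)\n",
    x$beta, x$k_beta, x$sigma, x$regime,
    if (x$valid) "" else paste0("; INVALID: ", x$reason)))
  invisible(x)
}

#' Diffusive regime from the anomalous exponent
#'
#' Subdiffusive for `beta <= 0.9`, Brownian for `0.9 < beta <= 1.1`,
#' superdiffusive for `beta > 1.1`.
#'
#' @param beta anomalous exponent(s).
#' @return character vector of regime labels.
#' @export
classify_regime <- function(beta) {
  stopifnot(all(is.finite(beta)))
  ifelse(beta <= 0.9, "subdiffusive",
         ifelse(beta <= 1.1, "brownian", "superdiffusive"))
}

#' Per-track kinetic fits for a dataset
#'
#' Convenience wrapper: [ta_msd] + [fit_anomalous] for every track.
#'
#' @param ds an [mfx_dataset].
#' @param track_ids tracks to fit (default: all).
#' @param ... passed to [ta_msd] and [fit_anomalous] (`dt_bin`, `delta0`,
#'   `max_lag`, `fit_max_lag`, `r_blur`, `n_starts`, `seed`).
#' @param dt_bin,delta0,max_lag see [ta_msd].
#' @param fit_max_lag see [fit_anomalous].
#' @return data.frame with one row per track: `track_id`, `roi_id`, `gamma`,
#'   `beta`, `sigma`, `k_beta`, `resid_sd`, `valid`, `regime`.
#' @export
fit_kinetics <- function(ds, track_ids = NULL, dt_bin = 132e-6,
                         delta0 = 84e-6, max_lag = 0.05,
                         fit_max_lag = 0.05, ...) {
  if (is.null(track_ids)) track_ids <- ds$tracks$track_id
  trs <- split_tracks(filter_tracks(ds, track_ids))
  rows <- lapply(names(trs), function(id) {
    cu <- ta_msd(trs[[id]], dt_bin = dt_bin, delta0 = delta0,
                 max_lag = max_lag)
    f <- fit_anomalous(cu, fit_max_lag = fit_max_lag, ...)
    data.frame(track_id = id,
               roi_id = ds$tracks$roi_id[ds$tracks$track_id == id],
               gamma = f$gamma, beta = f$beta, sigma = f$sigma,
               k_beta = f$k_beta, resid_sd = f$resid_sd, valid = f$valid,
               regime = ifelse(is.na(f$regime), NA_character_, f$regime),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regime fractions per ROI
#'
#' Fractions of valid fits classified subdiffusive / Brownian /
#' superdiffusive in each ROI, plus the mean and SEM of each fraction across
#' ROIs (reporting is ROI-averaged).
#'
#' @param fits data.frame as returned by [fit_kinetics].
#' @return list with `per_roi` (data.frame roi_id x regime fractions and
#'   `n_valid`) and `summary` (regime, mean, sem across ROIs).
#' @export
regime_fractions <- function(fits) {
  ok <- fits[fits$valid & !is.na(fits$regime), , drop = FALSE]
  if (nrow(ok) == 0) stop("no valid fits")
  regs <- c("subdiffusive", "brownian", "superdiffusive")
  per <- do.call(rbind, lapply(split(ok, ok$roi_id), function(d) {
    f <- as.numeric(table(factor(d$regime, levels = regs))) / nrow(d)
    data.frame(roi_id = d$roi_id[1], subdiffusive = f[1], brownian = f[2],
               superdiffusive = f[3], n_valid = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  summ <- data.frame(
    regime = regs,
    mean = vapply(regs, function(r) mean(per[[r]]), numeric(1)),
    sem = vapply(regs, function(r)
      stats::sd(per[[r]]) / sqrt(nrow(per)), numeric(1)),
    row.names = NULL)
  list(per_roi = per, summary = summ)
}
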