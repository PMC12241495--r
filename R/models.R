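#' Corrected MSD model: free diffusion
#'
#' `MSD_free(n dt) = 2 n_d D dt (n - 2R) + 2 n_d sigma^2`, where `n` is the
#' lag in units of the bin width and R the motion-blur factor.
#'
#' @param lag lag time(s) in s (`= n_steps_m * dt`).
#' @param d diffusion coefficient (nm^2/s).
#' @param sigma localisation uncertainty (nm).
#' @param r_blur blur factor (1/6.2).
#' @param n_steps_m lag in bin units (n).
#' @param n_d dimensionality (2).
#' @return model MSD (nm^2).
#' @export
msd_model_free <- function(lag, d, sigma, r_blur = 1 / 6.2, n_steps_m,
                           n_d = 2) {
  dt <- lag / n_steps_m
  2 * n_d * d * dt * (n_steps_m - 2 * r_blur) + 2 * n_d * sigma^2
}

#' Corrected MSD model: confined diffusion
#'
#' `MSD_conf = (L^2/3) [1 - exp(-12 D_mu n dt / L^2)] (n - 2R) +
#' 2 n_d sigma^2`, with the blur factor `(n - 2R)` applied to the saturating
#' term exactly as the model is specified. The uncorrected plateau form is
#' available as [msd_model_conf_plateau].
#'
#' @inheritParams msd_model_free
#' @param d_mu intra-compartment diffusion coefficient (nm^2/s).
#' @param l confinement domain side L (nm).
#' @return model MSD (nm^2).
#' @export
msd_model_conf <- function(lag, d_mu, l, sigma, r_blur = 1 / 6.2, n_steps_m,
                           n_d = 2) {
  (l^2 / 3) * (1 - exp(-12 * d_mu * lag / l^2)) * (n_steps_m - 2 * r_blur) +
    2 * n_d * sigma^2
}

#' Uncorrected confined MSD (plateau form)
#'
#' `MSD_conf(n dt) = (L^2/3) [1 - exp(-12 D_mu n dt / L^2)]`: saturates at
#' the plateau `L^2/3` (the mean squared distance between two random points
#' in a square of side L), with equilibration time `tau = L^2 / (12 D_mu)`.
#'
#' @param lag lag time(s) in s.
#' @param d_mu intra-compartment diffusion coefficient (nm^2/s).
#' @param l confinement domain side L (nm).
#' @return model MSD (nm^2).
#' @export
msd_model_conf_plateau <- function(lag, d_mu, l) {
  (l^2 / 3) * (1 - exp(-12 * d_mu * lag / l^2))
}

#' Corrected MSD model: hop diffusion
#'
#' `MSD_hop = 2 n_d dt {D_M + ((D_mu - D_M)/D_mu) (L_hop^2/(6 n_d n dt))
#' [1 - exp(-12 D_mu n dt / L_hop^2)]} (n - 2R) + 2 n_d sigma^2`.
#' Reduces identically to [msd_model_free] with `d = d_m` when
#' `d_m = d_mu`.
#'
#' @inheritParams msd_model_free
#' @param d_mu short-term (intra-compartment) diffusion coefficient (nm^2/s).
#' @param d_m long-term (inter-compartment) diffusion coefficient (nm^2/s).
#' @param l_hop compartment size (nm).
#' @return model MSD (nm^2).
#' @export
msd_model_hop <- function(lag, d_mu, d_m, l_hop, sigma, r_blur = 1 / 6.2,
                          n_steps_m, n_d = 2) {
  dt <- lag / n_steps_m
  inner <- d_m + ((d_mu - d_m) / d_mu) * (l_hop^2 / (6 * n_d * lag)) *
    (1 - exp(-12 * d_mu * lag / l_hop^2))
  2 * n_d * dt * inner * (n_steps_m - 2 * r_blur) + 2 * n_d * sigma^2
}

#' Bayesian information criterion for an MSD model fit
#'
#' `BIC = n * ln(SSR / 2) + k * ln(n)`.
#'
#' @param ssr sum of squared residuals (nm^4).
#' @param n_points number of fitted points.
#' @param k_params number of free parameters.
#' @return BIC value; a perfect fit (`ssr = 0`) returns `-Inf` with a
#'   warning.
#' @export
bic_score <- function(ssr, n_points, k_params) {
  stopifnot(ssr >= 0, n_points >= 2)
  if (ssr == 0) {
    warning("SSR = 0 (perfect fit); BIC is -Inf")
    return(-Inf)
  }
  n_points * log(ssr / 2) + k_params * log(n_points)
}

#' Compartmentalisation summary
#'
#' Strength `S = D_mu / D_M` and equilibration time
#' `tau = L^2 / (12 D_mu)`.
#'
#' @param d_mu,d_m,l hop-model parameters.
#' @return list `s_strength`, `tau`.
#' @export
compartment_summary <- function(d_mu, d_m, l) {
  list(s_strength = d_mu / d_m, tau = l^2 / (12 * d_mu))
}

# Approximately log-spaced subset of the first `frac` of the curve's bins,
# always including the first and last selected bin.
log_sample_bins <- function(curve, fit_fraction = 0.20, n_pts = 15L) {
  k <- max(4L, ceiling(fit_fraction * nrow(curve)))
  k <- min(k, nrow(curve))
  idx <- unique(round(exp(seq(0, log(k), length.out = n_pts))))
  idx <- sort(unique(pmin(pmax(idx, 1L), k)))
  curve[idx, , drop = FALSE]
}

# Fit one of the three corrected MSD models to (lag, msd) points by bounded
# least squares with random restarts; returns par list, ssr, bic. `lag` is
# the empirical mean pair separation of each bin (continuous n = lag/dt).
# `whiten` (optional) left-multiplies the residual vector, turning the
# ordinary fit into a generalized least-squares fit.
fit_msd_model <- function(lag, y, dt_bin, model = c("free", "conf", "hop"),
                          n_restarts = 100L, seed = 1L, r_blur = 1 / 6.2,
                          frac_max = 1, whiten = NULL) {
  model <- match.arg(model)
  m <- lag / dt_bin
  # parameters are log10 for the D's and L; hop's d_m = frac * d_mu with
  # frac in (0, frac_max] so D_mu > D_M (S > 1) holds by construction
  bounds <- switch(model,
    free = list(lo = c(ld = 1, sigma = 0), hi = c(ld = 7, sigma = 50)),
    conf = list(lo = c(ld = 1, ll = 1, sigma = 0),
                hi = c(ld = 7, ll = 3, sigma = 50)),
    hop = list(lo = c(ld = 1, frac = 1e-6, ll = 1, sigma = 0),
               hi = c(ld = 7, frac = frac_max, ll = 3, sigma = 50)))
  predict_fn <- switch(model,
    free = function(p) msd_model_free(lag, 10^p[1], p[2], r_blur, m),
    conf = function(p) msd_model_conf(lag, 10^p[1], 10^p[2], p[3], r_blur, m),
    hop = function(p) msd_model_hop(lag, 10^p[1], p[2] * 10^p[1], 10^p[3],
                                    p[4], r_blur, m))
  resid_fn <- if (is.null(whiten)) {
    function(p) predict_fn(p) - y
  } else {
    function(p) as.numeric(whiten %*% (predict_fn(p) - y))
  }
  np <- length(bounds$lo)
  starts <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(i)
      stats::runif(np, bounds$lo, bounds$hi))
  })
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = bounds$lo, upper = bounds$hi,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(par = fit$par, ssr = ssr)
  }
  if (is.null(best)) return(NULL)
  p <- best$par
  pars <- switch(model,
    free = list(d_free = 10^p[1], sigma = p[2]),
    conf = list(d_mu = 10^p[1], l = 10^p[2], sigma = p[3]),
    hop = list(d_mu = 10^p[1], d_m = p[2] * 10^p[1], frac = p[2],
               l_hop = 10^p[3], sigma = p[4]))
  k <- switch(model, free = 2L, conf = 3L, hop = 4L)
  bic <- suppressWarnings(bic_score(best$ssr, length(lag), k))
  c(pars, list(ssr = best$ssr, bic = bic, k_params = k,
               n_points = length(lag)))
}

#' Classify segments as free, confined, or hop diffusion
#'
#' The track is truncated into consecutive segments of `truncate_len`
#' localisations (a final partial segment of at least half that length is
#' kept). Per segment, the TA-MSD is computed over the segment and the
#' initial `fit_fraction` of its bins is resampled at approximately
#' log-spaced lags. Model choice and parameter reporting are separated:
#'
#' * Selection: the three corrected MSD models ([msd_model_free],
#'   [msd_model_conf], [msd_model_hop]) are fitted by generalized least
#'   squares, whitening the residuals with the single-track TA-MSD
#'   covariance model `C_ij = msd_i msd_j ((4/3) min(tau_i, tau_j)/T +
#'   (2/n_pairs_i) delta_ij)` (T = segment duration). The smooth, strongly
#'   correlated excursions of a single-track MSD otherwise mimic curvature
#'   and draw the flexible models onto Brownian segments; whitening removes
#'   that advantage. The model with the lowest BIC on the whitened residuals
#'   wins.
#' * Relabelling: a hop selection whose inter-compartment coefficient is
#'   unresolved (`D_M < d_m_floor`, default 1e4 nm^2/s, an order of
#'   magnitude below membrane-scale diffusion) is reported as confined -
#'   the regime the confined model exists for. When hop is retained, the
#'   compartmentalisation strength `S = D_mu / D_M` from the selection fit
#'   is reported. Conversely, a confined selection whose fitted
#'   equilibration time `L^2/(12 D_mu)` is below ten bin widths saturates
#'   essentially instantaneously (a domain at the localisation-noise
#'   scale); over the fitted range such a curve is a straight line, and the
#'   segment is reported free.
#' * Parameters: the reported coefficients come from ordinary (unweighted)
#'   least-squares fits of each model, which pin the curve amplitudes (and
#'   hence `L_hop`); for confined segments the domain size `l_conf` is
#'   estimated from the saturating plateau form ([msd_model_conf_plateau]
#'   plus a noise floor), whose plateau is the direct estimate of L^2/3.
#'
#' @param track data.frame with `t`, `x`, `y`.
#' @param truncate_len segment length (500 localisations).
#' @param fit_fraction initial fraction of MSD bins fitted (0.20).
#' @param n_restarts restarts per model fit (100).
#' @param seed integer seed for the restarts.
#' @param constraint `"s_gt_1"` (D_mu > D_M), `"s_gt_5"` (D_mu > 5 D_M), or
#'   `"none"`.
#' @param dt_bin,delta0 TA-MSD binning parameters.
#' @param r_blur blur factor.
#' @param n_log_pts number of log-spaced MSD points fitted.
#' @param d_m_floor D_M resolution floor (nm^2/s) for the hop-to-confined
#'   relabel.
#' @return data.frame with one row per segment: `segment`, `n_locs`,
#'   per-model parameters and unweighted SSRs (`d_free`, `sigma_free`,
#'   `ssr_free`, `d_mu_conf`, `l_conf`, `sigma_conf`, `ssr_conf`,
#'   `d_mu_hop`, `d_m_hop`, `l_hop`, `sigma_hop`, `ssr_hop`), the
#'   whitened-fit BICs (`bic_free`, `bic_conf`, `bic_hop`),
#'   `model_selected` (raw BIC winner), `class` (after the unresolved-D_M
#'   relabel), and `s_strength` (hop only).
#' @export
fit_and_select <- function(track, truncate_len = 500L, fit_fraction = 0.20,
                           n_restarts = 100L, seed = 1L,
                           constraint = c("s_gt_1", "s_gt_5", "none"),
                           dt_bin = 132e-6, delta0 = 84e-6,
                           r_blur = 1 / 6.2, n_log_pts = 15L,
                           d_m_floor = 1e4) {
  constraint <- match.arg(constraint)
  frac_max <- switch(constraint, s_gt_1 = 1, s_gt_5 = 0.2, none = 1)
  n <- nrow(track)
  stopifnot(n >= 50)
  n_seg <- max(1L, n %/% truncate_len)
  bounds <- seq(0L, n_seg * truncate_len, by = truncate_len)
  rem <- n - n_seg * truncate_len
  if (rem >= truncate_len / 2) bounds <- c(bounds, n)
  rows <- list()
  for (s in seq_len(length(bounds) - 1L)) {
    idx <- (bounds[s] + 1L):bounds[s + 1L]
    seg <- track[idx, , drop = FALSE]
    dur <- max(seg$t) - min(seg$t)
    cu <- ta_msd(seg, dt_bin = dt_bin, delta0 = delta0, max_lag = dur)
    pts <- log_sample_bins(cu, fit_fraction, n_log_pts)
    if (nrow(pts) < 5) next
    lag <- if (is.null(pts$tau_mean)) pts$m * dt_bin else pts$tau_mean
    y <- pts$msd
    # whitening transform from the single-track TA-MSD covariance model
    C <- outer(y, y) * ((4 / 3) * outer(lag, lag, pmin) / dur)
    diag(C) <- diag(C) + y^2 * 2 / pts$n_pairs
    whiten <- tryCatch(solve(t(chol(C))), error = function(e) NULL)
    fit_both <- function(model, stream, frac_max = 1) {
      list(sel = fit_msd_model(lag, y, dt_bin, model, n_restarts,
                               sub_seed(seed, stream), r_blur,
                               frac_max = frac_max, whiten = whiten),
           par = fit_msd_model(lag, y, dt_bin, model, n_restarts,
                               sub_seed(seed, stream + 1L), r_blur,
                               frac_max = frac_max))
    }
    fits <- list(free = fit_both("free", 6L * s),
                 conf = fit_both("conf", 6L * s + 2L),
                 hop = fit_both("hop", 6L * s + 4L, frac_max = frac_max))
    ok <- !vapply(fits, function(f) is.null(f$sel), logical(1))
    if (!any(ok) || is.null(whiten)) {
      rows[[s]] <- data.frame(segment = s, n_locs = length(idx),
                              model_selected = "unclassified",
                              class = "unclassified", s_strength = NA_real_)
      next
    }
    bics <- vapply(fits[ok], function(f) f$sel$bic, numeric(1))
    sel <- names(bics)[which.min(bics)]
    class <- sel
    s_strength <- NA_real_
    if (sel == "hop") {
      if (fits$hop$sel$d_m < d_m_floor) {
        class <- "conf"
      } else {
        s_strength <- fits$hop$sel$d_mu / fits$hop$sel$d_m
      }
    } else if (sel == "conf") {
      # a confined fit that equilibrates within the first few bins describes
      # a domain at the localisation-noise scale: over the fitted range the
      # curve is a straight line and carries no confinement evidence
      tau_eq_hat <- fits$conf$sel$l^2 / (12 * fits$conf$sel$d_mu)
      if (tau_eq_hat < 10 * dt_bin) class <- "free"
    }
    # confinement-size reporter: plateau-form fit (amplitude = L^2/3)
    plat <- fit_conf_plateau(lag, y, n_restarts = max(5L, n_restarts %/% 3L),
                             seed = sub_seed(seed, 6L * s + 5L))
    rows[[s]] <- data.frame(
      segment = s, n_locs = length(idx),
      d_free = fits$free$par$d_free %||% NA_real_,
      sigma_free = fits$free$par$sigma %||% NA_real_,
      ssr_free = fits$free$par$ssr %||% NA_real_,
      bic_free = fits$free$sel$bic %||% NA_real_,
      d_mu_conf = plat$d_mu %||% NA_real_,
      l_conf = plat$l %||% NA_real_,
      sigma_conf = plat$sigma %||% NA_real_,
      ssr_conf = fits$conf$par$ssr %||% NA_real_,
      bic_conf = fits$conf$sel$bic %||% NA_real_,
      d_mu_hop = fits$hop$par$d_mu %||% NA_real_,
      d_m_hop = fits$hop$par$d_m %||% NA_real_,
      l_hop = fits$hop$par$l_hop %||% NA_real_,
      sigma_hop = fits$hop$par$sigma %||% NA_real_,
      ssr_hop = fits$hop$par$ssr %||% NA_real_,
      bic_hop = fits$hop$sel$bic %||% NA_real_,
      model_selected = sel, class = class, s_strength = s_strength,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Saturating plateau-form fit: msd = (L^2/3)(1 - exp(-12 D_mu lag / L^2)) +
# 2 n_d sigma^2, ordinary least squares; direct estimator of the
# confinement domain size.
fit_conf_plateau <- function(lag, y, n_restarts = 30L, seed = 1L) {
  resid_fn <- function(p) {
    msd_model_conf_plateau(lag, 10^p[1], 10^p[2]) + 4 * p[3]^2 - y
  }
  lo <- c(1, 1, 0); hi <- c(7, 3, 50)
  starts <- with_seed(seed, lapply(seq_len(n_restarts), function(i)
    stats::runif(3, lo, hi)))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lo, upper = hi, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(par = fit$par, ssr = ssr)
  }
  if (is.null(best)) return(list(d_mu = NULL, l = NULL, sigma = NULL))
  list(d_mu = 10^best$par[1], l = 10^best$par[2], sigma = best$par[3])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ensemble MSD curves per selected diffusion class
#'
#' Averages the TA-MSD curves of the segments assigned to each class and
#' overlays the class's median-parameter model prediction. For the hop class
#' the two pure-diffusion reference lines at `D_mu` and `D_M`
#' (`4 D lag`) are included; they bracket the ensemble curve at short and
#' long lags respectively.
#'
#' @param curves list of `mfx_msd` curves, one per segment.
#' @param selection data.frame from [fit_and_select] (row-aligned with
#'   `curves`).
#' @param r_blur blur factor used in the model overlays.
#' @return named list per class: data.frame `lag`, `msd` (ensemble),
#'   `model` (fitted-model overlay), and for hop additionally `ref_d_mu`,
#'   `ref_d_m`.
#' @export
ensemble_model_curves <- function(curves, selection, r_blur = 1 / 6.2) {
  stopifnot(length(curves) == nrow(selection))
  out <- list()
  for (cls in c("free", "conf", "hop")) {
    sel <- which(selection$class == cls)
    if (length(sel) == 0) next
    ens <- ea_ta_msd(curves[sel])
    med <- function(col) stats::median(selection[[col]][sel], na.rm = TRUE)
    model <- switch(cls,
      free = msd_model_free(ens$lag, med("d_free"), med("sigma_free"),
                            r_blur, ens$m),
      conf = msd_model_conf(ens$lag, med("d_mu_conf"), med("l_conf"),
                            med("sigma_conf"), r_blur, ens$m),
      hop = msd_model_hop(ens$lag, med("d_mu_hop"), med("d_m_hop"),
                          med("l_hop"), med("sigma_hop"), r_blur, ens$m))
    df <- data.frame(lag = ens$lag, msd = ens$msd, model = model)
    if (cls == "hop") {
      df$ref_d_mu <- 4 * med("d_mu_hop") * ens$lag
      df$ref_d_m <- 4 * med("d_m_hop") * ens$lag
    }
    out[[cls]] <- df
  }
  out
}
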