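test_that("binned TA-MSD equals the classical fixed-lag oracle on regular sampling", {
  # regular interval 151 us: wider than one bin, so every offset k maps to
  # its own bin, and k*dt never coincides with a bin boundary for k <= 30
  set.seed(41)
  dt <- 151e-6
  for (rep in 1:5) {
    n <- 150
    tr <- toy_track(cumsum(rnorm(n, 0, 10)), cumsum(rnorm(n, 0, 10)),
                    t = (0:(n - 1)) * dt)
    cu <- ta_msd(tr, max_lag = 0.05)
    for (k in 1:30) {
      m_k <- floor((k * dt - 84e-6) / 132e-6) + 1
      row <- cu[cu$m == m_k, ]
      expect_equal(nrow(row), 1)
      expect_equal(row$msd, classical_tamsd(tr, k), tolerance = 1e-12)
      expect_equal(row$n_pairs, n - k)
    }
  }
})

test_that("TA-MSD degenerate cases", {
  # stationary noiseless track -> msd identically 0
  n <- 50
  tr <- toy_track(rep(5, n), rep(7, n), t = (0:(n - 1)) * 5e-4)
  expect_true(all(ta_msd(tr)$msd == 0))
  # two-point track -> exactly one populated bin with one pair
  tr2 <- toy_track(c(0, 10), c(0, 0), t = c(0, 5e-4))
  cu2 <- ta_msd(tr2)
  expect_equal(nrow(cu2), 1)
  expect_equal(cu2$n_pairs, 1)
  expect_equal(cu2$msd, 100)
})

test_that("TA-MSD is rigid-motion invariant and scales as s^2", {
  ds <- simulate_dataset(sim_config(seed = 42, n_tracks = 1, track_len = 300))
  tr <- get_track(ds, "t0001")
  cu <- ta_msd(tr)
  th <- 1.1
  rot <- toy_track(cos(th) * tr$x - sin(th) * tr$y + 100,
                   sin(th) * tr$x + cos(th) * tr$y - 50, t = tr$t)
  expect_equal(ta_msd(rot)$msd, cu$msd, tolerance = 1e-9)
  scl <- toy_track(3 * tr$x, 3 * tr$y, t = tr$t)
  expect_equal(ta_msd(scl)$msd, 9 * cu$msd, tolerance = 1e-12)
})

test_that("ensemble averaging is a weighted per-bin mean", {
  ds <- simulate_dataset(sim_config(seed = 43, n_tracks = 2, track_len = 200))
  trs <- split_tracks(ds)
  cu <- ta_msd(trs[[1]])
  # single curve -> itself
  e1 <- ea_ta_msd(list(cu))
  expect_equal(e1$msd, cu$msd)
  # two identical curves -> same curve
  e2 <- ea_ta_msd(list(cu, cu))
  expect_equal(e2$msd, cu$msd)
  expect_equal(e2$n_pairs, 2 * cu$n_pairs)
})

test_that("EA-TA-MSD of Brownian tracks has unit log-log slope", {
  cfg <- sim_config(seed = 44, n_tracks = 100, motion_model = "brownian",
                    sigma_loc = 0, track_len = 500)
  trs <- split_tracks(simulate_dataset(cfg))
  ens <- ea_ta_msd(lapply(trs, ta_msd))
  slope <- stats::coef(stats::lm(log(msd) ~ log(lag), data = ens))[2]
  expect_lt(abs(slope - 1), 0.05)
})

test_that("anomalous fit recovers exact model curves (inverse crime)", {
  m <- 1:60
  for (beta in c(0.5, 0.8, 1.0, 1.2, 1.5)) {
    gamma <- 2.5e4
    y <- anomalous_model(m, 132e-6, gamma, beta, 7)
    cu <- structure(data.frame(m = m, lag = m * 132e-6, msd = y,
                               n_pairs = 100),
                    class = c("mfx_msd", "data.frame"), dt_bin = 132e-6,
                    delta0 = 84e-6, m_max = 60, duration = 1)
    f <- fit_anomalous(cu)
    expect_lt(abs(f$gamma - gamma) / gamma, 1e-6)
    expect_lt(abs(f$beta - beta) / beta, 1e-6)
    expect_lt(abs(f$sigma - 7) / 7, 1e-6)
    expect_equal(f$k_beta, 4 * f$gamma)
    expect_true(f$valid)
  }
})

test_that("rejection rules flag noisy and sparse curves", {
  m <- 1:60
  y <- anomalous_model(m, 132e-6, 1e5, 1, 7)
  noisy <- y + rep(c(3000, -3000), 30)
  cu <- structure(data.frame(m = m, lag = m * 132e-6, msd = pmax(noisy, 1),
                             n_pairs = 100),
                  class = c("mfx_msd", "data.frame"), dt_bin = 132e-6,
                  delta0 = 84e-6, m_max = 60, duration = 1)
  f <- fit_anomalous(cu)
  expect_false(f$valid)
  expect_match(f$reason, "residual")

  sparse <- structure(data.frame(m = seq(1, 60, by = 4),
                                 lag = seq(1, 60, by = 4) * 132e-6,
                                 msd = y[seq(1, 60, by = 4)], n_pairs = 100),
                      class = c("mfx_msd", "data.frame"), dt_bin = 132e-6,
                      delta0 = 84e-6, m_max = 60, duration = 1)
  f2 <- fit_anomalous(sparse)
  expect_false(f2$valid)
  expect_match(f2$reason, "50%")
})

test_that("regime classification uses the beta thresholds", {
  expect_equal(classify_regime(0.8), "subdiffusive")
  expect_equal(classify_regime(0.9), "subdiffusive")   # boundary: beta <= 0.9
  expect_equal(classify_regime(1.0), "brownian")
  expect_equal(classify_regime(1.1), "brownian")       # boundary: beta <= 1.1
  expect_equal(classify_regime(1.2), "superdiffusive")
  expect_error(classify_regime(NaN))
})

test_that("regime fractions normalise per ROI and recover a known mixture", {
  fits <- data.frame(track_id = sprintf("t%02d", 1:40),
                     roi_id = rep(c("r1", "r2"), each = 20),
                     beta = rep(1.0, 40), valid = TRUE,
                     regime = "brownian", stringsAsFactors = FALSE)
  rf <- regime_fractions(fits)
  expect_equal(rf$per_roi$brownian, c(1, 1))
  expect_equal(rf$per_roi$subdiffusive + rf$per_roi$brownian +
                 rf$per_roi$superdiffusive, c(1, 1))

  # 20/30/50 mixture by construction
  regs <- c(rep("subdiffusive", 8), rep("brownian", 12),
            rep("superdiffusive", 20))
  fits2 <- data.frame(track_id = sprintf("t%02d", 1:40), roi_id = "r1",
                      beta = 1, valid = TRUE, regime = regs,
                      stringsAsFactors = FALSE)
  rf2 <- regime_fractions(fits2)
  expect_equal(rf2$per_roi$subdiffusive, 0.2)
  expect_equal(rf2$per_roi$brownian, 0.3)
  expect_equal(rf2$per_roi$superdiffusive, 0.5)
})

test_that("blur correction is negligible at large lags on blur-free data", {
  # fitted K_beta with R = 1/6.2 vs R = 0 differs < 5% when fitting m >> 1
  m <- 20:80
  y <- anomalous_model(m, 132e-6, 5e4, 1, 7, r_blur = 0)
  cu <- structure(data.frame(m = m, lag = m * 132e-6, msd = y, n_pairs = 100),
                  class = c("mfx_msd", "data.frame"), dt_bin = 132e-6,
                  delta0 = 84e-6, m_max = 80, duration = 1)
  fR <- fit_anomalous(cu, fit_max_lag = 0.012, r_blur = 1 / 6.2)
  f0 <- fit_anomalous(cu, fit_max_lag = 0.012, r_blur = 0)
  expect_lt(abs(fR$k_beta - f0$k_beta) / f0$k_beta, 0.05)
})
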