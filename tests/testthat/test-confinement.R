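test_that("recurrence states: no revisits -> free, tight cluster -> confined", {
  # straight-line walk with constant step never revisits a step circle
  n <- 100
  line <- toy_track(seq(0, by = 30, length.out = n), rep(0, n))
  expect_false(any(recurrence_states(line)))

  # 200 localisations inside a 20 nm disc revisit every circle
  set.seed(51)
  th <- runif(200, 0, 2 * pi)
  r <- 10 * sqrt(runif(200))
  disc <- toy_track(r * cos(th), r * sin(th))
  expect_true(all(recurrence_states(disc, v_th = 33)))

  # infinite threshold -> all free
  expect_false(any(recurrence_states(disc, v_th = Inf)))
})

test_that("majority smoothing follows the 3-step window rule", {
  C <- TRUE; F_ <- FALSE
  expect_equal(smooth_states(c(C, F_, C)), c(C, C, C))
  expect_equal(smooth_states(c(F_, F_, F_)), c(F_, F_, F_))
  # alternating C/F of length 12: windows (C,F,C)(F,C,F)(C,F,C)(F,C,F)
  alt <- rep(c(C, F_), 6)
  sm <- smooth_states(alt)
  expect_equal(sm, rep(c(C, C, C, F_, F_, F_), 2))
  # no isolated single-step states remain
  expect_true(all(rle(sm)$lengths >= 3))
  # trailing partial window: length 7, last window is a single F -> F
  expect_equal(smooth_states(c(C, C, C, C, C, C, F_))[7], F_)
  # trailing tie (2 steps, one each) inherits the previous window's state
  expect_equal(smooth_states(c(C, C, C, C, F_))[4:5], c(C, C))
})

test_that("sojourn segmentation partitions time and measures geometry", {
  # all confined -> r = 1, no transitions
  n <- 20
  tr <- toy_track(rnorm(n), rnorm(n), t = (0:(n - 1)) * 0.01)
  seg <- segment_sojourns(tr, rep(TRUE, n))
  expect_equal(seg$summary$confined_ratio_r, 1)
  expect_equal(seg$summary$transition_rate, 0)

  # one C->F change over a 0.1 s track -> 10 transitions per second
  tr2 <- toy_track(1:11, 1:11, t = seq(0, 0.1, length.out = 11))
  seg2 <- segment_sojourns(tr2, rep(c(TRUE, FALSE), c(5, 6)))
  expect_equal(seg2$summary$transition_rate, 10)
  # confined + free fractions partition the duration exactly
  expect_equal(seg2$summary$confined_ratio_r + seg2$summary$free_ratio, 1)

  # square of 4 points, side 10 nm -> hull area 100 nm^2
  sq <- toy_track(c(0, 10, 10, 0), c(0, 0, 10, 10))
  seg3 <- segment_sojourns(sq, rep(TRUE, 4))
  expect_equal(seg3$sojourns$hull_area, 100)
  expect_true(seg3$sojourns$eccentricity >= 0 &&
                seg3$sojourns$eccentricity < 1)

  # degenerate hull: < 3 unique points -> area 0, ellipse undefined
  two <- toy_track(c(0, 5, 0, 5), c(0, 0, 0, 0))
  seg4 <- segment_sojourns(two, rep(TRUE, 4))
  expect_equal(seg4$sojourns$hull_area, 0)
  expect_true(is.na(seg4$sojourns$eccentricity))
})

test_that("transition rate scales inversely with time units only", {
  set.seed(52)
  n <- 60
  tr <- toy_track(cumsum(rnorm(n)), cumsum(rnorm(n)), t = (0:(n - 1)) * 1e-3)
  st <- rep(c(TRUE, FALSE, TRUE), c(20, 20, 20))
  base <- segment_sojourns(tr, st)$summary$transition_rate
  # spatial rescaling leaves the rate unchanged
  sp <- toy_track(5 * tr$x, 5 * tr$y, t = tr$t)
  expect_equal(segment_sojourns(sp, st)$summary$transition_rate, base)
  # doubling all times halves the rate
  tm <- toy_track(tr$x, tr$y, t = 2 * tr$t)
  expect_equal(segment_sojourns(tm, st)$summary$transition_rate, base / 2)
})

test_that("detected confinement overlaps ground truth (Jaccard >= 0.7)", {
  cfg <- sim_config(seed = 53, n_tracks = 12, track_len = 1800, D_mu = 1e5)
  ds <- simulate_two_state_dataset(cfg, L_trap = 50)
  trs <- split_tracks(ds)
  jac <- r_err <- numeric(0)
  for (id in names(trs)) {
    tr <- trs[[id]]
    st <- smooth_states(recurrence_states(tr))
    truth <- tr$true_confined
    jac <- c(jac, sum(st & truth) / sum(st | truth))
    seg <- segment_sojourns(tr, st)
    r_true <- sum(diff(tr$t)[truth[-1]]) / (max(tr$t) - min(tr$t))
    r_err <- c(r_err, abs(seg$summary$confined_ratio_r - r_true))
  }
  expect_gte(mean(jac), 0.7)
  expect_lte(mean(r_err), 0.15)
})

test_that("sojourn kinetics fit confined portions as subdiffusive", {
  # simulated confined sojourns (50 nm domain) vs free Brownian sojourns,
  # each fitted as a single sojourn with the 25 ms segment-level fit range
  sojourn_betas <- function(model, seed, n) {
    cfg <- sim_config(seed = seed, n_tracks = n, motion_model = model,
                      D_mu = 1e5, L = 50, track_len = 600)
    trs <- split_tracks(simulate_dataset(cfg))
    vapply(trs, function(tr) {
      seg <- segment_sojourns(tr, rep(TRUE, nrow(tr)))
      sojourn_kinetics(tr, seg$sojourns, seed = 1)$beta[1]
    }, numeric(1))
  }
  b_conf <- sojourn_betas("confined", 54, 50)
  b_free <- sojourn_betas("brownian", 55, 50)
  expect_gte(mean(b_conf <= 0.9, na.rm = TRUE), 0.7)
  expect_gt(mean(b_free >= 0.9 & b_free <= 1.1, na.rm = TRUE), 0.5)

  # detected long confined sojourns in two-state tracks skew subdiffusive
  cfg <- sim_config(seed = 56, n_tracks = 6, track_len = 1800, D_mu = 1e5)
  ds <- simulate_two_state_dataset(cfg, L_trap = 50)
  trs <- split_tracks(ds)
  bc <- numeric(0)
  for (id in names(trs)) {
    tr <- trs[[id]]
    st <- smooth_states(recurrence_states(tr))
    seg <- segment_sojourns(tr, st)
    sk <- sojourn_kinetics(tr, seg$sojourns, seed = 1)
    bc <- c(bc, sk$beta[sk$kind == "confined" & sk$n_locs >= 50 &
                          !is.na(sk$beta)])
  }
  expect_gte(mean(bc <= 0.9), 0.7)

  # too-short sojourns are skipped
  n <- 30
  tr <- toy_track(cumsum(rnorm(n, 0, 10)), cumsum(rnorm(n, 0, 10)),
                  t = (0:(n - 1)) * 5e-4)
  st <- rep(c(TRUE, FALSE), c(5, 25))
  seg <- segment_sojourns(tr, st)
  sk <- sojourn_kinetics(tr, seg$sojourns, min_locs = 10)
  expect_true(is.na(sk$beta[sk$n_locs == 5]))
})
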