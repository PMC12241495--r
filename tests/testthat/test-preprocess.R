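test_that("frustrated events (single-step tracks) are removed", {
  tracks <- list(
    toy_track(c(0, 5), c(0, 0)),                  # 1 step -> removed
    toy_track(c(0, 5, 10), c(0, 0, 0)),           # 2 steps -> kept
    toy_track(cumsum(rep(1, 100)), rep(0, 100)))  # long -> kept
  ds <- toy_dataset(tracks)
  out <- suppressMessages(drop_frustrated(ds))
  expect_equal(n_tracks(out), 2)
  expect_equal(attr(out, "n_frustrated"), 1L)

  empty <- mfx_dataset(data.frame(track_id = character(0),
                                  roi_id = character(0), t = numeric(0),
                                  x = numeric(0), y = numeric(0)))
  expect_equal(n_tracks(drop_frustrated(empty)), 0)
})

test_that("radius of gyration matches geometry and a brute-force oracle", {
  expect_equal(radius_of_gyration(toy_track(rep(3, 5), rep(4, 5))), 0)
  # two points distance d apart -> d/2
  expect_equal(radius_of_gyration(toy_track(c(0, 6), c(0, 8))), 5)
  # large track vs direct two-pass summation
  set.seed(8)
  tr <- toy_track(rnorm(1e4, 0, 50), rnorm(1e4, 0, 50))
  brute <- sqrt(sum((tr$x - mean(tr$x))^2 + (tr$y - mean(tr$y))^2) / nrow(tr))
  expect_equal(radius_of_gyration(tr), brute, tolerance = 1e-9)
})

test_that("mobility classification separates immobile from Brownian tracks", {
  imm <- simulate_dataset(sim_config(seed = 31, n_tracks = 60,
                                     motion_model = "immobile",
                                     track_len = 500))
  mob <- simulate_dataset(sim_config(seed = 32, n_tracks = 60,
                                     motion_model = "brownian",
                                     track_len = 500))
  ds <- combine_datasets(imm, mob, prefixes = c("i.", "m."))
  calls <- classify_mobility(ds)
  truth <- ifelse(grepl("^i\\.", calls$track_id), "immobile", "mobile")
  err_imm <- mean(calls$label[truth == "immobile"] != "immobile")
  err_mob <- mean(calls$label[truth == "mobile"] != "mobile")
  expect_lte(err_imm, 0.05)
  expect_lte(err_mob, 0.05)
  # immobile fraction of the ~50/50 mixture
  expect_lt(abs(mean(calls$label == "immobile") - 0.5), 0.05)

  # explicit threshold 0 -> everything mobile
  all_mob <- classify_mobility(ds, threshold = 0)
  expect_true(all(all_mob$label == "mobile"))

  # too few tracks for the automatic threshold
  small <- filter_tracks(ds, ds$tracks$track_id[1:2])
  expect_error(classify_mobility(small), "3")
})

test_that("mobility ratio is invariant under rigid motions", {
  ds <- simulate_dataset(sim_config(seed = 33, n_tracks = 5, track_len = 200))
  r0 <- classify_mobility(ds, threshold = 1)$ratio
  th <- 0.7
  rot <- ds
  x <- ds$locs$x; y <- ds$locs$y
  rot$locs$x <- cos(th) * x - sin(th) * y + 1234
  rot$locs$y <- sin(th) * x + cos(th) * y - 987
  r1 <- classify_mobility(rot, threshold = 1)$ratio
  expect_equal(r1, r0, tolerance = 1e-12)
})

test_that("species assignment follows the DCR thresholds", {
  mk <- function(dcr) {
    n <- 20
    red <- round(dcr * 1000)
    data.frame(t = (0:(n - 1)) * 1e-3, x = rnorm(n, 500), y = rnorm(n, 500),
               counts_red = rep(red, n), counts_blue = rep(1000 - red, n),
               eco = 1000)
  }
  ds <- toy_dataset(list(mk(0.60), mk(0.30), mk(0.47)))
  sp <- classify_species(ds)
  expect_equal(sp$label, c("species_B", "species_A", "codiffusion_candidate"))

  no_counts <- toy_dataset(list(toy_track(1:5, 1:5)))
  expect_error(classify_species(no_counts), "channel")
})

test_that("species calls survive 2x subsampling when DCR is well separated", {
  dsA <- simulate_dataset(sim_config(seed = 34, n_tracks = 25,
                                     species = "species_A", track_len = 200))
  dsB <- simulate_dataset(sim_config(seed = 35, n_tracks = 25,
                                     species = "species_B", track_len = 200))
  ds <- combine_datasets(dsA, dsB, prefixes = c("A.", "B."))
  full <- classify_species(ds)
  sub <- ds
  sub$locs <- sub$locs[ave(seq_len(nrow(sub$locs)), sub$locs$track_id,
                           FUN = seq_along) %% 2 == 1, ]
  sub2 <- classify_species(mfx_dataset(sub$locs, rois = ds$rois))
  truth <- ifelse(grepl("^A\\.", full$track_id), "species_A", "species_B")
  expect_lt(mean(full$label != truth), 0.01)
  expect_lt(mean(sub2$label != truth[match(sub2$track_id, full$track_id)]),
            0.01)
})

test_that("DCR histogram of a mixed dataset is bimodal with the set means", {
  library(mclust)
  dsA <- simulate_dataset(sim_config(seed = 36, n_tracks = 30,
                                     species = "species_A", track_len = 300))
  dsB <- simulate_dataset(sim_config(seed = 37, n_tracks = 30,
                                     species = "species_B", track_len = 300))
  dcr <- c(dsA$locs$dcr, dsB$locs$dcr)
  fit <- mclust::Mclust(dcr, G = 2, modelNames = "V", verbose = FALSE)
  mu <- sort(fit$parameters$mean)
  expect_lt(abs(mu[1] - 0.30), 0.02)
  expect_lt(abs(mu[2] - 0.65), 0.02)
})

test_that("co-diffusion segments require corridor DCR plus elevated ECO", {
  n <- 60
  # all high DCR, flat eco -> nothing
  tr1 <- data.frame(t = (0:(n - 1)) * 1e-3, x = 1:n, y = 1:n,
                    dcr = rep(0.6, n), eco = rep(40, n))
  expect_equal(nrow(detect_codiffusion_segments(tr1)), 0)
  # corridor DCR but single-emitter eco -> nothing
  tr2 <- tr1
  tr2$dcr[20:40] <- 0.47
  expect_equal(nrow(detect_codiffusion_segments(tr2)), 0)
  # corridor + doubled eco -> one segment over the window
  tr3 <- tr2
  tr3$eco[20:40] <- 90
  seg <- detect_codiffusion_segments(tr3)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_index, 20)
  expect_equal(seg$end_index, 40)
  expect_true(seg$mean_dcr >= 0.40 && seg$mean_dcr <= 0.55)
})

test_that("detector recovers >= 80% of simulated joint windows", {
  cfg <- sim_config(seed = 38, n_tracks = 30, species = "species_A",
                    track_len = 250,
                    co_diffusion = list(pair_fraction = 1, joint_len = 50))
  ds <- simulate_dataset(cfg)
  trs <- split_tracks(ds)
  cover <- vapply(seq_len(nrow(ds$tracks)), function(i) {
    tr <- trs[[ds$tracks$track_id[i]]]
    seg <- detect_codiffusion_segments(tr)
    if (nrow(seg) == 0) return(0)
    truth <- ds$tracks$codiff_start[i]:ds$tracks$codiff_end[i]
    got <- unlist(lapply(seq_len(nrow(seg)), function(j)
      seg$start_index[j]:seg$end_index[j]))
    length(intersect(truth, got)) / length(truth)
  }, numeric(1))
  expect_gte(mean(cover), 0.8)
})
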