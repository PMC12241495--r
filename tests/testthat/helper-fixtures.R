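# Shared fixtures: small deterministic tracks and ROIs built in code.

toy_track <- function(x, y, t = seq_along(x) * 1e-3 - 1e-3) {
  data.frame(t = t, x = x, y = y)
}

unit_square_roi <- function(side = 1000, id = "roi1") {
  mfx_roi_rect(side, id = id)
}

# dataset from a list of track data.frames
toy_dataset <- function(tracks, roi = unit_square_roi()) {
  locs <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    d <- tracks[[i]]
    d$track_id <- sprintf("t%02d", i)
    d$roi_id <- roi$id
    d
  }))
  mfx_dataset(locs, rois = list(roi))
}

# classical fixed-lag TA-MSD oracle for regularly sampled tracks
classical_tamsd <- function(track, k) {
  n <- nrow(track)
  dx <- track$x[(1 + k):n] - track$x[1:(n - k)]
  dy <- track$y[(1 + k):n] - track$y[1:(n - k)]
  mean(dx^2 + dy^2)
}
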