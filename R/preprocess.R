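#' Remove frustrated events
#'
#' Drops tracks consisting of at most one displacement (two or fewer
#' localisations), which carry no kinetic information.
#'
#' @param ds an [mfx_dataset].
#' @return the filtered dataset; the number of removed tracks is attached as
#'   attribute `"n_frustrated"` and reported via `message()`.
#' @export
drop_frustrated <- function(ds) {
  keep <- ds$tracks$track_id[ds$tracks$n_locs > 2L]
  n_rm <- nrow(ds$tracks) - length(keep)
  out <- filter_tracks(ds, keep)
  attr(out, "n_frustrated") <- n_rm
  if (n_rm > 0) message(n_rm, " frustrated track(s) removed")
  out
}

#' Radius of gyration of a track
#'
#' `Rg = sqrt( (1/N) * sum_i |r_i - <r>|^2 )`, the root-mean-square deviation
#' of the localisations from their centroid.
#'
#' @param track data.frame with `x`, `y` columns (nm).
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(track) {
  stopifnot(nrow(track) >= 1)
  sqrt(mean((track$x - mean(track$x))^2 + (track$y - mean(track$y))^2))
}

#' Mean step length of a track
#' @param track data.frame with `x`, `y` columns; needs >= 2 localisations.
#' @return mean Euclidean displacement between consecutive localisations (nm).
#' @export
mean_step_length <- function(track) {
  stopifnot(nrow(track) >= 2)
  mean(sqrt(diff(track$x)^2 + diff(track$y)^2))
}

#' Classify tracks as immobile or mobile
#'
#' Immobility criterion based on the ratio of the radius of gyration to the
#' mean step length: an immobile emitter shows only localisation noise, so its
#' Rg stays at the noise scale while a mobile one accumulates displacement and
#' its ratio grows with track length. When no threshold is supplied it is
#' derived from the calibration tracks: the immobile mode of the (bimodal)
#' ratio distribution is located by a two-means split of the log ratios, and
#' the threshold is the upper bound of that mode's 95% band,
#' `mean + 1.96 * SD` over the lower cluster. Tracks with ratio below the
#' threshold are labelled immobile. When the distribution shows no separated
#' immobile mode a warning is issued and the fallback `mean(ratio) +
#' 1.96 * SE` over all calibration tracks is used; datasets without an
#' immobile subpopulation should instead supply an explicit threshold.
#'
#' @param ds an [mfx_dataset] (frustrated events already removed).
#' @param threshold optional explicit ratio threshold.
#' @param calibration_ids optional track ids used for the automatic threshold
#'   (defaults to all tracks).
#' @return data.frame with one row per track: `track_id`, `rg`, `mean_step`,
#'   `ratio`, `label` (`"immobile"`/`"mobile"`); the threshold used is in
#'   attribute `"threshold"`.
#' @export
classify_mobility <- function(ds, threshold = NULL, calibration_ids = NULL) {
  trs <- split_tracks(ds)
  rg <- vapply(trs, radius_of_gyration, numeric(1))
  ms <- vapply(trs, mean_step_length, numeric(1))
  ratio <- rg / ms
  if (is.null(threshold)) {
    cal <- if (is.null(calibration_ids)) ratio else
      ratio[names(trs) %in% calibration_ids]
    if (length(cal) < 3) {
      stop("need >= 3 calibration tracks to derive the mobility threshold")
    }
    lr <- log10(pmax(cal, 1e-12))
    km <- stats::kmeans(lr, centers = stats::quantile(lr, c(0.1, 0.9)))
    lower <- which.min(km$centers)
    sep <- abs(diff(as.numeric(km$centers)))
    if (sep > 0.5 && sum(km$cluster == lower) >= 3) {
      # clear immobile mode: threshold = upper bound of its 95% band
      imm <- cal[km$cluster == lower]
      threshold <- mean(imm) + 1.96 * stats::sd(imm)
    } else {
      warning("mobility-ratio distribution shows no separated immobile ",
              "mode; falling back to the CI-of-the-mean rule - consider ",
              "supplying an explicit threshold")
      threshold <- mean(cal) + 1.96 * stats::sd(cal) / sqrt(length(cal))
    }
  }
  out <- data.frame(track_id = names(trs), rg = rg, mean_step = ms,
                    ratio = ratio,
                    label = ifelse(ratio < threshold, "immobile", "mobile"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "threshold") <- threshold
  out
}

#' Assign species by mean detector channel ratio
#'
#' The detector channel ratio DCR = red / (red + blue) separates the two
#' fluorophores: the toxin-like high-DCR species sits above `high` (0.55) and
#' the cholesterol-like low-DCR species below `low` (0.40). Tracks whose mean
#' DCR falls in the \[low, high\] corridor are flagged as co-diffusion
#' candidates.
#'
#' @param ds an [mfx_dataset] whose localisations carry `dcr` (or channel
#'   counts from which it was derived).
#' @param low,high corridor bounds.
#' @return data.frame `track_id`, `mean_dcr`, `label` in
#'   `{species_A, species_B, codiffusion_candidate}`.
#' @export
classify_species <- function(ds, low = 0.40, high = 0.55) {
  if (!"dcr" %in% names(ds$locs) || anyNA(ds$locs$dcr)) {
    stop("dataset has no usable channel data (dcr)")
  }
  m <- tapply(ds$locs$dcr, factor(ds$locs$track_id,
                                  levels = ds$tracks$track_id), mean)
  lab <- ifelse(m > high, "species_B",
                ifelse(m < low, "species_A", "codiffusion_candidate"))
  data.frame(track_id = ds$tracks$track_id, mean_dcr = as.numeric(m),
             label = unname(lab), stringsAsFactors = FALSE)
}

#' Detect co-diffusion segments within a track
#'
#' A co-diffusing pair (both fluorophores in the detection volume) shows a
#' DCR inside the intermediate corridor together with an elevated intensity.
#' Both per-localisation traces are smoothed with a short running median
#' (window `smooth`) so that single-localisation photon-count excursions do
#' not fragment a joint window. Segments are maximal runs of at least
#' `min_run` consecutive localisations with smoothed `dcr` in `[low, high]`
#' AND smoothed `eco` above `eco_factor` times the track's median
#' single-emitter intensity.
#'
#' @param track data.frame with `dcr` and `eco` columns.
#' @param low,high DCR corridor bounds.
#' @param eco_factor intensity elevation factor (default 1.5).
#' @param min_run minimum run length (default 5 localisations).
#' @param smooth running-median window for the dcr/eco traces (odd; 5).
#' @return data.frame with one row per segment: `start_index`, `end_index`,
#'   `mean_dcr`, `mean_eco` (0 rows if none).
#' @export
detect_codiffusion_segments <- function(track, low = 0.40, high = 0.55,
                                        eco_factor = 1.5, min_run = 5L,
                                        smooth = 5L) {
  stopifnot(all(c("dcr", "eco") %in% names(track)))
  dcr_s <- if (nrow(track) >= smooth) stats::runmed(track$dcr, smooth)
           else track$dcr
  eco_s <- if (nrow(track) >= smooth) stats::runmed(track$eco, smooth)
           else track$eco
  base_eco <- stats::median(track$eco[dcr_s < low | dcr_s > high])
  if (is.na(base_eco)) base_eco <- stats::median(track$eco)
  hit <- dcr_s >= low & dcr_s <= high & eco_s > eco_factor * base_eco
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values & r$lengths >= min_run)
  if (length(sel) == 0L) {
    return(data.frame(start_index = integer(0), end_index = integer(0),
                      mean_dcr = numeric(0), mean_eco = numeric(0)))
  }
  data.frame(
    start_index = starts[sel], end_index = ends[sel],
    mean_dcr = vapply(sel, function(i)
      mean(track$dcr[starts[i]:ends[i]]), numeric(1)),
    mean_eco = vapply(sel, function(i)
      mean(track$eco[starts[i]:ends[i]]), numeric(1)),
    row.names = NULL)
}
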