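#' Confined-region overlap coefficient C
#'
#' A reference confinement hull "overlaps" when its convex hull intersects at
#' least one hull of the other species; the apparent overlap coefficient is
#' `C = (number of reference hulls with an intersection) / (number of
#' reference hulls)`. Both directions (A vs B, B vs A) are meaningful and
#' need not be equal.
#'
#' @param hulls_ref,hulls_other lists of convex polygons (n x 2 matrices).
#' @return list of class `mfx_overlap`: `coefficient_c`, `n_hulls_ref`,
#'   `n_hulls_overlapping`.
#' @export
confined_overlap_c <- function(hulls_ref, hulls_other) {
  if (length(hulls_ref) == 0) stop("empty reference hull list")
  hit <- vapply(hulls_ref, function(h) {
    any(vapply(hulls_other, function(g)
      convex_polygons_intersect(as.matrix(h), as.matrix(g)), logical(1)))
  }, logical(1))
  structure(list(coefficient_c = mean(hit),
                 n_hulls_ref = length(hulls_ref),
                 n_hulls_overlapping = sum(hit)),
            class = "mfx_overlap")
}

#' @export
print.mfx_overlap <- function(x, ...) {
  cat(sprintf("<mfx_overlap> C = %.3f (%d / %d hulls)\n", x$coefficient_c,
              x$n_hulls_overlapping, x$n_hulls_ref))
  invisible(x)
}

#' Free-walk proximity overlap
#'
#' Fraction of reference localisations (non-confined portions) that have at
#' least one other-species localisation within distance `radius` (strictly
#' closer). The default radius of 10 nm matches the localisation precision.
#' The fixed-radius search uses a uniform-grid spatial index that agrees
#' exactly with the brute-force all-pairs computation.
#'
#' @param steps_ref,steps_other n x 2 matrices of positions (nm).
#' @param radius proximity radius (nm).
#' @return fraction in \[0, 1\].
#' @export
free_overlap_kd <- function(steps_ref, steps_other, radius = 10) {
  steps_ref <- as.matrix(steps_ref)
  steps_other <- as.matrix(steps_other)
  stopifnot(nrow(steps_ref) > 0, nrow(steps_other) > 0)
  mean(has_neighbour_within(steps_ref, steps_other, radius))
}

#' Grid-occupancy intersection over union
#'
#' The ROI bounding box is divided into square cells (7 x 7 nm by default,
#' anchored at the bounding-box minimum corner, half-open cells
#' `[x, x + cell)`). A cell is occupied by a species when it contains at
#' least one of its confined localisations. IoU = occupied-by-both /
#' occupied-by-either; an empty union yields 0 with attribute
#' `"empty_union"`.
#'
#' @param locs_a,locs_b n x 2 matrices of confined localisations (nm).
#' @param roi an [mfx_roi] (defines the grid origin and extent).
#' @param cell cell side (nm).
#' @return IoU in \[0, 1\].
#' @export
grid_iou <- function(locs_a, locs_b, roi, cell = 7) {
  stopifnot(inherits(roi, "mfx_roi"))
  bb_lo <- apply(roi$vertices, 2, min)
  bb_hi <- apply(roi$vertices, 2, max)
  if (cell > min(bb_hi - bb_lo)) stop("cell size larger than the ROI")
  cells_of <- function(p) {
    if (is.null(p) || nrow(p) == 0) return(integer(0))
    ix <- floor((p[, 1] - bb_lo[1]) / cell)
    iy <- floor((p[, 2] - bb_lo[2]) / cell)
    span <- ceiling((bb_hi[1] - bb_lo[1]) / cell) + 2L
    unique(ix + 1L + iy * span)
  }
  ca <- cells_of(as.matrix(locs_a))
  cb <- cells_of(as.matrix(locs_b))
  uni <- length(union(ca, cb))
  if (uni == 0) {
    out <- 0
    attr(out, "empty_union") <- TRUE
    return(out)
  }
  length(intersect(ca, cb)) / uni
}

# Confined localisations per species from a dataset + confinement states.
confined_points_by_species <- function(ds, states) {
  trs <- split_tracks(ds)
  sp <- ds$tracks$species
  names(sp) <- ds$tracks$track_id
  out <- list(species_A = NULL, species_B = NULL)
  for (id in names(states)) {
    st <- states[[id]]
    if (!any(st)) next
    s <- sp[[id]]
    if (!s %in% names(out)) next
    tr <- trs[[id]]
    out[[s]] <- rbind(out[[s]], cbind(tr$x[st], tr$y[st]))
  }
  out
}

# Radii (nm) of confined sojourn zones from hull areas: r = sqrt(area / pi).
confinement_zone_radii <- function(sojourns, min_radius = 7) {
  a <- sojourns$hull_area[sojourns$kind == "confined"]
  a <- a[!is.na(a) & a > 0]
  if (length(a) == 0) return(numeric(0))
  pmax(sqrt(a / pi), min_radius)
}

# Lean null draw for the significance test: confined points per species from
# independently placed zones at ~10% ROI coverage. Vectorised across tracks
# and zones (one walk matrix, per-segment cumulative sums) so the Monte-Carlo
# calibration stays cheap.
null_confined_points <- function(bb_lo, bb_hi, area, radii, n_tracks,
                                 pts_per_track, n_zones_visit, step_sd) {
  # zone placement (cycled radii up to ~10% coverage)
  rs <- numeric(0); i <- 0L
  repeat {
    r_next <- radii[(i %% length(radii)) + 1L]
    if (sum(pi * rs^2) + pi * r_next^2 > 0.12 * area) break
    rs <- c(rs, r_next); i <- i + 1L
    if (sum(pi * rs^2) >= 0.10 * area) break
  }
  if (length(rs) == 0) stop("confinement radii cannot fit the ROI")
  nz <- length(rs)
  cx <- stats::runif(nz, bb_lo[1] + rs, bb_hi[1] - rs)
  cy <- stats::runif(nz, bb_lo[2] + rs, bb_hi[2] - rs)
  v <- min(n_zones_visit, nz)
  m <- max(1L, pts_per_track %/% v)
  # zone index per (track, zone-visit) segment
  zidx <- as.vector(vapply(seq_len(n_tracks), function(k)
    sample.int(nz, v), integer(v)))
  nseg <- length(zidx)
  # per-segment clamped random walks, one matrix per axis
  wx <- apply(matrix(stats::rnorm(m * nseg, 0, step_sd), m, nseg), 2, cumsum)
  wy <- apply(matrix(stats::rnorm(m * nseg, 0, step_sd), m, nseg), 2, cumsum)
  if (m == 1L) { wx <- matrix(wx, 1); wy <- matrix(wy, 1) }
  rz <- rep(rs[zidx], each = m)
  d <- sqrt(as.vector(wx)^2 + as.vector(wy)^2)
  shrink <- ifelse(d > rz, rz * 0.95 / pmax(d, 1e-12), 1)
  px <- as.vector(wx) * shrink + rep(cx[zidx], each = m)
  py <- as.vector(wy) * shrink + rep(cy[zidx], each = m)
  cbind(px, py)
}

#' Monte-Carlo significance test of the confined-region IoU
#'
#' The observed grid IoU between the two species' confined localisations is
#' compared with a null distribution in which, for every simulation,
#' surrogate trajectories move through confinement zones of the same radii
#' placed uniformly at random in the ROI (covering ~10% of its area,
#' independently per species). The overlap is significant when the observed
#' IoU exceeds the `1 - alpha` percentile of the simulated IoUs.
#'
#' @param ds an [mfx_dataset] with species labels assigned.
#' @param states named list of smoothed confinement state sequences.
#' @param roi an [mfx_roi].
#' @param n_sims number of null simulations (>= 20; default 100).
#' @param seed integer seed for the null draws.
#' @param alpha significance level (0.05).
#' @param cell IoU grid cell size (nm).
#' @param sojourns optional sojourn table (from [confinement_analysis]) used
#'   to extract zone radii.
#' @param radii optional explicit zone radii (nm) for the null placement;
#'   takes precedence over `sojourns`. When neither is given, 30 nm is
#'   used.
#' @return list of class `mfx_iou_test`: `iou_observed`, `iou_null` (vector),
#'   `threshold` (the 1-alpha percentile), `significant`, `alpha`, `cell`.
#' @export
iou_significance <- function(ds, states, roi, n_sims = 100L, seed = 1L,
                             alpha = 0.05, cell = 7, sojourns = NULL,
                             radii = NULL) {
  if (n_sims < 20) stop("n_sims must be >= 20 for a stable percentile")
  pts <- confined_points_by_species(ds, states)
  if (is.null(pts$species_A) || is.null(pts$species_B)) {
    stop("need confined localisations for both species")
  }
  obs <- grid_iou(pts$species_A, pts$species_B, roi, cell = cell)
  if (is.null(radii)) {
    radii <- if (!is.null(sojourns)) confinement_zone_radii(sojourns)
             else numeric(0)
  }
  if (length(radii) == 0) radii <- 30
  bb_lo <- apply(roi$vertices, 2, min)
  bb_hi <- apply(roi$vertices, 2, max)
  n_tr <- pmax(1L, as.integer(table(factor(ds$tracks$species,
                                           levels = c("species_A", "species_B")))))
  ppt <- pmax(10L, c(floor(nrow(pts$species_A) / n_tr[1]),
                     floor(nrow(pts$species_B) / n_tr[2])))
  null <- with_seed(seed, {
    vapply(seq_len(n_sims), function(s) {
      a <- null_confined_points(bb_lo, bb_hi, roi$area, radii, n_tr[1],
                                ppt[1], 2L, 10)
      b <- null_confined_points(bb_lo, bb_hi, roi$area, radii, n_tr[2],
                                ppt[2], 2L, 10)
      grid_iou(a, b, roi, cell = cell)
    }, numeric(1))
  })
  # exchangeability-exact Monte-Carlo critical value: the k-th order
  # statistic with k = ceiling((1 - alpha) (n_sims + 1))
  k <- min(n_sims, ceiling((1 - alpha) * (n_sims + 1)))
  thr <- sort(null)[k]
  structure(list(iou_observed = as.numeric(obs), iou_null = null,
                 threshold = thr, significant = as.numeric(obs) > thr,
                 alpha = alpha, cell = cell),
            class = "mfx_iou_test")
}

#' @export
print.mfx_iou_test <- function(x, ...) {
  cat(sprintf(
    "<mfx_iou_test> observed IoU = %.4f, null %g%% percentile = %.4f -> %s\n",
    x$iou_observed, 100 * (1 - x$alpha), x$threshold,
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Convex hulls of confined sojourns, per species
#'
#' Helper extracting, for each species, the list of convex-hull polygons of
#' its confined sojourns (degenerate hulls with < 3 unique points dropped).
#'
#' @param ds an [mfx_dataset] with species labels.
#' @param conf result of [confinement_analysis].
#' @return list with elements `species_A`, `species_B`: lists of n x 2
#'   matrices.
#' @export
confined_hulls_by_species <- function(ds, conf) {
  trs <- split_tracks(ds)
  sp <- ds$tracks$species
  names(sp) <- ds$tracks$track_id
  out <- list(species_A = list(), species_B = list())
  sj <- conf$sojourns
  sj <- sj[sj$kind == "confined" & !is.na(sj$hull_area) & sj$hull_area > 0, ,
           drop = FALSE]
  for (i in seq_len(nrow(sj))) {
    id <- sj$track_id[i]
    s <- sp[[id]]
    if (!s %in% names(out)) next
    tr <- trs[[id]]
    p <- unique(cbind(tr$x[sj$start_index[i]:sj$end_index[i]],
                      tr$y[sj$start_index[i]:sj$end_index[i]]))
    if (nrow(p) < 3) next
    h <- grDevices::chull(p)
    out[[s]][[length(out[[s]]) + 1L]] <- p[h, , drop = FALSE]
  }
  out
}
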