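#' Simulation configuration for synthetic MINFLUX tracks
#'
#' Defaults emulate the acquisition statistics of sub-millisecond MINFLUX
#' tracking: irregular sampling with mean interval 492 us and heavy-tailed
#' spread (SD 780 us, lognormal, clipped at 100 us), localisation noise
#' sigma = 7 nm, and membrane-scale diffusion (D ~ 1e5 nm^2/s) in free,
#' confined (reflective square of side `L`), hop (partially permeable square
#' compartment lattice), immobile, or drifting motion.
#'
#' @param seed integer RNG seed.
#' @param n_tracks number of tracks.
#' @param motion_model one of `"brownian"`, `"confined"`, `"hop"`,
#'   `"immobile"`, `"superdiffusive_drift"`.
#' @param D_free free diffusion coefficient (nm^2/s).
#' @param D_mu intra-compartment diffusion coefficient (nm^2/s) used by the
#'   confined and hop models.
#' @param L compartment side (nm) for confined/hop models.
#' @param p_hop probability that a boundary-crossing attempt succeeds.
#' @param sigma_loc localisation noise SD per axis (nm).
#' @param dt_mean mean sampling interval (s).
#' @param dt_model `"regular"` or `"lognormal"`.
#' @param dt_sd interval SD (s) for the lognormal model.
#' @param dt_min minimum interval (s); lognormal draws are clipped here.
#' @param track_len localisations per track.
#' @param drift_speed drift speed (nm/s) for `superdiffusive_drift`.
#' @param species species label attached to the tracks (`"species_A"` =
#'   low-DCR cholesterol-like probe, `"species_B"` = high-DCR toxin-like).
#' @param dcr_mean,dcr_sd per-localisation detector-channel-ratio mean/SD for
#'   this species (defaults: 0.30/0.05 for species_A, 0.65/0.05 for species_B,
#'   well separated around the 0.40 / 0.55 thresholds).
#' @param eco_mean mean single-emitter intensity (effective counts at offset).
#' @param eco_size negative-binomial size (overdispersion) of the intensity.
#' @param co_diffusion optional list `list(pair_fraction =, joint_len =)`; for
#'   that fraction of tracks a second emitter of the other species joins the
#'   detection volume for `joint_len` consecutive localisations, summing the
#'   channel counts (DCR moves into the 0.40-0.55 corridor, intensity about
#'   doubles). Ground-truth joint windows are recorded in the track table.
#' @param roi optional [mfx_roi]; track origins are drawn uniformly inside it.
#'   Default: a 10 x 10 um square.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_tracks = 50L,
                       motion_model = c("brownian", "confined", "hop",
                                        "immobile", "superdiffusive_drift"),
                       D_free = 1e5, D_mu = 4e4, L = 150, p_hop = 0.045,
                       sigma_loc = 7, dt_mean = 492e-6,
                       dt_model = c("lognormal", "regular"),
                       dt_sd = 780e-6, dt_min = 100e-6,
                       track_len = 500L, drift_speed = 1.5e4,
                       species = c("species_A", "species_B"),
                       dcr_mean = NULL, dcr_sd = 0.05,
                       eco_mean = 40, eco_size = 20,
                       co_diffusion = NULL, roi = NULL) {
  motion_model <- match.arg(motion_model)
  dt_model <- match.arg(dt_model)
  species <- match.arg(species)
  if (is.null(dcr_mean)) {
    dcr_mean <- if (species == "species_A") 0.30 else 0.65
  }
  stopifnot(D_free > 0, D_mu > 0, L > 0, p_hop >= 0, p_hop <= 1,
            sigma_loc >= 0, dt_mean > 0, track_len >= 1,
            dcr_mean >= 0, dcr_mean <= 1)
  if (is.null(roi)) roi <- mfx_roi_rect(1e4, id = "roi1")
  structure(list(seed = as.integer(seed), n_tracks = as.integer(n_tracks),
                 motion_model = motion_model, D_free = D_free, D_mu = D_mu,
                 L = L, p_hop = p_hop, sigma_loc = sigma_loc,
                 dt_mean = dt_mean, dt_model = dt_model, dt_sd = dt_sd,
                 dt_min = dt_min, track_len = as.integer(track_len),
                 drift_speed = drift_speed, species = species,
                 dcr_mean = dcr_mean, dcr_sd = dcr_sd, eco_mean = eco_mean,
                 eco_size = eco_size, co_diffusion = co_diffusion, roi = roi),
            class = "sim_config")
}

# Sampling intervals (s) per the configured interval model.
sim_intervals <- function(cfg, n) {
  if (n == 0) return(numeric(0))
  if (cfg$dt_model == "regular") return(rep(cfg$dt_mean, n))
  cv2 <- (cfg$dt_sd / cfg$dt_mean)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(cfg$dt_mean) - sdlog^2 / 2
  pmax(stats::rlnorm(n, meanlog, sdlog), cfg$dt_min)
}

# Fold positions into [lo, hi] by reflection (period 2*(hi-lo)).
reflect_fold <- function(z, lo, hi) {
  w <- hi - lo
  z <- (z - lo) %% (2 * w)
  lo + ifelse(z > w, 2 * w - z, z)
}

# Latent (noise-free) path for one track; returns n x 2 matrix.
sim_latent_path <- function(cfg, dts, origin) {
  n <- length(dts) + 1L
  model <- cfg$motion_model
  if (model == "immobile") {
    return(matrix(rep(origin, each = n), ncol = 2))
  }
  D <- if (model %in% c("confined", "hop")) cfg$D_mu else cfg$D_free
  sd_step <- sqrt(2 * D * dts)
  sx <- stats::rnorm(n - 1L, 0, sd_step)
  sy <- stats::rnorm(n - 1L, 0, sd_step)
  if (model == "brownian" || model == "superdiffusive_drift") {
    x <- origin[1] + c(0, cumsum(sx))
    y <- origin[2] + c(0, cumsum(sy))
    if (model == "superdiffusive_drift") {
      ang <- stats::runif(1, 0, 2 * pi)
      tt <- c(0, cumsum(dts))
      x <- x + cos(ang) * cfg$drift_speed * tt
      y <- y + sin(ang) * cfg$drift_speed * tt
    }
    return(cbind(x, y))
  }
  if (model == "confined") {
    # reflective square of side L centred on the origin
    lo <- origin - cfg$L / 2
    hi <- origin + cfg$L / 2
    x <- reflect_fold(origin[1] + c(0, cumsum(sx)), lo[1], hi[1])
    y <- reflect_fold(origin[2] + c(0, cumsum(sy)), lo[2], hi[2])
    return(cbind(x, y))
  }
  # hop: square lattice of side-L compartments anchored at (0, 0); a step that
  # would cross a compartment boundary succeeds with probability p_hop and is
  # otherwise reflected back into the current compartment.
  x <- numeric(n); y <- numeric(n)
  x[1] <- origin[1]; y[1] <- origin[2]
  L <- cfg$L
  cx <- floor(x[1] / L); cy <- floor(y[1] / L)
  for (i in 2:n) {
    px <- x[i - 1] + sx[i - 1]
    py <- y[i - 1] + sy[i - 1]
    ncx <- floor(px / L); ncy <- floor(py / L)
    if ((ncx != cx || ncy != cy) && stats::runif(1) < cfg$p_hop) {
      cx <- ncx; cy <- ncy        # crossing accepted
    } else {
      px <- reflect_fold(px, cx * L, (cx + 1) * L)
      py <- reflect_fold(py, cy * L, (cy + 1) * L)
    }
    x[i] <- px; y[i] <- py
  }
  cbind(x, y)
}

# Channel counts for one emitter: intensity ~ NegBin(eco_mean, eco_size),
# split between red/blue channels by a clipped-Gaussian per-localisation DCR.
sim_counts <- function(n, dcr_mean, dcr_sd, eco_mean, eco_size) {
  eco <- stats::rnbinom(n, size = eco_size, mu = eco_mean) + 1L
  dcr <- pmin(pmax(stats::rnorm(n, dcr_mean, dcr_sd), 0), 1)
  red <- round(dcr * eco)
  cbind(counts_red = red, counts_blue = eco - red)
}

#' Simulate a MINFLUX-like dataset
#'
#' Generates `cfg$n_tracks` tracks under the configured motion model, adds
#' per-axis Gaussian localisation noise `sigma_loc`, draws irregular (or
#' regular) timestamps, and attaches per-localisation channel counts so the
#' detector channel ratio follows the species' configured distribution.
#' Co-diffusing windows (if configured) sum the counts of two emitters.
#'
#' @param cfg a [sim_config].
#' @return an [mfx_dataset]; `$tracks` carries the ground-truth motion model
#'   and, when co-diffusion is simulated, the true joint window
#'   (`codiff_start`, `codiff_end` localisation indices, NA otherwise).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    other_dcr <- if (cfg$species == "species_A") 0.65 else 0.30
    bb_lo <- apply(cfg$roi$vertices, 2, min)
    bb_hi <- apply(cfg$roi$vertices, 2, max)
    pieces <- vector("list", cfg$n_tracks)
    codiff <- matrix(NA_integer_, cfg$n_tracks, 2)
    for (k in seq_len(cfg$n_tracks)) {
      n <- cfg$track_len
      dts <- sim_intervals(cfg, n - 1L)
      origin <- stats::runif(2, bb_lo + 0.1 * (bb_hi - bb_lo),
                             bb_hi - 0.1 * (bb_hi - bb_lo))
      path <- sim_latent_path(cfg, dts, origin)
      obs <- path + matrix(stats::rnorm(2 * n, 0, cfg$sigma_loc), ncol = 2)
      cnt <- sim_counts(n, cfg$dcr_mean, cfg$dcr_sd, cfg$eco_mean,
                        cfg$eco_size)
      if (!is.null(cfg$co_diffusion) &&
          stats::runif(1) < cfg$co_diffusion$pair_fraction) {
        jl <- min(cfg$co_diffusion$joint_len, n)
        j0 <- sample.int(n - jl + 1L, 1L)
        j1 <- j0 + jl - 1L
        extra <- sim_counts(jl, other_dcr, cfg$dcr_sd, cfg$eco_mean,
                            cfg$eco_size)
        cnt[j0:j1, ] <- cnt[j0:j1, ] + extra
        codiff[k, ] <- c(j0, j1)
      }
      pieces[[k]] <- data.frame(
        track_id = sprintf("t%04d", k), roi_id = cfg$roi$id,
        t = c(0, cumsum(dts)), x = obs[, 1], y = obs[, 2],
        counts_red = cnt[, 1], counts_blue = cnt[, 2],
        eco = cnt[, 1] + cnt[, 2], stringsAsFactors = FALSE)
    }
    locs <- do.call(rbind, pieces)
    ds <- mfx_dataset(locs, rois = list(cfg$roi),
                      meta = list(dt_mean = cfg$dt_mean,
                                  sigma_loc = cfg$sigma_loc,
                                  motion_model = cfg$motion_model))
    ds$tracks$species <- cfg$species
    ds$tracks$true_model <- cfg$motion_model
    ds$tracks$codiff_start <- codiff[, 1]
    ds$tracks$codiff_end <- codiff[, 2]
    ds
  })
}

#' Simulate two-state (trapped / free) tracks with a known schedule
#'
#' Tracks alternate between free Brownian episodes and confinement episodes in
#' a reflective square trap of side `L_trap` centred at the entry point, on a
#' fixed step schedule. The ground-truth per-localisation state is returned in
#' the localisation table (`true_confined`), which makes the generator usable
#' as an oracle for confinement-detection benchmarks.
#'
#' @param cfg a [sim_config] (its `D_free` drives the free episodes, `D_mu`
#'   the in-trap motion; `track_len`, noise and timing fields apply).
#' @param L_trap trap side (nm).
#' @param n_confined,n_free episode lengths in localisations. The defaults
#'   (600 confined / 300 free, ~0.3 s and ~0.15 s at the MINFLUX interval)
#'   put trap residencies in the operating regime of the recurrence
#'   criterion at its default visit threshold.
#' @param start_free if `TRUE` tracks start in the free state.
#' @return an [mfx_dataset] whose `locs` include logical `true_confined`.
#' @export
simulate_two_state_dataset <- function(cfg, L_trap = 50, n_confined = 600L,
                                       n_free = 300L, start_free = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    bb_lo <- apply(cfg$roi$vertices, 2, min)
    bb_hi <- apply(cfg$roi$vertices, 2, max)
    pieces <- vector("list", cfg$n_tracks)
    for (k in seq_len(cfg$n_tracks)) {
      n <- cfg$track_len
      dts <- sim_intervals(cfg, n - 1L)
      # build state schedule
      state <- logical(0)
      s <- !start_free
      while (length(state) < n) {
        len <- if (s) n_confined else n_free
        state <- c(state, rep(s, len))
        s <- !s
      }
      state <- state[seq_len(n)]        # TRUE = confined
      pos <- matrix(0, n, 2)
      pos[1, ] <- stats::runif(2, bb_lo + 0.1 * (bb_hi - bb_lo),
                               bb_hi - 0.1 * (bb_hi - bb_lo))
      trap_c <- pos[1, ]
      for (i in 2:n) {
        D <- if (state[i]) cfg$D_mu else cfg$D_free
        stp <- stats::rnorm(2, 0, sqrt(2 * D * dts[i - 1]))
        p <- pos[i - 1, ] + stp
        if (state[i]) {
          if (!state[i - 1]) trap_c <- pos[i - 1, ]  # entering a trap
          p <- c(reflect_fold(p[1], trap_c[1] - L_trap / 2, trap_c[1] + L_trap / 2),
                 reflect_fold(p[2], trap_c[2] - L_trap / 2, trap_c[2] + L_trap / 2))
        }
        pos[i, ] <- p
      }
      obs <- pos + matrix(stats::rnorm(2 * n, 0, cfg$sigma_loc), ncol = 2)
      cnt <- sim_counts(n, cfg$dcr_mean, cfg$dcr_sd, cfg$eco_mean,
                        cfg$eco_size)
      pieces[[k]] <- data.frame(
        track_id = sprintf("t%04d", k), roi_id = cfg$roi$id,
        t = c(0, cumsum(dts)), x = obs[, 1], y = obs[, 2],
        counts_red = cnt[, 1], counts_blue = cnt[, 2],
        eco = cnt[, 1] + cnt[, 2], true_confined = state,
        stringsAsFactors = FALSE)
    }
    ds <- mfx_dataset(do.call(rbind, pieces), rois = list(cfg$roi),
                      meta = list(two_state = TRUE, L_trap = L_trap))
    ds$tracks$species <- cfg$species
    ds$tracks$true_model <- "two_state"
    ds
  })
}

# Place circular zones (cycling through `radii`) uniformly in the ROI bounding
# box until total area reaches ~10% of the ROI area. Returns cbind(x, y, r).
place_null_zones <- function(roi, radii, coverage = 0.10) {
  A <- roi$area
  if (any(pi * radii^2 > 0.12 * A)) {
    stop("confinement radii cannot fit the ROI at ~10% coverage")
  }
  bb_lo <- apply(roi$vertices, 2, min)
  bb_hi <- apply(roi$vertices, 2, max)
  rs <- numeric(0)
  i <- 0L
  repeat {
    r_next <- radii[(i %% length(radii)) + 1L]
    if (sum(pi * rs^2) + pi * r_next^2 > 0.12 * A) break
    rs <- c(rs, r_next)
    i <- i + 1L
    if (sum(pi * rs^2) >= coverage * A) break
  }
  if (sum(pi * rs^2) < 0.08 * A) {
    stop("confinement radii cannot reach ~10% coverage of the ROI")
  }
  cx <- stats::runif(length(rs), bb_lo[1] + rs, bb_hi[1] - rs)
  cy <- stats::runif(length(rs), bb_lo[2] + rs, bb_hi[2] - rs)
  cbind(x = cx, y = cy, r = rs)
}

# One surrogate track through randomly chosen zones: confined stretches are
# random walks clamped inside each zone, linked by straight bridging walks.
# Returns list(xy, confined).
sim_null_track <- function(zones, n_locs, n_zones_visit, step_sd) {
  nz <- nrow(zones)
  visit <- sample.int(nz, min(n_zones_visit, nz))
  k <- length(visit)
  n_conf <- floor(0.6 * n_locs / k)
  n_free <- max(1L, floor((n_locs - k * n_conf) / max(1L, k - 1L)))
  xs <- list(); state <- list()
  for (j in seq_len(k)) {
    zc <- zones[visit[j], 1:2]; zr <- zones[visit[j], 3]
    w <- cbind(cumsum(stats::rnorm(n_conf, 0, step_sd)),
               cumsum(stats::rnorm(n_conf, 0, step_sd)))
    d <- sqrt(rowSums(w^2))
    out <- d > zr
    if (any(out)) w[out, ] <- w[out, ] * (zr * 0.95 / d[out])
    pts <- sweep(w, 2, zc, "+")
    xs[[length(xs) + 1L]] <- pts
    state[[length(state) + 1L]] <- rep(TRUE, n_conf)
    if (j < k) {
      a <- zones[visit[j], 1:2]; b <- zones[visit[j + 1], 1:2]
      fr <- seq_len(n_free) / (n_free + 1)
      br <- cbind(a[1] + fr * (b[1] - a[1]), a[2] + fr * (b[2] - a[2])) +
        matrix(stats::rnorm(2 * n_free, 0, step_sd), ncol = 2)
      xs[[length(xs) + 1L]] <- br
      state[[length(state) + 1L]] <- rep(FALSE, n_free)
    }
  }
  list(xy = do.call(rbind, xs), confined = unlist(state))
}

#' Simulate the null model of the confinement-overlap significance test
#'
#' For each requested track a surrogate trajectory is generated that moves
#' through circular confinement zones placed uniformly at random inside the
#' ROI. Zone radii are taken from `confinement_radii` (cycled), and the placed
#' zones cover ~10% of the ROI area (total zone area / ROI area in
#' \[0.08, 0.12\] by construction). Each species receives its own independent
#' random zone placement, which is exactly the spatial null hypothesis of the
#' grid-IoU significance test.
#'
#' @param roi an [mfx_roi].
#' @param confinement_radii zone radii (nm) observed in the real data.
#' @param n_tracks_per_species integer vector of length 2 (species_A,
#'   species_B counts).
#' @param seed integer seed.
#' @param track_len localisations per surrogate track.
#' @param n_zones_visit zones visited per track.
#' @param step_sd per-axis step SD (nm) of the surrogate walks; defaults to
#'   the step scale of membrane diffusion at the MINFLUX sampling interval.
#' @return an [mfx_dataset] with a logical `confined` column in `$locs`;
#'   attribute `"zones"` holds the per-species zone tables (x, y, r).
#' @export
simulate_null_confinement_rois <- function(roi, confinement_radii,
                                           n_tracks_per_species = c(10L, 10L),
                                           seed = 1L, track_len = 100L,
                                           n_zones_visit = 2L,
                                           step_sd = 10) {
  stopifnot(inherits(roi, "mfx_roi"), length(confinement_radii) >= 1)
  with_seed(seed, {
    species <- c("species_A", "species_B")
    zones <- list()
    pieces <- list()
    trk <- 0L
    for (s in 1:2) {
      n_tr <- n_tracks_per_species[s]
      if (n_tr == 0L) next
      zones[[species[s]]] <- place_null_zones(roi, confinement_radii)
      for (k in seq_len(n_tr)) {
        trk <- trk + 1L
        tr <- sim_null_track(zones[[species[s]]], track_len, n_zones_visit,
                             step_sd)
        n <- nrow(tr$xy)
        pieces[[trk]] <- data.frame(
          track_id = sprintf("n%04d", trk), roi_id = roi$id,
          t = seq(0, by = 492e-6, length.out = n),
          x = tr$xy[, 1], y = tr$xy[, 2], confined = tr$confined,
          species = species[s], stringsAsFactors = FALSE)
      }
    }
    if (length(pieces) == 0L) {
      ds <- mfx_dataset(
        data.frame(track_id = character(0), roi_id = character(0),
                   t = numeric(0), x = numeric(0), y = numeric(0)),
        rois = list(roi))
      attr(ds, "zones") <- zones
      return(ds)
    }
    locs <- do.call(rbind, pieces)
    ds <- mfx_dataset(locs[, setdiff(names(locs), "species")],
                      rois = list(roi))
    ds$tracks$species <- locs$species[match(ds$tracks$track_id,
                                            locs$track_id)]
    attr(ds, "zones") <- zones
    ds
  })
}

#' Concatenate datasets
#'
#' Track ids are prefixed per input to stay unique; ROIs are merged by id.
#' @param ... [mfx_dataset] objects.
#' @param prefixes optional character vector of id prefixes (default d1, d2,
#'   ...).
#' @return a combined [mfx_dataset].
#' @export
combine_datasets <- function(..., prefixes = NULL) {
  dss <- list(...)
  stopifnot(length(dss) >= 1)
  if (is.null(prefixes)) prefixes <- sprintf("d%d.", seq_along(dss))
  locs <- list(); tracks <- list(); rois <- list()
  for (i in seq_along(dss)) {
    ds <- dss[[i]]
    l <- ds$locs; l$track_id <- paste0(prefixes[i], l$track_id)
    tm <- ds$tracks; tm$track_id <- paste0(prefixes[i], tm$track_id)
    locs[[i]] <- l
    tracks[[i]] <- tm
    for (r in ds$rois) rois[[r$id]] <- r
  }
  all_cols <- unique(unlist(lapply(locs, names)))
  locs <- lapply(locs, function(l) {
    for (cn in setdiff(all_cols, names(l))) l[[cn]] <- NA
    l[, all_cols, drop = FALSE]
  })
  tcols <- unique(unlist(lapply(tracks, names)))
  tracks <- lapply(tracks, function(l) {
    for (cn in setdiff(tcols, names(l))) l[[cn]] <- NA
    l[, tcols, drop = FALSE]
  })
  out <- mfx_dataset(do.call(rbind, locs), rois = rois,
                     meta = dss[[1]]$meta)
  tm <- do.call(rbind, tracks)
  out$tracks <- tm[match(out$tracks$track_id, tm$track_id), , drop = FALSE]
  rownames(out$tracks) <- NULL
  out
}
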