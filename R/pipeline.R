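#' Run the full trajectory-analysis pipeline
#'
#' Orchestrates preprocessing (frustrated-event removal, immobile exclusion,
#' species assignment), per-track MSD kinetics and regime classification,
#' confinement segmentation, turning-angle statistics, two-species overlap
#' quantification with the IoU significance test, and (optionally)
#' free/confined/hop model selection. Reported means and SEMs are computed
#' across ROIs, never across tracks; per-track tables are returned alongside.
#'
#' @param ds an [mfx_dataset].
#' @param seed master seed; every stochastic stage receives a sub-seed
#'   derived from it, recorded in the manifest.
#' @param params list overriding defaults: `dcr_low` (0.40), `dcr_high`
#'   (0.55), `mobility_threshold` (NULL = automatic), `v_th` (33), `window`
#'   (3), `dt_bin` (132e-6), `delta0` (84e-6), `fit_max_lag` (0.05),
#'   `sojourn_fit_max_lag` (0.025), `step_lags` (c(1,4,8)), `cell` (7),
#'   `n_sims` (100), `alpha` (0.05), `radius` (10), `run_models` (FALSE),
#'   `n_restarts` (100).
#' @param out_dir optional directory; stage tables are written there as CSV
#'   plus a JSON run manifest.
#' @return list of class `mfx_report`: `tracks` (per-track table: mobility,
#'   species, kinetics, confinement summary), `regimes`, `angle_pdfs`,
#'   `overlap` (per-ROI), `models` (if run), `roi_report` (per-ROI means),
#'   `summary` (mean and SEM across ROIs), `manifest`.
#' @export
run_pipeline <- function(ds, seed = 1L, params = list(), out_dir = NULL) {
  p <- utils::modifyList(list(
    dcr_low = 0.40, dcr_high = 0.55, mobility_threshold = NULL,
    v_th = 33, window = 3L, min_radius = 7,
    dt_bin = 132e-6, delta0 = 84e-6, fit_max_lag = 0.05,
    sojourn_fit_max_lag = 0.025, step_lags = c(1L, 4L, 8L),
    cell = 7, n_sims = 100L, alpha = 0.05, radius = 10,
    run_models = FALSE, n_restarts = 100L), params)
  manifest <- list(seed = seed, params = p,
                   n_tracks_in = n_tracks(ds),
                   package_version = as.character(utils::packageVersion("minfluxsmt")))

  # --- preprocessing
  ds <- drop_frustrated(ds)
  manifest$n_frustrated <- attr(ds, "n_frustrated")
  mob <- classify_mobility(ds, threshold = p$mobility_threshold)
  manifest$mobility_threshold <- attr(mob, "threshold")
  mobile_ids <- mob$track_id[mob$label == "mobile"]
  has_dcr <- "dcr" %in% names(ds$locs) && !anyNA(ds$locs$dcr)
  spc <- if (has_dcr) classify_species(ds, p$dcr_low, p$dcr_high) else NULL
  if (!is.null(spc)) {
    ds$tracks$species <- ifelse(spc$label == "codiffusion_candidate",
                                ds$tracks$species, spc$label)
  }

  mob_ds <- filter_tracks(ds, mobile_ids)

  # --- kinetics
  fits <- fit_kinetics(mob_ds, dt_bin = p$dt_bin, delta0 = p$delta0,
                       max_lag = p$fit_max_lag,
                       fit_max_lag = p$fit_max_lag,
                       seed = sub_seed(seed, 1L))
  regimes <- tryCatch(regime_fractions(fits), error = function(e) NULL)

  # --- confinement
  conf <- confinement_analysis(mob_ds, v_th = p$v_th, window = p$window,
                               min_radius = p$min_radius)

  # --- turning angles
  angle_pdfs <- tryCatch(
    stratified_angle_pdfs(mob_ds, conf$states, step_lags = p$step_lags),
    error = function(e) NULL)

  # --- two-species overlap per ROI
  overlap <- NULL
  if (has_dcr || length(unique(ds$tracks$species)) > 1) {
    overlap <- lapply(ds$rois, function(roi) {
      ids_roi <- mob_ds$tracks$track_id[mob_ds$tracks$roi_id == roi$id]
      sub <- filter_tracks(mob_ds, ids_roi)
      if (length(unique(sub$tracks$species)) < 2) return(NULL)
      hulls <- confined_hulls_by_species(sub, conf)
      res <- list(roi_id = roi$id)
      if (length(hulls$species_A) > 0 && length(hulls$species_B) > 0) {
        res$c_A_vs_B <- confined_overlap_c(hulls$species_A, hulls$species_B)
        res$c_B_vs_A <- confined_overlap_c(hulls$species_B, hulls$species_A)
      }
      pts <- confined_points_by_species(sub, conf$states)
      free_pts <- free_points_by_species(sub, conf$states)
      if (!is.null(free_pts$species_A) && !is.null(free_pts$species_B)) {
        res$free_overlap <- free_overlap_kd(free_pts$species_A,
                                            free_pts$species_B, p$radius)
      }
      if (!is.null(pts$species_A) && !is.null(pts$species_B)) {
        res$iou <- tryCatch(
          iou_significance(sub, conf$states, roi, n_sims = p$n_sims,
                           seed = sub_seed(seed, 2L), alpha = p$alpha,
                           cell = p$cell, sojourns = conf$sojourns),
          error = function(e) NULL)
      }
      res
    })
    overlap <- Filter(Negate(is.null), overlap)
  }

  # --- model selection (heavier; off by default)
  models <- NULL
  if (isTRUE(p$run_models)) {
    trs <- split_tracks(mob_ds)
    models <- do.call(rbind, lapply(names(trs), function(id) {
      if (nrow(trs[[id]]) < 50) return(NULL)
      m <- fit_and_select(trs[[id]], n_restarts = p$n_restarts,
                          seed = sub_seed(seed, 3L),
                          dt_bin = p$dt_bin, delta0 = p$delta0)
      if (is.null(m) || nrow(m) == 0) return(NULL)
      m$track_id <- id
      m
    }))
  }

  # --- per-track master table
  tracks <- merge(ds$tracks, mob[, c("track_id", "ratio", "label")],
                  by = "track_id", all.x = TRUE)
  names(tracks)[names(tracks) == "label"] <- "mobility"
  if (!is.null(spc)) {
    tracks <- merge(tracks, spc[, c("track_id", "mean_dcr")],
                    by = "track_id", all.x = TRUE)
  }
  tracks <- merge(tracks, fits[, c("track_id", "beta", "k_beta", "sigma",
                                   "valid", "regime")],
                  by = "track_id", all.x = TRUE)
  if (!is.null(conf$summaries)) {
    tracks <- merge(tracks,
                    conf$summaries[, c("track_id", "confined_ratio_r",
                                       "transition_rate", "n_sojourns")],
                    by = "track_id", all.x = TRUE)
  }

  # --- ROI-level report
  roi_metric <- function(d, col) mean(d[[col]], na.rm = TRUE)
  per_roi <- do.call(rbind, lapply(split(tracks, tracks$roi_id), function(d) {
    dv <- d[!is.na(d$valid) & d$valid, , drop = FALSE]
    data.frame(
      roi_id = d$roi_id[1],
      n_tracks = nrow(d),
      immobile_fraction = mean(d$mobility == "immobile", na.rm = TRUE),
      beta = roi_metric(dv, "beta"),
      k_beta = roi_metric(dv, "k_beta"),
      confined_ratio_r = roi_metric(d, "confined_ratio_r"),
      transition_rate = roi_metric(d, "transition_rate"),
      stringsAsFactors = FALSE)
  }))
  rownames(per_roi) <- NULL
  num_cols <- setdiff(names(per_roi), c("roi_id", "n_tracks"))
  summary <- data.frame(
    metric = num_cols,
    mean = vapply(num_cols, function(cn) mean(per_roi[[cn]], na.rm = TRUE),
                  numeric(1)),
    sem = vapply(num_cols, function(cn) {
      v <- per_roi[[cn]][!is.na(per_roi[[cn]])]
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    }, numeric(1)),
    row.names = NULL)

  report <- structure(list(tracks = tracks, fits = fits, regimes = regimes,
                           confinement = conf, angle_pdfs = angle_pdfs,
                           overlap = overlap, models = models,
                           roi_report = per_roi, summary = summary,
                           manifest = manifest),
                      class = "mfx_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Non-confined localisations per species (free-walk portions).
free_points_by_species <- function(ds, states) {
  trs <- split_tracks(ds)
  sp <- ds$tracks$species
  names(sp) <- ds$tracks$track_id
  out <- list(species_A = NULL, species_B = NULL)
  for (id in names(states)) {
    st <- states[[id]]
    if (all(st)) next
    s <- sp[[id]]
    if (!s %in% names(out)) next
    tr <- trs[[id]]
    out[[s]] <- rbind(out[[s]], cbind(tr$x[!st], tr$y[!st]))
  }
  out
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$tracks, file.path(out_dir, "tracks.csv"),
                   row.names = FALSE)
  utils::write.csv(report$roi_report, file.path(out_dir, "roi_report.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(report$angle_pdfs)) {
    utils::write.csv(report$angle_pdfs, file.path(out_dir, "angle_pdfs.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$confinement$sojourns)) {
    utils::write.csv(report$confinement$sojourns,
                     file.path(out_dir, "sojourns.csv"), row.names = FALSE)
  }
  if (!is.null(report$models)) {
    utils::write.csv(report$models, file.path(out_dir, "models.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' @export
print.mfx_report <- function(x, ...) {
  cat(sprintf("<mfx_report> %d tracks over %d ROI(s)\n",
              nrow(x$tracks), nrow(x$roi_report)))
  print(x$summary)
  invisible(x)
}

#' Compare pipeline reports between experimental conditions
#'
#' Two conditions are compared metric-by-metric with the two-sample
#' Kolmogorov-Smirnov test on ROI-level values; three or more conditions
#' with the Kruskal-Wallis test. Statistical testing on ROI averages (not on
#' individual tracks) keeps the per-ROI correlation structure out of the
#' test.
#'
#' @param ... two or more `mfx_report` objects (named arguments become
#'   condition labels).
#' @param metrics metric columns of the ROI report to compare.
#' @return data.frame `metric`, `test`, `statistic`, `p_value`.
#' @export
compare_conditions <- function(..., metrics = c("beta", "k_beta",
                                                "confined_ratio_r",
                                                "transition_rate")) {
  reports <- list(...)
  stopifnot(length(reports) >= 2)
  for (r in reports) {
    if (nrow(r$roi_report) < 3) {
      stop("each condition needs >= 3 ROIs for a distribution-level test")
    }
  }
  rows <- lapply(metrics, function(mt) {
    vals <- lapply(reports, function(r) {
      v <- r$roi_report[[mt]]
      v[!is.na(v)]
    })
    if (length(reports) == 2) {
      tst <- suppressWarnings(stats::ks.test(vals[[1]], vals[[2]]))
      data.frame(metric = mt, test = "ks", statistic = unname(tst$statistic),
                 p_value = tst$p.value, stringsAsFactors = FALSE)
    } else {
      tst <- stats::kruskal.test(vals)
      data.frame(metric = mt, test = "kruskal-wallis",
                 statistic = unname(tst$statistic), p_value = tst$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
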