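#' MINFLUX track dataset
#'
#' Container for MINFLUX single-molecule tracking data. Localisations are kept
#' in a single data frame (one row per localisation) with strictly increasing
#' timestamps within each track; per-track metadata (ROI membership, species
#' label) live in a companion table, and regions of interest are stored as
#' polygons. Units are seconds and nanometres throughout.
#'
#' @param locs data.frame with columns `track_id`, `roi_id`, `t` (s), `x`, `y`
#'   (nm), and optionally `counts_red`, `counts_blue`, `eco`. A `dcr` column
#'   (detector channel ratio, red / (red + blue)) is derived from the counts
#'   when they are present.
#' @param rois list of [mfx_roi] objects (possibly named); may be empty.
#' @param meta list of free-form acquisition metadata.
#' @param sort_time if `TRUE`, localisations are re-sorted by time within each
#'   track; if `FALSE` (strict mode) non-monotone timestamps are an error.
#'
#' @return An object of class `mfx_dataset`: a list with elements `locs`
#'   (localisation table), `tracks` (per-track metadata with columns
#'   `track_id`, `roi_id`, `n_locs`, `species`), `rois`, `meta`.
#' @export
mfx_dataset <- function(locs, rois = list(), meta = list(), sort_time = FALSE) {
  req <- c("track_id", "roi_id", "t", "x", "y")
  miss <- setdiff(req, names(locs))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  locs <- as.data.frame(locs)
  if (nrow(locs) > 0) {
    if (any(!is.finite(locs$t)) || any(locs$t < 0)) {
      stop("timestamps must be finite and non-negative")
    }
    o <- order(match(locs$track_id, unique(locs$track_id)), locs$t)
    if (sort_time) {
      locs <- locs[o, , drop = FALSE]
      rownames(locs) <- NULL
    }
    dt <- ave(locs$t, locs$track_id, FUN = function(t) c(1, diff(t)))
    if (any(dt <= 0)) {
      bad <- unique(locs$track_id[dt <= 0])
      stop("non-increasing timestamps in track(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  if (all(c("counts_red", "counts_blue") %in% names(locs)) && nrow(locs) > 0) {
    tot <- locs$counts_red + locs$counts_blue
    locs$dcr <- ifelse(tot > 0, locs$counts_red / tot, NA_real_)
    if (any(locs$dcr < 0 | locs$dcr > 1, na.rm = TRUE)) {
      stop("derived DCR outside [0, 1]; check channel counts")
    }
  }
  ids <- unique(locs$track_id)
  tracks <- data.frame(
    track_id = ids,
    roi_id = locs$roi_id[match(ids, locs$track_id)],
    n_locs = as.integer(table(factor(locs$track_id, levels = ids))),
    species = rep("unassigned", length(ids)),
    stringsAsFactors = FALSE
  )
  roi_ids <- vapply(rois, function(r) r$id, character(1))
  if (length(rois) > 0) names(rois) <- roi_ids
  if (length(rois) > 0 && nrow(tracks) > 0) {
    unknown <- setdiff(unique(tracks$roi_id), roi_ids)
    if (length(unknown) > 0) {
      stop("track(s) reference unknown ROI id(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(list(locs = locs, tracks = tracks, rois = rois, meta = meta),
            class = "mfx_dataset")
}

#' Region of interest polygon
#'
#' @param vertices n x 2 numeric matrix of polygon vertices in nm (open ring;
#'   the closing edge is implicit). Must be a simple polygon of positive area.
#' @param id character identifier.
#' @return An object of class `mfx_roi` with elements `id`, `vertices`, `area`
#'   (nm^2, shoelace formula).
#' @export
mfx_roi <- function(vertices, id = "roi1") {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3)
  if (!polygon_is_simple(vertices)) stop("ROI polygon is self-intersecting")
  area <- polygon_area(vertices)
  if (area <= 0) stop("ROI polygon has zero area")
  structure(list(id = as.character(id), vertices = vertices, area = area),
            class = "mfx_roi")
}

#' A rectangular ROI helper
#' @param width,height side lengths in nm.
#' @param x0,y0 lower-left corner in nm.
#' @param id identifier.
#' @return An [mfx_roi].
#' @export
mfx_roi_rect <- function(width, height = width, x0 = 0, y0 = 0, id = "roi1") {
  mfx_roi(cbind(c(x0, x0 + width, x0 + width, x0),
                c(y0, y0, y0 + height, y0 + height)), id = id)
}

#' @export
print.mfx_dataset <- function(x, ...) {
  cat(sprintf("<mfx_dataset> %d tracks, %d localisations, %d ROI(s)\n",
              nrow(x$tracks), nrow(x$locs), length(x$rois)))
  invisible(x)
}

#' @export
print.mfx_roi <- function(x, ...) {
  cat(sprintf("<mfx_roi> '%s': %d vertices, area %.1f nm^2\n",
              x$id, nrow(x$vertices), x$area))
  invisible(x)
}

#' Number of tracks in a dataset
#' @param ds an [mfx_dataset].
#' @return integer count.
#' @export
n_tracks <- function(ds) nrow(ds$tracks)

#' Extract one track's localisations
#' @param ds an [mfx_dataset].
#' @param id track identifier.
#' @return data.frame of the track's localisations ordered by time.
#' @export
get_track <- function(ds, id) {
  tr <- ds$locs[ds$locs$track_id == id, , drop = FALSE]
  if (nrow(tr) == 0) stop("no such track: ", id)
  rownames(tr) <- NULL
  tr
}

#' Split a dataset's localisations by track
#' @param ds an [mfx_dataset].
#' @return named list of per-track data.frames, in `ds$tracks` order.
#' @export
split_tracks <- function(ds) {
  sp <- split(ds$locs, factor(ds$locs$track_id, levels = ds$tracks$track_id))
  lapply(sp, function(d) { rownames(d) <- NULL; d })
}

#' Keep a subset of tracks
#' @param ds an [mfx_dataset].
#' @param ids track identifiers to keep.
#' @return filtered [mfx_dataset] (ROIs and meta carried over).
#' @export
filter_tracks <- function(ds, ids) {
  ds$locs <- ds$locs[ds$locs$track_id %in% ids, , drop = FALSE]
  rownames(ds$locs) <- NULL
  ds$tracks <- ds$tracks[ds$tracks$track_id %in% ids, , drop = FALSE]
  rownames(ds$tracks) <- NULL
  ds
}

#' Read tracks from the package's on-disk dialect
#'
#' The CSV dialect has one row per localisation with columns
#' `track_id, roi_id, t_s, x_nm, y_nm, counts_red, counts_blue, eco`;
#' the JSON dialect mirrors it (object with `locs`, `rois`, `meta`).
#' ROI polygons ride along in JSON; for CSV they can be supplied separately.
#'
#' @param path file to read.
#' @param dialect `"csv"` or `"json"`.
#' @param rois optional list of [mfx_roi] (CSV carries no polygons).
#' @param sort_time passed to [mfx_dataset]; `FALSE` = strict monotonicity.
#' @return an [mfx_dataset].
#' @export
read_tracks <- function(path, dialect = c("csv", "json"), rois = list(),
                        sort_time = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "csv") {
    locs <- utils::read.csv(path, stringsAsFactors = FALSE)
    req <- c("track_id", "roi_id", "t_s", "x_nm", "y_nm")
    miss <- setdiff(req, names(locs))
    if (length(miss) > 0) {
      stop("schema error in ", path, ": missing column(s) ",
           paste(miss, collapse = ", "))
    }
    num <- intersect(c("t_s", "x_nm", "y_nm", "counts_red", "counts_blue", "eco"),
                     names(locs))
    for (cn in num) {
      if (nrow(locs) > 0 && !is.numeric(locs[[cn]])) {
        bad <- which(is.na(suppressWarnings(as.numeric(locs[[cn]]))) &
                       !is.na(locs[[cn]]))[1]
        stop("parse error in ", path, ", column '", cn, "' near line ",
             bad + 1L)
      }
    }
    names(locs)[names(locs) == "t_s"] <- "t"
    names(locs)[names(locs) == "x_nm"] <- "x"
    names(locs)[names(locs) == "y_nm"] <- "y"
    mfx_dataset(locs, rois = rois, sort_time = sort_time)
  } else {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    locs <- as.data.frame(obj$locs)
    if (nrow(locs) > 0) {
      names(locs)[names(locs) == "t_s"] <- "t"
      names(locs)[names(locs) == "x_nm"] <- "x"
      names(locs)[names(locs) == "y_nm"] <- "y"
    }
    rois_in <- rois
    if (!is.null(obj$rois) && length(obj$rois) > 0) {
      # jsonlite may return the roi list as a data.frame (id, vertices) or
      # as a list of records; normalise both
      rj <- obj$rois
      if (is.data.frame(rj)) {
        rois_in <- lapply(seq_len(nrow(rj)), function(i) {
          mfx_roi(matrix(unlist(rj$vertices[[i]]), ncol = 2,
                         byrow = FALSE), id = rj$id[i])
        })
      } else {
        rois_in <- lapply(rj, function(r) {
          mfx_roi(matrix(unlist(r$vertices), ncol = 2, byrow = FALSE),
                  id = r$id)
        })
      }
    }
    meta <- if (is.null(obj$meta)) list() else obj$meta
    mfx_dataset(locs, rois = rois_in, meta = meta, sort_time = sort_time)
  }
}

#' Write tracks in the package's on-disk dialect
#'
#' Lossless round-trip partner of [read_tracks]; numeric fields are written
#' with full double precision (15 significant digits).
#'
#' @param ds an [mfx_dataset].
#' @param path output file.
#' @param dialect `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ds, path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(ds, "mfx_dataset"))
  out <- ds$locs
  keep <- intersect(c("track_id", "roi_id", "t", "x", "y",
                      "counts_red", "counts_blue", "eco"), names(out))
  out <- out[, keep, drop = FALSE]
  names(out)[names(out) == "t"] <- "t_s"
  names(out)[names(out) == "x"] <- "x_nm"
  names(out)[names(out) == "y"] <- "y_nm"
  if (dialect == "csv") {
    con <- tryCatch(file(path, "w"), error = function(e)
      stop("cannot open for writing: ", path))
    on.exit(close(con))
    fmt <- out
    for (cn in names(fmt)) {
      if (is.numeric(fmt[[cn]])) fmt[[cn]] <- sprintf("%.15g", fmt[[cn]])
    }
    utils::write.csv(fmt, con, row.names = FALSE, quote = FALSE)
  } else {
    obj <- list(
      locs = out,
      rois = lapply(unname(ds$rois), function(r)
        list(id = r$id, vertices = unname(r$vertices))),
      meta = ds$meta
    )
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                         dataframe = "columns")
  }
  invisible(path)
}

#' Fraction of a track's localisations inside an ROI
#'
#' @param track data.frame with `x`, `y` columns (nm).
#' @param roi an [mfx_roi].
#' @return fraction in \[0, 1\].
#' @export
points_in_roi <- function(track, roi) {
  stopifnot(inherits(roi, "mfx_roi"))
  if (nrow(track) == 0) return(NaN)
  mean(points_in_polygon(track$x, track$y, roi$vertices))
}

#' Track duration in seconds
#' @param track data.frame with a `t` column.
#' @return `t_last - t_first` (0 for a single localisation).
#' @export
track_duration <- function(track) {
  max(track$t) - min(track$t)
}
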