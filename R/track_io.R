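#' Canonical marker names and required marker sets
#'
#' Marker trajectories are identified by canonical names; arbitrary table
#' headers are translated via a user-supplied `marker_map`. The ventral
#' (bottom-up) view must provide the snout, tailbase and both left paws; the
#' lateral (side) view must provide the hip and tailbase.
#'
#' @return `required_markers()` returns a named list of character vectors,
#'   one per camera view.
#' @export
required_markers <- function() {
  list(
    ventral = c("snout", "tailbase", "left_forepaw", "left_hindpaw"),
    lateral = c("hip", "tailbase")
  )
}

VIEWS <- c("ventral", "lateral")

#' Construct a marker track
#'
#' A marker track is one landmark's time series of image coordinates and
#' tracking likelihoods in one camera plane, on a uniform time base of
#' `frame_rate` frames per second. Coordinates are in pixels with the image
#' origin top-left (x rightward, y downward).
#'
#' @param marker Canonical marker name (e.g. `"tailbase"`).
#' @param view `"ventral"` or `"lateral"`.
#' @param x,y Numeric pixel coordinates, one value per frame.
#' @param likelihood Per-frame tracking confidence in \[0, 1\].
#' @param frame_rate Frames per second (> 0).
#' @param valid Logical mask; `FALSE` marks samples removed by the
#'   likelihood filter. Defaults to all `TRUE`.
#' @param imputed Logical mask; `TRUE` marks samples filled by
#'   interpolation. Defaults to all `FALSE`.
#' @return An object of class `marker_track`.
#' @export
marker_track <- function(marker, view, x, y, likelihood, frame_rate,
                         valid = NULL, imputed = NULL) {
  view <- match.arg(view, VIEWS)
  n <- length(x)
  if (length(y) != n || length(likelihood) != n)
    validation_error("x, y and likelihood must have equal length")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0)
    validation_error("frame_rate must be a single positive number")
  bad <- likelihood < 0 | likelihood > 1
  if (any(bad, na.rm = TRUE))
    validation_error(sprintf("likelihood outside [0, 1] at frame(s) %s",
                             paste(utils::head(which(bad), 5), collapse = ", ")))
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (is.null(imputed)) imputed <- rep(FALSE, n)
  structure(
    list(marker = marker, view = view,
         x = as.numeric(x), y = as.numeric(y),
         likelihood = as.numeric(likelihood),
         valid = as.logical(valid), imputed = as.logical(imputed),
         frame_rate = frame_rate),
    class = "marker_track"
  )
}

n_frames <- function(track) length(track$x)

#' @export
print.marker_track <- function(x, ...) {
  cat(sprintf("<marker_track> %s (%s view): %d frames @ %g fps, %d masked, %d imputed\n",
              x$marker, x$view, n_frames(x), x$frame_rate,
              sum(!x$valid), sum(x$imputed)))
  invisible(x)
}

#' Read a DeepLabCut-dialect trajectory table
#'
#' Parses the three-header-row CSV layout written by markerless tracking
#' software: row 1 repeats the scorer name per column, row 2 the bodypart
#' name (three columns each), row 3 cycles `x`, `y`, `likelihood`; column 0
#' holds the integer frame index.
#'
#' @param path CSV file path.
#' @param view Camera view the table belongs to (`"ventral"`/`"lateral"`).
#' @param frame_rate Frames per second of the recording.
#' @param marker_map Optional named character vector translating table
#'   bodypart headers to canonical marker names, e.g. `c(tb = "tailbase")`.
#' @return Named list of [marker_track] objects, one per bodypart.
#' @export
read_dlc_table <- function(path, view, frame_rate, marker_map = NULL) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE)
  if (nrow(raw) < 3)
    format_error(sprintf("%s: expected 3 header rows (scorer/bodyparts/coords), got %d rows",
                         path, nrow(raw)))
  hdr_labels <- tolower(trimws(raw[1:3, 1]))
  if (!identical(hdr_labels, c("scorer", "bodyparts", "coords")))
    format_error(sprintf(
      "%s: header rows must be labelled scorer/bodyparts/coords; row %d reads '%s'",
      path, which(hdr_labels != c("scorer", "bodyparts", "coords"))[1],
      raw[which(hdr_labels != c("scorer", "bodyparts", "coords"))[1], 1]))
  bodyparts <- as.character(raw[2, -1])
  coords <- tolower(trimws(as.character(raw[3, -1])))
  ncol_data <- length(coords)
  if (ncol_data %% 3 != 0 ||
      !all(coords == rep(c("x", "y", "likelihood"), ncol_data / 3)))
    format_error(sprintf(
      "%s: coords row must cycle x,y,likelihood per bodypart; got: %s",
      path, paste(utils::head(coords, 6), collapse = ",")))
  triple_names <- bodyparts[seq(1, ncol_data, by = 3)]
  if (any(bodyparts != rep(triple_names, each = 3)))
    format_error(sprintf("%s: bodyparts row does not repeat each name x3", path))

  body <- raw[-(1:3), , drop = FALSE]
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(body[, -1, drop = FALSE])),
           nrow = nrow(body)))
  bad <- which(is.na(vals) & as.matrix(body[, -1, drop = FALSE]) != "", arr.ind = TRUE)
  if (nrow(body) > 0 && length(bad) > 0)
    parse_error(sprintf("%s: non-numeric cell at data row %d, column %d",
                        path, bad[1, 1], bad[1, 2] + 1))
  if (anyNA(vals))
    parse_error(sprintf("%s: empty cell in data block", path))

  tracks <- list()
  for (i in seq_along(triple_names)) {
    name <- triple_names[i]
    canonical <- if (!is.null(marker_map) && name %in% names(marker_map))
      unname(marker_map[[name]]) else name
    j <- (i - 1) * 3
    tracks[[canonical]] <- marker_track(
      marker = canonical, view = view,
      x = vals[, j + 1], y = vals[, j + 2], likelihood = vals[, j + 3],
      frame_rate = frame_rate)
  }
  tracks
}

#' Write marker tracks as a DeepLabCut-dialect CSV
#'
#' Inverse of [read_dlc_table()]; round-trips losslessly to full double
#' precision (values are printed with 15 significant digits).
#'
#' @param tracks Named list of [marker_track] objects sharing one view and
#'   frame count.
#' @param path Output CSV path.
#' @param scorer Scorer label for header row 1.
#' @return `path`, invisibly.
#' @export
write_dlc_table <- function(tracks, path, scorer = "pdssm") {
  stopifnot(length(tracks) >= 1)
  n <- n_frames(tracks[[1]])
  names_row <- unlist(lapply(tracks, function(t) rep(t$marker, 3)))
  coords_row <- rep(c("x", "y", "likelihood"), length(tracks))
  data_cols <- do.call(cbind, lapply(tracks, function(t) {
    if (n_frames(t) != n) validation_error("tracks differ in frame count")
    cbind(t$x, t$y, t$likelihood)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("scorer", rep(scorer, length(coords_row))), collapse = ","), con)
  writeLines(paste(c("bodyparts", names_row), collapse = ","), con)
  writeLines(paste(c("coords", coords_row), collapse = ","), con)
  body <- cbind(seq_len(n) - 1L,
                format(data_cols, digits = 15, trim = TRUE, scientific = FALSE))
  writeLines(apply(body, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Mask low-likelihood samples
#'
#' Flags samples whose tracking likelihood is strictly below `threshold`
#' (default 0.25) as invalid. Samples are masked, never deleted, so frame
#' alignment across markers is preserved for the spectral stage; a sample
#' with likelihood exactly at the threshold is kept.
#'
#' @param track A [marker_track].
#' @param threshold Likelihood cutoff in \[0, 1\]; points with
#'   `likelihood < threshold` are masked.
#' @return The track with its `valid` mask updated. Idempotent.
#' @export
filter_low_likelihood <- function(track, threshold = 0.25) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    validation_error("threshold must lie in [0, 1]")
  track$valid <- track$valid & !(track$likelihood < threshold)
  track
}

#' Fill masked samples by linear interpolation
#'
#' Replaces each invalid interior sample's coordinates by linear
#' interpolation between the nearest valid neighbours on the frame-index
#' time base; leading/trailing runs with no valid neighbour on one side are
#' filled with the nearest valid value. Filled samples are flagged in the
#' `imputed` mask and become valid.
#'
#' @param track A [marker_track], typically after [filter_low_likelihood()].
#' @return The gap-filled track (no invalid samples remain).
#' @export
interpolate_gaps <- function(track) {
  ok <- track$valid
  if (sum(ok) < 2)
    insufficient_data_error(sprintf(
      "marker '%s': %d valid sample(s); need at least 2 to interpolate",
      track$marker, sum(ok)))
  if (all(ok)) return(track)
  idx <- seq_along(ok)
  track$x <- stats::approx(idx[ok], track$x[ok], xout = idx, rule = 2)$y
  track$y <- stats::approx(idx[ok], track$y[ok], xout = idx, rule = 2)$y
  track$imputed <- track$imputed | !ok
  track$valid <- rep(TRUE, length(ok))
  track
}

#' Construct a recording
#'
#' A recording bundles all marker tracks of both camera views for one
#' treadmill run, together with its acquisition metadata. It is the
#' pipeline's unit of work.
#'
#' @param animal_id Animal identifier.
#' @param condition Condition label (e.g. `"control"`, `"pd"`, `"stim"`).
#' @param tracks Nested named list `tracks[[view]][[marker]]` of
#'   [marker_track] objects.
#' @param frame_rate Frames per second (default 160).
#' @param treadmill_speed Belt speed in cm/s (default 20).
#' @param check_markers Require the canonical marker set per view
#'   (see [required_markers()]).
#' @return An object of class `recording`.
#' @export
recording <- function(animal_id, condition, tracks, frame_rate = 160,
                      treadmill_speed = 20, check_markers = TRUE) {
  for (view in names(tracks)) {
    if (!view %in% VIEWS)
      validation_error(sprintf("unknown view '%s'", view))
    for (tr in tracks[[view]]) {
      if (tr$frame_rate != frame_rate)
        validation_error("all tracks must share the recording frame_rate")
      if (tr$view != view)
        validation_error(sprintf("track '%s' labelled view '%s' stored under '%s'",
                                 tr$marker, tr$view, view))
    }
  }
  if (check_markers) {
    req <- required_markers()
    for (view in names(req)) {
      missing <- setdiff(req[[view]], names(tracks[[view]]))
      if (length(missing) > 0)
        validation_error(sprintf("%s view is missing required marker(s): %s",
                                 view, paste(missing, collapse = ", ")))
    }
  }
  nf <- n_frames(tracks[[1]][[1]])
  structure(
    list(animal_id = animal_id, condition = condition, tracks = tracks,
         frame_rate = frame_rate, treadmill_speed = treadmill_speed,
         duration_s = nf / frame_rate),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s [%s]: %.2f s @ %g fps, belt %g cm/s\n",
              x$animal_id, x$condition, x$duration_s, x$frame_rate,
              x$treadmill_speed))
  for (view in names(x$tracks))
    cat(sprintf("  %s: %s\n", view, paste(names(x$tracks[[view]]), collapse = ", ")))
  invisible(x)
}

get_track <- function(rec, view, marker) {
  tr <- rec$tracks[[view]][[marker]]
  if (is.null(tr))
    validation_error(sprintf("recording '%s' has no '%s' marker in the %s view",
                             rec$animal_id, marker, view))
  tr
}

#' Clean all tracks of a recording
#'
#' Applies the likelihood mask and linear gap interpolation to every marker
#' track, the standard pre-processing before feature extraction.
#'
#' @param rec A [recording].
#' @param threshold Likelihood cutoff passed to [filter_low_likelihood()].
#' @return The recording with all tracks masked and gap-filled.
#' @export
clean_recording <- function(rec, threshold = 0.25) {
  for (view in names(rec$tracks))
    for (m in names(rec$tracks[[view]]))
      rec$tracks[[view]][[m]] <-
        interpolate_gaps(filter_low_likelihood(rec$tracks[[view]][[m]], threshold))
  rec
}

#' Read a two-view recording from DLC CSV tables
#'
#' @param ventral_path,lateral_path CSV paths for the two camera views.
#' @param animal_id,condition Recording metadata.
#' @param frame_rate,treadmill_speed Acquisition parameters.
#' @param marker_map Optional header-to-canonical name map
#'   (see [read_dlc_table()]).
#' @return A [recording].
#' @export
read_recording <- function(ventral_path, lateral_path, animal_id,
                           condition = "unknown", frame_rate = 160,
                           treadmill_speed = 20, marker_map = NULL) {
  recording(
    animal_id = animal_id, condition = condition,
    tracks = list(
      ventral = read_dlc_table(ventral_path, "ventral", frame_rate, marker_map),
      lateral = read_dlc_table(lateral_path, "lateral", frame_rate, marker_map)),
    frame_rate = frame_rate, treadmill_speed = treadmill_speed)
}
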