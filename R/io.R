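#' Write a synthetic scene to disk
#'
#' Writes frames as zero-padded PNG files (`frame_000001.png`, ...), a JSON
#' sidecar (`scene.json`: fps, frame count, seed, scene parameters), the
#' landmark track as CSV (`landmarks.csv`: `frame_index`, `x_1`, `y_1`, ...)
#' and the reference trace as CSV (`reference.csv`: `time_s`, `ppg`,
#' `hr_bpm`). All CSV output is comma-separated UTF-8 with '.' decimal and a
#' header row.
#'
#' @param scene An `rppg_scene` from [generate_scene()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "rppg_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(scene$frames)
  for (i in seq_len(n)) {
    png::writePNG(aperm(scene$frames[[i]], c(1, 2, 3)) / 255,
                  file.path(dir, sprintf("frame_%06d.png", i)))
  }
  cfg <- scene$config
  sidecar <- list(fps = scene$fps, n_frames = n, width = cfg$width,
                  height = cfg$height, duration = cfg$duration,
                  seed = cfg$seed, tracking_lag = cfg$tracking_lag,
                  pulse_amplitude = cfg$pulse_amplitude)
  jsonlite::write_json(sidecar, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(landmarks_to_df(scene$landmarks),
                   file.path(dir, "landmarks.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(scene$reference),
                   file.path(dir, "reference.csv"), row.names = FALSE)
  invisible(dir)
}

landmarks_to_df <- function(lmk) {
  n <- dim(lmk)[1]; l <- dim(lmk)[2]
  out <- data.frame(frame_index = seq_len(n))
  for (j in seq_len(l)) {
    out[[paste0("x_", j)]] <- lmk[, j, 1]
    out[[paste0("y_", j)]] <- lmk[, j, 2]
  }
  out
}

#' Read scene components back from disk
#'
#' Counterparts of [write_scene()]: read a PNG frame directory with its JSON
#' sidecar, a landmark CSV, or a reference CSV.
#'
#' @param dir Directory written by [write_scene()] (or laid out the same
#'   way by a detector adapter).
#' @return `read_frames_dir`: list with `frames` (list of H x W x 3 integer
#'   arrays) and `fps`. `read_landmarks_csv`: n x l x 2 array.
#'   `read_reference_csv`: data frame `time_s`, `ppg`, `hr_bpm`.
#' @export
read_frames_dir <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "scene.json"),
                                 simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    img <- round(img * 255)
    storage.mode(img) <- "integer"
    img
  })
  list(frames = frames, fps = sidecar$fps)
}

#' @rdname read_frames_dir
#' @param path CSV file path.
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path)
  xs <- grep("^x_", names(df)); ys <- grep("^y_", names(df))
  stopifnot(length(xs) == length(ys), length(xs) >= 1)
  lmk <- array(NA_real_, dim = c(nrow(df), length(xs), 2))
  lmk[, , 1] <- as.matrix(df[, xs])
  lmk[, , 2] <- as.matrix(df[, ys])
  lmk
}

#' @rdname read_frames_dir
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "ppg") %in% names(df)))
  df
}

#' Write / read per-window records
#'
#' CSV round-trip for the window records produced by [extract_windows()]
#' and [label_windows()].
#'
#' @param records Window records data frame.
#' @param path CSV file path.
#' @return `read_windows_csv` returns the records data frame.
#' @export
write_windows_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows_csv
#' @export
read_windows_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
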