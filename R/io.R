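# File I/O: PNG salience stacks, gaze CSV, EEG CSV + JSON sidecar,
# score CSV. Everything is plain text or PNG; no binary containers.

#' Read a directory of per-frame salience PNGs
#'
#' Frames are read in lexicographic file order; RGB images are averaged to
#' grayscale. Values are normalized per frame (see [normalize_map()]).
#'
#' @param path directory containing the frames.
#' @param pattern filename regexp (default `"\\.png$"`).
#' @param frame_period seconds per frame.
#' @param video_id label; defaults to the directory name.
#' @return A [salience_map_sequence()].
#' @export
read_salience_dir <- function(path, pattern = "\\.png$", frame_period = 1,
                              video_id = NULL) {
  files <- sort(list.files(path, pattern = pattern, full.names = TRUE))
  if (!length(files)) stop_invalid("no frames matching '", pattern,
                                   "' under ", path)
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE],
                                             c(1, 2), mean)
    img
  })
  salience_map_sequence(frames, frame_period = frame_period,
                        video_id = video_id %||% basename(normalizePath(path)))
}

#' Write a salience sequence as a PNG stack
#'
#' @param seq a [salience_map_sequence()].
#' @param path output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_salience_dir <- function(seq, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_len(seq$n_frames), function(t) {
    f <- file.path(path, sprintf("frame_%05d.png", t))
    png::writePNG(seq$frames[[t]], f)
    f
  }, "")
  invisible(paths)
}

#' Read / write gaze tables as CSV
#'
#' CSV with header `observer,t,x,y`; frame indices 1-based, coordinates
#' normalized to \[0, 1\].
#'
#' @param path CSV file path.
#' @return [read_gaze_csv()]: a [gaze_table()].
#' @export
read_gaze_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("observer", "t", "x", "y")
  if (!all(need %in% names(df)))
    stop_invalid("gaze CSV needs columns observer,t,x,y")
  gaze_table(df$observer, df$t, df$x, df$y)
}

#' @param gaze a [gaze_table()].
#' @rdname read_gaze_csv
#' @export
write_gaze_csv <- function(gaze, path) {
  utils::write.csv(as.data.frame(gaze)[, c("observer", "t", "x", "y")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write an EEG recording as CSV plus JSON sidecar
#'
#' The CSV holds the channels-by-time sample matrix (one row per channel,
#' no header); the JSON sidecar carries `fs`, `channel_names`,
#' `subject_id` and `video_id`.
#'
#' @param csv_path path of the sample matrix CSV.
#' @param meta_path path of the JSON sidecar; defaults to `csv_path` with
#'   a `.json` extension.
#' @return [read_eeg_csv()]: an [eeg_recording()].
#' @export
read_eeg_csv <- function(csv_path, meta_path = NULL) {
  meta_path <- meta_path %||% sub("\\.csv$", ".json", csv_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  x <- as.matrix(utils::read.csv(csv_path, header = FALSE))
  dimnames(x) <- NULL
  eeg_recording(x, fs = meta$fs, channel_names = meta$channel_names,
                subject_id = meta$subject_id %||% "s1",
                video_id = meta$video_id %||% "video")
}

#' @param rec an [eeg_recording()].
#' @rdname read_eeg_csv
#' @export
write_eeg_csv <- function(rec, csv_path, meta_path = NULL) {
  meta_path <- meta_path %||% sub("\\.csv$", ".json", csv_path)
  utils::write.table(rec$samples, csv_path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, channel_names = rec$channel_names,
                            subject_id = rec$subject_id,
                            video_id = rec$video_id),
                       meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, meta_path))
}

#' Write temporal score series as CSV
#'
#' One row per timestep with 1-based index `t` and one column per score;
#' a comment line records the package version and configuration hash.
#'
#' @param path CSV file path.
#' @param video_id video label.
#' @param scores named list of equal-length numeric series (e.g.
#'   `list(s_v = ..., s_b = ...)`).
#' @param config_hash optional provenance fingerprint to embed.
#' @return Invisibly, `path`.
#' @export
write_score_csv <- function(path, video_id, scores, config_hash = NULL) {
  df <- data.frame(video_id = video_id, t = seq_along(scores[[1L]]))
  for (nm in names(scores)) df[[nm]] <- as.numeric(scores[[nm]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# eegsalience %s%s",
                     as.character(utils::packageVersion("eegsalience")),
                     if (is.null(config_hash)) ""
                     else paste0(" config=", config_hash)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# FNV-1a style fingerprint of an R object (provenance stamp, not crypto).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}
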