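# Plain-text file formats: PGM images, dictionary JSON, schedule CSV + sidecar.

#' Read a PGM grayscale image
#'
#' Supports plain (P2) and binary (P5) 8-bit portable graymaps.
#'
#' @param path Path to a `.pgm` file.
#' @return Numeric matrix of gray values.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  while (length(tokens) < 4) {
    line <- readLines(con, n = 1L)
    line <- sub("#.*", "", line)
    tokens <- c(tokens, strsplit(trimws(line), "\\s+")[[1]])
    tokens <- tokens[nzchar(tokens)]
  }
  magic <- tokens[1]
  nc <- as.integer(tokens[2])
  nr <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  if (!magic %in% c("P2", "P5")) stop("not a PGM (P2/P5) file: ", path)
  npix <- nr * nc
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n = npix))
  } else {
    scan(con, what = integer(), n = npix, quiet = TRUE)
  }
  if (length(vals) != npix) stop("truncated PGM data in ", path)
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}

#' Write a PGM grayscale image
#'
#' Writes a plain-text (P2) 8-bit portable graymap.
#'
#' @param image Numeric matrix; values are clamped to `[0, 255]` and rounded.
#' @param path Output path.
#' @export
write_pgm <- function(image, path) {
  v <- round(pmin(pmax(image, 0), 255))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), "255"), con)
  apply(v, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' Write / read a feature dictionary as JSON
#'
#' @param dict A `feature_dictionary`.
#' @param path JSON path.
#' @export
write_feature_dictionary <- function(dict, path) {
  jsonlite::write_json(
    list(kind = dict$kind, N = dict$N, W = dict$W,
         achieved_entropy = dict$achieved_entropy,
         patches = dict$patches, probs = dict$probs, empty = dict$empty),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_feature_dictionary
#' @export
read_feature_dictionary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- new_feature_dictionary(x$patches %||% integer(0),
                              x$probs %||% numeric(0),
                              x$N, x$W, x$kind, isTRUE(x$empty))
  d
}

#' Render a feature dictionary to PGM bitmaps with a CSV manifest
#'
#' Writes one PGM per patch (`cue_<code>.pgm`, luminances in cd/m2 stored as
#' gray values) plus `manifest.csv` with code, kind and mean luminance.
#'
#' @param dict A `feature_dictionary`.
#' @param dir Output directory (created if needed).
#' @inheritParams render_cue
#' @return Invisibly, the manifest data frame.
#' @export
write_cue_set <- function(dict, dir, patch_side = 3L, cell_px = 3L,
                          lum_black = 4, lum_white = 44) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dict$patches, function(code) {
    cue <- render_cue(code, patch_side, cell_px, lum_black, lum_white)
    path <- file.path(dir, sprintf("cue_%03d.pgm", code))
    write_pgm(cue$pixels, path)
    data.frame(code = code, kind = dict$kind,
               mean_luminance = mean(cue$pixels), file = basename(path),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Write / read a session schedule as CSV with a JSON sidecar
#'
#' The trial table goes to `path`; seed, counts and design metadata go to
#' `<path>.json`.
#'
#' @param schedule A [session_schedule][build_covert_schedule].
#' @param path CSV path.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  meta <- attributes(schedule)
  jsonlite::write_json(
    list(task = meta$task, seed = meta$seed, validity = meta$validity,
         soa_ms = meta$soa_ms, cue_eccentricity_deg = meta$cue_eccentricity_deg,
         cue_duration_ms = meta$cue_duration_ms,
         counts = schedule_counts(schedule)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("contrast", "tilt_deg")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  as_session_schedule(df, task = meta$task %||% df$task[1],
                      seed = meta$seed, validity = meta$validity,
                      soa_ms = meta$soa_ms %||% df$soa_ms[1],
                      cue_eccentricity_deg = meta$cue_eccentricity_deg %||%
                        df$cue_eccentricity_deg[1],
                      cue_duration_ms = meta$cue_duration_ms %||% 25)
}

#' Write a per-trial gaze trace as CSV
#'
#' @param trace A [gaze_trace][simulate_gaze_trial].
#' @param path CSV path (columns `t_ms`, `x_deg`, `y_deg`).
#' @export
write_gaze_trace <- function(trace, path) {
  utils::write.csv(
    data.frame(t_ms = trace$t, x_deg = trace$x, y_deg = trace$y),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze_trace
#' @param target_onset_ms,target_side,salient_side Trial metadata not stored
#'   in the CSV itself.
#' @export
read_gaze_trace <- function(path, target_onset_ms = 0, target_side = NA,
                            salient_side = NA) {
  df <- utils::read.csv(path)
  new_gaze_trace(df$t_ms, df$x_deg, df$y_deg,
                 target_onset_ms = target_onset_ms,
                 target_side = target_side, salient_side = salient_side)
}
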