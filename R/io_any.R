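# The "magic" reader: guess formats from extensions, scan directories, and
# group images and particles from the same tomogram under one experiment id
# via a name regex.

PARTICLE_EXTENSIONS <- c("star", "tbl", "box", "cbox")

#' Read a plain-text point list
#'
#' Reads manual picks from CSV/TSV text with columns x, y, z and an
#' optional strip/group column (header optional; the delimiter is guessed
#' from the first line).
#'
#' @param path Text file path.
#' @return Data frame with columns `x`, `y`, `z` and, when present,
#'   `group`.
#' @export
read_points <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1, warn = FALSE)
  sep <- if (grepl(",", first)) "," else ""
  header <- grepl("[A-Za-z]", first)
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) abort_format("point list needs at least 3 columns (x, y, z)")
  names(df)[1:3] <- c("x", "y", "z")
  if (ncol(df) >= 4) names(df)[4] <- "group"
  df <- df[, seq_len(min(ncol(df), 4)), drop = FALSE]
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]])) {
      abort_format(sprintf("point column '%s' is not numeric", nm))
    }
  }
  df
}

#' Write a plain-text point list
#'
#' @param points Matrix or data frame of points (x, y, z, optional group).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path) {
  df <- as.data.frame(points)
  names(df)[1:3] <- c("x", "y", "z")
  if (ncol(df) >= 4) names(df)[4] <- "group"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read any supported files, guessing formats
#'
#' Dispatches each path by extension (particles: STAR, TBL, BOX, CBOX;
#' images: MRC and variants, TIFF, EM). Directories are scanned
#' non-recursively. When `name_regex` is given, the first match on each
#' file stem becomes the object's `experiment_id`, so images and particles
#' from the same tomogram end up sharing an id. With `lazy = TRUE` image
#' voxel data is deferred (metadata loads eagerly; see [read_image()]).
#'
#' @param paths Character vector of files and/or directories.
#' @param name_regex Optional regular expression for experiment-id
#'   extraction from file stems.
#' @param lazy Defer image voxel loading?
#' @return List of [pose_set()] and [image_volume()] objects.
#' @export
read_any <- function(paths, name_regex = NULL, lazy = FALSE) {
  files <- unlist(lapply(paths, function(p) {
    if (dir.exists(p)) list.files(p, full.names = TRUE, recursive = FALSE)
    else p
  }))
  files <- files[!dir.exists(files)]
  out <- list()
  for (f in files) {
    if (!file.exists(f)) abort_format(sprintf("file not found: %s", f))
    ext <- tolower(tools::file_ext(f))
    stem <- tools::file_path_sans_ext(basename(f))
    id <- if (!is.null(name_regex)) {
      m <- regmatches(stem, regexpr(name_regex, stem))
      if (length(m)) m else stem
    } else NULL
    objs <- if (ext == "star") {
      read_star(f)
    } else if (ext == "tbl") {
      read_tbl(f)
    } else if (ext %in% c("box", "cbox")) {
      list(read_boxfile(f))
    } else if (ext %in% IMAGE_EXTENSIONS) {
      list(read_image(f, lazy = lazy))
    } else {
      abort_format(sprintf(
        "cannot guess format of '%s'; supported extensions: %s", f,
        paste(c(PARTICLE_EXTENSIONS, IMAGE_EXTENSIONS), collapse = ", ")))
    }
    if (!is.null(id)) {
      objs <- lapply(objs, function(o) { o$experiment_id <- id; o })
    }
    out <- c(out, objs)
  }
  out
}

#' Write particle pose sets, guessing the format from the extension
#'
#' @param posesets A [pose_set()] or list of them.
#' @param path Output path ending in `.star` or `.tbl`.
#' @return `path`, invisibly.
#' @export
write_particles <- function(posesets, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "star") write_star(posesets, path)
  else if (ext == "tbl") write_tbl(posesets, path)
  else abort_format(sprintf(
    "unsupported particle output extension '%s'; supported: star, tbl", ext))
}
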