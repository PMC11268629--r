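# EMAN .box and CrYOLO .cbox particle coordinate files. A .box line is
# "x y w h" (box corner plus size); a .cbox file is a STAR dialect with a
# cryolo block of corner coordinates, box sizes and a confidence column.

#' Read particle positions from a BOX or CBOX file
#'
#' Box entries are converted to box-centre positions
#' `(x + w/2, y + h/2[, z])`; orientations are identity. For CBOX files
#' the confidence column is kept as a feature.
#'
#' @param path File path.
#' @param dialect `"box"`, `"cbox"`, or `"auto"` (by file extension).
#' @param experiment_id Identifier for the resulting pose set.
#' @return A [pose_set()].
#' @export
read_boxfile <- function(path, dialect = c("auto", "box", "cbox"),
                         experiment_id = "") {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (tolower(tools::file_ext(path)) == "cbox") "cbox" else "box"
  }
  if (dialect == "box") read_box_plain(path, experiment_id)
  else read_cbox(path, experiment_id)
}

read_box_plain <- function(path, experiment_id) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0) {
    return(pose_set(matrix(numeric(0), 0, 3),
                    experiment_id = experiment_id))
  }
  centres <- matrix(0, length(keep), 3)
  for (r in seq_along(keep)) {
    i <- keep[r]
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (anyNA(v) || length(v) < 4) {
      abort_format(sprintf("malformed box line %d (need x y w h)", i))
    }
    centres[r, ] <- c(v[1] + v[3] / 2, v[2] + v[4] / 2, 0)
  }
  poses_from_points(centres, experiment_id = experiment_id)
}

read_cbox <- function(path, experiment_id) {
  blocks <- parse_star(path)
  tab <- NULL
  for (b in blocks) {
    if (is.data.frame(b) && "CoordinateX" %in% names(b)) { tab <- b; break }
  }
  if (is.null(tab)) abort_format("no cryolo coordinate table found in CBOX file")
  nr <- nrow(tab)
  getcol <- function(nm, default = 0) {
    if (nm %in% names(tab)) as.numeric(tab[[nm]]) else rep(default, nr)
  }
  pos <- cbind(getcol("CoordinateX") + getcol("Width") / 2,
               getcol("CoordinateY") + getcol("Height") / 2,
               getcol("CoordinateZ") + getcol("Depth") / 2)
  p <- poses_from_points(pos, experiment_id = experiment_id)
  if ("Confidence" %in% names(tab)) {
    p$features$confidence <- as.numeric(tab$Confidence)
  }
  p
}
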