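# Dynamo .tbl particle tables: whitespace-separated numeric rows with a
# fixed 1-indexed column layout. The columns used here are the documented
# core: 1 tag, 4-6 shifts (dx, dy, dz), 7-9 Euler angles (tdrot, tilt,
# narot, ZXZ), 20 volume id, 24-26 coordinates (x, y, z). Shorter tables
# are padded with zeros on read; 26 columns are always written.

TBL_NCOL <- 26L

#' Read particle poses from a Dynamo TBL file
#'
#' Positions are columns 24-26 plus the shifts in columns 4-6;
#' orientations come from the ZXZ Euler triple in columns 7-9; pose sets
#' are grouped by the volume id in column 20, and the particle tag (column
#' 1) is preserved as a feature.
#'
#' @param path TBL file path.
#' @return List of [pose_set()] objects (one per volume id).
#' @export
read_tbl <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(list(pose_set(matrix(numeric(0), 0, 3))))
  }
  rows <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(fields))
    if (anyNA(v)) {
      abort_format(sprintf("non-numeric TBL row at line %d", i))
    }
    length(v) <- TBL_NCOL
    v[is.na(v)] <- 0
    v
  })
  tab <- do.call(rbind, rows)

  pos <- tab[, 24:26, drop = FALSE] + tab[, 4:6, drop = FALSE]
  nr <- nrow(tab)
  ori <- array(0, dim = c(3, 3, nr))
  for (i in seq_len(nr)) {
    ori[, , i] <- euler_to_matrix(tab[i, 7:9], "dynamo_zxz")
  }
  vol <- tab[, 20]
  lapply(sort(unique(vol)), function(v) {
    sel <- which(vol == v)
    pose_set(pos[sel, , drop = FALSE], ori[, , sel, drop = FALSE],
             data.frame(tag = tab[sel, 1]),
             experiment_id = as.character(v))
  })
}

#' Write particle poses to a Dynamo TBL file
#'
#' Emits 26 zero-padded columns per particle; positions go fully into
#' columns 24-26 (shifts written as zero), orientations into the ZXZ triple
#' 7-9, the volume id into column 20 (one id per pose set, in order), and
#' the tag column from the `tag` feature when present (a running index
#' otherwise). Values are written at 6 decimals.
#'
#' @param posesets A [pose_set()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tbl <- function(posesets, path) {
  if (inherits(posesets, "pose_set")) posesets <- list(posesets)
  out <- character(0)
  tag0 <- 0L
  for (v in seq_along(posesets)) {
    p <- posesets[[v]]
    n <- n_poses(p)
    if (n == 0) next
    tab <- matrix(0, n, TBL_NCOL)
    tab[, 1] <- if ("tag" %in% names(p$features)) p$features$tag
      else tag0 + seq_len(n)
    tag0 <- tag0 + n
    for (i in seq_len(n)) {
      tab[i, 7:9] <- matrix_to_euler(p$orientations[, , i], "dynamo_zxz")
    }
    vol_id <- suppressWarnings(as.numeric(p$experiment_id))
    tab[, 20] <- if (length(vol_id) == 1 && !is.na(vol_id)) vol_id else v
    tab[, 24:26] <- p$positions
    out <- c(out, apply(tab, 1, function(r) paste(sprintf("%.6f", r),
                                                  collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}
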