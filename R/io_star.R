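# Minimal STAR (Self-defining Text Archive and Retrieval) reader/writer:
# data_ blocks containing either loop_ tables or key-value pairs, which is
# the subset used by Relion particle files and CrYOLO CBOX files.

# Parse a STAR file into a named list of blocks; each block is a data.frame
# (loop) or a named character list (pairs). Numeric-looking columns are
# converted.
parse_star <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("^\\s+|\\s+$", "", lines)
  blocks <- list()
  i <- 1L
  n <- length(lines)
  current <- NULL
  skip_comment <- function(x) nzchar(x) && !startsWith(x, "#")
  while (i <= n) {
    line <- lines[i]
    if (!skip_comment(line)) { i <- i + 1L; next }
    if (startsWith(line, "data_")) {
      current <- sub("^data_", "", line)
      if (!nzchar(current)) current <- sprintf("block_%d", length(blocks) + 1L)
      blocks[[current]] <- list()
      i <- i + 1L
    } else if (line == "loop_") {
      if (is.null(current)) abort_format("loop_ outside of a data block")
      i <- i + 1L
      tags <- character(0)
      while (i <= n && startsWith(lines[i], "_")) {
        tags <- c(tags, sub("\\s+#\\d+$", "", sub("^_", "", lines[i])))
        i <- i + 1L
      }
      rows <- list()
      while (i <= n && skip_comment(lines[i]) &&
             !startsWith(lines[i], "data_") && lines[i] != "loop_" &&
             !startsWith(lines[i], "_")) {
        fields <- gsub('^"|"$', "", strsplit(lines[i], "\\s+")[[1]])
        if (length(fields) != length(tags)) {
          abort_format(sprintf(
            "STAR row at line %d has %d fields, expected %d",
            i, length(fields), length(tags)))
        }
        rows[[length(rows) + 1L]] <- fields
        i <- i + 1L
      }
      df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
      if (nrow(df) == 0) {
        df <- as.data.frame(matrix(character(0), 0, length(tags)),
                            stringsAsFactors = FALSE)
      }
      names(df) <- tags
      for (cn in names(df)) {
        v <- suppressWarnings(as.numeric(df[[cn]]))
        if (!anyNA(v)) df[[cn]] <- v
      }
      blocks[[current]] <- df
    } else if (startsWith(line, "_")) {
      if (is.null(current)) abort_format("tag outside of a data block")
      parts <- strsplit(line, "\\s+")[[1]]
      key <- sub("^_", "", parts[1])
      val <- paste(parts[-1], collapse = " ")
      num <- suppressWarnings(as.numeric(val))
      blocks[[current]][[key]] <- if (!is.na(num)) num else val
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  blocks
}

format_star_value <- function(v) {
  if (is.numeric(v)) {
    ifelse(v == round(v) & abs(v) < 1e15, sprintf("%d", as.integer(round(v))),
           sprintf("%.6f", v))
  } else {
    v <- as.character(v)
    ifelse(nzchar(v), v, "\"\"")
  }
}

write_star_blocks <- function(blocks, path) {
  out <- character(0)
  for (name in names(blocks)) {
    block <- blocks[[name]]
    out <- c(out, "", sprintf("data_%s", name), "")
    if (is.data.frame(block)) {
      out <- c(out, "loop_",
               sprintf("_%s #%d", names(block), seq_along(block)))
      cols <- lapply(block, format_star_value)
      if (nrow(block) > 0) {
        out <- c(out, do.call(paste, cols))
      }
    } else {
      out <- c(out, sprintf("_%s %s", names(block),
                            vapply(block, format_star_value, character(1))))
    }
  }
  writeLines(out, path)
  invisible(path)
}

STAR_POSE_COLUMNS <- c(
  "rlnCoordinateX", "rlnCoordinateY", "rlnCoordinateZ",
  "rlnOriginX", "rlnOriginY", "rlnOriginZ",
  "rlnOriginXAngst", "rlnOriginYAngst", "rlnOriginZAngst",
  "rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi",
  "rlnMicrographName", "rlnTomoName", "rlnOpticsGroup")

#' Read particle poses from a Relion STAR file
#'
#' Supports Relion >= 3.0 particle tables, with or without a 3.1-style
#' `data_optics` block. Positions are
#' `rlnCoordinate{X,Y,Z} - rlnOrigin{X,Y,Z}Angst / pixel_spacing` (the
#' Angstrom origin dialect, converted through the optics-group pixel size)
#' or `- rlnOrigin{X,Y,Z}` (the 3.0 pixel dialect); orientations come from
#' `rlnAngle{Rot,Tilt,Psi}`. Particles are grouped into one pose set per
#' distinct `rlnMicrographName` (or `rlnTomoName`). Unrecognised columns
#' are preserved as features and written back by [write_star()].
#'
#' @param path STAR file path.
#' @return List of [pose_set()] objects.
#' @export
read_star <- function(path) {
  blocks <- parse_star(path)
  part <- NULL
  for (b in blocks) {
    if (is.data.frame(b) && "rlnCoordinateX" %in% names(b)) { part <- b; break }
  }
  if (is.null(part)) {
    abort_format("missing coordinate column rlnCoordinateX (no particle table found)")
  }
  for (nm in c("rlnCoordinateX", "rlnCoordinateY")) {
    if (!nm %in% names(part)) {
      abort_format(sprintf("missing coordinate column %s", nm))
    }
  }

  pixel_size <- 0
  optics <- blocks[["optics"]]
  if (!is.null(optics) && is.data.frame(optics) &&
      "rlnImagePixelSize" %in% names(optics)) {
    pixel_size <- optics$rlnImagePixelSize[1]
    if ("rlnOpticsGroup" %in% names(part) &&
        "rlnOpticsGroup" %in% names(optics)) {
      mm <- match(part$rlnOpticsGroup, optics$rlnOpticsGroup)
      per_row_pixel <- optics$rlnImagePixelSize[mm]
    } else {
      per_row_pixel <- rep(pixel_size, nrow(part))
    }
  } else {
    per_row_pixel <- rep(0, nrow(part))
  }

  nr <- nrow(part)
  getcol <- function(nm, default = 0) {
    if (nm %in% names(part)) as.numeric(part[[nm]]) else rep(default, nr)
  }
  pos <- cbind(getcol("rlnCoordinateX"), getcol("rlnCoordinateY"),
               getcol("rlnCoordinateZ"))
  if ("rlnOriginXAngst" %in% names(part) && any(per_row_pixel > 0)) {
    px <- ifelse(per_row_pixel > 0, per_row_pixel, 1)
    pos <- pos - cbind(getcol("rlnOriginXAngst"), getcol("rlnOriginYAngst"),
                       getcol("rlnOriginZAngst")) / px
  } else if ("rlnOriginX" %in% names(part)) {
    pos <- pos - cbind(getcol("rlnOriginX"), getcol("rlnOriginY"),
                       getcol("rlnOriginZ"))
  }

  rot <- getcol("rlnAngleRot"); tilt <- getcol("rlnAngleTilt")
  psi <- getcol("rlnAnglePsi")
  ori <- array(0, dim = c(3, 3, nr))
  for (i in seq_len(nr)) {
    ori[, , i] <- euler_to_matrix(c(rot[i], tilt[i], psi[i]), "relion_zyz")
  }

  group_col <- if ("rlnMicrographName" %in% names(part)) {
    as.character(part$rlnMicrographName)
  } else if ("rlnTomoName" %in% names(part)) {
    as.character(part$rlnTomoName)
  } else rep("", nr)

  feat <- part[, setdiff(names(part), STAR_POSE_COLUMNS), drop = FALSE]
  lapply(unique(group_col), function(g) {
    sel <- which(group_col == g)
    fr <- feat[sel, , drop = FALSE]
    rownames(fr) <- NULL
    if (ncol(fr) == 0) fr <- data.frame(particle = seq_along(sel))
    pose_set(pos[sel, , drop = FALSE], ori[, , sel, drop = FALSE], fr,
             experiment_id = g,
             pixel_spacing = if (any(per_row_pixel[sel] > 0))
               per_row_pixel[sel][1] else 0)
  })
}

#' Write particle poses to a Relion STAR file
#'
#' Writes a `data_particles` loop with coordinates, ZYZ Euler angles and
#' the experiment id as `rlnMicrographName`, plus every feature column.
#' When any pose set has a known pixel spacing a Relion 3.1 `data_optics`
#' block carrying `rlnImagePixelSize` is emitted. Floats are written at 6
#' decimals.
#'
#' @param posesets A [pose_set()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_star <- function(posesets, path) {
  if (inherits(posesets, "pose_set")) posesets <- list(posesets)
  tables <- lapply(posesets, function(p) {
    n <- n_poses(p)
    ang <- t(vapply(seq_len(n), function(i) {
      matrix_to_euler(p$orientations[, , i], "relion_zyz")
    }, numeric(3)))
    if (n == 0) ang <- matrix(numeric(0), 0, 3)
    df <- data.frame(
      rlnCoordinateX = p$positions[, 1],
      rlnCoordinateY = p$positions[, 2],
      rlnCoordinateZ = p$positions[, 3],
      rlnAngleRot = ang[, 1], rlnAngleTilt = ang[, 2], rlnAnglePsi = ang[, 3],
      rlnMicrographName = rep(p$experiment_id, n))
    feats <- p$features[, setdiff(names(p$features), names(df)), drop = FALSE]
    if (ncol(feats) > 0) df <- cbind(df, feats)
    df
  })
  all_cols <- Reduce(union, lapply(tables, names))
  tables <- lapply(tables, function(df) {
    for (nm in setdiff(all_cols, names(df))) df[[nm]] <- 0
    df[, all_cols, drop = FALSE]
  })
  part <- do.call(rbind, tables)
  rownames(part) <- NULL

  spacing <- vapply(posesets, `[[`, numeric(1), "pixel_spacing")
  blocks <- list()
  if (any(spacing > 0)) {
    blocks$optics <- data.frame(rlnOpticsGroup = 1,
                                rlnImagePixelSize = spacing[spacing > 0][1])
    part$rlnOpticsGroup <- 1
  }
  blocks$particles <- part
  write_star_blocks(blocks, path)
}
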