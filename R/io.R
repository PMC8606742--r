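#' Write bone transforms to CSV
#'
#' One row per frame. Two dialects are supported: `"matrix"` writes the 16
#' row-major homogeneous-matrix entries per bone
#' (`<bone>.m00 ... <bone>.m33`), `"euler"` writes 6 columns per bone
#' (`<bone>.tx, .ty, .tz, .rx, .ry, .rz`, mm and degrees).
#'
#' @param transforms Named list: bone -> list of `rigid_transform`s.
#' @param path Output file.
#' @param dialect `"matrix"` (default) or `"euler"`.
#' @param euler_order Euler order used by the euler dialect.
#' @return `path`, invisibly.
#' @export
write_transforms_csv <- function(transforms, path,
                                 dialect = c("matrix", "euler"),
                                 euler_order = "xyz") {
  dialect <- match.arg(dialect)
  stopifnot(length(transforms) >= 1L, !is.null(names(transforms)))
  n <- length(transforms[[1]])
  cols <- list()
  for (bone in names(transforms)) {
    Ts <- transforms[[bone]]
    stopifnot(length(Ts) == n)
    if (dialect == "matrix") {
      m <- t(vapply(Ts, function(tr) as.numeric(t(as.matrix(tr))),
                    numeric(16)))
      colnames(m) <- paste0(bone, ".m",
                            as.vector(t(outer(0:3, 0:3, paste0))))
    } else {
      m <- t(vapply(Ts, function(tr) {
        c(tr$t, matrix_to_euler(tr$R, euler_order))
      }, numeric(6)))
      colnames(m) <- paste0(bone, ".", c("tx", "ty", "tz", "rx", "ry", "rz"))
    }
    cols[[bone]] <- m
  }
  df <- data.frame(frame = seq_len(n), do.call(cbind, cols),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read bone transforms from CSV
#'
#' Auto-detects the dialect written by [write_transforms_csv()] from the
#' column suffixes and reports the detection.
#'
#' @param path CSV file.
#' @param euler_order Euler order assumed for the euler dialect.
#' @param quiet Suppress the detection message.
#' @return Named list: bone -> list of `rigid_transform`s, with attribute
#'   `dialect`.
#' @export
read_transforms_csv <- function(path, euler_order = "xyz", quiet = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE)
  cn <- setdiff(names(df), "frame")
  parts <- regmatches(cn, regexpr("\\.[^.]+$", cn))
  suff <- sub("^\\.", "", parts)
  bones <- unique(sub("\\.[^.]+$", "", cn))
  dialect <- if (all(grepl("^m[0-3][0-3]$", suff))) "matrix"
             else if (all(suff %in% c("tx", "ty", "tz", "rx", "ry", "rz")))
               "euler"
             else stop("unrecognised transform CSV dialect (columns: ",
                       paste(utils::head(cn, 4), collapse = ", "), " ...)",
                       call. = FALSE)
  if (!quiet) {
    message("transform CSV '", basename(path), "': ", dialect,
            " dialect, bones: ", paste(bones, collapse = ", "))
  }
  out <- lapply(bones, function(bone) {
    if (dialect == "matrix") {
      m <- as.matrix(df[paste0(bone, ".m",
                               as.vector(t(outer(0:3, 0:3, paste0))))])
      lapply(seq_len(nrow(m)), function(i) {
        H <- matrix(m[i, ], 4, 4, byrow = TRUE)
        rigid_transform(H[1:3, 1:3], H[1:3, 4])
      })
    } else {
      m <- as.matrix(df[paste0(bone, ".",
                               c("tx", "ty", "tz", "rx", "ry", "rz"))])
      lapply(seq_len(nrow(m)), function(i) {
        rigid_transform(euler_to_matrix(m[i, 4:6], euler_order), m[i, 1:3])
      })
    }
  })
  names(out) <- bones
  attr(out, "dialect") <- dialect
  out
}

#' Write point-marker trajectories to CSV
#'
#' Long format: `frame, marker_id, x, y, z` (mm).
#'
#' @param markers Named list of n x 3 matrices.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_markers_csv <- function(markers, path) {
  stopifnot(length(markers) >= 1L, !is.null(names(markers)))
  rows <- do.call(rbind, lapply(names(markers), function(id) {
    m <- markers[[id]]
    data.frame(frame = seq_len(nrow(m)), marker_id = id,
               x = m[, 1], y = m[, 2], z = m[, 3])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read point-marker trajectories from CSV
#' @param path CSV written by [write_markers_csv()].
#' @return Named list of n x 3 matrices, ordered by frame.
#' @export
read_markers_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "marker_id", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("marker CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(df, df$marker_id), function(g) {
    g <- g[order(g$frame), ]
    as.matrix(g[c("x", "y", "z")])
  })
}

#' Read per-specimen range records from CSV
#'
#' Columns: `specimen, side, joint, dof, min, max` (plus optional `unit`).
#'
#' @param path CSV file.
#' @return A [range_records()] data frame.
#' @export
read_range_records <- function(path) {
  df <- utils::read.csv(path)
  need <- c("specimen", "side", "joint", "dof", "min", "max")
  if (!all(need %in% names(df))) {
    stop("range CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- range_records(df$specimen, df$side, df$joint, df$dof, df$min,
                       df$max)
  if ("unit" %in% names(df)) out$unit <- df$unit
  out
}

#' Packaged echidna forelimb range table
#'
#' The per-specimen joint rotation and translation extremes measured on
#' passively manipulated echidna forelimbs (three animals, five
#' specimen-sides, three joints), shipped as the package's in-paper
#' worked-example data set. Pooling these per-dof reproduces the published
#' "total possible" ranges.
#'
#' @return A [range_records()] data frame with a `unit` column.
#' @examples
#' r <- echidna_forelimb_ranges()
#' pooled_range(r[r$joint == "scapulocoracoid", ])
#' @export
echidna_forelimb_ranges <- function() {
  read_range_records(system.file("extdata", "echidna_forelimb_ranges.csv",
                                 package = "momentarms", mustWork = TRUE))
}

#' Read a muscle architecture table from CSV
#'
#' Columns: `muscle, head, pcsa_mm2, lopt_mm, lslack_mm, pennation_deg`.
#'
#' @param path CSV file.
#' @param specific_tension N/mm^2 (default 0.3).
#' @return Data frame with an added `f_max_n` column.
#' @export
read_architecture_csv <- function(path, specific_tension = 0.3) {
  df <- utils::read.csv(path)
  need <- c("muscle", "head", "pcsa_mm2", "lopt_mm", "lslack_mm",
            "pennation_deg")
  if (!all(need %in% names(df))) {
    stop("architecture CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$f_max_n <- max_isometric_force(df$pcsa_mm2, specific_tension)
  df
}

#' Write a joint pose series as a SIMM-style motion (.mot) file
#'
#' Minimal common header (`name`, `datacolumns`, `datarows`, `range`,
#' `endheader`), a tab-delimited label row (`time` first), then the
#' numeric rows at full precision.
#'
#' @param poses Data frame of generalized coordinates (e.g. `rx ... tz`),
#'   one row per frame. A `time` column is used if present, otherwise
#'   built from `frame_rate`.
#' @param path Output file.
#' @param name Motion name for the header.
#' @param frame_rate Hz, used when `poses` has no `time` column.
#' @return `path`, invisibly.
#' @export
write_mot <- function(poses, path, name = "motion", frame_rate = 60) {
  poses <- as.data.frame(poses)
  if (!nrow(poses)) stop("cannot write an empty motion", call. = FALSE)
  if (!"time" %in% names(poses)) {
    poses <- cbind(time = (seq_len(nrow(poses)) - 1) / frame_rate, poses)
  } else {
    poses <- poses[c("time", setdiff(names(poses), "time"))]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("name", name),
               paste("datacolumns", ncol(poses)),
               paste("datarows", nrow(poses)),
               paste("range", format(min(poses$time), digits = 17),
                     format(max(poses$time), digits = 17)),
               "endheader",
               paste(names(poses), collapse = "\t")), con)
  utils::write.table(format(poses, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a SIMM-style motion (.mot) file
#'
#' @param path File written by [write_mot()] (or any minimal-header .mot).
#' @return List with `name` and `data` (data frame including `time`).
#'   Declared `datacolumns`/`datarows` are checked against the payload.
#' @export
read_mot <- function(path) {
  lines <- readLines(path)
  end <- match("endheader", lines)
  if (is.na(end)) stop("no 'endheader' line in ", path, call. = FALSE)
  header <- lines[seq_len(end - 1)]
  get_field <- function(key) {
    hit <- grep(paste0("^", key, "\\b"), header, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^", key, "\\s+"), "", hit[1])
  }
  labels <- strsplit(lines[end + 1], "\t")[[1]]
  body <- lines[-seq_len(end + 1)]
  body <- body[nzchar(body)]
  data <- utils::read.table(text = body, sep = "\t",
                            col.names = labels)
  nd <- as.integer(get_field("datarows"))
  nc <- as.integer(get_field("datacolumns"))
  if (!is.na(nd) && nd != nrow(data)) {
    stop("declared datarows ", nd, " but found ", nrow(data), call. = FALSE)
  }
  if (!is.na(nc) && nc != ncol(data)) {
    stop("declared datacolumns ", nc, " but found ", ncol(data),
         call. = FALSE)
  }
  list(name = get_field("name"), data = data)
}

#' Export an envelope boundary mesh
#'
#' Writes the boundary triangles of a [alpha_hull()] envelope as a
#' Wavefront OBJ or OFF mesh, plus (optionally) a JSON metadata sidecar
#' recording alpha, dialect and volume so outputs are self-describing.
#'
#' @param envelope A `rom_envelope`.
#' @param path Output mesh file.
#' @param format `"obj"` or `"off"`.
#' @param json_path Optional path for the metadata JSON.
#' @return `path`, invisibly.
#' @export
write_envelope_mesh <- function(envelope, path, format = c("obj", "off"),
                                json_path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(envelope, "rom_envelope"))
  used <- sort(unique(as.vector(envelope$faces)))
  remap <- match(seq_len(nrow(envelope$points)), used)
  V <- envelope$points[used, , drop = FALSE]
  Fc <- matrix(remap[envelope$faces], ncol = 3)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "obj") {
    writeLines(sprintf("v %.10g %.10g %.10g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("f %d %d %d", Fc[, 1], Fc[, 2], Fc[, 3]), con)
  } else {
    writeLines("OFF", con)
    writeLines(sprintf("%d %d 0", nrow(V), nrow(Fc)), con)
    writeLines(sprintf("%.10g %.10g %.10g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("3 %d %d %d", Fc[, 1] - 1L, Fc[, 2] - 1L,
                       Fc[, 3] - 1L), con)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(alpha = envelope$alpha, dialect = envelope$dialect,
           volume = envelope$volume, convex_volume = envelope$convex_volume,
           n_points = nrow(envelope$points), n_tets = nrow(envelope$tets)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
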