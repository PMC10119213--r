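#' Read a TIFF image stack
#'
#' Reads a single- or multi-page TIFF into an \linkS4class{ImageStack}, pages
#' ordered by page index. Calibration is mandatory user input: a resolution
#' tag present in the file is never used, and a warning is emitted if it
#' disagrees with the explicit calibration.
#'
#' @param path path to a TIFF file.
#' @param calibration a \linkS4class{PixelCalibration}.
#' @param depthOffset depth of the first page below the specimen border (um).
#' @return An \linkS4class{ImageStack}.
#' @export
readStack <- function(path, calibration, depthOffset = 0) {
  if (!file.exists(path)) sqStop("sqIOError", "cannot read TIFF: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
                    error = function(e) sqStop("sqIOError", "unreadable TIFF: ",
                                               conditionMessage(e)))
  if (length(pages) == 0) sqStop("sqFormatError", "TIFF has zero pages: ", path)
  shapes <- vapply(pages, function(p) dim(p)[1:2], numeric(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    sqStop("sqFormatError", "TIFF pages have mixed shapes")
  xres <- attr(pages[[1]], "x.resolution")
  if (!is.null(xres) && is.finite(xres) && xres > 0) {
    implied <- 1 / xres
    if (abs(implied - calibration@xySize) / calibration@xySize > 1e-6)
      warning(sprintf(paste0("TIFF resolution tag implies %.4g units/px; ",
                             "overridden by explicit calibration (%.4g um/px)"),
                      implied, calibration@xySize))
  }
  scalePage <- function(p) {
    p <- p[, , drop = TRUE]
    if (length(dim(p)) == 3) p <- p[, , 1]  # first channel of multichannel pages
    p
  }
  mats <- lapply(pages, scalePage)
  arr <- array(0, dim = c(length(mats), nrow(mats[[1]]), ncol(mats[[1]])))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  ImageStack(arr, calibration, depthOffset)
}

#' Write an image stack as multi-page TIFF
#'
#' Stacks are written as 8- or 16-bit unsigned integer TIFF; round-trip with
#' \code{\link{readStack}} is voxel-identical for integer-valued stacks.
#' Non-integer intensities are rounded to the integer grid with a warning
#' (rescale beforehand if sub-integer precision matters); values above 65535
#' are clipped with a warning.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  v <- stack@voxels
  if (any(v != round(v))) {
    warning("non-integer intensities rounded for TIFF export")
    v <- round(v)
  }
  if (max(v) > 65535) {
    warning("intensities above 65535 clipped for TIFF export")
    v <- pmin(v, 65535)
  }
  bits <- if (max(v) < 2^8) 8L else 16L
  n <- dim(v)[1]
  pages <- lapply(seq_len(n), function(i)
    matrix(v[i, , ], dim(v)[2], dim(v)[3]) / (2^bits - 1))
  tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = bits),
           error = function(e) sqStop("sqIOError", "cannot write TIFF: ",
                                      conditionMessage(e)))
  invisible(path)
}

# ---- boundary polygons -------------------------------------------------

polygonIsSimple <- function(v) {
  n <- nrow(v)
  if (n < 3) return(FALSE)
  segs <- cbind(v, v[c(2:n, 1), , drop = FALSE])  # r1 c1 r2 c2
  cross <- function(o, a, b) (a[2] - o[2]) * (b[1] - o[1]) - (a[1] - o[1]) * (b[2] - o[2])
  intersects <- function(p1, p2, p3, p4) {
    d1 <- cross(p3, p4, p1); d2 <- cross(p3, p4, p2)
    d3 <- cross(p1, p2, p3); d4 <- cross(p1, p2, p4)
    ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent segments (they share an endpoint)
      if (j == i + 1 || (i == 1 && j == n)) next
      if (intersects(segs[i, 1:2], segs[i, 3:4], segs[j, 1:2], segs[j, 3:4]))
        return(FALSE)
    }
  }
  TRUE
}

acceptedBoundaryLabels <- c("core_rim", "rim_invasion")

#' Read zone-boundary polygons
#'
#' Reads boundary polygons from a JSON polygon file
#' (\code{{"core_rim": [[r,c],...], "rim_invasion": [[r,c],...]}}), a single
#' ImageJ \code{.roi} file (label taken from the file name) or an ImageJ
#' \code{.zip} ROI container (labels from entry names). Coordinates are
#' returned 0-based as (row, col).
#'
#' @param path path to a \code{.json}, \code{.roi} or \code{.zip} file.
#' @return List of \linkS4class{BoundaryPolygon}.
#' @export
readBoundaries <- function(path) {
  if (!file.exists(path)) sqStop("sqIOError", "cannot read boundaries: ", path)
  ext <- tolower(tools::file_ext(path))
  mk <- function(verts, label) {
    label <- sub("\\.roi$", "", tolower(label))
    if (!label %in% acceptedBoundaryLabels)
      sqStop("sqFormatError", "unknown boundary label '", label,
             "'; accepted labels: ", paste(acceptedBoundaryLabels, collapse = ", "))
    if (nrow(verts) < 3)
      sqStop("sqFormatError", "polygon '", label, "' has fewer than 3 vertices")
    if (!polygonIsSimple(verts))
      sqStop("sqFormatError", "polygon '", label, "' is self-intersecting")
    BoundaryPolygon(verts, label)
  }
  if (ext == "json") {
    obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    return(lapply(names(obj), function(nm) {
      v <- obj[[nm]]
      if (is.list(v)) v <- do.call(rbind, v)
      mk(as.matrix(v), nm)
    }))
  }
  if (ext == "roi") {
    verts <- readImageJRoi(path)
    return(list(mk(verts, basename(path))))
  }
  if (ext == "zip") {
    tmp <- tempfile("rois")
    dir.create(tmp)
    on.exit(unlink(tmp, recursive = TRUE))
    files <- unzip(path, exdir = tmp)
    return(lapply(files, function(f) mk(readImageJRoi(f), basename(f))))
  }
  sqStop("sqFormatError", "unsupported boundary file type: .", ext)
}

# Minimal ImageJ .roi reader: polygon-family ROIs only. Header: bytes 0-3
# "Iout", byte 6 type, shorts at 8/10 top/left, short at 16 n, coordinates
# from byte 64 as shorts (x block then y block) relative to (left, top).
# ImageJ x = column, y = row; returned 0-based (row, col).
readImageJRoi <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout")
    sqStop("sqFormatError", "not an ImageJ ROI file: ", path)
  short <- function(off) {  # big-endian signed 16-bit at 0-based byte offset
    readBin(raw[(off + 1):(off + 2)], "integer", size = 2, endian = "big", signed = TRUE)
  }
  type <- as.integer(raw[7])
  if (!type %in% c(0L, 7L, 8L))  # polygon, freehand, traced
    sqStop("sqFormatError", "unsupported ImageJ ROI type ", type,
           " (only polygon-family ROIs are supported)")
  top <- short(8); left <- short(10); n <- short(16)
  if (n < 3) sqStop("sqFormatError", "ROI has fewer than 3 vertices")
  xs <- vapply(seq_len(n) - 1, function(i) short(64 + 2 * i), numeric(1))
  ys <- vapply(seq_len(n) - 1, function(i) short(64 + 2 * n + 2 * i), numeric(1))
  cbind(row = ys + top, col = xs + left)
}

# Counterpart writer (used to build test fixtures programmatically).
writeImageJRoi <- function(vertices, path) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  rows <- v[, 1]; cols <- v[, 2]
  top <- floor(min(rows)); left <- floor(min(cols))
  hdr <- raw(64)
  hdr[1:4] <- charToRaw("Iout")
  putShort <- function(buf, off, val) {
    b <- writeBin(as.integer(val), raw(), size = 2, endian = "big")
    buf[(off + 1):(off + 2)] <- b
    buf
  }
  hdr <- putShort(hdr, 4, 227L)         # version
  hdr[7] <- as.raw(0L)                  # type: polygon
  hdr <- putShort(hdr, 8, top)
  hdr <- putShort(hdr, 10, left)
  hdr <- putShort(hdr, 12, ceiling(max(rows)))
  hdr <- putShort(hdr, 14, ceiling(max(cols)))
  hdr <- putShort(hdr, 16, n)
  coords <- writeBin(as.integer(c(round(cols - left), round(rows - top))),
                     raw(), size = 2, endian = "big")
  writeBin(c(hdr, coords), path)
  invisible(path)
}

# ---- result tables -----------------------------------------------------

#' Write quantification results
#'
#' Writes the per-nucleus table, per-zone summary, per-(slice, zone) counts,
#' apoptosis events, mitoses, the SNR profile (when present) and a
#' run-metadata JSON (all parameters, seeds, package version, timestamp) to
#' \code{outDir}. Given identical inputs and seed the CSVs are byte-identical
#' across runs; only the metadata timestamp differs.
#'
#' @param result a \linkS4class{QuantResult}.
#' @param outDir output directory (created if needed).
#' @return Named list (manifest) of every file written, invisibly also saved
#'   as \code{manifest.json}.
#' @export
writeResults <- function(result, outDir) {
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(outDir, 2) != 0)
    sqStop("sqIOError", "output directory not writable: ", outDir)
  wcsv <- function(df, name) {
    f <- file.path(outDir, name)
    write.csv(df, f, row.names = FALSE, fileEncoding = "UTF-8")
    f
  }
  nuc <- result@nuclei
  nucOut <- data.frame(id = nuc$id, slice = nuc$slice,
                       centroid_row = nuc$row, centroid_col = nuc$col,
                       area_um2 = nuc$area_um2, mean_intensity = nuc$mean_intensity,
                       zone = nuc$zone, radial_distance_um = nuc$radial_um,
                       state = nuc$state)
  files <- list(
    nuclei = wcsv(nucOut, "nuclei.csv"),
    zone_summary = wcsv(result@zoneSummary, "zone_summary.csv"),
    slice_zone_counts = wcsv(result@sliceZoneCounts, "slice_zone_counts.csv"),
    events = wcsv(result@events, "apoptosis_events.csv"),
    mitoses = wcsv(result@mitoses, "mitoses.csv"))
  if (is(result@snr, "SNRProfile"))
    files$snr_profile <- wcsv(result@snr@profile, "snr_profile.csv")
  meta <- list(parameters = result@params,
               time_label = result@timeLabel,
               invasion_summary = result@invasionSummary,
               software = paste0("spheroidquant ", as.character(packageVersion("spheroidquant"))),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  metaPath <- file.path(outDir, "run_metadata.json")
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA, null = "null")
  files$metadata <- metaPath
  manifest <- list(out_dir = outDir, files = files)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$files$manifest <- file.path(outDir, "manifest.json")
  invisible(manifest)
}

#' Read a pipeline configuration file
#'
#' YAML or JSON, decided by file extension.
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return Nested list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) sqStop("sqIOError", "cannot read config: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) return(yaml::read_yaml(path))
  if (ext == "json") return(jsonlite::fromJSON(path, simplifyVector = TRUE))
  sqStop("sqFormatError", "unsupported config file type: .", ext)
}
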