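#' angioflow: image-based blood-flow quantification for dialysis access
#'
#' Bolus-tracking flow measurement on 2-D angiographic sequences: time-density
#' curves, parametric curve fitting, peak-to-peak and cross-correlation transit
#' times, vessel geometry extraction, volumetric flow, a synthetic flow-phantom
#' simulator with ground truth, and agreement statistics.
#'
#' @section Conventions:
#' All pixel coordinates are 0-based, `(row, col)` ordered; region-of-interest
#' bounds are half-open. Time index 0 is acquisition start. Pixel spacing is
#' isotropic (cm/px); intensities are arbitrary linear detector units.
#'
#' @importFrom stats approx coef convolve lm pnorm rnorm rpois runif sd setNames t.test
#' @importFrom utils head read.csv write.csv tail
#' @importFrom graphics lines legend abline points
#' @name angioflow
"_PACKAGE"

SEQ_MODALITIES <- c("DSA", "FLUORO")

#' Construct a validated angiographic image sequence
#'
#' The container every other module consumes: a time-ordered stack of 2-D
#' frames with temporal and spatial calibration and an imaging-modality tag.
#'
#' @param frames numeric array, `time x rows x cols`, arbitrary detector units.
#' @param frame_interval_s seconds per frame (\eqn{\Delta t > 0}).
#' @param pixel_spacing_cm isotropic cm per pixel (> 0).
#' @param modality `"DSA"` (subtracted, contrast bright on zero background) or
#'   `"FLUORO"` (unsubtracted, contrast dark on bright background).
#' @return an object of class `image_sequence`.
#' @examples
#' seq <- image_sequence(array(0, c(4, 8, 8)), 1 / 6, 0.03, "DSA")
#' dim(seq$frames)
#' @export
image_sequence <- function(frames, frame_interval_s, pixel_spacing_cm,
                           modality = c("DSA", "FLUORO")) {
  modality <- match.arg(modality)
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be a 3-D array (time x rows x cols)")
  if (dim(frames)[1] < 2L)
    stop("an image sequence needs at least 2 frames")
  if (!all(is.finite(frames)))
    stop("frames contain non-finite intensities")
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1L ||
      !is.finite(frame_interval_s) || frame_interval_s <= 0)
    stop("frame_interval_s must be a single positive number")
  if (!is.numeric(pixel_spacing_cm) || length(pixel_spacing_cm) != 1L ||
      !is.finite(pixel_spacing_cm) || pixel_spacing_cm <= 0)
    stop("pixel_spacing_cm must be a single positive number")
  structure(
    list(frames = frames,
         frame_interval_s = as.numeric(frame_interval_s),
         pixel_spacing_cm = as.numeric(pixel_spacing_cm),
         modality = modality),
    class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_sequence: %d frames of %d x %d px, %s\n",
              d[1], d[2], d[3], x$modality))
  cat(sprintf("  frame interval %.4g s (%.3g samples/s), pixel %.4g cm\n",
              x$frame_interval_s, 1 / x$frame_interval_s, x$pixel_spacing_cm))
  invisible(x)
}

#' @export
dim.image_sequence <- function(x) dim(x$frames)

n_frames <- function(seq) dim(seq$frames)[1]

#' Rectangular region of interest
#'
#' Pixel bounds are 0-based and half-open, so `roi(0, 10, 0, 10)` covers the
#' first ten rows and columns.
#'
#' @param row_start,row_end,col_start,col_end integer pixel bounds.
#' @param label optional text label.
#' @return an object of class `roi`.
#' @export
roi <- function(row_start, row_end, col_start, col_end, label = "") {
  v <- c(row_start, row_end, col_start, col_end)
  if (any(v != round(v)) || any(v < 0))
    stop("roi bounds must be non-negative integers")
  if (row_start >= row_end || col_start >= col_end)
    stop("roi bounds must satisfy start < end (half-open)")
  structure(list(row_start = as.integer(row_start),
                 row_end = as.integer(row_end),
                 col_start = as.integer(col_start),
                 col_end = as.integer(col_end),
                 label = as.character(label)),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("roi%s: rows [%d, %d), cols [%d, %d)\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$row_start, x$row_end, x$col_start, x$col_end))
  invisible(x)
}

roi_center_row <- function(r) as.integer(floor((r$row_start + r$row_end - 1) / 2))

check_roi_in <- function(r, seq_dims) {
  if (r$row_end > seq_dims[2] || r$col_end > seq_dims[3])
    stop("roi extends outside the frame bounds")
  invisible(TRUE)
}

# ---- file formats -----------------------------------------------------------

ARCHIVE_MAGIC <- "angioflow-sequence-v1"

#' Read an image sequence from disk
#'
#' Supported formats, chosen by extension: the package's native archive
#' (`.afs`, lossless, canonical), multi-page TIFF (`.tif`/`.tiff`, values as
#' stored; calibration must come from `overrides`), and uncompressed
#' Explicit-VR little-endian grayscale DICOM (`.dcm`, read-only).
#' TIFF and DICOM files missing temporal or spatial calibration require the
#' corresponding `overrides` entry, otherwise an error is raised.
#'
#' @param path file path.
#' @param overrides optional named list with any of `frame_interval_s`,
#'   `pixel_spacing_cm`, `modality`; overrides take precedence over metadata.
#' @return an [image_sequence()].
#' @seealso [write_sequence()]
#' @export
read_sequence <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    "afs" = read_archive(path),
    "tif" = ,
    "tiff" = read_tiff_stack(path),
    "dcm" = read_dicom_sequence(path),
    stop("unsupported sequence format: .", ext))
  for (k in c("frame_interval_s", "pixel_spacing_cm", "modality"))
    if (!is.null(overrides[[k]])) raw[[k]] <- overrides[[k]]
  if (is.null(raw$frame_interval_s))
    stop("no temporal calibration in file; supply overrides$frame_interval_s")
  if (is.null(raw$pixel_spacing_cm))
    stop("no pixel spacing in file; supply overrides$pixel_spacing_cm")
  if (is.null(raw$modality)) raw$modality <- "DSA"
  image_sequence(raw$frames, raw$frame_interval_s, raw$pixel_spacing_cm,
                 raw$modality)
}

#' Write an image sequence to disk
#'
#' The native archive (`.afs`) round-trips frames and calibration losslessly
#' and is what [read_sequence()] re-reads bit-identically. TIFF output rescales
#' intensities to the `[0, 1]` range the format stores (lossy interchange;
#' calibration is not embedded).
#'
#' @param seq an [image_sequence()].
#' @param path destination; extension selects the format (`.afs`, `.tif`).
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "image_sequence"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "afs") {
    obj <- list(magic = ARCHIVE_MAGIC,
                frames = seq$frames,
                frame_interval_s = seq$frame_interval_s,
                pixel_spacing_cm = seq$pixel_spacing_cm,
                modality = seq$modality)
    saveRDS(obj, path, compress = "gzip")
  } else if (ext %in% c("tif", "tiff")) {
    rng <- range(seq$frames)
    den <- if (diff(rng) > 0) diff(rng) else 1
    pages <- lapply(seq_len(n_frames(seq)), function(i)
      (seq$frames[i, , ] - rng[1]) / den)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else {
    stop("unsupported output format: .", ext)
  }
  invisible(path)
}

read_archive <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("unreadable native archive: ", conditionMessage(e)))
  if (!identical(obj$magic, ARCHIVE_MAGIC))
    stop("not an angioflow sequence archive")
  obj[c("frames", "frame_interval_s", "pixel_spacing_cm", "modality")]
}

read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) stop("single-frame input: need a multi-page stack")
  shp <- dim(pages[[1]])
  if (length(shp) > 2L) stop("only grayscale TIFF stacks are supported")
  frames <- array(0, c(length(pages), shp[1], shp[2]))
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), shp)) stop("frames differ in shape")
    frames[i, , ] <- pages[[i]]
  }
  list(frames = frames, frame_interval_s = NULL, pixel_spacing_cm = NULL,
       modality = NULL)
}

# ---- minimal DICOM reader ---------------------------------------------------
# Read-only support for uncompressed Explicit-VR little-endian grayscale
# DICOM, single- or multi-frame, as produced by an offline angiography export.
# Tags used: Rows, Columns, BitsAllocated, PixelRepresentation, NumberOfFrames,
# FrameTime (ms), CineRate (1/s), PixelSpacing (mm), Modality, PixelData.

read_dicom_sequence <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  bytes <- readBin(con, "raw", n = file.info(path)$size)
  if (length(bytes) < 132L || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic)")
  pos <- 133L
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  u16 <- function(i) as.integer(bytes[i]) + 256L * as.integer(bytes[i + 1L])
  u32 <- function(i) as.integer(bytes[i]) + 256 * as.integer(bytes[i + 1L]) +
    65536 * as.integer(bytes[i + 2L]) + 16777216 * as.integer(bytes[i + 3L])
  while (pos + 7L <= length(bytes)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit-VR or corrupted DICOM not supported")
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L)
      body <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      body <- pos + 8L
    }
    if (len == 4294967295 || (vr == "SQ"))
      stop("undefined-length/sequence DICOM elements not supported")
    key <- sprintf("%04x,%04x", group, elem)
    tags[[key]] <- list(vr = vr, start = body, len = len)
    pos <- body + len
    if (key == "7fe0,0010") break
  }
  getstr <- function(key) {
    t <- tags[[key]]
    if (is.null(t) || t$len == 0L) return(NULL)
    trimws(rawToChar(bytes[t$start:(t$start + t$len - 1L)]))
  }
  getu16val <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    u16(t$start)
  }
  rows <- getu16val("0028,0010"); cols <- getu16val("0028,0011")
  bits <- getu16val("0028,0100")
  if (is.null(rows) || is.null(cols)) stop("DICOM missing Rows/Columns")
  if (is.null(bits) || !(bits %in% c(8L, 16L)))
    stop("only 8- or 16-bit DICOM pixel data supported")
  signed <- identical(getu16val("0028,0103"), 1L)
  nf <- suppressWarnings(as.integer(getstr("0028,0008")))
  if (is.null(nf) || is.na(nf)) nf <- 1L
  if (nf < 2L) stop("single-frame input: need a multi-frame DICOM")
  pd <- tags[["7fe0,0010"]]
  if (is.null(pd)) stop("DICOM missing PixelData")
  npx <- as.numeric(rows) * cols * nf
  bpp <- bits %/% 8L
  if (pd$len < npx * bpp) stop("truncated DICOM pixel data")
  vals <- readBin(bytes[pd$start:(pd$start + pd$len - 1L)],
                  what = "integer", n = npx, size = bpp,
                  signed = if (bpp == 1L) FALSE else signed, endian = "little")
  if (bpp == 1L && signed) vals <- ifelse(vals > 127L, vals - 256L, vals)
  frames <- array(0, c(nf, rows, cols))
  for (i in seq_len(nf)) {
    off <- (i - 1L) * rows * cols
    # DICOM pixels are row-major
    frames[i, , ] <- matrix(vals[(off + 1L):(off + rows * cols)],
                            nrow = rows, ncol = cols, byrow = TRUE)
  }
  ft_ms <- suppressWarnings(as.numeric(getstr("0018,1063")))
  cine <- suppressWarnings(as.numeric(getstr("0018,0040")))
  dt <- if (length(ft_ms) && !is.na(ft_ms) && ft_ms > 0) ft_ms / 1000
        else if (length(cine) && !is.na(cine) && cine > 0) 1 / cine
        else NULL
  ps <- getstr("0028,0030")
  spacing <- NULL
  if (!is.null(ps)) {
    parts <- suppressWarnings(as.numeric(strsplit(ps, "\\\\")[[1]]))
    if (length(parts) == 2L && all(is.finite(parts))) {
      if (abs(parts[1] - parts[2]) > 1e-9 * max(parts))
        stop("anisotropic DICOM pixel spacing is not supported")
      spacing <- parts[1] / 10  # mm -> cm
    }
  }
  modality <- switch(getstr("0008,0060") %||% "",
                     "XA" = "DSA", "RF" = "FLUORO", NULL)
  list(frames = frames, frame_interval_s = dt, pixel_spacing_cm = spacing,
       modality = modality)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- flat key=value configuration ------------------------------------------

#' Read a flat key = value configuration file
#'
#' Lines are `key = value`; `#` starts a comment. Values that parse as numbers
#' are returned numeric, `true`/`false` as logical, everything else as text.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("malformed config line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <-
      if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
      else val
  }
  cfg
}

#' Write a flat key = value configuration file
#'
#' @param cfg named list of scalar values.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(is.list(cfg), length(names(cfg)) == length(cfg))
  writeLines(paste(names(cfg), unlist(lapply(cfg, format)), sep = " = "), path)
  invisible(path)
}
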