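#' Read a DICOM slice stack into a CT volume
#'
#' Reads every file in `directory` as an uncompressed little-endian DICOM
#' slice, orders slices by `InstanceNumber` (falling back to `SliceLocation`,
#' then to file name), and assembles them into a [ct_volume()]. Slice order
#' is a pure function of DICOM tags, never of directory listing order.
#' 16-bit intensities are preserved losslessly.
#'
#' @param directory path containing the slice files.
#' @param spacing_override optional `(dx, dy, dz)` in mm overriding the
#'   spacing tags.
#' @param allow_default_spacing if `TRUE`, fall back to 0.3 mm isotropic
#'   (the nominal resolution of the panicle scanner) when the files carry no
#'   spacing tags; otherwise missing spacing is an error.
#' @return A [ct_volume()].
#' @export
read_dicom_stack <- function(directory, spacing_override = NULL,
                             allow_default_spacing = FALSE) {
  if (!dir.exists(directory)) stop("no slices: directory does not exist")
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no slices found in directory")
  slices <- lapply(files, dicom_read_file)
  shapes <- vapply(slices, function(s) c(s$ncol, s$nrow), integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("ragged stack: slices have inconsistent in-plane shapes")
  inst <- vapply(slices, function(s) s$instance %||% NA_real_, numeric(1))
  loc <- vapply(slices, function(s) s$location %||% NA_real_, numeric(1))
  ord <- if (!anyNA(inst) && !anyDuplicated(inst)) {
    order(inst)
  } else if (!anyNA(loc) && !anyDuplicated(loc)) {
    order(loc)
  } else {
    order(basename(files))
  }
  slices <- slices[ord]
  nx <- slices[[1]]$ncol
  ny <- slices[[1]]$nrow
  nz <- length(slices)
  data <- array(0L, c(nx, ny, nz))
  for (k in seq_len(nz)) data[, , k] <- slices[[k]]$pixels
  spacing <- spacing_override
  if (is.null(spacing)) {
    ps <- slices[[1]]$pixel_spacing # (row spacing = dy, column spacing = dx)
    dz <- slices[[1]]$spacing_between %||% slices[[1]]$thickness
    if (!is.null(ps) && !is.null(dz)) {
      spacing <- c(ps[2], ps[1], dz)
    } else if (allow_default_spacing) {
      spacing <- c(0.3, 0.3, 0.3)
    } else {
      stop("unknown spacing: files carry no spacing tags and no override given")
    }
  }
  origin <- slices[[1]]$position %||% c(0, 0, 0)
  ct_volume(data, spacing = spacing, origin = origin)
}

#' Write a CT volume as a DICOM slice stack
#'
#' One uncompressed Explicit VR Little Endian file per z-slice, carrying the
#' tags needed for lossless round-tripping: instance number, slice location,
#' image position, pixel spacing and slice spacing.
#'
#' @param volume a [ct_volume()]; intensities are rounded to unsigned 16-bit.
#' @param directory output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_dicom_stack <- function(volume, directory, prefix = "slice") {
  stopifnot(inherits(volume, "ct_volume"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  d <- dim(volume$data)
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    paths[k] <- file.path(directory, sprintf("%s_%04d.dcm", prefix, k))
    dicom_write_file(paths[k],
                     pixels = volume$data[, , k],
                     instance = k,
                     spacing = volume$spacing,
                     position = volume$origin +
                       c(0, 0, (k - 1) * volume$spacing[3]))
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- minimal DICOM encoding (Explicit VR Little Endian) ---------------------

dicom_uint <- function(x, size) {
  writeBin(as.integer(x), raw(), size = size, endian = "little")
}

dicom_elem <- function(group, elem, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(value)
    if (length(value) %% 2L == 1L)
      value <- c(value, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  }
  head <- c(dicom_uint(group, 2), dicom_uint(elem, 2))
  if (vr %in% c("OB", "OW", "UT", "UN", "SQ")) {
    c(head, charToRaw(vr), raw(2), dicom_uint(length(value), 4), value)
  } else {
    c(head, charToRaw(vr), dicom_uint(length(value), 2), value)
  }
}

dicom_write_file <- function(path, pixels, instance, spacing, position) {
  pix <- as.integer(round(pixels))
  pix[pix < 0L] <- 0L
  pix[pix > 65535L] <- 65535L
  nx <- nrow(pixels)
  ny <- ncol(pixels)
  # unsigned 16-bit little endian; writeBin size=2 needs values < 2^15 signed
  pix_raw <- as.raw(rbind(pix %% 256L, pix %/% 256L))
  sop_instance <- sprintf("1.2.826.0.1.3680043.9.7643.1.%d", instance)
  ds <- function(x) paste(format(x, trim = TRUE, scientific = FALSE,
                                 digits = 10), collapse = "\\")
  meta <- c(
    dicom_elem(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dicom_elem(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.7"),
    dicom_elem(0x0002, 0x0003, "UI", sop_instance),
    dicom_elem(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    dicom_elem(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9.7643")
  )
  body <- c(
    dicom_elem(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.7"),
    dicom_elem(0x0008, 0x0018, "UI", sop_instance),
    dicom_elem(0x0018, 0x0050, "DS", ds(spacing[3])),
    dicom_elem(0x0018, 0x0088, "DS", ds(spacing[3])),
    dicom_elem(0x0020, 0x0013, "IS", as.character(instance)),
    dicom_elem(0x0020, 0x0032, "DS", ds(position)),
    dicom_elem(0x0020, 0x1041, "DS", ds(position[3])),
    dicom_elem(0x0028, 0x0002, "US", dicom_uint(1, 2)),
    dicom_elem(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dicom_elem(0x0028, 0x0010, "US", dicom_uint(ny, 2)),   # Rows
    dicom_elem(0x0028, 0x0011, "US", dicom_uint(nx, 2)),   # Columns
    dicom_elem(0x0028, 0x0030, "DS", ds(c(spacing[2], spacing[1]))),
    dicom_elem(0x0028, 0x0100, "US", dicom_uint(16, 2)),
    dicom_elem(0x0028, 0x0101, "US", dicom_uint(16, 2)),
    dicom_elem(0x0028, 0x0102, "US", dicom_uint(15, 2)),
    dicom_elem(0x0028, 0x0103, "US", dicom_uint(0, 2)),
    dicom_elem(0x7FE0, 0x0010, "OW", pix_raw)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(dicom_elem(0x0002, 0x0000, "UL", dicom_uint(length(meta), 4)),
             meta, body), con)
  invisible(path)
}

# --- minimal DICOM parsing --------------------------------------------------

dicom_read_u16 <- function(bytes, at) {
  as.integer(bytes[at]) + 256L * as.integer(bytes[at + 1L])
}

dicom_read_u32 <- function(bytes, at) {
  as.integer(bytes[at]) + 256 * as.integer(bytes[at + 1L]) +
    65536 * as.integer(bytes[at + 2L]) + 16777216 * as.integer(bytes[at + 3L])
}

# Parses uncompressed little-endian DICOM, detecting explicit vs implicit VR
# per element (two uppercase letters where the VR field would be).
dicom_read_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140L ||
      !identical(rawToChar(bytes[129:132]), "DICM"))
    stop(sprintf("'%s' is not a DICOM file", basename(path)))
  long_vrs <- c("OB", "OW", "OF", "UT", "UN", "SQ")
  pos <- 133L
  out <- list()
  want <- function(g, e) sprintf("%04X%04X", g, e)
  targets <- c(rows = want(0x0028, 0x0010), cols = want(0x0028, 0x0011),
               instance = want(0x0020, 0x0013),
               location = want(0x0020, 0x1041),
               position = want(0x0020, 0x0032),
               pixel_spacing = want(0x0028, 0x0030),
               thickness = want(0x0018, 0x0050),
               spacing_between = want(0x0018, 0x0088),
               pixeldata = want(0x7FE0, 0x0010))
  vals <- list()
  n <- length(bytes)
  while (pos + 8L <= n) {
    group <- dicom_read_u16(bytes, pos)
    elem <- dicom_read_u16(bytes, pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (grepl("^[A-Z]{2}$", vr)) {
      if (vr %in% long_vrs) {
        len <- dicom_read_u32(bytes, pos + 8L)
        data_at <- pos + 12L
      } else {
        len <- dicom_read_u16(bytes, pos + 6L)
        data_at <- pos + 8L
      }
    } else { # implicit VR
      len <- dicom_read_u32(bytes, pos + 4L)
      data_at <- pos + 8L
    }
    if (len < 0 || data_at + len - 1L > n)
      stop(sprintf("corrupt DICOM element at offset %d in '%s'",
                   pos, basename(path)))
    key <- sprintf("%04X%04X", group, elem)
    hit <- names(targets)[match(key, targets)]
    if (!is.na(hit))
      vals[[hit]] <- bytes[data_at:(data_at + len - 1L)]
    pos <- data_at + len
  }
  if (is.null(vals$rows) || is.null(vals$cols) || is.null(vals$pixeldata))
    stop(sprintf("'%s' lacks Rows/Columns/PixelData", basename(path)))
  num <- function(r) if (is.null(r)) NULL else
    as.numeric(strsplit(trimws(rawToChar(r)), "\\\\")[[1]])
  nrow_tag <- dicom_read_u16(vals$rows, 1L)      # Rows = ny
  ncol_tag <- dicom_read_u16(vals$cols, 1L)      # Columns = nx
  npix <- nrow_tag * ncol_tag
  if (length(vals$pixeldata) < 2L * npix)
    stop(sprintf("'%s': PixelData shorter than Rows x Columns", basename(path)))
  pix <- readBin(vals$pixeldata, "integer", n = npix, size = 2L,
                 signed = FALSE, endian = "little")
  list(nrow = nrow_tag, ncol = ncol_tag,
       pixels = matrix(pix, nrow = ncol_tag, ncol = nrow_tag),
       instance = if (!is.null(vals$instance))
         as.numeric(trimws(rawToChar(vals$instance))) else NULL,
       location = if (!is.null(vals$location)) num(vals$location)[1] else NULL,
       position = num(vals$position),
       pixel_spacing = num(vals$pixel_spacing),
       thickness = if (!is.null(vals$thickness)) num(vals$thickness)[1]
                   else NULL,
       spacing_between = if (!is.null(vals$spacing_between))
         num(vals$spacing_between)[1] else NULL)
}
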