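# Standard-format I/O: NIfTI volumes (RNifti), DICOM series (minimal native
# reader: uncompressed implicit/explicit VR little endian), centerlines as
# JSON and VTK legacy polylines, phantom specs as YAML, CPR previews as PNG.

#' Read a 3D volume
#'
#' NIfTI file or DICOM series directory. DICOM slices are sorted by position
#' along the slice normal; inconsistent slice spacing is an error naming the
#' offending slices.
#'
#' @param path Path to a `.nii`/`.nii.gz` file or a directory of DICOM
#'   slices.
#' @param kind Sequence kind tag for the returned volume.
#' @return A [vwi_volume].
#' @export
read_volume <- function(path, kind = "other") {
  if (!file.exists(path))
    stop("volume_not_found: ", path)
  if (dir.exists(path)) return(read_dicom_series(path, kind))
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  vwi_volume(array(as.numeric(img), dim(img)[1:3]), spacing, kind)
}

#' Write a volume (or mask) as NIfTI
#'
#' @param vol A [vwi_volume] or [vwi_mask].
#' @param path Output `.nii`/`.nii.gz` path.
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Minimal DICOM support (enough for uncompressed single-frame MR series).

read_uint <- function(raw, signed = FALSE) {
  sum(as.integer(raw) * 256^(seq_along(raw) - 1))
}

dicom_read_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file: ", path)
  pos <- 133L
  explicit <- TRUE
  ts <- "1.2.840.10008.1.2.1"
  elems <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8L <= length(raw)) {
    grp <- read_uint(raw[pos:(pos + 1)]); el <- read_uint(raw[(pos + 2):(pos + 3)])
    pos <- pos + 4L
    in_meta <- grp == 2L
    exp_here <- explicit || in_meta
    if (exp_here) {
      vr <- rawToChar(raw[pos:(pos + 1)])
      if (vr %in% long_vrs) {
        len <- read_uint(raw[(pos + 4):(pos + 7)]); pos <- pos + 8L
      } else {
        len <- read_uint(raw[(pos + 2):(pos + 3)]); pos <- pos + 4L
      }
    } else {
      vr <- ""
      len <- read_uint(raw[pos:(pos + 3)]); pos <- pos + 4L
    }
    if (len == 4294967295) stop("undefined-length DICOM elements unsupported")
    val <- if (len > 0) raw[pos:(pos + len - 1)] else raw(0)
    pos <- pos + len
    key <- sprintf("%04x,%04x", grp, el)
    elems[[key]] <- list(vr = vr, value = val)
    if (key == "0002,0010") {
      ts <- sub("\\s+$", "", rawToChar(val))
      explicit <- ts != "1.2.840.10008.1.2"
      if (!ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
        stop("unsupported transfer syntax: ", ts)
    }
  }
  elems
}

dicom_str <- function(elems, key, default = NULL) {
  e <- elems[[key]]
  if (is.null(e)) return(default)
  sub("\\s+$", "", rawToChar(e$value))
}
dicom_num <- function(elems, key, default = NULL) {
  s <- dicom_str(elems, key)
  if (is.null(s) || s == "") return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
dicom_us <- function(elems, key, default = NULL) {
  e <- elems[[key]]
  if (is.null(e)) return(default)
  read_uint(e$value[1:2])
}

read_dicom_series <- function(dir, kind = "other") {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("volume_not_found: empty DICOM directory ", dir)
  slices <- lapply(files, function(f) {
    e <- dicom_read_file(f)
    rows <- dicom_us(e, "0028,0010"); cols <- dicom_us(e, "0028,0011")
    bits <- dicom_us(e, "0028,0100", 16L)
    signed <- identical(dicom_us(e, "0028,0103", 0L), 1L)
    ps <- dicom_num(e, "0028,0030", c(1, 1))
    ipp <- dicom_num(e, "0020,0032", c(0, 0, 0))
    iop <- dicom_num(e, "0020,0037", c(1, 0, 0, 0, 1, 0))
    slope <- dicom_num(e, "0028,1053", 1)
    inter <- dicom_num(e, "0028,1052", 0)
    px <- e[["7fe0,0010"]]
    if (is.null(px)) stop("no PixelData in ", f)
    stopifnot(bits %in% c(8L, 16L))
    v <- if (bits == 16L) {
      readBin(px$value, "integer", n = rows * cols, size = 2,
              signed = signed, endian = "little")
    } else as.integer(px$value)
    if (bits == 16L && !signed) v[v < 0] <- v[v < 0] + 65536
    list(file = f, rows = rows, cols = cols, ps = ps, ipp = ipp, iop = iop,
         thick = dicom_num(e, "0018,0050", 1), data = v * slope + inter)
  })
  iop <- slices[[1]]$iop
  normal <- c(iop[2] * iop[6] - iop[3] * iop[5],
              iop[3] * iop[4] - iop[1] * iop[6],
              iop[1] * iop[5] - iop[2] * iop[4])
  z <- vapply(slices, function(s) sum(s$ipp * normal), 0)
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  if (length(slices) > 2) {
    dz <- diff(z)
    bad <- which(abs(dz - stats::median(dz)) > 1e-3 * max(1, abs(stats::median(dz))))
    if (length(bad) > 0)
      stop("inconsistent DICOM slice spacing at: ",
           paste(basename(vapply(slices[bad + 1], `[[`, "", "file")),
                 collapse = ", "))
  }
  rows <- slices[[1]]$rows; cols <- slices[[1]]$cols
  nz <- length(slices)
  arr <- array(0, c(cols, rows, nz))
  for (k in seq_len(nz)) {
    # DICOM pixel order: column index fastest within a row
    arr[, , k] <- matrix(slices[[k]]$data, nrow = cols, ncol = rows)
  }
  dz <- if (nz > 1) abs(z[2] - z[1]) else slices[[1]]$thick
  ps <- slices[[1]]$ps
  # PixelSpacing is (row spacing, column spacing): x = columns -> ps[2]
  vol <- vwi_volume(arr, c(ps[2], ps[1], dz), kind)
  attr(vol, "orientation") <- slices[[1]]$iop
  vol
}

# Internal: write a synthetic uncompressed explicit-VR-LE DICOM series.
# Used to build test fixtures programmatically; not a clinical exporter.
write_dicom_series <- function(vol, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vol$data)
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32r <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  elem <- function(grp, el, vr, value) {
    if (is.character(value)) {
      value <- charToRaw(value)
      if (length(value) %% 2 == 1) value <- c(value, charToRaw(" "))
    }
    hdr <- c(u16(grp), u16(el), charToRaw(vr))
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      c(hdr, as.raw(c(0, 0)), u32r(length(value)), value)
    } else c(hdr, u16(length(value)), value)
  }
  for (k in seq_len(d[3])) {
    sl <- vol$data[, , k]
    px <- writeBin(as.integer(round(pmax(0, pmin(65535, sl)))), raw(),
                   size = 2, endian = "little")
    meta <- c(elem(2L, 16L, "UI", "1.2.840.10008.1.2.1"))
    body <- c(
      elem(0x0008L, 0x0060L, "CS", "MR"),
      elem(0x0018L, 0x0050L, "DS", sprintf("%g", vol$spacing[3])),
      elem(0x0020L, 0x0032L, "DS",
           sprintf("%g\\%g\\%g", 0, 0, (k - 1) * vol$spacing[3])),
      elem(0x0020L, 0x0037L, "DS", "1\\0\\0\\0\\1\\0"),
      elem(0x0028L, 0x0002L, "US", u16(1L)),
      elem(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
      elem(0x0028L, 0x0010L, "US", u16(d[2])), # rows = y
      elem(0x0028L, 0x0011L, "US", u16(d[1])), # cols = x
      elem(0x0028L, 0x0030L, "DS",
           sprintf("%g\\%g", vol$spacing[2], vol$spacing[1])),
      elem(0x0028L, 0x0100L, "US", u16(16L)),
      elem(0x0028L, 0x0101L, "US", u16(16L)),
      elem(0x0028L, 0x0102L, "US", u16(15L)),
      elem(0x0028L, 0x0103L, "US", u16(0L)),
      elem(0x7fe0L, 0x0010L, "OW", px))
    con <- file(file.path(dir, sprintf("slice%03d.dcm", k)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
    close(con)
  }
  invisible(dir)
}

# ---------------------------------------------------------------------------
# Centerlines: JSON and VTK legacy polylines.

#' Write / read centerlines as JSON
#'
#' Each centerline is stored as its label, side, flags, bridged indices and
#' the list of `[x, y, z]` points in mm.
#'
#' @param lines List of [vwi_centerline].
#' @param path JSON file path.
#' @return `read_centerlines_json` returns the list of centerlines.
#' @export
write_centerlines_json <- function(lines, path) {
  payload <- lapply(lines, function(cl)
    list(label = cl$label, side = cl$side,
         bridged = as.integer(cl$bridged), flags = cl$flags,
         points_mm = unname(apply(cl$points, 1, as.numeric, simplify = FALSE))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_centerlines_json
#' @export
read_centerlines_json <- function(path) {
  payload <- jsonlite::read_json(path)
  lapply(payload, function(p)
    vwi_centerline(do.call(rbind, lapply(p$points_mm, unlist)),
                   p$label, p$side,
                   bridged = as.integer(unlist(p$bridged)),
                   flags = as.character(unlist(p$flags))))
}

#' Write / read centerlines as VTK legacy polylines
#'
#' ASCII VTK POLYDATA with one polyline per centerline and an integer cell
#' label index; labels/sides are recorded in a comment-compatible header
#' line.
#'
#' @param lines List of [vwi_centerline].
#' @param path `.vtk` file path.
#' @return `read_centerlines_vtk` returns the list of centerlines.
#' @export
write_centerlines_vtk <- function(lines, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# vtk DataFile Version 3.0", con)
  writeLines(paste0("vessel centerlines | ",
                    paste(vapply(lines, function(cl)
                      paste0(cl$label, "/", cl$side), ""), collapse = " ")),
             con)
  writeLines(c("ASCII", "DATASET POLYDATA"), con)
  npts <- sum(vapply(lines, function(cl) nrow(cl$points), 0L))
  writeLines(sprintf("POINTS %d float", npts), con)
  for (cl in lines)
    writeLines(apply(cl$points, 1, function(p)
      sprintf("%.6f %.6f %.6f", p[1], p[2], p[3])), con)
  writeLines(sprintf("LINES %d %d", length(lines),
                     length(lines) + npts), con)
  off <- 0L
  for (cl in lines) {
    n <- nrow(cl$points)
    writeLines(paste(c(n, off:(off + n - 1)), collapse = " "), con)
    off <- off + n
  }
  invisible(path)
}

#' @rdname write_centerlines_vtk
#' @export
read_centerlines_vtk <- function(path) {
  txt <- readLines(path)
  meta <- strsplit(sub("^vessel centerlines \\| ", "", txt[2]), " ")[[1]]
  ip <- grep("^POINTS", txt)
  npts <- as.integer(strsplit(txt[ip], " ")[[1]][2])
  pts <- do.call(rbind, lapply(txt[(ip + 1):(ip + npts)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  il <- grep("^LINES", txt)
  nl <- as.integer(strsplit(txt[il], " ")[[1]][2])
  out <- list()
  for (r in seq_len(nl)) {
    v <- as.integer(strsplit(trimws(txt[il + r]), "\\s+")[[1]])
    idx <- v[-1] + 1L
    ls <- strsplit(meta[r], "/")[[1]]
    out <- c(out, list(vwi_centerline(pts[idx, , drop = FALSE], ls[1], ls[2])))
  }
  out
}

# ---------------------------------------------------------------------------

#' Serialize / load a phantom spec as YAML
#'
#' @param spec A [phantom_spec()].
#' @param path YAML file path.
#' @return `read_phantom_spec` returns the [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  y <- list(grid_shape = spec$grid_shape, spacing_mm = spec$spacing_mm,
            noise_sigma = as.list(spec$noise_sigma),
            background_level = as.list(spec$background_level),
            lumen_level = as.list(spec$lumen_level),
            wall_level = as.list(spec$wall_level),
            seed = spec$seed,
            branches = lapply(spec$branches, function(br)
              list(label = br$label, side = br$side,
                   control_points = unname(apply(br$control_points, 1,
                                                 as.numeric, simplify = FALSE)),
                   radius_mm = br$radius_mm,
                   occlusion_span = br$occlusion_span)))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  y <- yaml::read_yaml(path)
  branches <- lapply(y$branches, function(b)
    vwi_branch(b$label, b$side,
               do.call(rbind, lapply(b$control_points, unlist)),
               unlist(b$radius_mm),
               occlusion_span = if (!is.null(b$occlusion_span))
                 unlist(b$occlusion_span)))
  phantom_spec(unlist(y$grid_shape), unlist(y$spacing_mm), branches,
               unlist(y$noise_sigma), unlist(y$background_level),
               unlist(y$lumen_level), unlist(y$wall_level), y$seed)
}

#' Write a CPR image as a windowed PNG preview (and optionally raw NIfTI)
#'
#' @param cpr A `vwi_cpr`.
#' @param path Output `.png` path.
#' @param window Intensity window `c(lo, hi)`; default the image range.
#' @return The path, invisibly.
#' @export
write_cpr_png <- function(cpr, path, window = NULL) {
  px <- cpr$pixels
  if (is.null(window)) window <- range(px)
  if (diff(window) <= 0) window <- window + c(0, 1)
  img <- pmin(pmax((px - window[1]) / diff(window), 0), 1)
  # rows = arc length (down the image), columns = cross-track
  png::writePNG(img, path)
  invisible(path)
}
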