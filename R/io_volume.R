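# Volume I/O: NIfTI via RNifti, DICOM series via a minimal built-in codec
# (explicit VR little endian, single-frame CT slices — the subset CBCT
# exports use). Everything is normalised to the LPS patient frame on load.

#' Read a CT volume
#'
#' Reads a NIfTI file or a DICOM series directory into a [ct_volume()] in the
#' LPS patient frame with intensities in Hounsfield units. NIfTI data (RAS
#' convention) are converted to LPS on load by flipping the first two axes as
#' needed; DICOM stored values are rescaled with the slope/intercept tags.
#'
#' @param path a `.nii`/`.nii.gz` file, a directory containing a DICOM
#'   series, or a single DICOM file.
#' @param format `"auto"` (default, sniffed from the path), `"nifti"` or
#'   `"dicom_series"`.
#' @return A [ct_volume()].
#' @details Only axis-aligned (non-oblique) orientations are supported.
#'   DICOM series must have consistent in-plane geometry and uniform slice
#'   spacing; a series lacking rescale tags is treated as already in HU with
#'   a warning, and a non-CT modality triggers a warning but is read anyway.
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom_series")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path) ||
                  grepl("\\.dcm$", path, ignore.case = TRUE))
      "dicom_series" else "nifti"
  }
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  switch(format,
         nifti = read_volume_nifti(path),
         dicom_series = read_volume_dicom(path))
}

#' Write a CT volume
#'
#' @param volume a [ct_volume()] (internally LPS).
#' @param path output file (NIfTI) or directory (DICOM series).
#' @param format `"nifti"` or `"dicom_series"`.
#' @param slope,intercept rescale applied when writing DICOM: stored value =
#'   (HU - intercept) / slope, recorded in the rescale tags.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = c("nifti", "dicom_series"),
                         slope = 1, intercept = -1024) {
  stopifnot(inherits(volume, "ct_volume"))
  format <- match.arg(format)
  switch(format,
         nifti = write_volume_nifti(volume, path),
         dicom_series = write_volume_dicom(volume, path, slope, intercept))
  invisible(path)
}

# ---- NIfTI -----------------------------------------------------------------

# NIfTI affines map 0-based indices to RAS. We write diag(-sx, -sy, sz) with
# translation (-ox, -oy, oz) so the array needs no flips, and on read we
# normalise arbitrary axis-aligned diagonal affines back to LPS.
write_volume_nifti <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  s <- volume$spacing
  o <- volume$origin
  if (volume$frame != "LPS")
    stop("internal volumes must be in the LPS frame", call. = FALSE)
  xf <- diag(c(-s[1], -s[2], s[3], 1))
  xf[1:3, 4] <- c(-o[1], -o[2], o[3])
  img <- RNifti::`qform<-`(img, structure(xf, code = 1L))
  img <- RNifti::`sform<-`(img, structure(xf, code = 1L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  data <- as.array(img)
  data <- array(as.vector(data), dim(data))  # drop RNifti attributes
  if (length(dim(data)) != 3)
    stop("expected a 3D NIfTI volume: ", path, call. = FALSE)
  xf <- unclass(RNifti::xform(img))
  A <- xf[1:3, 1:3]
  t_ras <- xf[1:3, 4]
  if (max(abs(A - diag(diag(A)))) > 1e-4 * max(abs(diag(A))))
    stop("oblique NIfTI orientations are not supported: ", path, call. = FALSE)
  d <- diag(A)
  eps_lps <- c(-1, -1, 1)           # RAS -> LPS sign per axis
  spacing <- abs(d)
  origin <- numeric(3)
  for (k in 1:3) {
    if (eps_lps[k] * d[k] > 0) {    # marching k already increases the LPS coord
      origin[k] <- eps_lps[k] * t_ras[k]
    } else {                        # flip the array along axis k
      n <- dim(data)[k]
      data <- flip_axis(data, k)
      origin[k] <- eps_lps[k] * (t_ras[k] + d[k] * (n - 1))
    }
  }
  ct_volume(data, spacing = spacing, origin = origin, frame = "LPS")
}

flip_axis <- function(a, axis) {
  idx <- lapply(dim(a), seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

#' Write / read a binary mask as NIfTI
#'
#' Masks are stored as 8-bit 0/1 volumes with the same geometry handling as
#' [write_volume()].
#'
#' @param mask a [ct_mask()].
#' @param path a `.nii`/`.nii.gz` file.
#' @return `read_mask()` returns a [ct_mask()]; `write_mask()` returns `path`
#'   invisibly.
#' @export
write_mask <- function(mask, path) {
  vol <- list(data = array(as.integer(mask$data), dim(mask$data)),
              spacing = mask$spacing, origin = mask$origin, frame = mask$frame)
  class(vol) <- "ct_volume"
  write_volume_nifti(vol, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  vol <- read_volume_nifti(path)
  ct_mask(vol$data > 0.5, spacing = vol$spacing, origin = vol$origin,
          frame = vol$frame)
}

# ---- minimal DICOM codec ---------------------------------------------------
# Explicit VR little endian, one single-frame CT image per file. This is the
# subset produced below and by typical CBCT exports; anything else errors.

dicom_uid_root <- "1.2.826.0.1.3680043.10.424."

dcm_element <- function(group, element, vr, value_raw) {
  hdr <- writeBin(c(as.integer(group), as.integer(element)), raw(),
                  size = 2, endian = "little")
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4, endian = "little"),
      value_raw)
  } else {
    c(hdr, charToRaw(vr),
      writeBin(as.integer(length(value_raw)), raw(), size = 2,
               endian = "little"),
      value_raw)
  }
}

dcm_str <- function(s, pad_null = FALSE) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1)
    r <- c(r, if (pad_null) as.raw(0) else charToRaw(" "))
  r
}

dcm_us <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")

write_dicom_slice <- function(path, slice, rows, cols, pos, pixel_spacing,
                              orientation, slope, intercept, instance,
                              series_uid, thickness) {
  ds <- c(
    dcm_element(0x0008, 0x0016, "UI", dcm_str("1.2.840.10008.5.1.4.1.1.2", pad_null = TRUE)),
    dcm_element(0x0008, 0x0018, "UI",
                dcm_str(paste0(dicom_uid_root, "1.", instance), pad_null = TRUE)),
    dcm_element(0x0008, 0x0060, "CS", dcm_str("CT")),
    dcm_element(0x0018, 0x0050, "DS", dcm_str(format(thickness, digits = 10))),
    dcm_element(0x0020, 0x000E, "UI", dcm_str(series_uid, pad_null = TRUE)),
    dcm_element(0x0020, 0x0013, "IS", dcm_str(as.character(instance))),
    dcm_element(0x0020, 0x0032, "DS",
                dcm_str(paste(format(pos, digits = 10), collapse = "\\"))),
    dcm_element(0x0020, 0x0037, "DS",
                dcm_str(paste(format(orientation, digits = 10), collapse = "\\"))),
    dcm_element(0x0028, 0x0002, "US", dcm_us(1)),
    dcm_element(0x0028, 0x0004, "CS", dcm_str("MONOCHROME2")),
    dcm_element(0x0028, 0x0010, "US", dcm_us(rows)),
    dcm_element(0x0028, 0x0011, "US", dcm_us(cols)),
    dcm_element(0x0028, 0x0030, "DS",
                dcm_str(paste(format(pixel_spacing, digits = 10), collapse = "\\"))),
    dcm_element(0x0028, 0x0100, "US", dcm_us(16)),
    dcm_element(0x0028, 0x0101, "US", dcm_us(16)),
    dcm_element(0x0028, 0x0102, "US", dcm_us(15)),
    dcm_element(0x0028, 0x0103, "US", dcm_us(1)),
    dcm_element(0x0028, 0x1052, "DS", dcm_str(format(intercept, digits = 10))),
    dcm_element(0x0028, 0x1053, "DS", dcm_str(format(slope, digits = 10))),
    dcm_element(0x7FE0, 0x0010, "OW",
                writeBin(as.integer(slice), raw(), size = 2, endian = "little"))
  )
  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI", dcm_str("1.2.840.10008.5.1.4.1.1.2", pad_null = TRUE)),
    dcm_element(0x0002, 0x0003, "UI",
                dcm_str(paste0(dicom_uid_root, "1.", instance), pad_null = TRUE)),
    dcm_element(0x0002, 0x0010, "UI", dcm_str("1.2.840.10008.1.2.1", pad_null = TRUE)),
    dcm_element(0x0002, 0x0012, "UI", dcm_str(paste0(dicom_uid_root, "0.1"), pad_null = TRUE))
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL",
                        writeBin(length(meta), raw(), size = 4,
                                 endian = "little")),
            meta)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

write_volume_dicom <- function(volume, dir, slope, intercept) {
  if (volume$frame != "LPS")
    stop("internal volumes must be in the LPS frame", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(volume$data)
  stored <- round((volume$data - intercept) / slope)
  if (min(stored) < -32768 || max(stored) > 32767)
    stop("HU range not representable with the given rescale slope/intercept",
         call. = FALSE)
  series_uid <- paste0(dicom_uid_root, "2.",
                       format(as.integer(d[1]) * 7919L + as.integer(d[3])))
  # DICOM row direction = +x (columns index x), column direction = +y;
  # PixelSpacing is (between-rows, between-columns) = (sy, sx).
  for (k in seq_len(d[3])) {
    pos <- volume$origin + c(0, 0, (k - 1) * volume$spacing[3])
    write_dicom_slice(
      file.path(dir, sprintf("slice_%04d.dcm", k)),
      slice = stored[, , k], rows = d[2], cols = d[1], pos = pos,
      pixel_spacing = c(volume$spacing[2], volume$spacing[1]),
      orientation = c(1, 0, 0, 0, 1, 0), slope = slope,
      intercept = intercept, instance = k, series_uid = series_uid,
      thickness = volume$spacing[3])
  }
  invisible(dir)
}

# Parse one explicit-VR-LE single-frame file; returns the tags we need.
read_dicom_file <- function(path) {
  bytes <- readBin(path, raw(), file.info(path)$size)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  pos <- 133L
  n <- length(bytes)
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  u16 <- function(i) readBin(bytes[i:(i + 1)], "integer", size = 2,
                             endian = "little", signed = FALSE)
  u32 <- function(i) readBin(bytes[i:(i + 3)], "integer", size = 4,
                             endian = "little")
  while (pos + 7 <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit VR or unsupported encoding in ", path, call. = FALSE)
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); data_start <- pos + 12L
    } else {
      len <- u16(pos + 6L); data_start <- pos + 8L
    }
    if (len < 0 || data_start + len - 1 > n)
      stop("truncated DICOM element in ", path, call. = FALSE)
    key <- sprintf("%04x,%04x", group, element)
    val_raw <- if (len > 0) bytes[data_start:(data_start + len - 1)] else raw(0)
    tags[[key]] <- list(vr = vr, raw = val_raw)
    pos <- data_start + len
  }
  tags
}

dcm_get_str <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$raw[el$raw != as.raw(0)]))
}

dcm_get_num <- function(tags, key) {
  s <- dcm_get_str(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_get_us <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  readBin(el$raw, "integer", size = 2, endian = "little", signed = FALSE)
}

read_volume_dicom <- function(path) {
  files <- if (dir.exists(path)) {
    list.files(path, full.names = TRUE,
               pattern = "\\.(dcm|DCM|ima|IMA)$")
  } else path
  if (length(files) == 0)
    files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0)
    stop("no DICOM files found in ", path, call. = FALSE)
  slices <- lapply(files, function(f) {
    tags <- tryCatch(read_dicom_file(f),
                     error = function(e)
                       stop("failed to read DICOM file ", f, ": ",
                            conditionMessage(e), call. = FALSE))
    modality <- dcm_get_str(tags, "0008,0060")
    rows <- dcm_get_us(tags, "0028,0010")
    cols <- dcm_get_us(tags, "0028,0011")
    ipp <- dcm_get_num(tags, "0020,0032")
    iop <- dcm_get_num(tags, "0020,0037")
    ps <- dcm_get_num(tags, "0028,0030")
    bits <- dcm_get_us(tags, "0028,0100")
    pixrep <- dcm_get_us(tags, "0028,0103")
    px <- tags[["7fe0,0010"]]
    if (is.null(rows) || is.null(cols) || is.null(ipp) || is.null(ps) ||
        is.null(px))
      stop("missing required DICOM tags in ", f, call. = FALSE)
    if (!is.null(bits) && bits != 16)
      stop("only 16-bit DICOM pixel data is supported: ", f, call. = FALSE)
    vals <- readBin(px$raw, "integer", n = rows * cols, size = 2,
                    endian = "little", signed = is.null(pixrep) || pixrep == 1)
    slope <- dcm_get_num(tags, "0028,1053")
    intercept <- dcm_get_num(tags, "0028,1052")
    list(file = f, modality = modality, rows = rows, cols = cols, ipp = ipp,
         iop = iop, ps = ps, vals = vals, slope = slope, intercept = intercept)
  })
  s1 <- slices[[1]]
  if (!is.null(s1$modality) && !identical(s1$modality, "CT"))
    warning("non-CT modality '", s1$modality, "' - reading anyway")
  if (!is.null(s1$iop) && max(abs(s1$iop - c(1, 0, 0, 0, 1, 0))) > 1e-6)
    stop("only axial identity orientation DICOM series are supported",
         call. = FALSE)
  for (s in slices[-1]) {
    if (s$rows != s1$rows || s$cols != s1$cols ||
        max(abs(s$ps - s1$ps)) > 1e-9)
      stop("inconsistent slice geometry in series (", s$file, ")",
           call. = FALSE)
  }
  z <- vapply(slices, function(s) s$ipp[3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  if (length(z) > 1) {
    dz <- diff(z)
    if (any(dz <= 0) || (max(dz) - min(dz)) > 1e-4 * mean(dz))
      stop("inconsistent slice spacing in series near ",
           slices[[which.max(abs(dz - mean(dz)))]]$file, call. = FALSE)
    sz <- mean(dz)
  } else sz <- 1
  no_rescale <- is.null(s1$slope) || is.null(s1$intercept)
  if (no_rescale)
    warning("rescale tags absent; treating stored values as HU")
  data <- array(0, dim = c(s1$cols, s1$rows, length(slices)))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    slope <- if (no_rescale) 1 else s$slope
    intercept <- if (no_rescale) 0 else s$intercept
    data[, , k] <- matrix(s$vals * slope + intercept, s1$cols, s1$rows)
  }
  ct_volume(data, spacing = c(s1$ps[2], s1$ps[1], sz),
            origin = slices[[1]]$ipp, frame = "LPS")
}
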