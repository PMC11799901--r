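# Minimal DICOM support for the three radiotherapy objects the pipeline
# consumes: CT image series, RTDOSE grids and RTSTRUCT contour sets.
# Reading handles explicit and implicit VR little endian (uncompressed);
# writing always emits explicit VR little endian.  Only the tags the
# pipeline needs are decoded; everything else is carried as raw bytes.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_ROOT <- "1.2.826.0.1.3680043.10.1337"
SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"
SOP_RTDOSE <- "1.2.840.10008.5.1.4.1.1.481.2"
SOP_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"

# VRs with the 4-byte length / 2-byte reserved header layout
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# implicit-VR dictionary for the tags this package decodes
DICOM_DICT <- c(
  "0008,0016" = "UI", "0008,0018" = "UI", "0008,0060" = "CS",
  "0020,000D" = "UI", "0020,000E" = "UI", "0020,0013" = "IS",
  "0020,0032" = "DS", "0020,0037" = "DS",
  "0028,0002" = "US", "0028,0004" = "CS", "0028,0008" = "IS",
  "0028,0010" = "US", "0028,0011" = "US", "0028,0030" = "DS",
  "0028,0100" = "US", "0028,0101" = "US", "0028,0102" = "US",
  "0028,0103" = "US", "0028,1052" = "DS", "0028,1053" = "DS",
  "3004,000C" = "DS", "3004,000E" = "DS",
  "3006,0020" = "SQ", "3006,0022" = "IS", "3006,0026" = "LO",
  "3006,0039" = "SQ", "3006,0040" = "SQ", "3006,0042" = "CS",
  "3006,0046" = "IS", "3006,0050" = "DS", "3006,0084" = "IS",
  "7FE0,0010" = "OW")

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_tag_key <- function(group, elem) sprintf("%04X,%04X", group, elem)

# serialize one data element (explicit VR LE)
dcm_element <- function(group, elem, vr, value) {
  if (vr == "SQ") {
    items <- lapply(value, function(it)
      c(u16le(0xFFFE), u16le(0xE000), u32le(length(it)), it))
    body <- do.call(c, c(items, list(raw(0))))
    return(c(u16le(group), u16le(elem), charToRaw("SQ"), as.raw(c(0, 0)),
             u32le(length(body)), body))
  }
  body <- if (vr %in% c("OB", "OW")) {
    as.raw(value)
  } else if (vr == "US") {
    writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else if (vr == "UL") {
    writeBin(as.integer(value), raw(), size = 4, endian = "little")
  } else {
    charToRaw(paste(as.character(value), collapse = "\\"))
  }
  if (length(body) %% 2 == 1)
    body <- c(body, if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" "))
  hdr <- if (vr %in% LONG_VRS)
    c(charToRaw(vr), as.raw(c(0, 0)), u32le(length(body)))
  else c(charToRaw(vr), u16le(length(body)))
  c(u16le(group), u16le(elem), hdr, body)
}

# serialize a full Part-10 file: preamble, DICM, file meta, dataset
dcm_file <- function(path, sop_class, sop_instance, dataset) {
  meta <- c(dcm_element(2L, 2L, "UI", sop_class),
            dcm_element(2L, 3L, "UI", sop_instance),
            dcm_element(2L, 0x10L, "UI", UID_EXPLICIT_LE))
  meta <- c(dcm_element(2L, 0L, "UL", length(meta)), meta)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, dataset), con)
  invisible(path)
}

r_u16 <- function(raw, pos)
  readBin(raw[pos:(pos + 1)], "integer", size = 2, signed = FALSE,
          endian = "little")
r_u32 <- function(raw, pos) {
  v <- readBin(raw[pos:(pos + 3)], "integer", size = 4, endian = "little")
  if (v < 0) v + 2^32 else v
}

# parse a dataset; returns list(elements = named list(vr, raw), pos).
# Stops at `end` or at an item/sequence delimiter (whose tag is consumed).
dcm_parse <- function(raw, pos, end, explicit) {
  out <- list()
  while (pos + 7 <= end + 1 && pos + 7 <= length(raw) + 1) {
    group <- r_u16(raw, pos); elem <- r_u16(raw, pos + 2)
    if (group == 0xFFFE && elem %in% c(0xE00D, 0xE0DD))
      return(list(elements = out, pos = pos + 8))
    key <- dcm_tag_key(group, elem)
    if (explicit) {
      vr <- rawToChar(raw[(pos + 4):(pos + 5)])
      if (vr %in% LONG_VRS) {
        len <- r_u32(raw, pos + 8); body_at <- pos + 12
      } else {
        len <- r_u16(raw, pos + 6); body_at <- pos + 8
      }
    } else {
      vr <- unname(DICOM_DICT[key]); if (is.na(vr)) vr <- "UN"
      len <- r_u32(raw, pos + 4); body_at <- pos + 8
    }
    if (len == 4294967295) {             # undefined length: SQ of items
      items <- list()
      pos <- body_at
      repeat {
        g2 <- r_u16(raw, pos); e2 <- r_u16(raw, pos + 2)
        if (g2 == 0xFFFE && e2 == 0xE0DD) { pos <- pos + 8; break }
        if (!(g2 == 0xFFFE && e2 == 0xE000)) stop("malformed sequence")
        il <- r_u32(raw, pos + 4)
        if (il == 4294967295) {
          it <- dcm_parse(raw, pos + 8, length(raw), explicit)
        } else {
          it <- dcm_parse(raw, pos + 8, pos + 7 + il, explicit)
          it$pos <- pos + 8 + il
        }
        items[[length(items) + 1]] <- it$elements
        pos <- it$pos
      }
      out[[key]] <- list(vr = "SQ", items = items)
    } else if (vr == "SQ") {
      items <- list()
      p2 <- body_at
      while (p2 < body_at + len) {
        il <- r_u32(raw, p2 + 4)
        it <- dcm_parse(raw, p2 + 8, p2 + 7 + il, explicit)
        items[[length(items) + 1]] <- it$elements
        p2 <- p2 + 8 + il
      }
      out[[key]] <- list(vr = "SQ", items = items)
      pos <- body_at + len
    } else {
      body <- if (len > 0) raw[body_at:(body_at + len - 1)] else raw(0)
      out[[key]] <- list(vr = vr, raw = body)
      pos <- body_at + len
    }
    if (!(len == 4294967295) && vr != "SQ") next
  }
  list(elements = out, pos = pos)
}

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop(sprintf("'%s' is not a DICOM Part-10 file", path))
  pos <- 133
  elements <- list()
  # parse file meta group (always explicit), remember where it ends
  repeat {
    group <- r_u16(raw, pos)
    if (group != 2) break
    one <- dcm_parse_one_len(raw, pos)
    elements[[one$key]] <- one$el
    pos <- one$pos
  }
  ts <- dcm_str(elements, "0002,0010")
  explicit <- !identical(ts, UID_IMPLICIT_LE)
  body <- dcm_parse(raw, pos, length(raw), explicit)
  c(elements, body$elements)
}

# parse exactly one explicit-VR element (used for the file meta group)
dcm_parse_one_len <- function(raw, pos) {
  group <- r_u16(raw, pos); elem <- r_u16(raw, pos + 2)
  vr <- rawToChar(raw[(pos + 4):(pos + 5)])
  if (vr %in% LONG_VRS) {
    len <- r_u32(raw, pos + 8); body_at <- pos + 12
  } else {
    len <- r_u16(raw, pos + 6); body_at <- pos + 8
  }
  body <- if (len > 0) raw[body_at:(body_at + len - 1)] else raw(0)
  list(key = dcm_tag_key(group, elem), el = list(vr = vr, raw = body),
       pos = body_at + len)
}

dcm_str <- function(ds, tag) {
  el <- ds[[tag]]
  if (is.null(el)) return(NULL)
  r <- el$raw
  while (length(r) > 0 && r[length(r)] %in% as.raw(c(0L, 32L)))
    r <- r[-length(r)]
  rawToChar(r)
}
dcm_num <- function(ds, tag) {
  s <- dcm_str(ds, tag)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
dcm_us <- function(ds, tag) {
  el <- ds[[tag]]
  if (is.null(el)) return(NULL)
  readBin(el$raw, "integer", n = length(el$raw) / 2, size = 2,
          signed = FALSE, endian = "little")
}

#' Write a synthetic CT series as DICOM files
#'
#' One explicit-VR little-endian file per slice.  HU are stored as unsigned
#' 16-bit with rescale slope 1 / intercept -1024, so values are quantized to
#' whole HU.
#'
#' @param x an `sct_volume` in HU.
#' @param dir output directory (created if needed).
#' @param series_uid DICOM series instance UID (deterministic default).
#' @return Character vector of file paths, invisibly.
#' @export
write_dicom_ct_series <- function(x, dir, series_uid = paste0(UID_ROOT, ".1.1")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(x$values)
  intercept <- -1024
  files <- character(d[3])
  for (k in seq_len(d[3]) - 1L) {
    ipp <- index_to_world(x, cbind(0, 0, k))[1, ]
    stored <- round(x$values[, , k + 1]) - intercept  # column index fastest
    stored <- pmin(pmax(stored, 0), 65535)
    pix <- writeBin(as.integer(stored), raw(), size = 2, endian = "little")
    sop <- paste0(series_uid, ".", k + 1)
    ds <- c(
      dcm_element(0x0008L, 0x0016L, "UI", SOP_CT),
      dcm_element(0x0008L, 0x0018L, "UI", sop),
      dcm_element(0x0008L, 0x0060L, "CS", "CT"),
      dcm_element(0x0020L, 0x000EL, "UI", series_uid),
      dcm_element(0x0020L, 0x0013L, "IS", k + 1),
      dcm_element(0x0020L, 0x0032L, "DS", sprintf("%.6f", ipp)),
      dcm_element(0x0020L, 0x0037L, "DS",
                  sprintf("%.9f", c(x$axes[, 1], x$axes[, 2]))),
      dcm_element(0x0028L, 0x0002L, "US", 1),
      dcm_element(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
      dcm_element(0x0028L, 0x0010L, "US", d[2]),   # rows
      dcm_element(0x0028L, 0x0011L, "US", d[1]),   # columns
      dcm_element(0x0028L, 0x0030L, "DS",
                  sprintf("%.6f", c(x$spacing[2], x$spacing[1]))),
      dcm_element(0x0028L, 0x0100L, "US", 16),
      dcm_element(0x0028L, 0x0101L, "US", 16),
      dcm_element(0x0028L, 0x0102L, "US", 15),
      dcm_element(0x0028L, 0x0103L, "US", 0),
      dcm_element(0x0028L, 0x1052L, "DS", sprintf("%d", intercept)),
      dcm_element(0x0028L, 0x1053L, "DS", "1"),
      dcm_element(0x7FE0L, 0x0010L, "OW", pix))
    f <- file.path(dir, sprintf("ct_%04d.dcm", k + 1))
    dcm_file(f, SOP_CT, sop, ds)
    files[k + 1] <- f
  }
  invisible(files)
}

#' Read a DICOM CT series as a volume in HU
#'
#' Applies the rescale slope/intercept and orders slices by their physical
#' position along the slice axis.  A directory holding more than one series,
#' inconsistent orientations, or non-uniform slice spacing (beyond 0.01 mm)
#' is rejected.
#'
#' @param directory path containing the `.dcm` files of one CT series.
#' @param frame_id frame label to assign to the volume.
#' @return An `sct_volume` in HU.
#' @export
read_dicom_ct_series <- function(directory, frame_id = "frame-0") {
  files <- list.files(directory, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0) stop("no .dcm files in ", directory)
  slices <- lapply(files, read_dicom_file)
  uids <- vapply(slices, dcm_str, "", tag = "0020,000E")
  if (length(unique(uids)) != 1)
    stop("mixed series in directory: ", paste(unique(uids), collapse = ", "))
  iops <- vapply(slices, dcm_num, numeric(6), tag = "0020,0037")
  if (max(apply(iops, 1, function(r) diff(range(r)))) > 1e-6)
    stop("inconsistent slice orientation within series")
  iop <- iops[, 1]
  col_dir <- iop[1:3]; row_dir <- iop[4:6]
  slice_dir <- c(col_dir[2] * row_dir[3] - col_dir[3] * row_dir[2],
                 col_dir[3] * row_dir[1] - col_dir[1] * row_dir[3],
                 col_dir[1] * row_dir[2] - col_dir[2] * row_dir[1])
  ipps <- t(vapply(slices, dcm_num, numeric(3), tag = "0020,0032"))
  z <- as.numeric(ipps %*% slice_dir)
  ord <- order(z)
  slices <- slices[ord]; ipps <- ipps[ord, , drop = FALSE]; z <- z[ord]
  gaps <- diff(z)
  if (length(gaps) > 0 && diff(range(gaps)) > 0.01)
    stop(sprintf("non-uniform slice spacing: gaps range %.4f-%.4f mm",
                 min(gaps), max(gaps)))
  dz <- if (length(gaps) > 0) mean(gaps) else 1
  s1 <- slices[[1]]
  rows <- dcm_us(s1, "0028,0010"); cols <- dcm_us(s1, "0028,0011")
  ps <- dcm_num(s1, "0028,0030")  # (row spacing, column spacing)
  vals <- array(0, c(cols, rows, length(slices)))
  for (k in seq_along(slices)) {
    sk <- slices[[k]]
    slope <- dcm_num(sk, "0028,1053") %||% 1
    inter <- dcm_num(sk, "0028,1052") %||% 0
    signed <- isTRUE((dcm_us(sk, "0028,0103") %||% 0) == 1)
    stored <- readBin(sk[["7FE0,0010"]]$raw, "integer", n = rows * cols,
                      size = 2, signed = signed, endian = "little")
    vals[, , k] <- array(stored, c(cols, rows)) * slope + inter
  }
  volume(vals, ipps[1, ], c(ps[2], ps[1], dz),
         cbind(col_dir, row_dir, slice_dir), frame_id)
}

#' Write / read an RTDOSE grid
#'
#' Dose is stored as unsigned 32-bit integers times `DoseGridScaling`;
#' reading reconstructs Gy and the geometry from the per-frame offset
#' vector.  Non-uniform frame offsets or a missing scaling tag are rejected.
#'
#' @param x an `sct_volume` in Gy.
#' @param file output path.
#' @param scaling Gy per stored unit; defaults to `max(dose) / 2^30`.
#' @return `file`, invisibly.
#' @export
write_rtdose <- function(x, file, scaling = NULL) {
  d <- dim(x$values)
  if (is.null(scaling)) {
    mx <- max(x$values)
    scaling <- if (mx > 0) mx / 2^30 else 1e-7
  }
  stored <- round(x$values / scaling)
  # within a frame pixels are stored row by row, column index fastest,
  # which matches the array's first index
  pix <- writeBin(as.integer(stored), raw(), size = 4, endian = "little")
  ipp <- index_to_world(x, cbind(0, 0, 0))[1, ]
  offs <- (seq_len(d[3]) - 1) * x$spacing[3]
  sop <- paste0(UID_ROOT, ".2.1")
  ds <- c(
    dcm_element(0x0008L, 0x0016L, "UI", SOP_RTDOSE),
    dcm_element(0x0008L, 0x0018L, "UI", sop),
    dcm_element(0x0008L, 0x0060L, "CS", "RTDOSE"),
    dcm_element(0x0020L, 0x0032L, "DS", sprintf("%.6f", ipp)),
    dcm_element(0x0020L, 0x0037L, "DS",
                sprintf("%.9f", c(x$axes[, 1], x$axes[, 2]))),
    dcm_element(0x0028L, 0x0002L, "US", 1),
    dcm_element(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
    dcm_element(0x0028L, 0x0008L, "IS", d[3]),
    dcm_element(0x0028L, 0x0010L, "US", d[2]),
    dcm_element(0x0028L, 0x0011L, "US", d[1]),
    dcm_element(0x0028L, 0x0030L, "DS",
                sprintf("%.6f", c(x$spacing[2], x$spacing[1]))),
    dcm_element(0x0028L, 0x0100L, "US", 32),
    dcm_element(0x0028L, 0x0103L, "US", 0),
    dcm_element(0x3004L, 0x000CL, "DS", sprintf("%.6f", offs)),
    dcm_element(0x3004L, 0x000EL, "DS", sprintf("%.10e", scaling)),
    dcm_element(0x7FE0L, 0x0010L, "OW", pix))
  dcm_file(file, SOP_RTDOSE, sop, ds)
  invisible(file)
}

#' @rdname write_rtdose
#' @param frame_id frame label for the returned volume.
#' @export
read_rtdose <- function(file, frame_id = "frame-0") {
  ds <- read_dicom_file(file)
  scaling <- dcm_num(ds, "3004,000E")
  if (is.null(scaling)) stop("RTDOSE without DoseGridScaling tag")
  offs <- dcm_num(ds, "3004,000C")
  if (length(offs) > 2 && diff(range(diff(offs))) > 0.01)
    stop("non-uniform dose grid frame offsets")
  rows <- dcm_us(ds, "0028,0010"); cols <- dcm_us(ds, "0028,0011")
  nfr <- length(offs)
  iop <- dcm_num(ds, "0020,0037")
  col_dir <- iop[1:3]; row_dir <- iop[4:6]
  slice_dir <- c(col_dir[2] * row_dir[3] - col_dir[3] * row_dir[2],
                 col_dir[3] * row_dir[1] - col_dir[1] * row_dir[3],
                 col_dir[1] * row_dir[2] - col_dir[2] * row_dir[1])
  ps <- dcm_num(ds, "0028,0030")
  dz <- if (nfr > 1) mean(diff(offs)) else 1
  stored <- readBin(ds[["7FE0,0010"]]$raw, "integer", n = rows * cols * nfr,
                    size = 4, endian = "little")
  stored[stored < 0] <- stored[stored < 0] + 2^32
  # within a frame pixels are stored row by row, column index fastest
  vals <- array(stored, c(cols, rows, nfr))
  volume(vals * scaling, dcm_num(ds, "0020,0032"), c(ps[2], ps[1], dz),
         cbind(col_dir, row_dir, slice_dir), frame_id)
}

#' Write a synthetic RTSTRUCT file from planar contours
#'
#' Fixture/export writer for contour sets (synthetic data only; clinical
#' RTSTRUCT export is out of scope).  Each structure is a list of closed
#' planar contours, each an n x 3 matrix of world coordinates in mm.
#'
#' @param structures named list; element = list of n x 3 contour matrices.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_rtstruct_synthetic <- function(structures, file) {
  sop <- paste0(UID_ROOT, ".3.1")
  roi_items <- lapply(seq_along(structures), function(i)
    c(dcm_element(0x3006L, 0x0022L, "IS", i),
      dcm_element(0x3006L, 0x0026L, "LO", names(structures)[i])))
  contour_items <- lapply(seq_along(structures), function(i) {
    cs <- lapply(structures[[i]], function(pts)
      c(dcm_element(0x3006L, 0x0042L, "CS", "CLOSED_PLANAR"),
        dcm_element(0x3006L, 0x0046L, "IS", nrow(pts)),
        dcm_element(0x3006L, 0x0050L, "DS",
                    sprintf("%.6f", as.vector(t(pts))))))
    c(dcm_element(0x3006L, 0x0040L, "SQ", cs),
      dcm_element(0x3006L, 0x0084L, "IS", i))
  })
  ds <- c(
    dcm_element(0x0008L, 0x0016L, "UI", SOP_RTSTRUCT),
    dcm_element(0x0008L, 0x0018L, "UI", sop),
    dcm_element(0x0008L, 0x0060L, "CS", "RTSTRUCT"),
    dcm_element(0x3006L, 0x0020L, "SQ", roi_items),
    dcm_element(0x3006L, 0x0039L, "SQ", contour_items))
  dcm_file(file, SOP_RTSTRUCT, sop, ds)
  invisible(file)
}

# even-odd point-in-polygon on all voxel centers of one slice (index coords)
rasterize_polygon <- function(px, py, nx, ny) {
  inside <- matrix(FALSE, nx, ny)
  cx <- seq_len(nx) - 1
  cy <- seq_len(ny) - 1
  n <- length(px)
  jprev <- n
  for (e in seq_len(n)) {
    x1 <- px[jprev]; y1 <- py[jprev]; x2 <- px[e]; y2 <- py[e]
    jprev <- e
    ycross <- (y1 > cy) != (y2 > cy)
    if (!any(ycross)) next
    xs <- x1 + (x2 - x1) * (cy - y1) / (y2 - y1)
    for (j in which(ycross)) {
      hit <- cx < xs[j]
      inside[hit, j] <- !inside[hit, j]
    }
  }
  inside
}

#' Rasterize an RTSTRUCT contour set onto a volume grid
#'
#' A voxel belongs to a structure iff its center lies inside the contour
#' polygon on its slice (even-odd rule).  Contours lying on slices not
#' present in the grid are skipped with a warning.
#'
#' @param file RTSTRUCT DICOM path.
#' @param grid an `sct_volume` defining the target geometry.
#' @return Named list of [structure_mask()] objects (source `"contour"`).
#' @export
rasterize_rtstruct <- function(file, grid) {
  ds <- read_dicom_file(file)
  rois <- ds[["3006,0020"]]$items
  if (is.null(rois)) stop("no StructureSetROISequence in ", file)
  names_by_num <- list()
  for (it in rois)
    names_by_num[[dcm_str(it, "3006,0022")]] <- dcm_str(it, "3006,0026")
  d <- dim(grid$values)
  out <- list()
  for (it in ds[["3006,0039"]]$items) {
    num <- dcm_str(it, "3006,0084")
    nm <- names_by_num[[num]] %||% paste0("ROI-", num)
    acc <- array(FALSE, d)
    for (ct in (it[["3006,0040"]]$items %||% list())) {
      pts <- matrix(dcm_num(ct, "3006,0050"), ncol = 3, byrow = TRUE)
      idx <- world_to_index(grid, pts)
      k <- round(mean(idx[, 3]))
      if (max(abs(idx[, 3] - k)) > 0.01)
        stop("contour not planar in the grid's slice direction")
      if (k < 0 || k > d[3] - 1) {
        warning(sprintf("contour of '%s' on slice z-index %g outside grid; skipped",
                        nm, k))
        next
      }
      sl <- rasterize_polygon(idx[, 1], idx[, 2], d[1], d[2])
      acc[, , k + 1] <- xor(acc[, , k + 1], sl)
    }
    m <- structure_mask(nm, acc, volume_geometry(grid), source = "contour")
    if (m$empty) warning(sprintf("structure '%s' rasterized to an empty mask", nm))
    out[[nm]] <- m
  }
  out
}
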