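#' Write / read a volume as NIfTI plus a JSON geometry sidecar
#'
#' NIfTI is the canonical on-disk format for synthetic volumes and masks.
#' The JSON sidecar (`<file>.json`) is the authoritative record of the
#' geometry (origin, spacing, axes, frame_id) plus any extra metadata such
#' as the prescription; the NIfTI header carries an equivalent affine for
#' interoperability with external viewers.
#'
#' @param x an `sct_volume`.
#' @param file output path, conventionally ending in `.nii` or `.nii.gz`.
#' @param meta optional named list of extra metadata stored in the sidecar.
#' @return `file`, invisibly.
#' @export
write_volume <- function(x, file, meta = list()) {
  img <- RNifti::asNifti(x$values)
  aff <- rbind(cbind(x$axes %*% diag(x$spacing), x$origin), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, file, datatype = "double")
  side <- c(list(origin = x$origin, spacing = x$spacing,
                 axes = as.numeric(x$axes), frame_id = x$frame_id), meta)
  jsonlite::write_json(side, sidecar_path(file), digits = NA,
                       auto_unbox = TRUE)
  invisible(file)
}

sidecar_path <- function(file) {
  base <- sub("\\.nii(\\.gz)?$", "", file)
  paste0(base, ".json")
}

#' @rdname write_volume
#' @export
read_volume <- function(file) {
  img <- RNifti::readNifti(file)
  vals <- array(as.numeric(img), dim = dim(img))
  sp <- sidecar_path(file)
  if (file.exists(sp)) {
    side <- jsonlite::read_json(sp, simplifyVector = TRUE)
    v <- volume(vals, side$origin, side$spacing,
                matrix(side$axes, 3, 3), side$frame_id)
    attr(v, "meta") <- side[setdiff(names(side),
                                    c("origin", "spacing", "axes", "frame_id"))]
    v
  } else {
    aff <- RNifti::xform(img)
    sp3 <- sqrt(colSums(aff[1:3, 1:3]^2))
    volume(vals, aff[1:3, 4], sp3, sweep(aff[1:3, 1:3], 2, sp3, "/"))
  }
}

#' Write / read a structure mask as NIfTI (0/1) plus sidecar
#'
#' @param mask an `sct_mask`.
#' @param file output path.
#' @export
write_mask <- function(mask, file) {
  v <- volume(array(as.numeric(mask$mask), dim(mask$mask)),
              mask$geometry$origin, mask$geometry$spacing,
              mask$geometry$axes, mask$geometry$frame_id)
  write_volume(v, file, meta = list(structure = mask$name,
                                    source = mask$source))
  invisible(file)
}

#' @rdname write_mask
#' @export
read_mask <- function(file) {
  v <- read_volume(file)
  meta <- attr(v, "meta")
  structure_mask(meta$structure %||% "structure", v$values > 0.5,
                 volume_geometry(v), meta$source %||% "synthetic")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
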