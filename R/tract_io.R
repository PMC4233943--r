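# I/O: TCK (MRtrix) and TRK (TrackVis) tractograms, NIfTI volumes via
# RNifti, FSL bval/bvec gradient tables.

#' Tractogram container
#'
#' A list of streamlines (polylines in world mm), optional per-streamline
#' weights, and the reference affine of the space they live in.
#'
#' @param streamlines list of n x 3 matrices (world mm).
#' @param weights optional numeric vector, one weight per streamline.
#' @param affine optional 4x4 reference voxel-to-world transform.
#' @return An object of class `tractogram`.
#' @export
tractogram <- function(streamlines, weights = NULL, affine = NULL) {
  streamlines <- lapply(streamlines, as_point_matrix)
  for (s in streamlines) {
    if (nrow(s) < 2) stop("each streamline needs >= 2 points")
    if (any(rowSums(diff(s)^2) == 0))
      stop("consecutive streamline points must be distinct")
  }
  if (!is.null(weights) && length(weights) != length(streamlines))
    stop("one weight per streamline required")
  structure(list(streamlines = streamlines, weights = weights,
                 affine = affine),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  np <- vapply(x$streamlines, nrow, 0L)
  cat("Tractogram:", length(x$streamlines), "streamlines")
  if (length(np)) cat(" (", min(np), "-", max(np), " points)", sep = "")
  cat(if (is.null(x$weights)) ", unweighted\n" else ", weighted\n")
  invisible(x)
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

# ---------------------------------------------------------------------------
# TCK (MRtrix): text header, Float32LE triplets, NaN-separated, Inf-ended.
# Coordinates are world (scanner) mm.
# ---------------------------------------------------------------------------

write_tck <- function(tract, path) {
  n <- length(tract$streamlines)
  header_of <- function(offset) {
    paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ", n,
           "\nfile: . ", offset, "\nEND\n")
  }
  # fixed-point iteration on the offset digits
  offset <- nchar(header_of(0))
  offset <- nchar(header_of(offset))
  offset <- nchar(header_of(offset))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header_of(offset), con, eos = NULL)
  for (s in tract$streamlines) {
    writeBin(as.vector(t(s)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

read_tck <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  end_pat <- charToRaw("\nEND\n")
  hdr_end <- NA_integer_
  limit <- min(length(raw), 65536)
  for (i in seq_len(limit - length(end_pat) + 1)) {
    if (identical(raw[i:(i + 4)], end_pat)) { hdr_end <- i + 4; break }
  }
  if (is.na(hdr_end)) stop("malformed TCK header: no END marker")
  hdr <- strsplit(rawToChar(raw[1:hdr_end]), "\n")[[1]]
  if (hdr[1] != "mrtrix tracks")
    stop("malformed TCK header: missing 'mrtrix tracks' magic line")
  kv <- hdr[grepl(":", hdr, fixed = TRUE)]
  keys <- sub(":.*", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  dtype <- vals[match("datatype", keys)]
  if (is.na(dtype) || !dtype %in% c("Float32LE", "Float32BE"))
    stop("malformed TCK header: unsupported or missing 'datatype'")
  fl <- vals[match("file", keys)]
  if (is.na(fl)) stop("malformed TCK header: missing 'file' field")
  offset <- as.integer(sub("^\\.\\s*", "", fl))
  if (is.na(offset)) stop("malformed TCK header: unparseable 'file' offset")
  endian <- if (dtype == "Float32LE") "little" else "big"
  nfloat <- (length(raw) - offset) %/% 4
  v <- readBin(raw[(offset + 1):length(raw)], "double", n = nfloat, size = 4,
               endian = endian)
  pts <- matrix(v, ncol = 3, byrow = TRUE)
  streamlines <- list()
  cur <- 1
  for (j in seq_len(nrow(pts))) {
    if (all(is.infinite(pts[j, ]))) break
    if (all(is.nan(pts[j, ]))) {
      if (j > cur)
        streamlines[[length(streamlines) + 1]] <- pts[cur:(j - 1), ,
                                                      drop = FALSE]
      cur <- j + 1
    }
  }
  tractogram(streamlines)
}

# ---------------------------------------------------------------------------
# TRK (TrackVis): 1000-byte binary header (version 2), points stored in
# "voxmm" coordinates (voxel index + 0.5, scaled by voxel size).
# ---------------------------------------------------------------------------

write_trk <- function(tract, path, affine, voxel_size, dims) {
  inv <- solve(affine)
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s, width) {
    r <- charToRaw(s)
    writeBin(c(r, raw(width - length(r))), con)
  }
  wchar("TRACK", 6)
  writeBin(as.integer(dims), con, size = 2, endian = "little")
  writeBin(as.numeric(voxel_size), con, size = 4, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")     # origin
  writeBin(0L, con, size = 2, endian = "little")             # n_scalars
  writeBin(raw(200), con)
  writeBin(0L, con, size = 2, endian = "little")             # n_properties
  writeBin(raw(200), con)
  writeBin(as.numeric(t(affine)), con, size = 4, endian = "little")
  writeBin(raw(444), con)
  wchar("RAS", 4)                                            # voxel_order
  writeBin(raw(4), con)                                      # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4, endian = "little")
  writeBin(raw(2), con)                                      # pad1
  writeBin(raw(6), con)                                      # invert/swap
  writeBin(length(tract$streamlines), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")             # version
  writeBin(1000L, con, size = 4, endian = "little")          # hdr_size
  for (s in tract$streamlines) {
    vox <- cbind(s, 1) %*% t(inv)
    voxmm <- sweep(vox[, 1:3, drop = FALSE] + 0.5, 2, voxel_size, `*`)
    writeBin(nrow(s), con, size = 4, endian = "little")
    writeBin(as.vector(t(voxmm)), con, size = 4, endian = "little")
  }
  invisible(path)
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (rawToChar(magic[1:5]) != "TRACK")
    stop("malformed TRK header: bad magic 'id_string'")
  dims <- readBin(con, "integer", 3, size = 2, endian = "little")
  voxel_size <- readBin(con, "double", 3, size = 4, endian = "little")
  readBin(con, "double", 3, size = 4, endian = "little")     # origin
  n_scalars <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "raw", 200)
  n_props <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "raw", 200)
  affine <- matrix(readBin(con, "double", 16, size = 4, endian = "little"),
                   4, 4, byrow = TRUE)
  readBin(con, "raw", 444 + 4 + 4 + 24 + 2 + 6)
  n_count <- readBin(con, "integer", 1, size = 4, endian = "little")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (hdr_size != 1000)
    stop("malformed TRK header: 'hdr_size' is ", hdr_size, ", expected 1000")
  if (version == 2 && all(affine == 0))
    stop("malformed TRK header: zero 'vox_to_ras' matrix")
  if (version < 2) affine <- diag(c(voxel_size, 1))
  streamlines <- list()
  repeat {
    np <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(np) == 0) break
    v <- readBin(con, "double", np * (3 + n_scalars), size = 4,
                 endian = "little")
    if (n_props > 0) readBin(con, "double", n_props, size = 4,
                             endian = "little")
    m <- matrix(v, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(m, 2, voxel_size, `/`) - 0.5
    world <- cbind(vox, 1) %*% t(affine)
    streamlines[[length(streamlines) + 1]] <- world[, 1:3, drop = FALSE]
  }
  if (n_count > 0 && length(streamlines) != n_count)
    warning("TRK 'n_count' (", n_count, ") does not match streamlines read (",
            length(streamlines), ")")
  tractogram(streamlines, affine = affine)
}

weights_sidecar <- function(path) {
  paste0(sub("\\.(tck|trk)$", "", path, ignore.case = TRUE), "_weights.txt")
}

#' Read a tractogram (TCK or TRK)
#'
#' Streamline coordinates are returned in world mm regardless of the on-disk
#' convention (TRK stores voxel-mm, TCK world mm). If a `*_weights.txt`
#' sidecar (one float per line, same order) exists next to the file it is
#' loaded as per-streamline weights.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format "tck" or "trk".
#' @return A [tractogram()].
#' @export
read_tractogram <- function(path, format = c("auto", "tck", "trk")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- tolower(sub(".*\\.", "", path))
  if (!file.exists(path)) stop("file not found: ", path)
  out <- switch(format,
                tck = read_tck(path),
                trk = read_trk(path),
                stop("unsupported tractogram format: ", format))
  wpath <- weights_sidecar(path)
  if (file.exists(wpath)) {
    w <- scan(wpath, quiet = TRUE)
    if (length(w) == length(out$streamlines)) out$weights <- w
    else warning("weights sidecar length mismatch; ignored")
  }
  out
}

#' Write a tractogram (TCK or TRK)
#'
#' TRK needs the reference grid geometry (affine, voxel size, dims), taken
#' from `reference` (a [tissue_model()] or [attenuation_volume()]) or from
#' the tractogram's own affine. Weights, if present, are written to a
#' `*_weights.txt` sidecar.
#'
#' @param tract a [tractogram()].
#' @param path output path (.tck or .trk).
#' @param reference optional grid reference for TRK.
#' @param format "tck" or "trk" (default from extension).
#' @return The path, invisibly.
#' @export
write_tractogram <- function(tract, path, reference = NULL,
                             format = c("auto", "tck", "trk")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- tolower(sub(".*\\.", "", path))
  if (format == "tck") {
    write_tck(tract, path)
  } else if (format == "trk") {
    if (!is.null(reference)) {
      g <- grid_geometry(reference)
      affine <- g$affine; dims <- g$dims
      voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
    } else if (!is.null(tract$affine)) {
      affine <- tract$affine
      voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
      dims <- c(0L, 0L, 0L)
    } else stop("TRK output needs a grid reference")
    write_trk(tract, path, affine, voxel_size, dims)
  } else stop("unsupported tractogram format: ", format)
  if (!is.null(tract$weights))
    writeLines(format(tract$weights, digits = 17), weights_sidecar(path))
  invisible(path)
}

# ---------------------------------------------------------------------------
# NIfTI volumes and FSL gradient tables
# ---------------------------------------------------------------------------

#' Write a volume as NIfTI-1
#'
#' @param arr 3D or 4D array.
#' @param affine 4x4 voxel-to-world transform (stored as sform/qform).
#' @param path output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
write_nifti_vol <- function(arr, affine, path) {
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume and its affine
#'
#' @param path NIfTI file.
#' @return list with `data` (array) and `affine` (4x4, voxel-to-world,
#'   0-based indices).
#' @export
read_nifti_vol <- function(path) {
  img <- RNifti::readNifti(path)
  affine <- RNifti::xform(img, useQuaternionFirst = FALSE)
  list(data = as.array(img), affine = matrix(as.numeric(affine), 4, 4))
}

#' Read a diffusion acquisition into an attenuation volume
#'
#' S0 is the mean over all b0 volumes; every measurement is divided
#' voxelwise by S0. Voxels with S0 <= 0 get attenuation 0 and are excluded
#' from the validity mask (and hence from the energy).
#'
#' @param nifti_path 4D NIfTI of diffusion-weighted signals.
#' @param bval_path,bvec_path FSL-style gradient table.
#' @param b0_threshold b-values at or below this count as b0.
#' @return An [attenuation_volume()].
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path, b0_threshold = 10) {
  vol <- read_nifti_vol(nifti_path)
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- as.matrix(read.table(bvec_path))
  if (nrow(bvecs) == 3) bvecs <- t(bvecs)
  if (length(bvals) != dim(vol$data)[4] || nrow(bvecs) != length(bvals))
    stop("bval/bvec entries must match the 4th NIfTI dimension")
  scheme <- gradient_scheme(bvecs, bvals, b0_threshold)
  if (!any(scheme$b0_mask)) stop("no b0 volume present: cannot normalize")
  b0 <- vol$data[, , , scheme$b0_mask, drop = FALSE]
  S0 <- apply(b0, 1:3, mean)
  ok <- S0 > 0
  atten <- vol$data
  for (g in seq_len(dim(atten)[4])) {
    sl <- atten[, , , g]
    sl[ok] <- sl[ok] / S0[ok]
    sl[!ok] <- 0
    atten[, , , g] <- pmax(sl, 0)
  }
  attenuation_volume(atten, scheme, vol$affine, mask = ok)
}

#' Write an attenuation volume as a diffusion acquisition
#'
#' Inverse of [read_dwi()]: scales attenuations by a nominal S0 of 1000 and
#' writes the 4D NIfTI plus FSL bval/bvec files.
#'
#' @param vol an [attenuation_volume()].
#' @param prefix output prefix; writes `<prefix>.nii.gz`, `<prefix>.bval`,
#'   `<prefix>.bvec`.
#' @param s0 nominal non-weighted signal (default 1000).
#' @return The NIfTI path, invisibly.
#' @export
write_dwi <- function(vol, prefix, s0 = 1000) {
  path <- paste0(prefix, ".nii.gz")
  write_nifti_vol(vol$data * s0, vol$affine, path)
  writeLines(paste(format(vol$scheme$bvalues, trim = TRUE), collapse = " "),
             paste0(prefix, ".bval"))
  bv <- t(vol$scheme$directions)
  writeLines(apply(bv, 1, function(r)
    paste(format(r, digits = 10, trim = TRUE), collapse = " ")),
    paste0(prefix, ".bvec"))
  invisible(path)
}

#' Write a phantom dataset to disk
#'
#' Writes the simulated acquisition (NIfTI + bval/bvec), the tissue volumes,
#' the ground-truth centerlines as TCK, and a JSON manifest of region pairs
#' and generating weights.
#'
#' @param phantom output of [generate_phantom()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dwi(phantom$dwi, file.path(dir, "dwi"))
  write_nifti_vol(phantom$tissue$gm_labels, phantom$tissue$affine,
                  file.path(dir, "gm_labels.nii.gz"))
  write_nifti_vol(phantom$tissue$wm_mask * 1L, phantom$tissue$affine,
                  file.path(dir, "wm_mask.nii.gz"))
  write_tractogram(tractogram(phantom$truth$centerlines),
                   file.path(dir, "truth_bundles.tck"))
  manifest <- list(
    pairs = phantom$truth$pairs,
    weights = phantom$truth$weights,
    roi_centers = phantom$truth$roi_centers,
    n_rois = phantom$truth$n_rois,
    snr = phantom$spec$snr,
    bvalue = phantom$spec$bvalue,
    seed = phantom$spec$seed)
  jsonlite::write_json(manifest, file.path(dir, "truth_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
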