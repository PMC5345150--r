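# Volume, tensor and gradient-table I/O (NIfTI, TIFF stacks, FSL dialect).

#' Read a 3D/4D volume from NIfTI or a multi-page TIFF stack
#'
#' @param path file path; .nii/.nii.gz are read with RNifti, .tif/.tiff as
#'   a page-per-slice stack.
#' @return list with \code{data} (array) and \code{voxelSize} (micrometres;
#'   NIfTI pixdim is interpreted as mm and converted, TIFF has no scale and
#'   returns NA).
#' @export
readVolume <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    data <- array(unlist(pages), c(dim(pages[[1]])[1:2], length(pages)))
    return(list(data = data, voxelSize = NA_real_))
  }
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)),
       voxelSize = RNifti::pixdim(img)[1] * 1000)
}

#' Write a 3D/4D volume
#'
#' @param data numeric array.
#' @param path output path (.nii/.nii.gz or .tif).
#' @param voxelSize isotropic voxel size in micrometres (NIfTI only).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(data, path, voxelSize = 1) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    rng <- range(data, finite = TRUE)
    scaled <- if (diff(rng) > 0) (data - rng[1]) / diff(rng) else data * 0
    pages <- lapply(seq_len(dim(data)[3]), function(z) scaled[, , z])
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    return(invisible(path))
  }
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- rep(voxelSize / 1000, min(3L, length(dim(data))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a tensor field as 4D NIfTI plus JSON metadata
#'
#' Elements are stored along the fourth dimension in lower-triangular
#' (xx, xy, yy, xz, yz, zz) order; the sidecar records the order, voxel
#' size and provenance.
#'
#' @param tf a [TensorField-class].
#' @param path output .nii/.nii.gz path; the sidecar replaces the
#'   extension with .json.
#' @return \code{path}, invisibly.
#' @export
writeTensorField <- function(tf, path) {
  stopifnot(is(tf, "TensorField"))
  writeVolume(tf@elements, path, tf@voxelSize)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(order = c("xx", "xy", "yy", "xz", "yz", "zz"),
                            voxelSizeUm = tf@voxelSize,
                            provenance = tf@provenance),
                       side, auto_unbox = TRUE)
  invisible(path)
}

#' Read a tensor field written by [writeTensorField()]
#'
#' @param path the .nii/.nii.gz path.
#' @return A [TensorField-class].
#' @export
readTensorField <- function(path) {
  v <- readVolume(path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  .tensorField(v$data, meta$voxelSizeUm, meta$provenance)
}

#' Write FSL-style bval/bvec text files
#'
#' One row of b-values; three rows of direction components. b = 0 entries
#' precede the weighted directions, matching the volume order produced by
#' [simulateDwi()].
#'
#' @param protocol a [DwiProtocol-class].
#' @param basePath path prefix; writes basePath.bval and basePath.bvec.
#' @return character(2) of the written paths, invisibly.
#' @export
writeBvalBvec <- function(protocol, basePath) {
  stopifnot(is(protocol, "DwiProtocol"))
  bvals <- c(rep(0, protocol@nB0),
             rep(protocol@bValue, nrow(protocol@directions)))
  bvecs <- cbind(matrix(0, 3, protocol@nB0), t(protocol@directions))
  bvalPath <- paste0(basePath, ".bval")
  bvecPath <- paste0(basePath, ".bvec")
  writeLines(paste(format(bvals, trim = TRUE), collapse = " "), bvalPath)
  writeLines(apply(bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvecPath)
  invisible(c(bvalPath, bvecPath))
}

#' Read FSL-style bval/bvec files into a protocol
#'
#' Assumes a single non-zero shell with the b = 0 volumes first.
#'
#' @param basePath path prefix used by [writeBvalBvec()].
#' @return A [DwiProtocol-class].
#' @export
readBvalBvec <- function(basePath) {
  bvals <- scan(paste0(basePath, ".bval"), quiet = TRUE)
  bvecs <- matrix(scan(paste0(basePath, ".bvec"), quiet = TRUE),
                  nrow = 3, byrow = TRUE)
  nb0 <- sum(bvals == 0)
  dwiProtocol(bValue = max(bvals),
              directions = t(bvecs[, bvals > 0, drop = FALSE]),
              nB0 = nb0)
}

#' Write a phantom specification as a JSON sidecar
#'
#' @param spec a [PhantomSpec-class].
#' @param path output .json path.
#' @return \code{path}, invisibly.
#' @export
writePhantomSpec <- function(spec, path) {
  stopifnot(is(spec, "PhantomSpec"))
  sl <- slotNames(spec)
  vals <- lapply(sl, function(s) slot(spec, s))
  names(vals) <- sl
  jsonlite::write_json(vals, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a phantom specification from JSON
#'
#' @param path the .json path.
#' @return A [PhantomSpec-class].
#' @export
readPhantomSpec <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(phantomSpec, vals)
}
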