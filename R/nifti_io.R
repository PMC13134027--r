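#' Read a binary mask from a NIfTI file
#'
#' Reads a 3-D NIfTI volume and binarizes it: every nonzero voxel becomes 1.
#' Grid shape, spacing and voxel-to-world affine are taken from the header
#' (sform/qform as resolved by RNifti). A trailing singleton 4th dimension is
#' tolerated and dropped; anything else non-3-D is an error.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
    if (!file.exists(path))
        stop(sprintf("mask file not found: '%s'", path), call. = FALSE)
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop(sprintf(
                        "cannot read '%s' as NIfTI: %s", path,
                        conditionMessage(e)), call. = FALSE))
    d <- dim(img)
    if (length(d) == 4L && d[4] == 1L) {
        d <- d[1:3]
    } else if (length(d) != 3L) {
        stop(sprintf("'%s' is not a 3-D volume (dims: %s)", path,
                     paste(dim(img), collapse = "x")), call. = FALSE)
    }
    spacing <- RNifti::pixdim(img)[1:3]
    aff <- unclass(RNifti::xform(img))
    attributes(aff) <- list(dim = c(4L, 4L))
    grid <- volume_grid(d, spacing, aff)
    vox <- array(as.numeric(img), dim = d)
    if (anyNA(vox))
        stop(sprintf("'%s' contains NA voxels", path), call. = FALSE)
    binary_mask(vox, grid)
}

#' Write a binary mask to a NIfTI file
#'
#' Writes the mask as an integer NIfTI volume carrying the grid spacing and
#' affine, so that `read_mask(write_mask(m, p))` reproduces `m` bit-exactly.
#'
#' @param mask a [binary_mask()].
#' @param path destination path (`.nii` or `.nii.gz`); parent must exist or be
#'   creatable.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
    stopifnot(inherits(mask, "binary_mask"))
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    img <- RNifti::asNifti(array(as.integer(mask$voxels),
                                 dim = mask$grid$shape))
    RNifti::pixdim(img) <- mask$grid$spacing
    RNifti::qform(img) <- structure(mask$grid$affine, code = 2L)
    RNifti::sform(img) <- structure(mask$grid$affine, code = 2L)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Resample a binary mask onto a target grid by nearest neighbor
#'
#' Pulls each target voxel back through `transform` (a world-to-world affine
#' mapping target world coordinates into source world coordinates) and the
#' source grid affine, and copies the nearest source voxel. Target voxels whose
#' nearest source voxel falls outside the source field of view are set to 0
#' (masks are absence-default). Output is always binary and always on `target`.
#'
#' Halfway coordinates round toward the higher index (`floor(x + 0.5)`), a
#' fixed deterministic tie-break.
#'
#' @param mask source [binary_mask()].
#' @param target target [volume_grid()].
#' @param transform 4x4 invertible world mapping, target world -> source world.
#'   Defaults to identity.
#' @return A [binary_mask()] on `target`.
#' @export
resample_nearest <- function(mask, target, transform = diag(4)) {
    stopifnot(inherits(mask, "binary_mask"), inherits(target, "volume_grid"))
    transform <- as.matrix(transform)
    if (!all(dim(transform) == c(4L, 4L)))
        stop("'transform' must be a 4x4 matrix", call. = FALSE)
    det_t <- det(transform)
    if (!is.finite(det_t) || abs(det_t) < 1e-12)
        stop("'transform' is singular", call. = FALSE)

    # composite 0-based voxel map: target index -> source index
    M <- solve(mask$grid$affine) %*% transform %*% target$affine

    sh <- target$shape
    i <- rep(seq_len(sh[1]) - 1L, times = sh[2] * sh[3])
    j <- rep(rep(seq_len(sh[2]) - 1L, each = sh[1]), times = sh[3])
    k <- rep(seq_len(sh[3]) - 1L, each = sh[1] * sh[2])

    sx <- floor(M[1, 1] * i + M[1, 2] * j + M[1, 3] * k + M[1, 4] + 0.5)
    sy <- floor(M[2, 1] * i + M[2, 2] * j + M[2, 3] * k + M[2, 4] + 0.5)
    sz <- floor(M[3, 1] * i + M[3, 2] * j + M[3, 3] * k + M[3, 4] + 0.5)

    ssh <- mask$grid$shape
    inside <- sx >= 0 & sx < ssh[1] & sy >= 0 & sy < ssh[2] & sz >= 0 & sz < ssh[3]
    out <- integer(length(i))
    lin <- sx[inside] + ssh[1] * (sy[inside] + ssh[2] * sz[inside]) + 1
    out[inside] <- mask$voxels[lin]
    binary_mask(array(out, dim = sh), target)
}
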