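#' Sampling grid for a 3-D volume
#'
#' A `volume_grid` describes the common sampling lattice shared by all masks of
#' a case: the array shape, the voxel spacing in mm, and the 4x4 voxel-to-world
#' affine. The reference analysis space is a 1-mm isotropic atlas grid, but any
#' positive spacing (including anisotropic) is supported.
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 1).
#' @param spacing numeric vector of length 3, mm per voxel per axis (each > 0).
#' @param affine optional 4x4 voxel-to-world matrix (mm). Voxel indices are
#'   0-based in the affine convention (NIfTI style). Defaults to a diagonal
#'   affine built from `spacing` with the origin at voxel (0,0,0).
#' @return An object of class `volume_grid`.
#' @export
#' @examples
#' g <- volume_grid(c(32, 32, 32))
#' voxel_volume_mm3(g)
volume_grid <- function(shape, spacing = c(1, 1, 1), affine = NULL) {
    shape <- as.integer(shape)
    spacing <- as.numeric(spacing)
    if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
        stop("'shape' must be three integers >= 1", call. = FALSE)
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
        stop("'spacing' must be three positive numbers (mm)", call. = FALSE)
    if (is.null(affine)) {
        affine <- diag(c(spacing, 1))
    } else {
        affine <- as.matrix(affine)
        if (!all(dim(affine) == c(4L, 4L)) || any(!is.finite(affine)))
            stop("'affine' must be a finite 4x4 matrix", call. = FALSE)
    }
    structure(list(shape = shape, spacing = spacing, affine = affine),
              class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
    cat("<volume_grid> ", paste(x$shape, collapse = " x "),
        " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
        " mm\n", sep = "")
    invisible(x)
}

#' Voxel volume of a grid in cubic millimetres
#'
#' @param grid a [volume_grid()].
#' @return Scalar voxel volume, `prod(spacing)` (mm^3), strictly positive.
#' @export
voxel_volume_mm3 <- function(grid) {
    stopifnot(inherits(grid, "volume_grid"))
    prod(grid$spacing)
}

#' Test two grids for compatibility
#'
#' Grids are compatible when shapes are identical and spacings and affine
#' entries agree within a relative tolerance. Header round-off in real NIfTI
#' files motivates the tolerance; genuinely different orientations are never
#' silently reconciled.
#'
#' @param a,b [volume_grid()] objects.
#' @param tol relative tolerance for spacing/affine comparison.
#' @return Logical scalar.
#' @export
grids_compatible <- function(a, b, tol = 1e-4) {
    stopifnot(inherits(a, "volume_grid"), inherits(b, "volume_grid"))
    if (!identical(a$shape, b$shape)) return(FALSE)
    rel <- function(x, y) abs(x - y) <= tol * pmax(abs(x), abs(y), 1)
    all(rel(a$spacing, b$spacing)) && all(rel(a$affine, b$affine))
}

stop_grid_mismatch <- function(a, b, what = "masks") {
    stop(sprintf(
        "grid mismatch between %s: [%s | %s mm] vs [%s | %s mm]",
        what,
        paste(a$shape, collapse = "x"), paste(format(a$spacing), collapse = "x"),
        paste(b$shape, collapse = "x"), paste(format(b$spacing), collapse = "x")),
        call. = FALSE)
}

#' Binary mask on a volume grid
#'
#' Couples a 3-D array of 0/1 voxels to its [volume_grid()]. Any nonzero,
#' non-missing value in `voxels` is coerced to 1; `NA` is rejected.
#'
#' @param voxels 3-D array conforming to `grid$shape`.
#' @param grid a [volume_grid()]. If missing, a unit-spacing grid matching
#'   `dim(voxels)` is created.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, grid = NULL) {
    if (length(dim(voxels)) != 3L)
        stop("'voxels' must be a 3-D array", call. = FALSE)
    if (anyNA(voxels))
        stop("mask voxels must not contain NA", call. = FALSE)
    if (is.null(grid)) grid <- volume_grid(dim(voxels))
    stopifnot(inherits(grid, "volume_grid"))
    if (!identical(as.integer(dim(voxels)), grid$shape))
        stop("voxel array shape does not match grid shape", call. = FALSE)
    v <- array(as.integer(voxels != 0), dim = grid$shape)
    structure(list(grid = grid, voxels = v), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
    cat("<binary_mask> ", paste(x$grid$shape, collapse = " x "),
        ", ", mask_count(x), " foreground voxels\n", sep = "")
    invisible(x)
}

#' Number of foreground voxels in a mask
#'
#' @param mask a [binary_mask()].
#' @return Integer count of voxels equal to 1.
#' @export
mask_count <- function(mask) {
    stopifnot(inherits(mask, "binary_mask"))
    sum(mask$voxels)
}

#' World coordinates of voxel centers
#'
#' Maps 1-based array indices to world (mm) coordinates through the grid
#' affine (which uses 0-based indices, NIfTI convention).
#'
#' @param grid a [volume_grid()].
#' @param ijk n x 3 matrix of 1-based voxel indices.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(grid, ijk) {
    stopifnot(inherits(grid, "volume_grid"))
    ijk <- matrix(as.numeric(ijk), ncol = 3L)
    h <- cbind(ijk - 1, 1) %*% t(grid$affine)
    h[, 1:3, drop = FALSE]
}

#' Bundle of per-case inputs
#'
#' A tumor mask and a skull mask on one verified common grid, plus optional
#' clinical covariates (age, sex, location, symptom flags).
#'
#' @param case_id character scalar.
#' @param tumor,skull [binary_mask()] objects on compatible grids.
#' @param covariates optional single-row data.frame or named list.
#' @return An object of class `case_inputs`.
#' @export
case_inputs <- function(case_id, tumor, skull, covariates = NULL) {
    stopifnot(is.character(case_id), length(case_id) == 1L,
              inherits(tumor, "binary_mask"), inherits(skull, "binary_mask"))
    if (!grids_compatible(tumor$grid, skull$grid))
        stop_grid_mismatch(tumor$grid, skull$grid,
                           sprintf("tumor and skull masks of case '%s'", case_id))
    structure(list(case_id = case_id, tumor = tumor, skull = skull,
                   covariates = covariates),
              class = "case_inputs")
}

#' @export
print.case_inputs <- function(x, ...) {
    cat("<case_inputs> ", x$case_id, ": tumor ", mask_count(x$tumor),
        " vox, skull ", mask_count(x$skull), " vox\n", sep = "")
    invisible(x)
}
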