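#' Juxta-osseous layer specification
#'
#' Parameters governing construction of the compartment map: the thickness of
#' the juxta-osseous ("dural") inner-table layer, the lattice connectivity used
#' for cavity filling and connected components, and the radius of the metric
#' closing that seals skull-base foramina before the cavity fill.
#'
#' The default 5-mm thickness is the primary analysis layer; 2 mm and 3 mm are
#' the standard sensitivity settings.
#'
#' @param thickness_mm layer thickness in mm (>= 0). Default 5.
#' @param connectivity 6, 18 or 26; neighborhood for fill/components. Default 6
#'   (conservative fill avoids diagonal leaks through thin shells).
#' @param closing_radius_mm radius (mm, >= 0) of the metric closing applied to
#'   the skull before cavity extraction. Default 2.
#' @return An object of class `layer_spec`.
#' @export
layer_spec <- function(thickness_mm = 5, connectivity = 6,
                       closing_radius_mm = 2) {
    thickness_mm <- as.numeric(thickness_mm)
    closing_radius_mm <- as.numeric(closing_radius_mm)
    connectivity <- as.integer(connectivity)
    if (length(thickness_mm) != 1L || !is.finite(thickness_mm) || thickness_mm < 0)
        stop("'thickness_mm' must be a single number >= 0", call. = FALSE)
    if (length(closing_radius_mm) != 1L || !is.finite(closing_radius_mm) ||
        closing_radius_mm < 0)
        stop("'closing_radius_mm' must be a single number >= 0", call. = FALSE)
    if (!connectivity %in% c(6L, 18L, 26L))
        stop("'connectivity' must be 6, 18 or 26", call. = FALSE)
    structure(list(thickness_mm = thickness_mm, connectivity = connectivity,
                   closing_radius_mm = closing_radius_mm),
              class = "layer_spec")
}

#' Euclidean distance (mm) to the nearest foreground voxel
#'
#' Exact voxel-center-to-voxel-center Euclidean distance transform honoring
#' anisotropic spacing, computed by the separable parabolic-envelope
#' algorithm. Foreground voxels have distance 0; an empty mask yields `Inf`
#' everywhere.
#'
#' @param mask a [binary_mask()].
#' @return 3-D numeric array of distances in mm, same shape as the mask.
#' @export
mask_distance_mm <- function(mask) {
    stopifnot(inherits(mask, "binary_mask"))
    d <- edt3d_cpp(as.logical(mask$voxels), mask$grid$shape,
                   mask$grid$spacing)
    array(d, dim = mask$grid$shape)
}

#' Connected components of a mask
#'
#' Deterministic BFS labelling (labels in column-major discovery order).
#'
#' @param mask a [binary_mask()].
#' @param connectivity 6, 18 or 26.
#' @return 3-D integer array of component labels (0 = background).
#' @export
mask_components <- function(mask, connectivity = 6) {
    stopifnot(inherits(mask, "binary_mask"))
    lab <- label_components_cpp(as.logical(mask$voxels), mask$grid$shape,
                                as.integer(connectivity))
    array(lab, dim = mask$grid$shape)
}

# Metric closing: dilation by a Euclidean ball of radius r (dist <= r), then
# erosion (complement distance > r). radius 0 is the identity.
close_mask <- function(mask, radius_mm) {
    if (radius_mm <= 0) return(mask)
    dil <- mask_distance_mm(mask) <= radius_mm
    dil_mask <- binary_mask(array(as.integer(dil), dim = mask$grid$shape),
                            mask$grid)
    comp <- binary_mask(array(as.integer(!dil), dim = mask$grid$shape),
                        mask$grid)
    ero <- mask_distance_mm(comp) > radius_mm
    binary_mask(array(as.integer(ero & dil), dim = mask$grid$shape), mask$grid)
}

border_labels <- function(lab) {
    d <- dim(lab)
    unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
}

#' Extract the intracranial cavity enclosed by a skull mask
#'
#' The cavity is the bounded region enclosed by the skull: the skull is first
#' sealed by a metric closing of radius `spec$closing_radius_mm` (foramina and
#' small perforations), the complement of the sealed skull is partitioned into
#' connected components, components touching the grid border are discarded as
#' exterior, and the largest remaining component — minus any skull voxels — is
#' returned. The result is always disjoint from the skull.
#'
#' @param skull non-empty skull [binary_mask()].
#' @param spec a [layer_spec()].
#' @return A [binary_mask()] of cavity voxels.
#' @export
extract_intracranial_cavity <- function(skull, spec = layer_spec()) {
    stopifnot(inherits(skull, "binary_mask"), inherits(spec, "layer_spec"))
    if (mask_count(skull) == 0L)
        stop("skull mask is empty; cannot extract a cavity", call. = FALSE)
    sealed <- close_mask(skull, spec$closing_radius_mm)
    comp <- binary_mask(array(as.integer(sealed$voxels == 0L),
                              dim = skull$grid$shape), skull$grid)
    lab <- mask_components(comp, spec$connectivity)
    exterior <- setdiff(border_labels(lab), 0L)
    enclosed <- setdiff(setdiff(unique(as.vector(lab)), 0L), exterior)
    if (length(enclosed) == 0L)
        stop(paste("no enclosed cavity found: the skull shell appears open;",
                   "consider a larger 'closing_radius_mm'"), call. = FALSE)
    sizes <- tabulate(lab[lab %in% enclosed], nbins = max(lab))
    best <- which.max(sizes)
    cav <- lab == best & skull$voxels == 0L
    binary_mask(array(as.integer(cav), dim = skull$grid$shape), skull$grid)
}

#' Juxta-osseous ("dural") inner-table layer
#'
#' The layer is the set of cavity voxels whose Euclidean distance (mm, voxel
#' center to voxel center, honoring spacing) to the nearest skull voxel is at
#' most `spec$thickness_mm`. It is by construction a subset of the cavity and
#' never extends into extracranial space. A zero thickness yields an empty
#' layer, since skull and cavity are disjoint.
#'
#' @param skull skull [binary_mask()].
#' @param cavity cavity [binary_mask()] disjoint from the skull (as returned by
#'   [extract_intracranial_cavity()]).
#' @param spec a [layer_spec()].
#' @return A [binary_mask()], subset of `cavity`.
#' @export
make_juxtaosseous_layer <- function(skull, cavity, spec = layer_spec()) {
    stopifnot(inherits(skull, "binary_mask"), inherits(cavity, "binary_mask"),
              inherits(spec, "layer_spec"))
    if (!grids_compatible(skull$grid, cavity$grid))
        stop_grid_mismatch(skull$grid, cavity$grid, "skull and cavity")
    if (any(skull$voxels == 1L & cavity$voxels == 1L))
        stop("cavity overlaps skull; it must be disjoint", call. = FALSE)
    if (mask_count(cavity) == 0L || mask_count(skull) == 0L)
        return(binary_mask(array(0L, dim = skull$grid$shape), skull$grid))
    d <- mask_distance_mm(skull)
    lay <- cavity$voxels == 1L & d <= spec$thickness_mm
    binary_mask(array(as.integer(lay), dim = skull$grid$shape), skull$grid)
}

#' Assemble the mutually exclusive compartment map
#'
#' Combines skull, layer and cavity into a single labelled volume with codes
#' 0 = background/extracranial, 1 = osseous, 2 = juxta-osseous/dural,
#' 3 = intradural. Overlaps (possible after resampling) are resolved by
#' priority osseous > juxta-osseous > intradural, so the codes always
#' partition the grid.
#'
#' @param skull,layer,cavity [binary_mask()] objects on one grid.
#' @param spec the [layer_spec()] used to build `layer` (recorded in the map).
#' @return An object of class `compartment_map` with fields `grid`, `labels`
#'   (3-D integer array of codes 0-3) and `layer` (the spec).
#' @export
build_compartment_map <- function(skull, layer, cavity, spec = layer_spec()) {
    stopifnot(inherits(skull, "binary_mask"), inherits(layer, "binary_mask"),
              inherits(cavity, "binary_mask"), inherits(spec, "layer_spec"))
    if (!grids_compatible(skull$grid, layer$grid))
        stop_grid_mismatch(skull$grid, layer$grid, "skull and layer")
    if (!grids_compatible(skull$grid, cavity$grid))
        stop_grid_mismatch(skull$grid, cavity$grid, "skull and cavity")
    lab <- array(0L, dim = skull$grid$shape)
    lab[cavity$voxels == 1L] <- 3L
    lab[layer$voxels == 1L] <- 2L
    lab[skull$voxels == 1L] <- 1L
    structure(list(grid = skull$grid, labels = lab, layer = spec),
              class = "compartment_map")
}

#' @export
print.compartment_map <- function(x, ...) {
    n <- tabulate(x$labels + 1L, nbins = 4L)
    cat("<compartment_map> ", paste(x$grid$shape, collapse = " x "),
        "; osseous ", n[2], ", juxta-osseous ", n[3], ", intradural ", n[4],
        " vox; layer ", x$layer$thickness_mm, " mm\n", sep = "")
    invisible(x)
}

#' One-call compartment map from a skull mask
#'
#' Convenience composition: cavity extraction, layer construction, and map
#' assembly with one [layer_spec()].
#'
#' @param skull skull [binary_mask()].
#' @param spec a [layer_spec()].
#' @param cavity optional precomputed cavity (reused across thicknesses, since
#'   the cavity does not depend on `thickness_mm`).
#' @return A `compartment_map`.
#' @export
compartment_map_from_skull <- function(skull, spec = layer_spec(),
                                       cavity = NULL) {
    if (is.null(cavity)) cavity <- extract_intracranial_cavity(skull, spec)
    lay <- make_juxtaosseous_layer(skull, cavity, spec)
    build_compartment_map(skull, lay, cavity, spec)
}

#' Write a compartment map as NIfTI plus a JSON sidecar
#'
#' @param cmap a `compartment_map`.
#' @param path destination NIfTI path; the sidecar goes to the same path with
#'   extension `.json` and records the layer specification and label codes.
#' @return `path`, invisibly.
#' @export
write_compartment_map <- function(cmap, path) {
    stopifnot(inherits(cmap, "compartment_map"))
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    img <- RNifti::asNifti(array(as.integer(cmap$labels), dim = cmap$grid$shape))
    RNifti::pixdim(img) <- cmap$grid$spacing
    RNifti::qform(img) <- structure(cmap$grid$affine, code = 2L)
    RNifti::sform(img) <- structure(cmap$grid$affine, code = 2L)
    RNifti::writeNifti(img, path)
    side <- sub("\\.nii(\\.gz)?$", ".json", path)
    jsonlite::write_json(list(
        labels = list(background = 0, osseous = 1, juxta_osseous = 2,
                      intradural = 3),
        layer = unclass(cmap$layer)), side, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
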