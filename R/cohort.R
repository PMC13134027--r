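#' Voxelwise lesion frequency map
#'
#' Sums binary masks voxelwise over a cohort (or a subtype subgroup): each
#' voxel carries the number of cases whose tumor covers it. Counts are stored
#' losslessly; a normalized fraction-of-cases variant is available for
#' display.
#'
#' @param masks non-empty list of [binary_mask()] objects on one grid.
#' @param tag optional subgroup tag (e.g. a subtype code).
#' @param normalized also store `fraction = counts / n_cases`.
#' @return An object of class `density_map` with fields `grid`, `counts`
#'   (3-D integer array), `n_cases`, `tag` and optionally `fraction`.
#' @export
frequency_map <- function(masks, tag = NULL, normalized = FALSE) {
    if (!length(masks)) stop("'masks' must be non-empty", call. = FALSE)
    g <- masks[[1]]$grid
    counts <- array(0L, dim = g$shape)
    for (m in masks) {
        stopifnot(inherits(m, "binary_mask"))
        if (!grids_compatible(g, m$grid))
            stop_grid_mismatch(g, m$grid, "masks in frequency_map")
        counts <- counts + m$voxels
    }
    out <- list(grid = g, counts = counts, n_cases = length(masks), tag = tag)
    if (normalized) out$fraction <- counts / length(masks)
    structure(out, class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
    cat("<density_map> ", paste(x$grid$shape, collapse = " x "), ", ",
        x$n_cases, " cases",
        if (!is.null(x$tag)) paste0(" [", x$tag, "]"), ", max overlap ",
        max(x$counts), "\n", sep = "")
    invisible(x)
}

#' Write a density map as NIfTI plus a JSON sidecar
#'
#' @param dmap a `density_map`.
#' @param path destination NIfTI path; the `.json` sidecar records `n_cases`
#'   and the subgroup tag.
#' @return `path`, invisibly.
#' @export
write_density_map <- function(dmap, path) {
    stopifnot(inherits(dmap, "density_map"))
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    img <- RNifti::asNifti(array(as.integer(dmap$counts),
                                 dim = dmap$grid$shape))
    RNifti::pixdim(img) <- dmap$grid$spacing
    RNifti::qform(img) <- structure(dmap$grid$affine, code = 2L)
    RNifti::sform(img) <- structure(dmap$grid$affine, code = 2L)
    RNifti::writeNifti(img, path)
    side <- sub("\\.nii(\\.gz)?$", ".json", path)
    jsonlite::write_json(list(n_cases = dmap$n_cases, subtype = dmap$tag),
                         side, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Select one index tumor per patient
#'
#' The index tumor is the patient's lesion with the largest total tumor volume
#' (osseous plus soft tissue). Exact ties break to the lexicographically
#' smallest `case_id`, with a warning.
#'
#' @param cases data.frame with columns `patient_id`, `case_id` and
#'   `total_cm3` (or a column named by `volume_col`).
#' @param volume_col name of the total-volume column.
#' @return The subset of `cases` with one row per patient.
#' @export
select_index_tumors <- function(cases, volume_col = "total_cm3") {
    stopifnot(is.data.frame(cases),
              all(c("patient_id", "case_id", volume_col) %in% names(cases)))
    pick <- unlist(lapply(split(seq_len(nrow(cases)), cases$patient_id),
                          function(rows) {
        v <- cases[[volume_col]][rows]
        best <- rows[v == max(v)]
        if (length(best) > 1L) {
            best <- best[order(cases$case_id[best])]
            warning(sprintf(
                "patient '%s': volume tie, keeping case '%s'",
                cases$patient_id[best[1]], cases$case_id[best[1]]),
                call. = FALSE)
        }
        best[1]
    }))
    out <- cases[sort(pick), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Dice and Jaccard overlap between two masks
#'
#' Dice = 2|A n B| / (|A| + |B|); Jaccard = |A n B| / |A u B|. When both masks
#' are empty the metrics are defined as 1 (perfect agreement on absence) and a
#' warning is emitted, rather than propagating NaN through batch reports.
#'
#' @param a,b [binary_mask()] objects on one grid.
#' @return Numeric scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
    ov <- mask_overlap(a, b)
    if (ov$na + ov$nb == 0) {
        warning("both masks empty; Dice defined as 1", call. = FALSE)
        return(1)
    }
    2 * ov$inter / (ov$na + ov$nb)
}

#' @rdname dice
#' @export
jaccard <- function(a, b) {
    ov <- mask_overlap(a, b)
    uni <- ov$na + ov$nb - ov$inter
    if (uni == 0) {
        warning("both masks empty; Jaccard defined as 1", call. = FALSE)
        return(1)
    }
    ov$inter / uni
}

mask_overlap <- function(a, b) {
    stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
    if (!grids_compatible(a$grid, b$grid))
        stop_grid_mismatch(a$grid, b$grid, "overlap operands")
    list(inter = sum(a$voxels == 1L & b$voxels == 1L),
         na = mask_count(a), nb = mask_count(b))
}

#' Pearson correlation of paired volumes with a Fisher-z confidence interval
#'
#' Standard product-moment correlation; the CI is
#' `tanh(atanh(r) +/- z / sqrt(n - 3))` with the normal quantile for the
#' requested level.
#'
#' @param v1,v2 numeric vectors of paired volumes (length >= 3, non-degenerate
#'   variance in each).
#' @param conf_level confidence level (default 0.95).
#' @return List `r`, `ci_low`, `ci_high`, `n`.
#' @export
volume_correlation <- function(v1, v2, conf_level = 0.95) {
    if (length(v1) != length(v2) || length(v1) < 3L)
        stop("need >= 3 paired volumes", call. = FALSE)
    if (sd(v1) == 0 || sd(v2) == 0)
        stop("degenerate variance in a coordinate", call. = FALSE)
    r <- cor(v1, v2)
    z <- qnorm(1 - (1 - conf_level) / 2)
    if (abs(r) < 1) {
        zr <- atanh(r)
        half <- z / sqrt(length(v1) - 3)
        ci <- tanh(c(zr - half, zr + half))
    } else {
        ci <- c(r, r)  # perfectly collinear pairs
    }
    list(r = r, ci_low = ci[1], ci_high = ci[2], n = length(v1))
}

#' Pairwise inter-rater agreement report
#'
#' Per-pair Dice and Jaccard for two raters' segmentations plus the volume
#' correlation across pairs.
#'
#' @param masks_a,masks_b equal-length lists of [binary_mask()] objects,
#'   paired by position.
#' @return An object of class `agreement_report`: data.frame `pairs`
#'   (case-level dice, jaccard, volumes in cm^3) and `volume_cor` (see
#'   [volume_correlation()], `NULL` when fewer than 3 pairs).
#' @export
agreement_report <- function(masks_a, masks_b) {
    if (length(masks_a) != length(masks_b) || !length(masks_a))
        stop("mask lists must be non-empty and of equal length", call. = FALSE)
    rows <- lapply(seq_along(masks_a), function(i) {
        a <- masks_a[[i]]; b <- masks_b[[i]]
        k <- voxel_volume_mm3(a$grid) / 1000
        data.frame(pair = i, dice = dice(a, b), jaccard = jaccard(a, b),
                   vol_a_cm3 = mask_count(a) * k,
                   vol_b_cm3 = mask_count(b) * k)
    })
    pairs <- do.call(rbind, rows)
    vc <- if (nrow(pairs) >= 3L && sd(pairs$vol_a_cm3) > 0 &&
              sd(pairs$vol_b_cm3) > 0)
        volume_correlation(pairs$vol_a_cm3, pairs$vol_b_cm3) else NULL
    structure(list(pairs = pairs, volume_cor = vc),
              class = "agreement_report")
}
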