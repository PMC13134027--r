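#' Per-compartment tumor voxel counts
#'
#' Tallies tumor voxels by the compartment code they intersect on the mutually
#' exclusive map: `n_bone` (osseous, code 1), `n_dura` (juxta-osseous/dural,
#' code 2), `n_intra` (intradural, code 3) and `n_other` (tumor voxels outside
#' all three compartments, code 0 — e.g. subcutaneous extension). Percentages
#' use the total tumor voxel count (including `n_other`) as denominator.
#'
#' @param tumor tumor [binary_mask()].
#' @param cmap a `compartment_map` on the same grid.
#' @return An object of class `compartment_counts`: integer fields `n_bone`,
#'   `n_dura`, `n_intra`, `n_other`, `total`; numeric `voxel_volume_mm3`; and
#'   `pct`, the named vector of fractions (empty-total tumors get all-NA
#'   fractions).
#' @export
count_compartment_voxels <- function(tumor, cmap) {
    stopifnot(inherits(tumor, "binary_mask"), inherits(cmap, "compartment_map"))
    if (!grids_compatible(tumor$grid, cmap$grid))
        stop_grid_mismatch(tumor$grid, cmap$grid, "tumor and compartment map")
    codes <- cmap$labels[tumor$voxels == 1L]
    n <- tabulate(codes + 1L, nbins = 4L)
    compartment_counts(n_bone = n[2], n_dura = n[3], n_intra = n[4],
                       n_other = n[1],
                       voxel_volume_mm3 = voxel_volume_mm3(tumor$grid))
}

#' Construct compartment counts directly
#'
#' @param n_bone,n_dura,n_intra,n_other non-negative integer voxel counts.
#' @param voxel_volume_mm3 voxel volume in mm^3 (> 0).
#' @return A `compartment_counts` object; see [count_compartment_voxels()].
#' @export
compartment_counts <- function(n_bone, n_dura, n_intra, n_other = 0,
                               voxel_volume_mm3 = 1) {
    n <- c(n_bone = n_bone, n_dura = n_dura, n_intra = n_intra,
           n_other = n_other)
    if (any(n < 0) || any(n != round(n)))
        stop("counts must be non-negative integers", call. = FALSE)
    if (voxel_volume_mm3 <= 0)
        stop("'voxel_volume_mm3' must be positive", call. = FALSE)
    n <- as.integer(round(n))
    names(n) <- c("n_bone", "n_dura", "n_intra", "n_other")
    total <- sum(n)
    pct <- if (total > 0) n / total else rep(NA_real_, 4)
    names(pct) <- names(n)
    structure(list(n_bone = n[[1]], n_dura = n[[2]], n_intra = n[[3]],
                   n_other = n[[4]], total = total, pct = pct,
                   voxel_volume_mm3 = as.numeric(voxel_volume_mm3)),
              class = "compartment_counts")
}

#' @export
print.compartment_counts <- function(x, ...) {
    cat(sprintf(
        "<compartment_counts> bone %d, dura %d, intra %d, other %d (total %d)\n",
        x$n_bone, x$n_dura, x$n_intra, x$n_other, x$total))
    invisible(x)
}

#' Deterministic osteomeningioma subtype from compartment counts
#'
#' The rule, a pure function of (`n_bone`, `n_dura`, `n_intra`):
#' \itemize{
#'   \item POM: `n_bone > 0`, `n_dura == 0`, `n_intra == 0` (tumor confined to
#'     the osseous compartment);
#'   \item SOM-I: `n_bone > 0`, `n_dura > 0`, `n_intra == 0`;
#'   \item SOM-IIA: all three positive and `n_bone >= n_intra` (ties go to
#'     SOM-IIA by definition);
#'   \item SOM-IIB: all three positive and `n_intra > n_bone`.
#' }
#' Two patterns are flagged as anomalies rather than classified:
#' `not_osteomeningioma` when `n_bone == 0` (every rule requires osseous
#' involvement), and `skipped_layer` when `n_bone > 0`, `n_dura == 0` but
#' `n_intra > 0` (geometrically anomalous: intradural tumor without
#' juxta-osseous involvement). `n_other` never influences the call.
#'
#' @param counts a `compartment_counts` object.
#' @param thickness_mm the layer thickness used to derive `counts` (recorded).
#' @return An object of class `subtype_call` with fields `subtype` (one of
#'   `"POM"`, `"SOM_I"`, `"SOM_IIA"`, `"SOM_IIB"`, or `NA` when invalid),
#'   `valid`, `anomaly` (`NA` when valid), `counts`, `thickness_mm`.
#' @export
classify_osteomeningioma <- function(counts, thickness_mm = NA_real_) {
    stopifnot(inherits(counts, "compartment_counts"))
    b <- counts$n_bone; d <- counts$n_dura; i <- counts$n_intra
    subtype <- NA_character_; anomaly <- NA_character_
    if (b == 0L) {
        anomaly <- "not_osteomeningioma"
    } else if (d == 0L && i > 0L) {
        anomaly <- "skipped_layer"
    } else if (d == 0L && i == 0L) {
        subtype <- "POM"
    } else if (i == 0L) {
        subtype <- "SOM_I"
    } else if (b >= i) {
        subtype <- "SOM_IIA"
    } else {
        subtype <- "SOM_IIB"
    }
    structure(list(subtype = subtype, valid = is.na(anomaly),
                   anomaly = anomaly, counts = counts,
                   thickness_mm = as.numeric(thickness_mm)),
              class = "subtype_call")
}

#' @export
print.subtype_call <- function(x, ...) {
    if (x$valid) {
        cat("<subtype_call> ", x$subtype, "\n", sep = "")
    } else {
        cat("<subtype_call> invalid (", x$anomaly, ")\n", sep = "")
    }
    invisible(x)
}

#' Ordered subtype levels
#'
#' Severity ordering used by the monotonicity property of the thickness
#' sensitivity analysis (POM < SOM-I < SOM-IIA < SOM-IIB).
#' @return Character vector of the four subtype codes in order.
#' @export
subtype_levels <- function() c("POM", "SOM_I", "SOM_IIA", "SOM_IIB")

#' Component volumes in cubic centimetres
#'
#' Converts compartment counts to the reported volume components: the osseous
#' component (`n_bone`), the intracranial soft-tissue component (`n_dura +
#' n_intra`, i.e. dural enhancement plus intradural expansion), the residual
#' extracompartmental component (`n_other`), and the total. Conversion is
#' `count * voxel_volume_mm3 / 1000`.
#'
#' @param counts a `compartment_counts` object.
#' @return Named list `osseous_cm3`, `intracranial_soft_tissue_cm3`,
#'   `other_cm3`, `total_cm3`.
#' @export
component_volumes <- function(counts) {
    stopifnot(inherits(counts, "compartment_counts"))
    k <- counts$voxel_volume_mm3 / 1000
    list(osseous_cm3 = counts$n_bone * k,
         intracranial_soft_tissue_cm3 = (counts$n_dura + counts$n_intra) * k,
         other_cm3 = counts$n_other * k,
         total_cm3 = counts$total * k)
}

#' Classify one case end to end
#'
#' Composition of the full per-case pipeline: cavity extraction, layer
#' construction, compartment map assembly, tumor voxel counting, and the
#' deterministic subtype rule.
#'
#' @param case a [case_inputs()].
#' @param spec a [layer_spec()].
#' @param cavity optional precomputed cavity mask (saves recomputation across
#'   thicknesses).
#' @return A `subtype_call` (see [classify_osteomeningioma()]).
#' @export
classify_case <- function(case, spec = layer_spec(), cavity = NULL) {
    stopifnot(inherits(case, "case_inputs"))
    cmap <- compartment_map_from_skull(case$skull, spec, cavity = cavity)
    counts <- count_compartment_voxels(case$tumor, cmap)
    classify_osteomeningioma(counts, thickness_mm = spec$thickness_mm)
}

#' Thickness sensitivity analysis over a cohort
#'
#' Reclassifies every case at each layer thickness and summarizes stability:
#' the per-case subtype at each thickness, the fraction of cases keeping one
#' subtype across all thicknesses, and subtype transition matrices for every
#' thickness pair.
#'
#' @param cases list of [case_inputs()].
#' @param thicknesses numeric vector of layer thicknesses in mm (default
#'   `c(2, 3, 5)`).
#' @param spec base [layer_spec()] supplying connectivity and closing radius.
#' @return An object of class `reclassification_table`: `table` (data.frame,
#'   one row per case, one column per thickness plus validity), `stable_n`,
#'   `stable_fraction`, and `transitions` (named list of contingency matrices,
#'   one per ordered thickness pair).
#' @export
thickness_sensitivity <- function(cases, thicknesses = c(2, 3, 5),
                                  spec = layer_spec()) {
    if (!length(thicknesses) || any(thicknesses < 0))
        stop("'thicknesses' must be non-empty and non-negative", call. = FALSE)
    if (!length(cases)) stop("'cases' must be non-empty", call. = FALSE)
    thicknesses <- sort(unique(as.numeric(thicknesses)))
    cols <- paste0("t", format(thicknesses, trim = TRUE), "mm")
    calls <- matrix(NA_character_, nrow = length(cases),
                    ncol = length(thicknesses),
                    dimnames = list(NULL, cols))
    ids <- vapply(cases, function(cs) cs$case_id, character(1))
    for (ci in seq_along(cases)) {
        cavity <- extract_intracranial_cavity(cases[[ci]]$skull, spec)
        for (ti in seq_along(thicknesses)) {
            sp <- layer_spec(thickness_mm = thicknesses[ti],
                             connectivity = spec$connectivity,
                             closing_radius_mm = spec$closing_radius_mm)
            call <- classify_case(cases[[ci]], sp, cavity = cavity)
            calls[ci, ti] <- if (call$valid) call$subtype else
                paste0("invalid:", call$anomaly)
        }
    }
    stable <- apply(calls, 1L, function(r) length(unique(r)) == 1L)
    lev <- c(subtype_levels(),
             unique(grep("^invalid:", as.vector(calls), value = TRUE)))
    transitions <- list()
    if (length(thicknesses) > 1L) {
        for (i in seq_len(length(thicknesses) - 1L)) {
            for (j in seq(i + 1L, length(thicknesses))) {
                key <- paste0(cols[i], "_vs_", cols[j])
                transitions[[key]] <- table(
                    factor(calls[, i], levels = lev),
                    factor(calls[, j], levels = lev),
                    dnn = c(cols[i], cols[j]))
            }
        }
    }
    tab <- data.frame(case_id = ids, calls, stable = stable,
                      stringsAsFactors = FALSE, check.names = FALSE)
    structure(list(table = tab, thicknesses = thicknesses,
                   stable_n = sum(stable),
                   stable_fraction = mean(stable),
                   transitions = transitions),
              class = "reclassification_table")
}

#' @export
print.reclassification_table <- function(x, ...) {
    cat(sprintf(
        "<reclassification_table> %d cases x %d thicknesses; %d/%d stable (%.1f%%)\n",
        nrow(x$table), length(x$thicknesses), x$stable_n, nrow(x$table),
        100 * x$stable_fraction))
    invisible(x)
}

#' Per-case classification report as a plain list (JSON-ready)
#'
#' @param call a `subtype_call`.
#' @param case_id optional case identifier to embed.
#' @return Nested list with counts, percentages, volumes (cm^3), subtype,
#'   thickness and anomaly flag, suitable for `jsonlite::write_json()`.
#' @export
case_report <- function(call, case_id = NULL) {
    stopifnot(inherits(call, "subtype_call"))
    cn <- call$counts
    list(case_id = case_id,
         subtype = if (call$valid) call$subtype else NULL,
         valid = call$valid,
         anomaly = if (call$valid) NULL else call$anomaly,
         thickness_mm = call$thickness_mm,
         counts = list(n_bone = cn$n_bone, n_dura = cn$n_dura,
                       n_intra = cn$n_intra, n_other = cn$n_other,
                       total = cn$total),
         percentages = as.list(cn$pct),
         volumes_cm3 = component_volumes(cn))
}
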