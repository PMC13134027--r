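# Seeded synthetic phantoms: skull geometries with analytically known
# cavities, lesions with exact per-compartment ground truth, and synthetic
# clinical cohorts. These stand in for patient MRIs so every pipeline stage is
# testable with known answers.

with_seed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

#' Spherical-shell skull geometry
#'
#' @param center_mm world coordinates (mm) of the shell center.
#' @param outer_r_mm,inner_r_mm outer and inner radii in mm
#'   (`outer_r_mm > inner_r_mm > 0`).
#' @return Geometry descriptor for [make_skull()].
#' @export
shell_geometry <- function(center_mm, outer_r_mm, inner_r_mm) {
    if (!(outer_r_mm > inner_r_mm && inner_r_mm > 0))
        stop("need outer_r_mm > inner_r_mm > 0", call. = FALSE)
    structure(list(type = "shell", center = as.numeric(center_mm),
                   outer_r = as.numeric(outer_r_mm),
                   inner_r = as.numeric(inner_r_mm)),
              class = "skull_geometry")
}

#' Slab (closed-box) skull geometry
#'
#' A rectangular closed box whose face on one side of the cavity is a thick
#' bone plate: voxels with index along `axis` inside `bone_range` form the
#' plate, the remaining box walls are one voxel thick, and the enclosed cavity
#' is exactly the voxels with `axis` index in `cavity_range` and all other
#' indices in `2:(shape-1)`.
#'
#' @param axis 1, 2 or 3.
#' @param bone_range,cavity_range integer index ranges `c(lo, hi)` (1-based)
#'   along `axis`; must be disjoint and adjacent (`bone` immediately next to
#'   `cavity` on one side).
#' @return Geometry descriptor for [make_skull()].
#' @export
slab_geometry <- function(axis, bone_range, cavity_range) {
    axis <- as.integer(axis)
    b <- as.integer(bone_range); cv <- as.integer(cavity_range)
    if (!axis %in% 1:3) stop("'axis' must be 1, 2 or 3", call. = FALSE)
    if (b[1] > b[2] || cv[1] > cv[2])
        stop("ranges must be c(lo, hi) with lo <= hi", call. = FALSE)
    if (!(b[2] + 1L == cv[1] || cv[2] + 1L == b[1]))
        stop("bone_range and cavity_range must be adjacent and disjoint",
             call. = FALSE)
    structure(list(type = "slab", axis = axis, bone_range = b,
                   cavity_range = cv),
              class = "skull_geometry")
}

#' Build a synthetic skull mask
#'
#' For `shell` geometry, skull voxels are those whose center lies at distance
#' in `(inner_r, outer_r]` from the center; the enclosed cavity is the open
#' ball of radius `inner_r`. For `slab` geometry the skull is a closed box
#' with one thick bone plate (see [slab_geometry()]).
#'
#' @param grid a [volume_grid()].
#' @param geometry a [shell_geometry()] or [slab_geometry()].
#' @return A skull [binary_mask()].
#' @export
make_skull <- function(grid, geometry) {
    stopifnot(inherits(grid, "volume_grid"), inherits(geometry, "skull_geometry"))
    sh <- grid$shape
    if (geometry$type == "shell") {
        idx <- as.matrix(expand.grid(i = seq_len(sh[1]), j = seq_len(sh[2]),
                                     k = seq_len(sh[3])))
        w <- voxel_to_world(grid, idx)
        d <- sqrt(rowSums((w - matrix(geometry$center, nrow(w), 3,
                                      byrow = TRUE))^2))
        v <- as.integer(d > geometry$inner_r & d <= geometry$outer_r)
        return(binary_mask(array(v, dim = sh), grid))
    }
    # slab: closed box; hull spans bone plate + cavity + one-voxel cap
    a <- geometry$axis
    b <- geometry$bone_range; cv <- geometry$cavity_range
    lo <- min(b[1], cv[1]); hi <- max(b[2], cv[2])
    if (b[2] < cv[1]) hi <- hi + 1L else lo <- lo - 1L  # cap beyond cavity
    if (lo < 1L || hi > sh[a])
        stop("slab geometry does not fit inside the grid", call. = FALSE)
    if (any(sh[-a] < 3L))
        stop("slab geometry needs at least 3 voxels on the other axes",
             call. = FALSE)
    v <- array(0L, dim = sh)
    hull_idx <- lapply(1:3, function(ax) if (ax == a) lo:hi else seq_len(sh[ax]))
    v[hull_idx[[1]], hull_idx[[2]], hull_idx[[3]]] <- 1L
    cav_idx <- lapply(1:3, function(ax) if (ax == a) cv[1]:cv[2]
                      else 2:(sh[ax] - 1L))
    v[cav_idx[[1]], cav_idx[[2]], cav_idx[[3]]] <- 0L
    binary_mask(v, grid)
}

#' Declared cavity of a slab skull
#'
#' The set-construction counterpart of [extract_intracranial_cavity()] for
#' slab geometry: exactly the interior box of the slab phantom.
#'
#' @param grid the [volume_grid()] the slab skull lives on.
#' @param geometry a [slab_geometry()].
#' @return A [binary_mask()] of the declared cavity voxels.
#' @export
slab_cavity <- function(grid, geometry) {
    stopifnot(inherits(geometry, "skull_geometry"), geometry$type == "slab")
    sh <- grid$shape
    v <- array(0L, dim = sh)
    cv <- geometry$cavity_range; a <- geometry$axis
    cav_idx <- lapply(1:3, function(ax) if (ax == a) cv[1]:cv[2]
                      else 2:(sh[ax] - 1L))
    v[cav_idx[[1]], cav_idx[[2]], cav_idx[[3]]] <- 1L
    binary_mask(v, grid)
}

neighbor_indices <- function(idx, sh) {
    # 6-connected neighbors of linear indices (1-based), vectorized
    i <- ((idx - 1L) %% sh[1]) + 1L
    j <- (((idx - 1L) %/% sh[1]) %% sh[2]) + 1L
    k <- ((idx - 1L) %/% (sh[1] * sh[2])) + 1L
    off <- rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L), c(0L, 1L, 0L),
                 c(0L, 0L, -1L), c(0L, 0L, 1L))
    res <- integer(0)
    for (r in seq_len(nrow(off))) {
        ii <- i + off[r, 1]; jj <- j + off[r, 2]; kk <- k + off[r, 3]
        ok <- ii >= 1L & ii <= sh[1] & jj >= 1L & jj <= sh[2] &
            kk >= 1L & kk <= sh[3]
        res <- c(res, (kk[ok] - 1L) * sh[1] * sh[2] + (jj[ok] - 1L) * sh[1] +
                     ii[ok])
    }
    unique(res)
}

grow_quota <- function(avail, seeds, quota, sh, priority = NULL) {
    # seeded random-frontier growth of `quota` voxels inside the index set
    # `avail`, starting from ONE randomly chosen seed voxel (keeping each
    # phase's blob connected); with `priority` (a per-voxel score), the
    # highest-priority frontier voxel is taken first (ties broken at random),
    # steering the blob, e.g., inward through the layer. Falls back to random
    # top-up if the reachable component is smaller than the quota.
    selected <- integer(0)
    in_avail <- logical(prod(sh)); in_avail[avail] <- TRUE
    picked <- logical(prod(sh))
    frontier <- intersect(seeds, avail)
    if (length(frontier) > 1L)
        frontier <- frontier[sample.int(length(frontier), 1L)]
    while (length(selected) < quota) {
        frontier <- frontier[!picked[frontier]]
        if (!length(frontier)) {
            rest <- avail[!picked[avail]]
            top <- rest[sample.int(length(rest), quota - length(selected))]
            picked[top] <- TRUE
            selected <- c(selected, top)
            break
        }
        if (is.null(priority)) {
            pick <- frontier[sample.int(length(frontier), 1L)]
        } else {
            best <- which(priority[frontier] == max(priority[frontier]))
            pick <- frontier[best[sample.int(length(best), 1L)]]
        }
        picked[pick] <- TRUE
        selected <- c(selected, pick)
        nb <- neighbor_indices(pick, sh)
        frontier <- c(frontier, nb[in_avail[nb] & !picked[nb]])
    }
    selected
}

#' Synthetic lesion with exact per-compartment voxel counts
#'
#' Draws a lesion mask whose true composition equals the requested counts
#' exactly, on the supplied compartment map. With `contiguous = TRUE` the
#' lesion is grown as adjacent blobs crossing the inner table (bone voxels
#' near the cavity first, then juxta-osseous voxels adjacent to the bone blob,
#' then intradural voxels adjacent to the layer blob, then extracranial voxels
#' adjacent to the outer bone surface); if a compartment's reachable region is
#' smaller than its quota the remainder is placed at random within that
#' compartment. Deterministic for a fixed seed.
#'
#' @param cmap a `compartment_map`.
#' @param n_bone,n_dura,n_intra,n_other requested voxel counts per compartment.
#' @param contiguous grow a connected lesion (default `TRUE`).
#' @param seed integer seed.
#' @return List with `mask` (the lesion [binary_mask()]) and `counts` (the
#'   ground-truth `compartment_counts`, equal to the request by construction).
#' @export
make_lesion_by_counts <- function(cmap, n_bone, n_dura, n_intra, n_other = 0,
                                  contiguous = TRUE, seed = 1L) {
    stopifnot(inherits(cmap, "compartment_map"))
    sh <- cmap$grid$shape
    lab <- as.vector(cmap$labels)
    quota <- c(n_bone, n_dura, n_intra, n_other)
    codes <- c(1L, 2L, 3L, 0L)
    names(quota) <- c("osseous", "juxta-osseous", "intradural", "background")
    avail <- lapply(codes, function(cd) which(lab == cd))
    for (q in seq_along(quota)) {
        if (quota[q] > length(avail[[q]]))
            stop(sprintf(
                "infeasible lesion request: %d voxels asked in the %s compartment, only %d available",
                quota[q], names(quota)[q], length(avail[[q]])), call. = FALSE)
    }
    with_seed(seed, {
        sel <- vector("list", 4L)
        if (!contiguous) {
            for (q in seq_along(quota)) {
                sel[[q]] <- if (quota[q] > 0)
                    avail[[q]][sample.int(length(avail[[q]]), quota[q])]
                else integer(0)
            }
        } else {
            adj_to <- function(pool, anchor) {
                if (!length(anchor)) return(pool)
                nb <- unique(unlist(lapply(anchor, neighbor_indices, sh = sh)))
                hit <- intersect(nb, pool)
                if (length(hit)) hit else pool
            }
            # bone seeded at the inner table (adjacent to cavity labels 2/3)
            cav_idx <- which(lab == 2L | lab == 3L)
            bone_seed <- adj_to(avail[[1]],
                                if (length(cav_idx)) cav_idx else integer(0))
            sel[[1]] <- if (quota[1] > 0)
                grow_quota(avail[[1]], bone_seed, quota[1], sh) else integer(0)
            # when intradural voxels are requested too, steer the layer blob
            # inward (away from bone) so it reaches the intradural interface
            layer_priority <- if (quota[3] > 0 && quota[2] > 0) {
                skull_only <- binary_mask(
                    array(as.integer(cmap$labels == 1L), dim = sh), cmap$grid)
                as.vector(mask_distance_mm(skull_only))
            } else NULL
            sel[[2]] <- if (quota[2] > 0)
                grow_quota(avail[[2]], adj_to(avail[[2]], sel[[1]]), quota[2],
                           sh, priority = layer_priority) else integer(0)
            anchor3 <- if (length(sel[[2]])) sel[[2]] else sel[[1]]
            sel[[3]] <- if (quota[3] > 0)
                grow_quota(avail[[3]], adj_to(avail[[3]], anchor3), quota[3],
                           sh) else integer(0)
            sel[[4]] <- if (quota[4] > 0)
                grow_quota(avail[[4]], adj_to(avail[[4]], sel[[1]]), quota[4],
                           sh) else integer(0)
        }
        v <- integer(prod(sh))
        v[unlist(sel)] <- 1L
        mask <- binary_mask(array(v, dim = sh), cmap$grid)
        list(mask = mask,
             counts = compartment_counts(
                 n_bone, n_dura, n_intra, n_other,
                 voxel_volume_mm3 = voxel_volume_mm3(cmap$grid)))
    })
}

#' Spherical lesion crossing the inner table
#'
#' Ball of voxel centers within `radius_mm` of a world-space center; a
#' continuous, realistic lesion that can span several compartments.
#'
#' @param grid a [volume_grid()] (or a `compartment_map`, whose grid is used).
#' @param center_mm world coordinates (mm).
#' @param radius_mm sphere radius in mm (> 0).
#' @return A [binary_mask()].
#' @export
make_transmural_sphere <- function(grid, center_mm, radius_mm) {
    if (inherits(grid, "compartment_map")) grid <- grid$grid
    stopifnot(inherits(grid, "volume_grid"), radius_mm > 0)
    sh <- grid$shape
    idx <- as.matrix(expand.grid(i = seq_len(sh[1]), j = seq_len(sh[2]),
                                 k = seq_len(sh[3])))
    w <- voxel_to_world(grid, idx)
    d2 <- rowSums((w - matrix(as.numeric(center_mm), nrow(w), 3,
                              byrow = TRUE))^2)
    binary_mask(array(as.integer(d2 <= radius_mm^2), dim = sh), grid)
}

#' Specification of a synthetic clinical cohort
#'
#' Class sizes, class-conditional symptom probabilities, demographic and
#' volume distribution parameters for [make_synthetic_cohort()]. The defaults
#' reproduce the structure of the reference osteomeningioma cohort (n = 168):
#' subtype sizes 6/37/57/68, per-subtype symptom frequencies, ~90% female,
#' per-subtype age means/SDs, and per-subtype log-normal component-volume
#' distributions matched to the reported medians and IQRs.
#'
#' @param n_per_subtype named integer vector over
#'   `c("POM","SOM_I","SOM_IIA","SOM_IIB")`.
#' @param symptom_probs numeric matrix, rows = subtypes, columns = symptoms
#'   (Bernoulli probability of each symptom in each subtype).
#' @param female_prob,skull_base_prob per-subtype probabilities.
#' @param age_mean,age_sd per-subtype normal age parameters (years).
#' @param osseous_meanlog,osseous_sdlog,soft_meanlog,soft_sdlog per-subtype
#'   log-normal parameters for the osseous and intracranial soft-tissue
#'   component volumes (cm^3); an `NA` meanlog means the component is
#'   identically zero (POM has no soft-tissue component).
#' @return An object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(
        n_per_subtype = c(POM = 6L, SOM_I = 37L, SOM_IIA = 57L, SOM_IIB = 68L),
        symptom_probs = NULL,
        female_prob = c(5 / 6, 36 / 37, 53 / 57, 57 / 68),
        skull_base_prob = c(0, 24 / 37, 27 / 57, 32 / 68),
        age_mean = c(52.3, 53.8, 58.5, 56.6),
        age_sd = c(12.4, 9.8, 13.9, 12.6),
        osseous_meanlog = log(c(23.9, 16.1, 16.5, 7.8)),
        osseous_sdlog = c(0.52, 0.84, 0.97, 1.02),
        soft_meanlog = c(NA, log(1.6), log(5.8), log(19.6)),
        soft_sdlog = c(NA, 0.94, 1.12, 0.99)) {
    lev <- subtype_levels()
    if (is.null(symptom_probs)) {
        symptom_probs <- rbind(
            POM     = c(edema = 0,       mass_effect = 0,      seizure = 0,
                        icp = 1 / 6,     exophthalmos = 0,
                        subcutaneous_mass = 3 / 6,  incidental = 2 / 6),
            SOM_I   = c(2 / 37,  1 / 37,  0,       1 / 37,  14 / 37, 5 / 37,
                        16 / 37),
            SOM_IIA = c(14 / 57, 8 / 57,  6 / 57,  4 / 57,  11 / 57, 8 / 57,
                        23 / 57),
            SOM_IIB = c(49 / 68, 35 / 68, 15 / 68, 21 / 68, 5 / 68,  0,
                        17 / 68))
    }
    stopifnot(all(names(n_per_subtype) == lev),
              all(rownames(symptom_probs) == lev),
              all(symptom_probs >= 0 & symptom_probs <= 1),
              all(n_per_subtype >= 0))
    structure(list(n_per_subtype = n_per_subtype,
                   symptom_probs = symptom_probs,
                   female_prob = female_prob,
                   skull_base_prob = skull_base_prob,
                   age_mean = age_mean, age_sd = age_sd,
                   osseous_meanlog = osseous_meanlog,
                   osseous_sdlog = osseous_sdlog,
                   soft_meanlog = soft_meanlog, soft_sdlog = soft_sdlog),
              class = "synthetic_cohort_spec")
}

#' Generate a synthetic clinical cohort table
#'
#' Draws one case per row: ground-truth subtype, age, sex, location,
#' class-conditional Bernoulli symptom flags, and log-normal component
#' volumes. Deterministic for a fixed seed.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param seed integer seed.
#' @return data.frame with columns `case_id`, `patient_id`, `subtype`, `age`,
#'   `sex`, `location`, one 0/1 column per symptom, `osseous_cm3`, `soft_cm3`,
#'   `total_cm3`.
#' @export
make_synthetic_cohort <- function(spec = synthetic_cohort_spec(), seed = 1L) {
    stopifnot(inherits(spec, "synthetic_cohort_spec"))
    lev <- subtype_levels()
    n <- sum(spec$n_per_subtype)
    if (n == 0L) {
        out <- data.frame(case_id = character(), patient_id = character(),
                          subtype = character(), age = numeric(),
                          sex = character(), location = character(),
                          stringsAsFactors = FALSE)
        for (s in colnames(spec$symptom_probs)) out[[s]] <- integer()
        out$osseous_cm3 <- numeric(); out$soft_cm3 <- numeric()
        out$total_cm3 <- numeric()
        return(out)
    }
    with_seed(seed, {
        cls <- rep(lev, times = spec$n_per_subtype)
        ci <- match(cls, lev)
        out <- data.frame(
            case_id = sprintf("case%04d", seq_len(n)),
            patient_id = sprintf("pt%04d", seq_len(n)),
            subtype = cls,
            age = round(rnorm(n, spec$age_mean[ci], spec$age_sd[ci]), 1),
            sex = ifelse(runif(n) < spec$female_prob[ci], "F", "M"),
            location = ifelse(runif(n) < spec$skull_base_prob[ci],
                              "skull_base", "convexity"),
            stringsAsFactors = FALSE)
        for (s in colnames(spec$symptom_probs))
            out[[s]] <- rbinom(n, 1L, spec$symptom_probs[ci, s])
        oss <- rlnorm(n, spec$osseous_meanlog[ci],
                      ifelse(is.na(spec$osseous_sdlog[ci]), 0,
                             spec$osseous_sdlog[ci]))
        oss[is.na(spec$osseous_meanlog[ci])] <- 0
        soft <- rlnorm(n, ifelse(is.na(spec$soft_meanlog[ci]), 0,
                                 spec$soft_meanlog[ci]),
                       ifelse(is.na(spec$soft_sdlog[ci]), 0,
                              spec$soft_sdlog[ci]))
        soft[is.na(spec$soft_meanlog[ci])] <- 0
        out$osseous_cm3 <- round(oss, 2)
        out$soft_cm3 <- round(soft, 2)
        out$total_cm3 <- out$osseous_cm3 + out$soft_cm3
        out
    })
}

#' Asymptotic ("true") collapsed odds ratio implied by a cohort spec
#'
#' For exposure `subtype == target` versus all other classes combined, the
#' estimand of the collapsed 2x2 table is `[p1/(1-p1)] / [p0/(1-p0)]` where
#' `p1` is the symptom probability in the target class and `p0` the class-size
#' weighted mean probability over the remaining classes.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param symptom column name of `spec$symptom_probs`.
#' @param target subtype defining the exposed group.
#' @return The true odds ratio (positive real).
#' @export
cohort_true_or <- function(spec, symptom, target) {
    stopifnot(inherits(spec, "synthetic_cohort_spec"),
              symptom %in% colnames(spec$symptom_probs),
              target %in% subtype_levels())
    lev <- subtype_levels()
    p <- spec$symptom_probs[, symptom]
    w <- spec$n_per_subtype
    p1 <- p[[target]]
    rest <- setdiff(lev, target)
    p0 <- sum(w[rest] * p[rest]) / sum(w[rest])
    (p1 / (1 - p1)) / (p0 / (1 - p0))
}

#' Write a phantom cohort as a BIDS-style tree
#'
#' Builds one skull per subject, grows a by-counts lesion per case, writes the
#' masks under the standard layout, writes `participants.tsv` from a synthetic
#' clinical table, and records the ground-truth counts in a JSON sidecar per
#' case.
#'
#' @param root destination directory.
#' @param skull skull [binary_mask()] shared by all subjects.
#' @param cmap `compartment_map` of that skull (ground-truth reference).
#' @param requests data.frame with columns `n_bone`, `n_dura`, `n_intra` and
#'   optionally `n_other`, one row per case.
#' @param seed integer seed (per-case seeds are derived from it).
#' @return data.frame of case ids and ground-truth counts, invisibly.
#' @export
write_phantom_cohort <- function(root, skull, cmap, requests, seed = 1L) {
    if (is.null(requests$n_other)) requests$n_other <- 0L
    gt <- vector("list", nrow(requests))
    for (r in seq_len(nrow(requests))) {
        les <- make_lesion_by_counts(cmap, requests$n_bone[r],
                                     requests$n_dura[r], requests$n_intra[r],
                                     requests$n_other[r],
                                     seed = seed + r)
        sub <- sprintf("%04d", r)
        cid <- write_bids_case(root, sub, les$mask, skull)
        side <- file.path(root, paste0("sub-", sub), "anat",
                          sprintf("sub-%s_desc-tumor_groundtruth.json", sub))
        jsonlite::write_json(list(case_id = cid, n_bone = requests$n_bone[r],
                                  n_dura = requests$n_dura[r],
                                  n_intra = requests$n_intra[r],
                                  n_other = requests$n_other[r]),
                             side, auto_unbox = TRUE, digits = NA)
        gt[[r]] <- data.frame(case_id = cid, requests[r, , drop = FALSE],
                              stringsAsFactors = FALSE)
    }
    invisible(do.call(rbind, gt))
}
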