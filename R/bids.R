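#' BIDS-style layout helpers
#'
#' Cases live in a BIDS-style tree:
#' `<root>/sub-<ID>/anat/sub-<ID>_desc-tumor_mask.nii.gz` (tumor) and
#' `..._desc-skull_mask.nii.gz` (skull), with optional cohort covariates at
#' `<root>/participants.tsv`. Subjects with several lesions use descriptors
#' `tumor`, `tumor2`, `tumor3`, ... against a single shared skull mask; the
#' case id is then `<ID>` for the first lesion and `<ID>-tumor<k>` otherwise.
#'
#' @name bids_layout
NULL

bids_paths <- function(root, sub, tumor_desc = "tumor") {
    anat <- file.path(root, paste0("sub-", sub), "anat")
    list(
        anat = anat,
        tumor = file.path(anat, sprintf("sub-%s_desc-%s_mask.nii.gz", sub, tumor_desc)),
        skull = file.path(anat, sprintf("sub-%s_desc-skull_mask.nii.gz", sub))
    )
}

bids_case_id <- function(sub, tumor_desc) {
    if (identical(tumor_desc, "tumor")) sub else paste0(sub, "-", tumor_desc)
}

#' Discover cases in a BIDS-style tree
#'
#' @param root dataset root directory.
#' @return data.frame with columns `case_id`, `sub`, `tumor_desc`,
#'   `tumor_path`, `skull_path`, one row per lesion.
#' @export
discover_bids_cases <- function(root) {
    if (!dir.exists(root))
        stop(sprintf("BIDS root not found: '%s'", root), call. = FALSE)
    subs <- sort(basename(list.dirs(root, recursive = FALSE)))
    subs <- sub("^sub-", "", subs[grepl("^sub-", subs)])
    rows <- list()
    for (s in subs) {
        anat <- file.path(root, paste0("sub-", s), "anat")
        tum <- sort(list.files(anat, pattern = sprintf(
            "^sub-%s_desc-tumor[0-9]*_mask\\.nii(\\.gz)?$", s)))
        for (tf in tum) {
            desc <- sub(sprintf("^sub-%s_desc-", s), "", tf)
            desc <- sub("_mask\\.nii(\\.gz)?$", "", desc)
            rows[[length(rows) + 1L]] <- data.frame(
                case_id = bids_case_id(s, desc), sub = s, tumor_desc = desc,
                tumor_path = file.path(anat, tf),
                skull_path = bids_paths(root, s)$skull,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(case_id = character(), sub = character(),
                          tumor_desc = character(), tumor_path = character(),
                          skull_path = character(), stringsAsFactors = FALSE))
    do.call(rbind, rows)
}

#' Load one case from a BIDS-style tree
#'
#' Loads the tumor and skull masks for a case, verifies grid compatibility,
#' and joins covariates from `<root>/participants.tsv` when present (matched
#' on its `case_id` column).
#'
#' @param root dataset root directory.
#' @param case_id case identifier as produced by [discover_bids_cases()].
#' @return A [case_inputs()].
#' @export
load_bids_case <- function(root, case_id) {
    cases <- discover_bids_cases(root)
    row <- cases[cases$case_id == case_id, , drop = FALSE]
    if (nrow(row) == 0L)
        stop(sprintf("case '%s' not found under '%s'", case_id, root),
             call. = FALSE)
    tumor <- read_mask(row$tumor_path[1])
    skull <- read_mask(row$skull_path[1])
    if (!grids_compatible(tumor$grid, skull$grid))
        stop_grid_mismatch(tumor$grid, skull$grid,
                           sprintf("tumor and skull of case '%s'", case_id))
    cov <- NULL
    ptsv <- file.path(root, "participants.tsv")
    if (file.exists(ptsv)) {
        tab <- read.delim(ptsv, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(case_id = "character"))
        if ("case_id" %in% names(tab)) {
            hit <- tab[tab$case_id == case_id, , drop = FALSE]
            if (nrow(hit) >= 1L) cov <- hit[1, , drop = FALSE]
        }
    }
    case_inputs(case_id, tumor, skull, covariates = cov)
}

#' Write one case into a BIDS-style tree
#'
#' Companion writer used by the phantom generator; creates the `sub-<ID>/anat`
#' directory and writes tumor and skull masks under the documented names.
#'
#' @param root dataset root directory.
#' @param sub subject identifier (no `sub-` prefix).
#' @param tumor,skull [binary_mask()] objects.
#' @param tumor_desc lesion descriptor, `"tumor"` or `"tumor<k>"`.
#' @param write_skull overwrite/write the shared skull mask (set `FALSE` when
#'   adding extra lesions to an existing subject).
#' @return The case id, invisibly.
#' @export
write_bids_case <- function(root, sub, tumor, skull, tumor_desc = "tumor",
                            write_skull = TRUE) {
    p <- bids_paths(root, sub, tumor_desc)
    dir.create(p$anat, recursive = TRUE, showWarnings = FALSE)
    write_mask(tumor, p$tumor)
    if (write_skull) write_mask(skull, p$skull)
    invisible(bids_case_id(sub, tumor_desc))
}
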