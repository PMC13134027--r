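#' Reference cohort per-subtype symptom counts
#'
#' Published per-subtype symptom counts from the reference osteomeningioma
#' cohort (168 tumors: 6 POM, 37 SOM-I, 57 SOM-IIA, 68 SOM-IIB), shipped with
#' the package. Each symptom column holds the number of symptom-positive
#' tumors in that subtype.
#'
#' @return data.frame with columns `subtype`, `n`, and one count column per
#'   symptom.
#' @export
reference_cohort_counts <- function() {
    read.delim(system.file("extdata", "reference_cohort_counts.tsv",
                           package = "osteomap", mustWork = TRUE),
               sep = "\t", stringsAsFactors = FALSE)
}

#' Expand per-subtype counts into per-case subtype and flag vectors
#'
#' Inverse of tabulation for one symptom: produces aligned `subtypes` and 0/1
#' `outcome` vectors whose cross-tabulation reproduces the counts, ready for
#' [contingency_from_cohort()].
#'
#' @param counts data.frame in the shape of [reference_cohort_counts()].
#' @param symptom name of a symptom count column.
#' @return List with `subtypes` and `outcome` vectors.
#' @export
expand_cohort_counts <- function(counts, symptom) {
    stopifnot(symptom %in% names(counts))
    subtypes <- rep(counts$subtype, counts$n)
    outcome <- unlist(lapply(seq_len(nrow(counts)), function(i) {
        yes <- counts[[symptom]][i]
        c(rep(1L, yes), rep(0L, counts$n[i] - yes))
    }))
    list(subtypes = subtypes, outcome = as.integer(outcome))
}

#' Predefined univariable subtype-symptom odds ratios
#'
#' The four predefined univariable comparisons: SOM-IIB versus all other
#' classes for brain edema, epileptic seizure, and raised intracranial
#' pressure; SOM-I versus all other classes for exophthalmos. Each is a 2x2
#' collapse of the per-subtype counts with a Woolf-interval odds ratio.
#'
#' @param counts per-subtype counts, default [reference_cohort_counts()].
#' @return data.frame with one row per comparison: `symptom`, `target`, the
#'   2x2 cells `a`, `b`, `c`, `d`, `or`, `ci_low`, `ci_high`.
#' @export
univariable_or_table <- function(counts = reference_cohort_counts()) {
    pairs <- data.frame(
        symptom = c("edema", "seizure", "icp", "exophthalmos"),
        target = c("SOM_IIB", "SOM_IIB", "SOM_IIB", "SOM_I"),
        stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
        ex <- expand_cohort_counts(counts, pairs$symptom[i])
        t2 <- contingency_from_cohort(ex$subtypes, ex$outcome, pairs$target[i])
        orr <- odds_ratio_woolf(t2)
        data.frame(symptom = pairs$symptom[i], target = pairs$target[i],
                   a = t2$a, b = t2$b, c = t2$c, d = t2$d,
                   or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
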