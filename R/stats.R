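# Statistical layer: 2x2 contingency construction, odds ratios with Woolf
# (logit) intervals, Fisher exact and Kruskal-Wallis tests, exploratory
# logistic regression with separation diagnostics, descriptive summaries.
# All subtype-symptom comparisons are exploratory; no multiplicity adjustment
# is applied by design.

#' 2x2 contingency table
#'
#' Cell convention: `a` = exposed & outcome present, `b` = exposed & outcome
#' absent, `c` = unexposed & outcome present, `d` = unexposed & outcome
#' absent. Exposure is membership in the target subtype group (e.g. SOM-IIB
#' versus all other classes combined).
#'
#' @param a,b,c,d non-negative integer cell counts, not all zero.
#' @return An object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
    cells <- c(a = a, b = b, c = c, d = d)
    if (any(cells < 0) || any(cells != round(cells)))
        stop("cells must be non-negative integers", call. = FALSE)
    if (sum(cells) == 0)
        stop("all-zero table", call. = FALSE)
    cells <- as.list(setNames(as.integer(round(cells)), names(cells)))
    structure(cells, class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
    cat(sprintf("<contingency_2x2> [[%d, %d], [%d, %d]]\n",
                x$a, x$b, x$c, x$d))
    invisible(x)
}

#' Collapse a cohort into a 2x2 table for one subtype-symptom pair
#'
#' Exposure is `subtype == target`; all other classes are pooled. Cases with a
#' missing outcome flag are dropped (complete-case analysis) with a message
#' reporting how many.
#'
#' @param subtypes character vector of per-case subtype calls (or a list of
#'   `subtype_call` objects; invalid calls are excluded with a message).
#' @param outcome per-case 0/1 outcome flags, aligned with `subtypes`; `NA`
#'   allowed (excluded).
#' @param target exposure-defining subtype, one of [subtype_levels()].
#' @return A [contingency_2x2()].
#' @export
contingency_from_cohort <- function(subtypes, outcome, target) {
    if (is.list(subtypes) && length(subtypes) &&
        inherits(subtypes[[1]], "subtype_call")) {
        valid <- vapply(subtypes, function(x) x$valid, logical(1))
        if (any(!valid))
            message(sum(!valid), " invalid (anomalous) calls excluded")
        outcome <- outcome[valid]
        subtypes <- vapply(subtypes[valid], function(x) x$subtype, character(1))
    }
    subtypes <- as.character(subtypes)
    if (length(subtypes) != length(outcome))
        stop("'subtypes' and 'outcome' lengths differ", call. = FALSE)
    if (!target %in% subtype_levels())
        stop("'target' must be one of ", paste(subtype_levels(), collapse = ", "),
             call. = FALSE)
    keep <- !is.na(outcome) & !is.na(subtypes)
    if (any(!keep))
        message(sum(!keep), " cases with missing data excluded (complete-case)")
    subtypes <- subtypes[keep]
    outcome <- as.integer(outcome[keep])
    if (!length(subtypes)) stop("empty cohort after exclusions", call. = FALSE)
    exp_ <- subtypes == target
    contingency_2x2(sum(exp_ & outcome == 1L), sum(exp_ & outcome == 0L),
                    sum(!exp_ & outcome == 1L), sum(!exp_ & outcome == 0L))
}

#' Odds ratio with a Woolf (logit) confidence interval
#'
#' OR = ad/(bc); the CI is `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`
#' with `z = qnorm(1 - alpha/2)` (1.959964 at alpha = 0.05). If any cell is
#' zero, the Haldane-Anscombe +0.5 correction is applied to all four cells and
#' flagged in the result.
#'
#' @param t a [contingency_2x2()].
#' @param alpha two-sided significance level (default 0.05).
#' @return An object of class `odds_ratio_result`: `or`, `ci_low`, `ci_high`,
#'   `correction_applied`, `alpha`.
#' @export
odds_ratio_woolf <- function(t, alpha = 0.05) {
    stopifnot(inherits(t, "contingency_2x2"))
    cells <- c(t$a, t$b, t$c, t$d)
    correction <- any(cells == 0L)
    if (correction) cells <- cells + 0.5
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    z <- qnorm(1 - alpha / 2)
    se <- sqrt(sum(1 / cells))
    ci <- exp(log(or) + c(-1, 1) * z * se)
    structure(list(or = or, ci_low = ci[1], ci_high = ci[2],
                   correction_applied = correction, alpha = alpha),
              class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
    cat(sprintf("OR %.2f, %d%% CI %.2f-%.2f%s\n", x$or,
                round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
                if (x$correction_applied) " (Haldane-Anscombe corrected)" else ""))
    invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value as the sum of hypergeometric probabilities, over all
#' tables with the observed margins, of tables whose point probability does
#' not exceed the observed one (within a small relative slack for floating
#' ties). A degenerate margin (an all-zero row or column) yields p = 1 by
#' convention, with a message.
#'
#' @param t a [contingency_2x2()].
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(t) {
    stopifnot(inherits(t, "contingency_2x2"))
    m <- matrix(c(t$a, t$c, t$b, t$d), 2L)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
        message("degenerate margin; Fisher p = 1 by convention")
        return(1)
    }
    fisher.test(m)$p.value
}

#' Kruskal-Wallis rank test across groups
#'
#' Mid-rank treatment of ties with the standard tie-correction divisor; the
#' p-value is from the chi-square distribution with (number of groups - 1)
#' degrees of freedom. All-identical values give H = 0, p = 1.
#'
#' @param groups list (length >= 2) of numeric vectors, each non-empty; total
#'   n >= 3.
#' @return List `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
    if (!is.list(groups) || length(groups) < 2L)
        stop("'groups' must be a list of >= 2 numeric vectors", call. = FALSE)
    if (any(vapply(groups, length, integer(1)) == 0L))
        stop("empty group", call. = FALSE)
    x <- unlist(groups)
    if (length(x) < 3L) stop("need total n >= 3", call. = FALSE)
    g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
    if (length(unique(x)) == 1L)
        return(list(H = 0, df = length(groups) - 1L, p = 1))
    kt <- kruskal.test(x, g)
    list(H = unname(kt$statistic), df = unname(kt$parameter),
         p = kt$p.value)
}

#' Log-transformed total volume
#'
#' `log(v + 1)` (natural log); the +1 keeps zero volumes defined and preserves
#' monotonicity. Right-skewed volume distributions enter regression models
#' through this transform.
#'
#' @param v total tumor volume(s) in cm^3, each >= 0.
#' @return `log(v + 1)`.
#' @export
log1_volume <- function(v) {
    if (any(!is.finite(v)) || any(v < 0))
        stop("volumes must be finite and >= 0", call. = FALSE)
    log1p(v)
}

#' Descriptive summary of a numeric vector
#'
#' Mean with sample SD (n-1 denominator), median, and the [25th, 75th]
#' percentile IQR with linear interpolation. A single observation has an
#' undefined SD; it is reported as 0 with `sd_defined = FALSE`.
#'
#' @param values non-empty numeric vector (NAs dropped).
#' @return List `n`, `mean`, `sd`, `sd_defined`, `median`, `q25`, `q75`.
#' @export
describe <- function(values) {
    values <- values[!is.na(values)]
    if (!length(values)) stop("empty input", call. = FALSE)
    q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
    one <- length(values) == 1L
    list(n = length(values), mean = mean(values),
         sd = if (one) 0 else sd(values), sd_defined = !one,
         median = median(values), q25 = q[1], q75 = q[2])
}

#' Exploratory multivariable logistic regression with separation diagnostics
#'
#' Maximum-likelihood logistic fit (IRLS via `glm`) of a binary outcome on a
#' covariate table, reporting per-term adjusted odds ratios `exp(coef)` with
#' Wald 95% CIs `exp(coef +/- 1.96 * SE)`. Each term is screened for
#' quasi-separation / sparse data: a binary covariate with an empty cell in
#' its 2x2 margin against the outcome, or a fitted |coefficient| above
#' `separation_coef` (default 10 on the log-odds scale), is flagged unstable.
#' Non-convergence is flagged, never silent.
#'
#' @param outcome 0/1 vector, not constant.
#' @param design data.frame of covariates (numeric or two-level factors);
#'   columns are entered additively. Must be of full column rank.
#' @param conf_level Wald CI level (default 0.95).
#' @param separation_coef |coefficient| threshold flagging instability.
#' @param maxit IRLS iteration cap.
#' @return An object of class `logistic_fit`: data.frame `terms` (term,
#'   estimate, se, aOR, ci_low, ci_high, p, unstable), plus `converged`.
#' @export
logistic_fit <- function(outcome, design, conf_level = 0.95,
                         separation_coef = 10, maxit = 100) {
    outcome <- as.integer(outcome)
    if (any(is.na(outcome)) || !all(outcome %in% 0:1))
        stop("'outcome' must be 0/1 without NA", call. = FALSE)
    if (length(unique(outcome)) < 2L)
        stop("constant outcome", call. = FALSE)
    stopifnot(is.data.frame(design), nrow(design) == length(outcome))
    X <- model.matrix(~ ., data = design)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
        stop("design is rank deficient; offending column(s): ",
             paste(dropped, collapse = ", "), call. = FALSE)
    }
    dat <- cbind(data.frame(.y = outcome), design)
    fit <- suppressWarnings(glm(.y ~ ., data = dat, family = binomial(),
                                control = list(epsilon = 1e-12,
                                               maxit = maxit)))
    est <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    z <- qnorm(1 - (1 - conf_level) / 2)
    pvals <- 2 * pnorm(-abs(est / se))
    unstable <- abs(est) > separation_coef
    # empty-margin screen for binary covariates
    for (nm in names(design)) {
        v <- design[[nm]]
        lv <- unique(v[!is.na(v)])
        if (length(lv) == 2L) {
            tab <- table(factor(v, levels = sort(lv)), factor(outcome, 0:1))
            if (any(tab == 0L)) {
                hit <- grepl(nm, names(est), fixed = TRUE)
                unstable[hit] <- TRUE
            }
        }
    }
    terms <- data.frame(term = names(est), estimate = unname(est),
                        se = unname(se), aOR = exp(unname(est)),
                        ci_low = exp(unname(est) - z * unname(se)),
                        ci_high = exp(unname(est) + z * unname(se)),
                        p = unname(pvals), unstable = unname(unstable),
                        stringsAsFactors = FALSE)
    structure(list(terms = terms, converged = fit$converged),
              class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
    cat("<logistic_fit>", if (!x$converged) "(NOT converged)", "\n")
    print(x$terms, digits = 4)
    invisible(x)
}

NULL
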