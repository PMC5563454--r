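#' Confidence interval for a case-series proportion
#'
#' Interval for the frequency of a variant among disease cases (carriers /
#' cohort size). The default is the Wald normal approximation
#' p +/- z * sqrt(p(1-p)/n), clamped to \[0, 1\], which is the convention
#' used when quoting case frequencies alongside architecture estimates;
#' Wilson (score) and Clopper-Pearson exact intervals are available for
#' users who prefer them at small counts.
#'
#' @param carriers number of cases (or case alleles) carrying the variant.
#' @param total cohort denominator (individuals or alleles, as counted).
#' @param confidence two-sided confidence level, default 0.95.
#' @param method `"wald"` (default), `"wilson"`, or `"exact"`.
#' @return named numeric vector `c(estimate, lower, upper)`.
#' @examples
#' proportion_ci(104, 6179)  # 1.7%, 95% CI 1.4-2.0%
#' @export
proportion_ci <- function(carriers, total, confidence = 0.95,
                          method = c("wald", "wilson", "exact")) {
  method <- match.arg(method)
  check_confidence(confidence)
  if (!is.numeric(carriers) || !is.numeric(total) || length(carriers) != 1L ||
      length(total) != 1L || is.na(carriers) || is.na(total))
    stop("carriers and total must be numeric scalars", call. = FALSE)
  if (total <= 0) stop("total must be positive", call. = FALSE)
  if (carriers < 0 || carriers > total)
    stop("carriers must lie in [0, total]", call. = FALSE)
  p <- carriers / total
  ci <- switch(method,
    wald = {
      z <- qnorm(1 - (1 - confidence) / 2)
      half <- z * sqrt(p * (1 - p) / total)
      c(p - half, p + half)
    },
    wilson = stats::prop.test(carriers, total, conf.level = confidence,
                              correct = FALSE)$conf.int,
    exact = stats::binom.test(carriers, total,
                              conf.level = confidence)$conf.int)
  c(estimate = p,
    lower = max(0, ci[1]),
    upper = min(1, ci[2]))
}

#' Maximum allelic contribution estimated from case series
#'
#' The maximum allelic contribution of a disease is estimated as the upper
#' confidence bound of the frequency of the most common causal variant seen
#' across published case series: no newly identified variant is expected to
#' exceed it in well-studied ancestries. Optionally rounds the bound *up*
#' to a number of significant figures, the conservative choice when
#' extrapolating the estimate to related disorders.
#'
#' @param carriers integer vector, carrier count per series.
#' @param total integer vector, cohort denominator per series.
#' @param confidence two-sided confidence level for the bound, default 0.95.
#' @param method interval type passed to [proportion_ci()].
#' @param round_up_sig if non-NULL, round the result up to this many
#'   significant figures.
#' @return the largest upper bound across the series, in (0, 1\].
#' @examples
#' max_allelic_contribution(104, 6179)                   # 0.02
#' max_allelic_contribution(24, 361, round_up_sig = 1)   # 0.1
#' @export
max_allelic_contribution <- function(carriers, total, confidence = 0.95,
                                     method = "wald", round_up_sig = NULL) {
  if (length(carriers) == 0L || length(total) != length(carriers))
    stop("carriers and total must be non-empty and of equal length",
         call. = FALSE)
  uppers <- mapply(function(k, n)
    proportion_ci(k, n, confidence, method)[["upper"]], carriers, total)
  out <- max(uppers)
  if (!is.null(round_up_sig)) out <- signif_ceiling(out, round_up_sig)
  min(out, 1)
}

# round x up to `digits` significant figures (0.092 -> 0.1 at 1 sf)
signif_ceiling <- function(x, digits) {
  if (x <= 0) return(x)
  scale <- 10^(floor(log10(x)) - digits + 1)
  ceiling(x / scale - 1e-12) * scale
}

#' Case/control burden odds ratio
#'
#' OR = (cases with variant / cases without) / (controls with variant /
#' controls without). The confidence interval uses the normal approximation
#' on the log odds ratio; when exactly one cell is zero the
#' Haldane-Anscombe correction (0.5 added to every cell) is applied for the
#' interval and flagged. A zero `controls_with` cell yields an infinite
#' point estimate, flagged rather than silently propagated.
#'
#' @param cases_with,cases_without,controls_with,controls_without
#'   non-negative cell counts of the 2x2 table.
#' @param confidence two-sided confidence level, default 0.95.
#' @return object of class `burden_or`: list with `or`, `lower`, `upper`,
#'   `corrected` (Haldane-Anscombe applied), `undefined` (infinite or
#'   degenerate OR).
#' @examples
#' burden_odds_ratio(10, 90, 5, 95)
#' @export
burden_odds_ratio <- function(cases_with, cases_without,
                              controls_with, controls_without,
                              confidence = 0.95) {
  cells <- c(cases_with, cases_without, controls_with, controls_without)
  if (any(!is.finite(cells)) || any(cells < 0))
    stop("all cell counts must be finite and non-negative", call. = FALSE)
  if (cases_without <= 0 || controls_without <= 0)
    stop("both 'without' cells must be positive to form odds", call. = FALSE)
  check_confidence(confidence)
  or <- (cases_with / cases_without) / (controls_with / controls_without)
  undefined <- !is.finite(or)
  n_zero <- sum(cells == 0)
  corrected <- n_zero == 1L
  ci_cells <- if (corrected) cells + 0.5 else cells
  if (all(ci_cells > 0)) {
    z <- qnorm(1 - (1 - confidence) / 2)
    log_or <- log((ci_cells[1] / ci_cells[2]) / (ci_cells[3] / ci_cells[4]))
    se <- sqrt(sum(1 / ci_cells))
    lower <- exp(log_or - z * se)
    upper <- exp(log_or + z * se)
  } else {
    lower <- NA_real_; upper <- NA_real_
  }
  structure(list(or = or, lower = lower, upper = upper,
                 corrected = corrected, undefined = undefined,
                 confidence = confidence),
            class = "burden_or")
}

#' @export
print.burden_or <- function(x, digits = 3, ...) {
  cat("Burden odds ratio: ", format(signif(x$or, digits)), sep = "")
  if (is.finite(x$lower))
    cat(" (", format(100 * x$confidence), "% CI ",
        format(signif(x$lower, digits)), "-",
        format(signif(x$upper, digits)), ")", sep = "")
  if (x$corrected) cat("  [Haldane-Anscombe corrected CI]")
  if (x$undefined) cat("  [undefined: zero denominator cell]")
  cat("\n")
  invisible(x)
}

#' Allele-frequency bins for stratified burden testing
#'
#' Defines non-overlapping, left-open/right-closed bins `(a, b]` from a
#' strictly increasing set of breakpoints in (0, 1), plus an overflow bin
#' above the last breakpoint. The defaults are the breakpoints used for
#' rare-variant burden odds ratios in cardiomyopathy gene panels.
#'
#' @param breakpoints strictly increasing numeric vector in (0, 1).
#' @return object of class `af_bins`.
#' @export
af_bins <- function(breakpoints = c(4e-5, 1e-4, 5e-4, 1e-3)) {
  if (!is.numeric(breakpoints) || length(breakpoints) == 0L ||
      any(is.na(breakpoints)) || any(breakpoints <= 0) ||
      any(breakpoints >= 1) || is.unsorted(breakpoints, strictly = TRUE))
    stop("breakpoints must be strictly increasing fractions in (0, 1)",
         call. = FALSE)
  structure(list(breakpoints = breakpoints), class = "af_bins")
}

#' @export
print.af_bins <- function(x, ...) {
  cat("AF bins:", paste(af_bin_labels(x), collapse = ", "), "\n")
  invisible(x)
}

af_bin_labels <- function(bins) {
  b <- vapply(bins$breakpoints, format, character(1))
  n <- length(b)
  c(paste0("(0,", b[1], "]"),
    if (n > 1) paste0("(", b[-n], ",", b[-1], "]"),
    paste0(">", b[n]))
}

#' Assign variants to allele-frequency bins
#'
#' Each variant goes to exactly one bin: right-closed intervals between
#' breakpoints, an overflow bin above the last breakpoint, and variants
#' absent from the reference (AF 0) in the lowest bin.
#'
#' @param id vector of variant identifiers.
#' @param af numeric vector of allele frequencies in \[0, 1\].
#' @param bins an [af_bins()] definition.
#' @return named list mapping bin label to the ids it contains (all labels
#'   present, possibly empty); the per-variant factor of bin labels is
#'   attached as attribute `"bin"`.
#' @examples
#' bin_by_af(c("v1", "v2", "v3"), c(3e-5, 4e-5, 2e-3), af_bins())
#' @export
bin_by_af <- function(id, af, bins = af_bins()) {
  if (!inherits(bins, "af_bins")) bins <- af_bins(bins)
  if (length(id) != length(af))
    stop("id and af must have equal length", call. = FALSE)
  if (any(is.na(af)) || any(af < 0) || any(af > 1))
    stop("af must be in [0, 1]", call. = FALSE)
  labels <- af_bin_labels(bins)
  # strict > makes bins right-closed; af = 0 lands in the lowest bin
  idx <- vapply(af, function(x) sum(x > bins$breakpoints), integer(1)) + 1L
  f <- factor(labels[idx], levels = labels)
  out <- split(id, f)
  attr(out, "bin") <- f
  out
}

#' Estimate variant penetrance from case and population frequencies
#'
#' A variant enriched in cases relative to the reference population implies
#' a penetrance of roughly prevalence x case AF / population AF: the share
#' of carriers who are affected. Estimates above 1 are capped and flagged
#' (attribute `"capped"`) — they indicate that the assumed prevalence,
#' case frequency and population frequency are mutually inconsistent, which
#' is itself informative. A population AF of 0 leaves penetrance undefined
#' and returns NA with a warning.
#'
#' @param prevalence disease prevalence (fraction or "1/500"-style string).
#' @param case_af variant frequency among case chromosomes (or cases).
#' @param population_af variant frequency in the reference population.
#' @return penetrance estimate in (0, 1\], with attribute `capped`.
#' @examples
#' estimate_penetrance("1/500", 0.01, 4e-5)  # 0.5
#' @export
estimate_penetrance <- function(prevalence, case_af, population_af) {
  prevalence <- parse_prevalence(prevalence)
  stop_if_not_fraction(prevalence, "prevalence", open_upper = TRUE)
  if (!is.numeric(case_af) || any(case_af < 0) || any(case_af > 1))
    stop("case_af must be in [0, 1]", call. = FALSE)
  if (!is.numeric(population_af) || any(population_af < 0) ||
      any(population_af > 1))
    stop("population_af must be in [0, 1]", call. = FALSE)
  raw <- prevalence * case_af / population_af
  if (any(population_af == 0)) {
    warning("population_af is 0: penetrance undefined, returning NA")
    raw[population_af == 0] <- NA_real_
  }
  out <- pmin(raw, 1)
  attr(out, "capped") <- !is.na(raw) & raw > 1
  out
}
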