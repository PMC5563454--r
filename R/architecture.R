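#' Parse a prevalence given as a decimal or a "1/500"-style fraction
#'
#' Disease prevalences are conventionally quoted as "1 in N"; this helper
#' accepts both `"1/500"` (or `"1 / 500"`) and plain decimals, returning a
#' numeric fraction.
#'
#' @param x character or numeric scalar/vector.
#' @return numeric vector of fractions in (0, 1).
#' @examples
#' parse_prevalence("1/500")
#' parse_prevalence(0.002)
#' @export
parse_prevalence <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  out <- vapply(x, function(s) {
    if (grepl("/", s, fixed = TRUE)) {
      parts <- strsplit(s, "/", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stop("cannot parse prevalence: ", s, call. = FALSE)
      num <- suppressWarnings(as.numeric(trimws(parts[1])))
      den <- suppressWarnings(as.numeric(trimws(parts[2])))
      if (is.na(num) || is.na(den) || den == 0)
        stop("cannot parse prevalence: ", s, call. = FALSE)
      num / den
    } else {
      v <- suppressWarnings(as.numeric(s))
      if (is.na(v)) stop("cannot parse prevalence: ", s, call. = FALSE)
      v
    }
  }, numeric(1), USE.NAMES = FALSE)
  out
}

#' Describe the genetic architecture of a Mendelian disease
#'
#' Bundles the parameters that bound how common a pathogenic allele can
#' plausibly be: disease prevalence, inheritance mode, the maximum allelic
#' contribution (the largest share of cases, for dominant disease, or of the
#' gene's pathogenic alleles, for recessive disease, attributable to a single
#' variant), the maximum genetic contribution (the largest share of cases
#' attributable to the gene; recessive only, fixed at 1 for dominant), and
#' penetrance (the probability that a genotype-positive individual is
#' affected).
#'
#' @param prevalence disease prevalence as a fraction in (0, 1); accepts
#'   "1/500"-style strings (see [parse_prevalence()]).
#' @param inheritance `"dominant"` or `"recessive"`.
#' @param max_allelic_contribution fraction in (0, 1].
#' @param penetrance fraction in (0, 1]; defaults to 1 (fully penetrant).
#' @param max_genetic_contribution fraction in (0, 1]; required for
#'   recessive inheritance, forced to 1 for dominant.
#' @param disease optional label carried through to printing.
#' @return an object of class `disease_architecture`.
#' @examples
#' # hypertrophic cardiomyopathy: most common causal variant explains <= 2%
#' # of cases, reported penetrance 0.5
#' disease_architecture("1/500", "dominant", 0.02, penetrance = 0.5)
#' @seealso [max_credible_af()], [disease_preset()]
#' @export
disease_architecture <- function(prevalence,
                                 inheritance = c("dominant", "recessive"),
                                 max_allelic_contribution,
                                 penetrance = 1,
                                 max_genetic_contribution = NULL,
                                 disease = NULL) {
  inheritance <- match.arg(inheritance)
  prevalence <- parse_prevalence(prevalence)
  stop_if_not_fraction(prevalence, "prevalence", open_upper = TRUE)
  stop_if_not_fraction(max_allelic_contribution, "max_allelic_contribution")
  stop_if_not_fraction(penetrance, "penetrance")
  if (inheritance == "recessive") {
    if (is.null(max_genetic_contribution))
      stop("max_genetic_contribution is required for recessive inheritance",
           call. = FALSE)
    stop_if_not_fraction(max_genetic_contribution, "max_genetic_contribution")
  } else {
    max_genetic_contribution <- 1
  }
  structure(
    list(prevalence = prevalence,
         inheritance = inheritance,
         max_allelic_contribution = max_allelic_contribution,
         max_genetic_contribution = max_genetic_contribution,
         penetrance = penetrance,
         disease = disease),
    class = "disease_architecture")
}

# scalar (0,1] check; open_upper excludes 1 (prevalence must be < 1)
stop_if_not_fraction <- function(x, name, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 ||
      (if (open_upper) x >= 1 else x > 1))
    stop(name, " must be a fraction in (0, 1", if (open_upper) ")" else "]",
         ", got ", deparse(substitute(x)), " = ", format(x), call. = FALSE)
  invisible(x)
}

#' @export
print.disease_architecture <- function(x, ...) {
  cat("Disease genetic architecture",
      if (!is.null(x$disease)) paste0(" (", x$disease, ")"), "\n", sep = "")
  cat("  inheritance:              ", x$inheritance, "\n", sep = "")
  cat("  prevalence:               ", format(x$prevalence), "\n", sep = "")
  cat("  max allelic contribution: ", format(x$max_allelic_contribution),
      "\n", sep = "")
  if (x$inheritance == "recessive")
    cat("  max genetic contribution: ", format(x$max_genetic_contribution),
        "\n", sep = "")
  cat("  penetrance:               ", format(x$penetrance), "\n", sep = "")
  invisible(x)
}

#' Maximum credible population allele frequency for a disease
#'
#' The highest true population frequency compatible with a variant being
#' causal for the disease described by `arch`. For dominant disease,
#'
#'   AF_max = prevalence x 1/2 x max allelic contribution / penetrance
#'
#' (the 1/2 converts a per-individual prevalence into a per-chromosome
#' frequency; heterozygous carriers carry one causal chromosome). For
#' recessive disease, under Hardy-Weinberg random mating with free compound
#' heterozygosity among the gene's pathogenic alleles, the summed frequency
#' of the gene's pathogenic alleles satisfies q^2 = prevalence x genetic
#' contribution / penetrance, and a single variant can account for at most
#' the allelic-contribution share of q:
#'
#'   AF_max = sqrt(prevalence x max genetic contribution / penetrance)
#'            x max allelic contribution
#'
#' Results are capped at 1 so that extreme exploratory inputs remain usable.
#'
#' @param arch a [disease_architecture()].
#' @return an object of class `disease_threshold` with elements
#'   `max_credible_af` and `architecture`. Use [predict()][predict.disease_threshold]
#'   to obtain the maximum tolerated allele count in a reference sample.
#' @examples
#' hcm <- disease_architecture("1/500", "dominant", 0.02, penetrance = 0.5)
#' max_credible_af(hcm)                      # 4e-05
#' predict(max_credible_af(hcm), an = 121412)  # 9
#' @export
max_credible_af <- function(arch) {
  if (!inherits(arch, "disease_architecture"))
    stop("arch must be a disease_architecture", call. = FALSE)
  af <- if (arch$inheritance == "dominant") {
    arch$prevalence * 0.5 * arch$max_allelic_contribution / arch$penetrance
  } else {
    sqrt(arch$prevalence * arch$max_genetic_contribution / arch$penetrance) *
      arch$max_allelic_contribution
  }
  structure(list(max_credible_af = min(af, 1), architecture = arch),
            class = "disease_threshold")
}

#' @export
print.disease_threshold <- function(x, digits = 2, ...) {
  cat("Maximum credible population AF",
      if (!is.null(x$architecture$disease))
        paste0(" (", x$architecture$disease, ")"),
      ": ", format(signif(x$max_credible_af, digits)), "\n", sep = "")
  invisible(x)
}

#' Maximum tolerated allele count implied by a disease threshold
#'
#' Applies [max_tolerated_ac()] to the threshold's maximum credible AF: the
#' largest allele count in a reference sample of `an` chromosomes that is
#' consistent, at the given one-sided confidence, with a true population AF
#' at or below the threshold.
#'
#' @param object a `disease_threshold` from [max_credible_af()].
#' @param an allele number (genotyped chromosomes) of the reference sample;
#'   the full ExAC cohort corresponds to 121,412.
#' @param confidence one-sided confidence level, default 0.95.
#' @param ... unused.
#' @return integer vector of maximum tolerated allele counts, one per `an`.
#' @export
predict.disease_threshold <- function(object, an, confidence = 0.95, ...) {
  max_tolerated_ac(object$max_credible_af, an, confidence = confidence)
}

#' Highest penetrance compatible with an observed population frequency
#'
#' Inverts the dominant maximum-credible-AF formula: given a disease
#' prevalence, a maximum allelic contribution, and a variant's observed
#' population AF, returns the largest penetrance under which the variant
#' could still be causal. Values above 1 are capped at 1 (the observation
#' places no constraint); an observed AF of 0 leaves penetrance unconstrained
#' and returns NA with a warning.
#'
#' @param prevalence disease prevalence (fraction, or "1/500"-style string).
#' @param max_allelic_contribution fraction in (0, 1].
#' @param observed_af observed population allele frequency in \[0, 1\].
#' @return numeric penetrance in (0, 1\], or NA when `observed_af` is 0.
#' @examples
#' implied_min_penetrance("1/500", 0.02, 4e-5)  # 0.5
#' implied_min_penetrance("1/500", 0.02, 4e-4)  # 0.05
#' @export
implied_min_penetrance <- function(prevalence, max_allelic_contribution,
                                   observed_af) {
  prevalence <- parse_prevalence(prevalence)
  stop_if_not_fraction(prevalence, "prevalence", open_upper = TRUE)
  stop_if_not_fraction(max_allelic_contribution, "max_allelic_contribution")
  if (!is.numeric(observed_af) || any(observed_af < 0) || any(observed_af > 1))
    stop("observed_af must be in [0, 1]", call. = FALSE)
  out <- prevalence * 0.5 * max_allelic_contribution / observed_af
  if (any(observed_af == 0)) {
    warning("observed_af is 0: any penetrance is compatible; returning NA")
    out[observed_af == 0] <- NA_real_
  }
  pmin(out, 1)
}
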