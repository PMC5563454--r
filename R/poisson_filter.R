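#' Canonical continental population labels
#'
#' The five major continental populations used for popmax aggregation:
#' African/African-American (AFR), admixed American (AMR), East Asian (EAS),
#' non-Finnish European (NFE) and South Asian (SAS). Bottlenecked populations
#' (e.g. Finnish) and residual groupings are excluded by default because
#' founder effects can inflate frequencies of genuinely pathogenic alleles;
#' pass your own label set to the popmax functions to override.
#'
#' @return character vector of population labels.
#' @export
exac_populations <- function() c("AFR", "AMR", "EAS", "NFE", "SAS")

#' Maximum tolerated allele count in a finite reference sample
#'
#' The number of observations of an allele in a sample of `an` chromosomes
#' is modelled as Poisson with mean `af * an`. The maximum tolerated allele
#' count is the allele count at the upper bound of the one-tailed confidence
#' interval: the smallest integer k whose Poisson CDF at that mean is at
#' least `confidence`. A variant observed more often than this is unlikely
#' (at the 1 - confidence error rate) to have a true population frequency at
#' or below `af`.
#'
#' @param af maximum credible population allele frequency, in \[0, 1\].
#'   Vectorised.
#' @param an allele number (genotyped chromosomes), non-negative. Vectorised.
#' @param confidence one-sided confidence level in (0, 1), default 0.95.
#' @return integer vector of maximum tolerated allele counts.
#' @examples
#' max_tolerated_ac(1e-4, 100000)   # a true AF of 1e-4 yields <= 15 alleles
#' max_tolerated_ac(4e-5, 121412)   # 9
#' @export
max_tolerated_ac <- function(af, an, confidence = 0.95) {
  check_confidence(confidence)
  if (!is.numeric(af) || any(is.na(af)) || any(af < 0) || any(af > 1))
    stop("af must be in [0, 1]", call. = FALSE)
  if (!is.numeric(an) || any(is.na(an)) || any(an < 0))
    stop("an must be non-negative", call. = FALSE)
  as.integer(qpois(confidence, af * an))
}

check_confidence <- function(confidence) {
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      is.na(confidence) || confidence <= 0 || confidence >= 1)
    stop("confidence must be in (0, 1)", call. = FALSE)
  invisible(confidence)
}

#' Filtering allele frequency of an observed allele count
#'
#' Inverts [max_tolerated_ac()] per variant: the filtering AF is the highest
#' maximum-credible-AF threshold at which the variant's observed allele
#' count would still be deemed too common — equivalently, the largest
#' multiple of `granularity` (millionths by default) whose maximum tolerated
#' AC is strictly below the observed AC. A disease-specific filter then
#' removes the variant whenever its filtering AF is greater than or equal to
#' the disease's maximum credible AF.
#'
#' Variants observed at most once get a filtering AF of 0 (never filtered):
#' a single observation carries almost no information about the true
#' frequency. The boundary is located in closed form via the gamma-Poisson
#' identity (the largest Poisson mean with CDF at `ac - 1` still >=
#' `confidence` is the lower `1 - confidence` quantile of a Gamma(ac)
#' distribution) and then snapped to the granularity grid, with an explicit
#' check so results are identical to a brute-force grid scan.
#'
#' @param ac observed allele count, non-negative integer. Vectorised.
#' @param an allele number, with `ac <= an`. Vectorised.
#' @param confidence one-sided confidence level, default 0.95.
#' @param granularity grid step for the returned frequency, default 1e-6.
#' @return numeric vector of filtering AFs (multiples of `granularity`).
#' @examples
#' filtering_af(2, 10000)    # 3.5e-05
#' filtering_af(1, 121412)   # 0: singletons are never filtered
#' @export
filtering_af <- function(ac, an, confidence = 0.95, granularity = 1e-6) {
  check_confidence(confidence)
  if (!is.numeric(granularity) || length(granularity) != 1L ||
      is.na(granularity) || granularity <= 0 || granularity >= 1)
    stop("granularity must be in (0, 1)", call. = FALSE)
  if (!is.numeric(ac) || any(is.na(ac)) || any(ac < 0) ||
      !is.numeric(an) || any(is.na(an)) || any(an < 0))
    stop("ac and an must be non-negative", call. = FALSE)
  if (any(ac > an))
    stop("ac exceeds an: inconsistent counts", call. = FALSE)
  n <- max(length(ac), length(an))
  ac <- rep_len(ac, n); an <- rep_len(an, n)
  vapply(seq_len(n), function(i)
    filtering_af_scalar(ac[i], an[i], confidence, granularity), numeric(1))
}

filtering_af_scalar <- function(ac, an, confidence, granularity) {
  if (ac <= 1 || an == 0) return(0)
  # largest lambda with ppois(ac - 1, lambda) >= confidence
  lambda_star <- qgamma(1 - confidence, shape = ac)
  m <- floor(lambda_star / an / granularity + 1e-9)
  # snap to the grid exactly as the grid-scan definition demands
  while (max_tolerated_ac((m + 1) * granularity, an, confidence) < ac)
    m <- m + 1
  while (m > 0 && max_tolerated_ac(m * granularity, an, confidence) >= ac)
    m <- m - 1
  m * granularity
}

#' Popmax filtering allele frequency across populations
#'
#' Computes [filtering_af()] for each population's AC/AN and returns the
#' highest value with the population attaining it: a variant relatively
#' common in any one continental population is unlikely to be pathogenic
#' even if rare elsewhere. Populations with allele number 0 (or below
#' `min_an`) are excluded rather than treated as frequency 0; ties are
#' broken in favour of the first population in `populations` order.
#'
#' @param counts a data.frame with columns `population`, `ac`, `an`
#'   (one row per population at one variant site).
#' @param confidence one-sided confidence level, default 0.95.
#' @param granularity grid step, default 1e-6.
#' @param populations labels participating in popmax, in canonical tie-break
#'   order; rows with other labels are ignored. Default [exac_populations()].
#' @param min_an populations with `an < min_an` or `an == 0` are excluded.
#' @return an object of class `filtering_result`: list with
#'   `per_population` (named numeric), `popmax_af`, `popmax_population`
#'   (NA when no population is eligible), and `confidence`.
#' @examples
#' popmax_filtering_af(data.frame(population = c("AFR", "NFE"),
#'                                ac = c(0, 2), an = c(8000, 10000)))
#' @export
popmax_filtering_af <- function(counts, confidence = 0.95,
                                granularity = 1e-6,
                                populations = exac_populations(),
                                min_an = 0) {
  if (!is.data.frame(counts) ||
      !all(c("population", "ac", "an") %in% names(counts)))
    stop("counts must be a data.frame with columns population, ac, an",
         call. = FALSE)
  if (nrow(counts) == 0L)
    stop("counts is empty: at least one population is required", call. = FALSE)
  counts$population <- as.character(counts$population)
  counts <- counts[counts$population %in% populations, , drop = FALSE]
  # canonical order fixes the tie-break
  counts <- counts[order(match(counts$population, populations)), , drop = FALSE]
  eligible <- !is.na(counts$an) & counts$an > 0 & counts$an >= min_an
  counts <- counts[eligible, , drop = FALSE]
  if (nrow(counts) == 0L) {
    res <- list(per_population = setNames(numeric(0), character(0)),
                popmax_af = 0, popmax_population = NA_character_,
                confidence = confidence)
    return(structure(res, class = "filtering_result"))
  }
  faf <- filtering_af(counts$ac, counts$an, confidence, granularity)
  names(faf) <- counts$population
  imax <- which.max(faf)  # first max under canonical order
  structure(list(per_population = faf,
                 popmax_af = unname(faf[imax]),
                 popmax_population = counts$population[imax],
                 confidence = confidence),
            class = "filtering_result")
}

#' @export
print.filtering_result <- function(x, ...) {
  cat("Filtering AF (one-sided confidence ", format(x$confidence), ")\n",
      sep = "")
  if (length(x$per_population)) {
    for (p in names(x$per_population))
      cat(sprintf("  %-4s %g\n", p, x$per_population[[p]]))
  } else {
    cat("  (no population with non-zero allele number)\n")
  }
  cat("  popmax: ", format(x$popmax_af),
      if (!is.na(x$popmax_population)) paste0(" (", x$popmax_population, ")"),
      "\n", sep = "")
  invisible(x)
}
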