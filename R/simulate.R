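#' Configuration for a synthetic multi-population reference panel
#'
#' Describes a panel of variant sites genotyped across several continental
#' populations: how many sites, how many chromosomes per population, the
#' shape of the site-frequency spectrum, how far per-population frequencies
#' diverge from the global frequency, and a number of "pathogenic-like"
#' spiked sites with true population frequency 0 (absent from the panel, as
#' a rare fully ascertainment-free causal variant would be). Global
#' frequencies are drawn from a discretised 1/x density truncated to
#' `[sfs_min, sfs_max]` — a neutral-like spectrum heavy in rare variants —
#' and perturbed per population on the logit scale with standard deviation
#' `divergence`.
#'
#' @param n_sites number of segregating sites, default 1000.
#' @param populations population labels, default [exac_populations()].
#' @param an chromosomes genotyped per population (recycled), default
#'   20000 — a desk-scale panel rather than a full exome aggregate.
#' @param sfs_min,sfs_max truncation of the frequency spectrum, defaults
#'   1e-6 and 0.5.
#' @param divergence logit-scale SD of per-population perturbation,
#'   default 0.5.
#' @param n_pathogenic number of spiked zero-frequency sites, default 0.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_sites = 1000,
                              populations = exac_populations(),
                              an = 20000,
                              sfs_min = 1e-6, sfs_max = 0.5,
                              divergence = 0.5,
                              n_pathogenic = 0,
                              seed = 1) {
  if (n_sites < 1 || n_pathogenic < 0)
    stop("n_sites must be positive and n_pathogenic non-negative",
         call. = FALSE)
  an <- rep_len(as.integer(an), length(populations))
  if (all(an == 0)) stop("all populations have an = 0", call. = FALSE)
  if (any(an < 0)) stop("an must be non-negative", call. = FALSE)
  if (sfs_min <= 0 || sfs_max > 1 || sfs_min >= sfs_max)
    stop("require 0 < sfs_min < sfs_max <= 1", call. = FALSE)
  structure(list(n_sites = as.integer(n_sites),
                 populations = as.character(populations),
                 an = stats::setNames(an, populations),
                 sfs_min = sfs_min, sfs_max = sfs_max,
                 divergence = divergence,
                 n_pathogenic = as.integer(n_pathogenic),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Simulate a multi-population reference panel
#'
#' Draws a global true AF per site from the configured spectrum, perturbs
#' it per population (logit-normal), and draws each population's observed
#' allele count as Binomial(AN, population AF). Spiked pathogenic-like
#' sites have true AF 0 everywhere and hence AC 0. Fully reproducible under
#' the config seed.
#'
#' @param config a [simulation_config()].
#' @return object of class `reference_panel`: list with `truth` (data.frame
#'   of per-site global and per-population true AFs, and a `pathogenic`
#'   flag) and `counts` (data.frame in the [read_population_counts()]
#'   layout, ready for [annotate_filtering_af()]).
#' @export
simulate_reference_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  pops <- config$populations
  n_bg <- config$n_sites
  n_all <- n_bg + config$n_pathogenic
  # inverse-CDF sample from density 1/x on [min, max]
  u <- runif(n_bg)
  p_global <- config$sfs_min * (config$sfs_max / config$sfs_min)^u
  p_global <- c(p_global, rep(0, config$n_pathogenic))
  pathogenic <- c(rep(FALSE, n_bg), rep(TRUE, config$n_pathogenic))
  truth <- data.frame(
    variant_id = sprintf("1:%d_A/T", seq_len(n_all) * 100L),
    chrom = "1", pos = seq_len(n_all) * 100L,
    ref = "A", alt = "T",
    true_af = p_global, pathogenic = pathogenic,
    stringsAsFactors = FALSE)
  counts <- truth[, c("variant_id", "chrom", "pos", "ref", "alt")]
  counts$has_counts <- TRUE
  for (p in pops) {
    pp <- ifelse(p_global > 0,
                 inv_logit(logit(pmin(pmax(p_global, 1e-12), 1 - 1e-12)) +
                             rnorm(n_all, 0, config$divergence)),
                 0)
    truth[[paste0("true_af_", p)]] <- pp
    counts[[paste0("ac_", p)]] <- rbinom(n_all, config$an[[p]], pp)
    counts[[paste0("an_", p)]] <- config$an[[p]]
  }
  structure(list(truth = truth, counts = counts, config = config),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("Synthetic reference panel: ", nrow(x$counts), " sites (",
      sum(x$truth$pathogenic), " pathogenic-like), populations ",
      paste(x$config$populations, collapse = ", "), ", seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a simulated panel as VCF plus truth table
#'
#' Emits a VCF with per-population `AC_<POP>`/`AN_<POP>` INFO fields (the
#' layout [read_population_counts()] consumes) and a tab-separated truth
#' table of the true allele frequencies. Output is byte-identical for a
#' fixed config seed.
#'
#' @param panel a `reference_panel` from [simulate_reference_panel()].
#' @param vcf_path path of the VCF to write.
#' @param truth_path optional path of the truth TSV.
#' @return invisibly, `vcf_path`.
#' @export
write_panel_vcf <- function(panel, vcf_path, truth_path = NULL) {
  stopifnot(inherits(panel, "reference_panel"))
  pops <- panel$config$populations
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=1>",
           unlist(lapply(pops, function(p) c(
             sprintf("##INFO=<ID=AC_%s,Number=A,Type=Integer,Description=\"Alternate allele count in %s\">", p, p),
             sprintf("##INFO=<ID=AN_%s,Number=1,Type=Integer,Description=\"Allele number in %s\">", p, p)))),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  cn <- panel$counts
  info <- vapply(seq_len(nrow(cn)), function(i)
    paste(unlist(lapply(pops, function(p)
      c(sprintf("AC_%s=%d", p, cn[[paste0("ac_", p)]][i]),
        sprintf("AN_%s=%d", p, cn[[paste0("an_", p)]][i])))),
      collapse = ";"), character(1))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                  cn$chrom, cn$pos, cn$ref, cn$alt, info)
  writeLines(c(hdr, body), vcf_path)
  if (!is.null(truth_path))
    utils::write.table(panel$truth, truth_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(vcf_path)
}

#' Desk-scale filtering-efficiency experiment
#'
#' Emulates a Mendelian variant-discovery analysis: held-out carrier
#' samples are drawn from the same frequency spectrum as a simulated
#' reference panel, their variants are annotated with popmax filtering AFs
#' derived from the panel, and the mean number of variants retained per
#' sample is reported across a ladder of maximum-credible-AF cutoffs.
#' Each sample is a diploid individual from one population (cycled across
#' populations) carrying each background site with probability
#' 1 - (1 - AF)^2; when the panel contains spiked pathogenic-like sites,
#' each sample additionally carries one of them, as the causal variant of a
#' simulated proband absent from the reference.
#'
#' Tightening the cutoff (lowering the maximum credible AF) filters more
#' variants, so mean retained counts are non-decreasing in the cutoff.
#' Pathogenic-like sites have filtering AF 0 and are retained at any
#' positive cutoff.
#'
#' @param config a [simulation_config()].
#' @param cutoffs increasing vector of maximum credible AFs to filter at.
#' @param n_samples number of held-out samples, default 50.
#' @param confidence one-sided confidence level, default 0.95.
#' @return data.frame with one row per cutoff: `cutoff`, `mean_retained`
#'   (mean variants per sample surviving the filter), and
#'   `pathogenic_retained` (fraction of carried pathogenic-like sites
#'   retained; NaN when none were spiked).
#' @export
filtering_efficiency_experiment <- function(config, cutoffs,
                                            n_samples = 50,
                                            confidence = 0.95) {
  stopifnot(inherits(config, "simulation_config"))
  if (any(cutoffs <= 0) || is.unsorted(cutoffs))
    stop("cutoffs must be positive and sorted increasing", call. = FALSE)
  panel <- simulate_reference_panel(config)
  ann <- annotate_filtering_af(panel$counts, confidence = confidence,
                               populations = config$populations)
  faf <- ann$faf_popmax
  pops <- config$populations
  n_sites <- nrow(ann)
  is_path <- panel$truth$pathogenic
  path_idx <- which(is_path)
  retained <- matrix(0, n_samples, length(cutoffs))
  path_carried <- 0L
  path_retained <- numeric(length(cutoffs))
  for (s in seq_len(n_samples)) {
    pop <- pops[((s - 1L) %% length(pops)) + 1L]
    p_pop <- panel$truth[[paste0("true_af_", pop)]]
    carry_prob <- 1 - (1 - p_pop)^2
    carried <- runif(n_sites) < carry_prob
    if (length(path_idx)) {
      causal <- path_idx[((s - 1L) %% length(path_idx)) + 1L]
      carried[causal] <- TRUE
    }
    for (j in seq_along(cutoffs)) {
      keep <- carried & (faf < cutoffs[j])
      retained[s, j] <- sum(keep)
      if (length(path_idx))
        path_retained[j] <- path_retained[j] + sum(keep & is_path)
    }
    if (length(path_idx)) path_carried <- path_carried + sum(carried & is_path)
  }
  data.frame(cutoff = cutoffs,
             mean_retained = colMeans(retained),
             pathogenic_retained = path_retained / path_carried)
}
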