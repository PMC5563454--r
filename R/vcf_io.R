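#' Read per-population allele counts from a VCF
#'
#' Parses a VCF whose INFO fields carry per-population allele counts and
#' allele numbers (ExAC/gnomAD style, e.g. `AC_NFE`/`AN_NFE`), decomposing
#' multi-allelic lines into one record per alternate allele with
#' allele-indexed (Number=A) INFO values aligned to the correct alt.
#' Populations whose AN is missing at a record are treated as absent from
#' that record; records where any population has AC > AN are dropped with a
#' warning. Records carrying none of the mapped INFO keys are kept with
#' empty counts and flagged in the `has_counts` column.
#'
#' @param path VCF file (plain or bgzipped).
#' @param populations population labels to extract, default
#'   [exac_populations()].
#' @param ac_pattern,an_pattern `sprintf` patterns mapping a population
#'   label to its INFO keys, defaults `"AC_%s"` / `"AN_%s"`.
#' @param genome genome tag passed to the VCF reader (metadata only).
#' @return a data.frame with one row per (site, alt allele): columns
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`, `has_counts`, and per
#'   population `ac_<POP>` and `an_<POP>` (NA where absent).
#' @export
read_population_counts <- function(path, populations = exac_populations(),
                                   ac_pattern = "AC_%s",
                                   an_pattern = "AN_%s",
                                   genome = "unknown") {
  vcf <- VariantAnnotation::readVcf(path, genome = genome)
  vcf <- VariantAnnotation::expand(vcf)
  vcf_to_counts(vcf, populations, ac_pattern, an_pattern)$counts
}

# shared extraction from an expanded VCF object
vcf_to_counts <- function(vcf, populations, ac_pattern = "AC_%s",
                          an_pattern = "AN_%s") {
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(VariantAnnotation::alt(vcf)),
    stringsAsFactors = FALSE)
  df$variant_id <- paste0(df$chrom, ":", df$pos, "_", df$ref, "/", df$alt)
  n <- nrow(df)
  any_key <- rep(FALSE, n)
  for (p in populations) {
    ack <- sprintf(ac_pattern, p); ank <- sprintf(an_pattern, p)
    ac <- if (ack %in% names(info)) scalarize_info(info[[ack]], n) else
      rep(NA_real_, n)
    an <- if (ank %in% names(info)) scalarize_info(info[[ank]], n) else
      rep(NA_real_, n)
    any_key <- any_key | !is.na(ac) | !is.na(an)
    # an AC without a usable AN carries no frequency information
    ac[is.na(an)] <- NA_real_
    df[[paste0("ac_", p)]] <- ac
    df[[paste0("an_", p)]] <- an
  }
  df$has_counts <- any_key
  if (any(!any_key))
    message(sum(!any_key), " record(s) carry none of the mapped AC/AN keys")
  bad <- rep(FALSE, n)
  for (p in populations) {
    ac <- df[[paste0("ac_", p)]]; an <- df[[paste0("an_", p)]]
    bad <- bad | (!is.na(ac) & !is.na(an) & ac > an)
  }
  if (any(bad)) {
    warning(sum(bad), " record(s) with AC > AN skipped: ",
            paste(utils::head(df$variant_id[bad], 5), collapse = ", "))
    df <- df[!bad, , drop = FALSE]
    vcf <- vcf[!bad, ]
  }
  cols <- c("variant_id", "chrom", "pos", "ref", "alt", "has_counts",
            unlist(lapply(populations, function(p)
              paste0(c("ac_", "an_"), p))))
  list(counts = df[, cols], vcf = vcf)
}

# collapse a per-record INFO column (atomic or List of length-1 after
# expand()) to a plain numeric vector
scalarize_info <- function(x, n) {
  if (is.atomic(x)) return(as.numeric(x))
  vapply(as.list(x), function(v)
    if (length(v) == 0L || is.na(v[1])) NA_real_ else as.numeric(v[1]),
    numeric(1))
}

#' Annotate variant records with per-population and popmax filtering AFs
#'
#' For each record, computes [filtering_af()] from each population's AC/AN
#' and the popmax across populations. Works on the data.frame returned by
#' [read_population_counts()] (or any frame with `ac_<POP>`/`an_<POP>`
#' columns).
#'
#' @param records data.frame with `ac_<POP>`/`an_<POP>` columns.
#' @param confidence one-sided confidence level, default 0.95.
#' @param granularity filtering-AF grid step, default 1e-6.
#' @param populations populations participating in popmax.
#' @return `records` with added columns `faf_<POP>` (NA where the
#'   population is absent), `faf_popmax` and `faf_popmax_pop`.
#' @export
annotate_filtering_af <- function(records, confidence = 0.95,
                                  granularity = 1e-6,
                                  populations = exac_populations()) {
  present <- populations[paste0("an_", populations) %in% names(records)]
  if (length(present) == 0L)
    stop("records carry no ac_<POP>/an_<POP> columns for ",
         paste(populations, collapse = ", "), call. = FALSE)
  n <- nrow(records)
  faf <- matrix(NA_real_, n, length(present),
                dimnames = list(NULL, present))
  for (p in present) {
    ac <- records[[paste0("ac_", p)]]
    an <- records[[paste0("an_", p)]]
    ok <- !is.na(ac) & !is.na(an) & an > 0
    if (any(ok))
      faf[ok, p] <- filtering_af(ac[ok], an[ok], confidence, granularity)
  }
  for (p in present) records[[paste0("faf_", p)]] <- faf[, p]
  all_na <- apply(faf, 1L, function(r) all(is.na(r)))
  popmax <- apply(faf, 1L, function(r) if (all(is.na(r))) 0 else
    max(r, na.rm = TRUE))
  # first population attaining the max, in canonical order
  popmax_pop <- vapply(seq_len(n), function(i) {
    r <- faf[i, ]
    if (all(is.na(r))) NA_character_ else present[which.max(r)]
  }, character(1))
  records$faf_popmax <- popmax
  records$faf_popmax_pop <- popmax_pop
  if (any(all_na))
    message(sum(all_na), " record(s) had no eligible population; popmax 0")
  records
}

#' Annotate a VCF with filtering allele frequencies
#'
#' Reads a VCF with per-population AC/AN INFO fields, decomposes
#' multi-allelic sites, computes per-population and popmax filtering AFs,
#' and writes a VCF with new INFO keys (`FAF95_<POP>`, `FAF95_popmax`,
#' `FAF95_popmax_pop` by default, declared in the header with Number=A
#' semantics) while passing all other fields through. Values are written at
#' 6 decimal digits, matching the default 1e-6 granularity.
#'
#' @inheritParams read_population_counts
#' @param output path of the VCF to write (plain text, or bgzipped when
#'   ending in `.gz`).
#' @param confidence one-sided confidence level, default 0.95.
#' @param granularity filtering-AF grid step, default 1e-6.
#' @param key_prefix prefix of the INFO keys written, default `"FAF95"`.
#' @return invisibly, the annotated records data.frame.
#' @export
annotate_vcf <- function(path, output, populations = exac_populations(),
                         confidence = 0.95, granularity = 1e-6,
                         ac_pattern = "AC_%s", an_pattern = "AN_%s",
                         key_prefix = "FAF95", genome = "unknown") {
  vcf <- VariantAnnotation::readVcf(path, genome = genome)
  vcf <- VariantAnnotation::expand(vcf)
  parsed <- vcf_to_counts(vcf, populations, ac_pattern, an_pattern)
  ann <- annotate_filtering_af(parsed$counts, confidence, granularity,
                               populations)
  vcf <- parsed$vcf
  present <- populations[paste0("faf_", populations) %in% names(ann)]
  hdr <- VariantAnnotation::header(vcf)
  digits <- max(0, ceiling(-log10(granularity)))
  keys <- c(paste0(key_prefix, "_", present),
            paste0(key_prefix, "_popmax"), paste0(key_prefix, "_popmax_pop"))
  newhdr <- S4Vectors::DataFrame(
    Number = rep("A", length(keys)),
    Type = c(rep("Float", length(present) + 1L), "String"),
    Description = c(
      sprintf("Filtering allele frequency (one-sided %g%% CI) in %s",
              100 * confidence, present),
      sprintf("Highest per-population filtering allele frequency (one-sided %g%% CI)",
              100 * confidence),
      "Population attaining the popmax filtering allele frequency"),
    row.names = keys)
  VariantAnnotation::info(hdr) <-
    rbind(VariantAnnotation::info(hdr), newhdr)
  VariantAnnotation::header(vcf) <- hdr
  inf <- VariantAnnotation::info(vcf)
  for (p in present)
    inf[[paste0(key_prefix, "_", p)]] <-
      round(ann[[paste0("faf_", p)]], digits)
  inf[[paste0(key_prefix, "_popmax")]] <- round(ann$faf_popmax, digits)
  pop <- ann$faf_popmax_pop
  pop[is.na(pop)] <- "."
  inf[[paste0(key_prefix, "_popmax_pop")]] <- pop
  VariantAnnotation::info(vcf) <- inf
  VariantAnnotation::writeVcf(vcf, output)
  invisible(ann)
}

#' Apply a disease-specific frequency filter to annotated records
#'
#' A variant is filtered when its popmax filtering AF is greater than or
#' equal to the disease's maximum credible population AF; otherwise it
#' remains a candidate. Lower thresholds therefore filter more variants.
#'
#' @param records annotated data.frame carrying a `faf_popmax` column (from
#'   [annotate_filtering_af()] or [annotate_vcf()]).
#' @param threshold a `disease_threshold` from [max_credible_af()], or a
#'   bare numeric maximum credible AF.
#' @return `records` with added columns `threshold_used` and `decision`
#'   (factor, `"filtered"`/`"retained"`); a summary message reports counts.
#' @examples
#' rec <- data.frame(variant_id = "v1", ac_NFE = 2, an_NFE = 10000)
#' rec <- annotate_filtering_af(rec)
#' apply_disease_filter(rec, 4e-5)
#' @export
apply_disease_filter <- function(records, threshold) {
  t <- if (inherits(threshold, "disease_threshold"))
    threshold$max_credible_af else threshold
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t <= 0 || t > 1)
    stop("threshold must be a disease_threshold or a fraction in (0, 1]",
         call. = FALSE)
  if (!("faf_popmax" %in% names(records)))
    stop("records are not annotated: run annotate_filtering_af() first",
         call. = FALSE)
  if (any(is.na(records$faf_popmax))) {
    bad <- records$variant_id[is.na(records$faf_popmax)]
    stop("unannotated record(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  records$threshold_used <- t
  records$decision <- factor(
    ifelse(records$faf_popmax >= t, "filtered", "retained"),
    levels = c("filtered", "retained"))
  message(sum(records$decision == "filtered"), " filtered, ",
          sum(records$decision == "retained"), " retained at threshold ",
          format(t))
  records
}

#' Filter a VCF against a disease threshold
#'
#' Annotates the VCF (unless it already carries popmax filtering-AF keys)
#' and writes a VCF containing only the retained records — those whose
#' popmax filtering AF is below the disease's maximum credible AF.
#'
#' @inheritParams annotate_vcf
#' @param threshold `disease_threshold`, bare numeric maximum credible AF,
#'   or a disease name resolvable by [disease_preset()].
#' @return invisibly, the full decision data.frame (both filtered and
#'   retained records).
#' @export
filter_vcf <- function(path, output, threshold,
                       populations = exac_populations(),
                       confidence = 0.95, granularity = 1e-6,
                       ac_pattern = "AC_%s", an_pattern = "AN_%s",
                       genome = "unknown") {
  if (is.character(threshold))
    threshold <- max_credible_af(disease_preset(threshold)$architecture)
  vcf <- VariantAnnotation::readVcf(path, genome = genome)
  vcf <- VariantAnnotation::expand(vcf)
  parsed <- vcf_to_counts(vcf, populations, ac_pattern, an_pattern)
  ann <- annotate_filtering_af(parsed$counts, confidence, granularity,
                               populations)
  decisions <- apply_disease_filter(ann, threshold)
  keep <- decisions$decision == "retained"
  VariantAnnotation::writeVcf(parsed$vcf[keep, ], output)
  invisible(decisions)
}
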