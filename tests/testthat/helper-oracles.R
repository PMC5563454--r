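# independent oracles: direct probability-mass summation, no quantile calls

# smallest k with sum_{i<=k} Poisson pmf(i; lambda) >= confidence
oracle_max_tolerated_ac <- function(af, an, confidence = 0.95) {
  lambda <- af * an
  k_hi <- max(10, ceiling(lambda + 20 * sqrt(lambda) + 20))
  cdf <- cumsum(dpois(0:k_hi, lambda))
  which(cdf >= confidence)[1] - 1L
}

# exhaustive scan over multiples of `granularity`: largest f with
# tolerated AC < ac (0 for ac <= 1)
oracle_filtering_af <- function(ac, an, confidence = 0.95,
                                granularity = 1e-6) {
  if (ac <= 1 || an == 0) return(0)
  m <- 1
  repeat {
    if (qpois(confidence, m * granularity * an) >= ac)
      return((m - 1) * granularity)
    m <- m + 1
  }
}

# fixture VCF exercising multi-allelic decomposition, a missing-INFO line,
# and (optionally) an inconsistent AC > AN line
write_test_vcf <- function(path, include_bad = FALSE) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##INFO=<ID=AC_AFR,Number=A,Type=Integer,Description=\"AFR AC\">",
    "##INFO=<ID=AN_AFR,Number=1,Type=Integer,Description=\"AFR AN\">",
    "##INFO=<ID=AC_NFE,Number=A,Type=Integer,Description=\"NFE AC\">",
    "##INFO=<ID=AN_NFE,Number=1,Type=Integer,Description=\"NFE AN\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "1\t100\t.\tA\tT\t.\t.\tAC_AFR=0;AN_AFR=8000;AC_NFE=2;AN_NFE=10000",
    "1\t200\t.\tG\tC,T\t.\t.\tAC_AFR=1,5;AN_AFR=8000;AC_NFE=2,7;AN_NFE=10000",
    "1\t300\t.\tT\tG\t.\t.\tAN_AFR=8000",
    "1\t350\t.\tA\tC\t.\t.\tAC_AFR=1;AN_AFR=8000;AC_NFE=0;AN_NFE=10000",
    "1\t400\t.\tC\tA\t.\t.\t.",
    if (include_bad)
      "1\t500\t.\tG\tA\t.\t.\tAC_AFR=9000;AN_AFR=8000;AC_NFE=1;AN_NFE=10000")
  writeLines(lines, path)
  path
}
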