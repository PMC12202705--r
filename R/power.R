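# Probability of failing to observe a clonal somatic mutation given tumor
# purity, zygosity and sequencing coverage.

#' Expected variant allele fraction from tumor purity
#'
#' A clonal mutation present in every tumor-lineage cell appears in reads
#' at `f = phi * zygosity_factor`: half the tumor DNA fraction for a
#' heterozygous variant, all of it for a homozygous one.
#'
#' @param tumor_fraction tumor-derived DNA fraction `phi` in `(0, 1]`.
#' @param zygosity_factor fraction of tumor-cell alleles carrying the
#'   variant, in `(0, 1]`; default `0.5` (heterozygous).
#' @return the allele fraction `f`.
#' @examples
#' allele_fraction(0.19)   # 0.095
#' @export
allele_fraction <- function(tumor_fraction, zygosity_factor = 0.5) {
  phi <- check_scalar(tumor_fraction, "tumor_fraction", lower = 0,
                      upper = 1, lower_open = TRUE)
  z <- check_scalar(zygosity_factor, "zygosity_factor", lower = 0,
                    upper = 1, lower_open = TRUE)
  phi * z
}

#' Probability of missing a clonal mutation at given coverage
#'
#' Models detection as observing at least `min_supporting_reads` variant
#' reads among `coverage` independent reads, each carrying the variant with
#' probability `f = tumor_fraction * zygosity_factor`. The miss probability
#' is the lower binomial tail `P(X < m)`, which for the default `m = 1`
#' reduces to the closed form `(1 - f)^coverage`.
#'
#' Requiring more than one supporting read (`min_supporting_reads > 1`)
#' reflects real variant callers and is provided as an extension of the
#' single-read detection model.
#'
#' @param coverage number of reads covering the site (non-negative).
#' @param tumor_fraction tumor-derived DNA fraction `phi` in `(0, 1]`.
#' @param zygosity_factor see [allele_fraction()]; default heterozygous.
#' @param min_supporting_reads reads required to call the variant
#'   (default 1).
#' @return an object of class `power_result` with fields
#'   `allele_fraction`, `p_miss`, `p_detect`, `p_miss_percent` (the miss
#'   probability on the percent scale, unrounded), plus the query fields.
#' @examples
#' p_miss(coverage = 40, tumor_fraction = 0.19)   # ~1.8%
#' @export
p_miss <- function(coverage, tumor_fraction, zygosity_factor = 0.5,
                   min_supporting_reads = 1L) {
  coverage <- check_scalar(coverage, "coverage", lower = 0, integer = TRUE)
  m <- check_scalar(min_supporting_reads, "min_supporting_reads",
                    lower = 1, integer = TRUE)
  f <- allele_fraction(tumor_fraction, zygosity_factor)
  if (m > coverage) {
    warning("min_supporting_reads (", m, ") exceeds coverage (", coverage,
            "); the mutation can never be detected", call. = FALSE)
  }
  p <- stats::pbinom(m - 1L, size = coverage, prob = f)
  structure(
    list(allele_fraction = f,
         p_miss = p,
         p_detect = 1 - p,
         p_miss_percent = 100 * p,
         coverage = coverage,
         tumor_fraction = tumor_fraction,
         zygosity_factor = zygosity_factor,
         min_supporting_reads = m),
    class = "power_result"
  )
}

#' Format a percentage at reporting precision
#'
#' Rounds to a given number of significant figures (default 2, e.g.
#' `0.036`), the convention used for reporting miss probabilities.
#'
#' @param x percentage value(s).
#' @param digits significant figures.
#' @return numeric vector rounded for reporting.
#' @export
format_percent <- function(x, digits = 2L) {
  signif(x, digits)
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    paste0("Mutation detection at %dX coverage ",
           "(tumor fraction %.3g, allele fraction %.3g):\n"),
    x$coverage, x$tumor_fraction, x$allele_fraction
  ))
  cat(sprintf("  P(miss)   = %.4g (%.2g%%)\n", x$p_miss, x$p_miss_percent))
  cat(sprintf("  P(detect) = %.4g\n", x$p_detect))
  if (x$min_supporting_reads > 1L) {
    cat(sprintf("  (requiring >= %d supporting reads)\n",
                x$min_supporting_reads))
  }
  invisible(x)
}
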