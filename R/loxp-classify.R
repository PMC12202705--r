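# Junction classification of loxP-containing reads and tumor-purity
# estimation from the class counts.

#' Classify loxP-spanning reads into junction classes
#'
#' Scans each read (and, by default, its reverse complement) for exact
#' occurrences of the 34-bp loxP core. Every hit with at least `min_flank`
#' context bases on both sides is assigned by comparing those bases with
#' the configured flanks: upstream matching `A` and downstream `B` is an
#' unrecombined 5' site, `C`/`D` an unrecombined 3' site, and `A`/`D` the
#' recombined junction; any other combination — or a hit too close to a
#' read end to expose `min_flank` bases — is ambiguous. A read increments
#' each class at most once, so an overlapping fragment is never counted
#' twice for the same junction.
#'
#' @param reads one of: a path to a FASTA/FASTQ file (optionally
#'   gzip-compressed, recognized by extension), a
#'   [`Biostrings::DNAStringSet`], or a character vector of sequences.
#' @param config a [loxp_config()].
#' @return an object of class `loxp_class_counts` with fields `u5`, `u3`,
#'   `rec`, `ambiguous`, `total_core_hits` (the sum of the four) and
#'   attribute `n_reads` (records scanned).
#' @seealso [estimate_purity()]
#' @export
classify_reads <- function(reads, config) {
  stopifnot(inherits(config, "loxp_config"))
  seqs <- as_sequence_vector(reads)
  k <- config$min_flank
  core <- config$core
  up_a <- substring(config$flank_5prime_up,
                    nchar(config$flank_5prime_up) - k + 1L)
  up_c <- substring(config$flank_3prime_up,
                    nchar(config$flank_3prime_up) - k + 1L)
  down_b <- substring(config$flank_5prime_down, 1L, k)
  down_d <- substring(config$flank_3prime_down, 1L, k)
  tol <- config$max_flank_mismatch
  matches <- function(x, key) {
    nchar(x) == nchar(key) && hamming(x, key) <= tol
  }

  classify_hit <- function(seq, pos) {
    if (pos - k < 1L || pos + 34L + k - 1L > nchar(seq)) return("ambiguous")
    up <- substring(seq, pos - k, pos - 1L)
    down <- substring(seq, pos + 34L, pos + 34L + k - 1L)
    up_is_a <- matches(up, up_a)
    up_is_c <- matches(up, up_c)
    down_is_b <- matches(down, down_b)
    down_is_d <- matches(down, down_d)
    if (up_is_a && down_is_b) "u5"
    else if (up_is_c && down_is_d) "u3"
    else if (up_is_a && down_is_d) "rec"
    else "ambiguous"
  }

  counts <- c(u5 = 0L, u3 = 0L, rec = 0L, ambiguous = 0L)
  seqs <- toupper(seqs)
  bad <- is.na(seqs) | nchar(seqs) == 0L | grepl("[^ACGTN]", seqs)
  n_bad <- sum(bad)
  ok <- which(!bad)
  rc <- if (config$scan_both_strands && length(ok)) {
    reverse_complement(seqs[ok])
  }
  for (j in seq_along(ok)) {
    s <- seqs[ok[j]]
    variants <- s
    if (config$scan_both_strands) {
      variants <- c(variants, rc[j])
    }
    seen <- character(0)
    for (v in variants) {
      hits <- gregexpr(core, v, fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      for (pos in as.integer(hits)) {
        seen <- union(seen, classify_hit(v, pos))
      }
    }
    for (cl in seen) counts[cl] <- counts[cl] + 1L
  }
  if (n_bad > 0L) {
    warning(n_bad, " unreadable/non-ACGT record(s) skipped", call. = FALSE)
  }
  loxp_class_counts(counts[["u5"]], counts[["u3"]], counts[["rec"]],
                    counts[["ambiguous"]], n_reads = length(seqs))
}

as_sequence_vector <- function(reads) {
  if (methods::is(reads, "DNAStringSet")) return(as.character(reads))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", reads, ignore.case = TRUE)) {
      "fastq"
    } else "fasta"
    return(as.character(Biostrings::readDNAStringSet(reads, format = fmt)))
  }
  if (is.character(reads)) return(reads)
  stop("'reads' must be a file path, DNAStringSet or character vector",
       call. = FALSE)
}

#' Construct loxP junction class counts
#'
#' @param u5,u3 unrecombined 5'/3' junction read counts.
#' @param rec recombined junction read counts.
#' @param ambiguous reads with a core hit that could not be assigned.
#' @param n_reads total records scanned (attribute, optional).
#' @return an object of class `loxp_class_counts`.
#' @export
loxp_class_counts <- function(u5, u3, rec, ambiguous = 0L,
                              n_reads = NA_integer_) {
  out <- list(
    u5 = check_scalar(u5, "u5", lower = 0, integer = TRUE),
    u3 = check_scalar(u3, "u3", lower = 0, integer = TRUE),
    rec = check_scalar(rec, "rec", lower = 0, integer = TRUE),
    ambiguous = check_scalar(ambiguous, "ambiguous", lower = 0,
                             integer = TRUE)
  )
  out$total_core_hits <- out$u5 + out$u3 + out$rec + out$ambiguous
  structure(out, n_reads = n_reads, class = "loxp_class_counts")
}

#' @export
print.loxp_class_counts <- function(x, ...) {
  cat("loxP junction class counts\n")
  cat(sprintf("  unrecombined 5' (U5): %d\n", x$u5))
  cat(sprintf("  unrecombined 3' (U3): %d\n", x$u3))
  cat(sprintf("  recombined      (R) : %d\n", x$rec))
  cat(sprintf("  ambiguous           : %d\n", x$ambiguous))
  invisible(x)
}

#' Estimate the recombined-cell (tumor DNA) fraction from junction counts
#'
#' The point estimate is `R / (R + (U5 + U3) / 2)`: the number of
#' recombined junction reads over recombined reads plus half the
#' unrecombined reads, the halving correcting for unrecombined cells
#' carrying two loxP sites where recombined cells carry one. The interval
#' is a percentile bootstrap over the informative reads (multinomial
#' resampling of the three classes).
#'
#' @param counts a [loxp_class_counts()] (or anything with `u5`, `u3`,
#'   `rec` fields).
#' @param bootstrap_reps bootstrap replicates (default 2000).
#' @param conf_level confidence level (default 0.95).
#' @param seed optional RNG seed for the bootstrap.
#' @return an object of class `purity_estimate` with fields `rho`,
#'   `ci_low`, `ci_high`, `n_informative`, `conf_level`.
#' @examples
#' estimate_purity(loxp_class_counts(u5 = 45, u3 = 55, rec = 10))
#' @export
estimate_purity <- function(counts, bootstrap_reps = 2000L,
                            conf_level = 0.95, seed = NULL) {
  u5 <- counts$u5; u3 <- counts$u3; rec <- counts$rec
  n_inf <- u5 + u3 + rec
  if (n_inf < 1L) {
    stop("no informative loxP reads (R + U5 + U3 = 0); ",
         "purity is undefined", call. = FALSE)
  }
  rho_of <- function(r, u) r / (r + u / 2)
  rho <- rho_of(rec, u5 + u3)
  bootstrap_reps <- check_scalar(bootstrap_reps, "bootstrap_reps",
                                 lower = 0, integer = TRUE)
  ci <- c(NA_real_, NA_real_)
  if (bootstrap_reps > 0L) {
    boot <- function() {
      draws <- stats::rmultinom(bootstrap_reps, n_inf,
                                prob = c(u5, u3, rec) / n_inf)
      rho_of(draws[3, ], draws[1, ] + draws[2, ])
    }
    rho_b <- if (is.null(seed)) boot() else with_seed(seed, boot())
    alpha <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(rho_b, c(alpha, 1 - alpha)))
  }
  structure(
    list(rho = rho, ci_low = ci[1], ci_high = ci[2],
         n_informative = n_inf, conf_level = conf_level),
    class = "purity_estimate"
  )
}

#' @export
print.purity_estimate <- function(x, ...) {
  cat(sprintf(
    "Recombined-cell fraction (tumor purity): %.3f [%s, %s] (%d informative reads)\n",
    x$rho,
    if (is.na(x$ci_low)) "NA" else sprintf("%.3f", x$ci_low),
    if (is.na(x$ci_high)) "NA" else sprintf("%.3f", x$ci_high),
    x$n_informative
  ))
  invisible(x)
}
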