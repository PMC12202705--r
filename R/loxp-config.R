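# Description of the engineered loxP locus: core sequence and the genomic
# context flanking the two unrecombined sites.

#' The canonical 34-bp loxP core sequence
#'
#' Two 13-bp palindromic Cre-binding arms around an asymmetric 8-bp spacer.
#'
#' @return a 34-character string.
#' @export
loxp_core_sequence <- function() {
  "ATAACTTCGTATAATGTATGCTATACGAAGTTAT"
}

#' Configure loxP junction classification for an engineered allele
#'
#' An unrecombined conditional allele carries two loxP sites, each in unique
#' genomic context: the 5' site reads `A-loxP-B` and the 3' site `C-loxP-D`.
#' Cre recombination excises the intervening DNA, fusing the outer flanks
#' into the single junction `A-loxP-D`. Reads spanning the core plus at
#' least `min_flank` bases of context on both sides can therefore be
#' assigned unambiguously to one of the three junction classes.
#'
#' @param flank_5prime_up,flank_5prime_down context immediately up/downstream
#'   of the unrecombined 5' loxP site (sequences `A` and `B`).
#' @param flank_3prime_up,flank_3prime_down context around the unrecombined
#'   3' site (sequences `C` and `D`).
#' @param core loxP core; must be 34 bases. Default the canonical sequence.
#' @param min_flank minimum number of context bases required on each side of
#'   the core for classification (default 3).
#' @param scan_both_strands also scan the reverse complement of each read
#'   (default `TRUE`).
#' @param max_flank_mismatch substitutions tolerated per flank when matching
#'   context (default 0, exact matching).
#' @return an object of class `loxp_config`.
#' @seealso [classify_reads()], [simulate_loxp_library()]
#' @export
loxp_config <- function(flank_5prime_up, flank_5prime_down,
                        flank_3prime_up, flank_3prime_down,
                        core = loxp_core_sequence(),
                        min_flank = 3L, scan_both_strands = TRUE,
                        max_flank_mismatch = 0L) {
  core <- toupper(core)
  if (nchar(core) != 34L || grepl("[^ACGT]", core)) {
    stop("'core' must be a 34-base ACGT sequence", call. = FALSE)
  }
  min_flank <- check_scalar(min_flank, "min_flank", lower = 1,
                            integer = TRUE)
  max_flank_mismatch <- check_scalar(max_flank_mismatch,
                                     "max_flank_mismatch", lower = 0,
                                     integer = TRUE)
  flanks <- toupper(c(flank_5prime_up = flank_5prime_up,
                      flank_5prime_down = flank_5prime_down,
                      flank_3prime_up = flank_3prime_up,
                      flank_3prime_down = flank_3prime_down))
  if (any(grepl("[^ACGT]", flanks))) {
    stop("flank sequences must be ACGT only", call. = FALSE)
  }
  if (any(nchar(flanks) < min_flank)) {
    stop("every flank must be at least 'min_flank' bases long",
         call. = FALSE)
  }
  k <- min_flank
  up_keys <- substring(flanks[c(1, 3)],
                       nchar(flanks[c(1, 3)]) - k + 1L)
  down_keys <- substring(flanks[c(2, 4)], 1L, k)
  if (up_keys[1] == up_keys[2]) {
    stop("upstream flanks A and C are identical in their last ", k,
         " bases; the two unrecombined sites cannot be distinguished",
         call. = FALSE)
  }
  if (down_keys[1] == down_keys[2]) {
    stop("downstream flanks B and D are identical in their first ", k,
         " bases; junction classes cannot be distinguished", call. = FALSE)
  }
  structure(
    list(core = core,
         flank_5prime_up = unname(flanks[1]),
         flank_5prime_down = unname(flanks[2]),
         flank_3prime_up = unname(flanks[3]),
         flank_3prime_down = unname(flanks[4]),
         min_flank = k,
         scan_both_strands = isTRUE(scan_both_strands),
         max_flank_mismatch = max_flank_mismatch),
    class = "loxp_config"
  )
}

#' Generate a loxP configuration with random distinct flanks
#'
#' Convenience for simulation when the real genomic context of the
#' engineered allele is unavailable: draws four random, mutually distinct
#' flank sequences.
#'
#' @param flank_length length of each generated flank (default 33, so that
#'   100-bp reads fit inside a single junction template).
#' @param seed RNG seed.
#' @inheritParams loxp_config
#' @return a `loxp_config`.
#' @export
random_loxp_config <- function(flank_length = 33L, seed = 1L,
                               min_flank = 3L, scan_both_strands = TRUE) {
  flank_length <- check_scalar(flank_length, "flank_length",
                               lower = min_flank, integer = TRUE)
  flanks <- with_seed(seed, {
    repeat {
      f <- random_dna(4L, flank_length)
      keys <- c(substring(f[c(1, 3)], flank_length - min_flank + 1L),
                substring(f[c(2, 4)], 1L, min_flank))
      if (keys[1] != keys[2] && keys[3] != keys[4]) break
    }
    f
  })
  loxp_config(flank_5prime_up = flanks[1], flank_5prime_down = flanks[2],
              flank_3prime_up = flanks[3], flank_3prime_down = flanks[4],
              min_flank = min_flank, scan_both_strands = scan_both_strands)
}

#' Write / read a loxP configuration as YAML
#'
#' @param config a [loxp_config()].
#' @param path file path.
#' @return `write_loxp_config` returns `path` invisibly; `read_loxp_config`
#'   returns the `loxp_config`.
#' @export
write_loxp_config <- function(config, path) {
  stopifnot(inherits(config, "loxp_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_loxp_config
#' @export
read_loxp_config <- function(path) {
  x <- yaml::read_yaml(path)
  loxp_config(flank_5prime_up = x$flank_5prime_up,
              flank_5prime_down = x$flank_5prime_down,
              flank_3prime_up = x$flank_3prime_up,
              flank_3prime_down = x$flank_3prime_down,
              core = if (is.null(x$core)) loxp_core_sequence() else x$core,
              min_flank = if (is.null(x$min_flank)) 3L else x$min_flank,
              scan_both_strands = !isFALSE(x$scan_both_strands),
              max_flank_mismatch =
                if (is.null(x$max_flank_mismatch)) 0L
                else x$max_flank_mismatch)
}
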