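# Synthetic read libraries from an engineered loxP locus.

#' Specify a synthetic loxP junction read library
#'
#' Models bulk sequencing of a tissue in which a fraction `rho_true` of
#' cells carry the recombined allele. Each unrecombined cell contributes
#' two junction templates (the 5' site `A-loxP-B` and the 3' site
#' `C-loxP-D`); each recombined cell contributes one (`A-loxP-D`) — the
#' 2:1 site-count asymmetry that the purity estimator later corrects for.
#'
#' @param rho_true true recombined-cell fraction in `[0, 1]`.
#' @param n_cells_sampled number of cells whose loxP loci are sequenced.
#' @param read_length read length in bases (>= 40).
#' @param per_base_error independent per-base substitution probability.
#' @param seed integer RNG seed.
#' @return an object of class `loxp_library_spec`.
#' @export
loxp_library_spec <- function(rho_true, n_cells_sampled,
                              read_length = 100L, per_base_error = 0,
                              seed = 1L) {
  structure(
    list(rho_true = check_scalar(rho_true, "rho_true", 0, 1),
         n_cells_sampled = check_scalar(n_cells_sampled, "n_cells_sampled",
                                        lower = 1, integer = TRUE),
         read_length = check_scalar(read_length, "read_length", lower = 40,
                                    integer = TRUE),
         per_base_error = check_scalar(per_base_error, "per_base_error",
                                       0, 1),
         seed = check_scalar(seed, "seed", integer = TRUE)),
    class = "loxp_library_spec"
  )
}

#' Simulate reads spanning loxP junctions at a known cell-fraction mix
#'
#' Each sampled cell is recombined with probability `rho_true`. Recombined
#' cells emit one read from the fused `A-loxP-D` junction; unrecombined
#' cells emit one read from each of the `A-loxP-B` and `C-loxP-D` sites.
#' Reads are placed uniformly over template positions that keep the full
#' core plus at least `min_flank` context bases on both sides inside the
#' read, half are reverse-complemented, and independent per-base
#' substitution errors are applied. The truth record stores the junction
#' class of every read, making the library its own classification oracle.
#'
#' @param spec a [loxp_library_spec()].
#' @param config a [loxp_config()]; flanks must be long enough that
#'   `read_length <= 34 + 2 * min(flank lengths)`.
#' @return a list of class `loxp_sim` with elements `reads` (named
#'   character vector of sequences), `truth` (data frame: `read_id`,
#'   `class`, `cell`, `strand`, `n_errors`), `class_counts` (table of true
#'   classes), `config` and `spec`.
#' @examples
#' cfg <- random_loxp_config(seed = 5)
#' lib <- simulate_loxp_library(
#'   loxp_library_spec(rho_true = 0.36, n_cells_sampled = 100, seed = 7),
#'   cfg
#' )
#' table(lib$truth$class)
#' @export
simulate_loxp_library <- function(spec, config) {
  stopifnot(inherits(spec, "loxp_library_spec"),
            inherits(config, "loxp_config"))
  k <- config$min_flank
  L <- spec$read_length
  if (L < 34L + 2L * k) {
    stop("read_length (", L, ") too short to span the 34-bp core plus ",
         k, " flank bases on each side", call. = FALSE)
  }
  flank_len <- min(nchar(config$flank_5prime_up),
                   nchar(config$flank_5prime_down),
                   nchar(config$flank_3prime_up),
                   nchar(config$flank_3prime_down))
  if (L > 34L + 2L * flank_len) {
    stop("read_length (", L, ") exceeds the junction template; supply ",
         "flanks of at least ", ceiling((L - 34L) / 2), " bases",
         call. = FALSE)
  }

  templates <- c(
    unrecombined_5 = paste0(config$flank_5prime_up, config$core,
                            config$flank_5prime_down),
    unrecombined_3 = paste0(config$flank_3prime_up, config$core,
                            config$flank_3prime_down),
    recombined = paste0(config$flank_5prime_up, config$core,
                        config$flank_3prime_down)
  )

  with_seed(spec$seed, {
    n <- spec$n_cells_sampled
    recombined <- stats::runif(n) < spec$rho_true
    cell <- c(which(recombined),
              rep(which(!recombined), each = 2L))
    class <- c(rep("recombined", sum(recombined)),
               rep(c("unrecombined_5", "unrecombined_3"),
                   times = sum(!recombined)))
    m <- length(class)
    ord <- sample.int(m)           # interleave classes in output order
    cell <- cell[ord]
    class <- class[ord]

    reads <- character(m)
    strand <- character(m)
    n_err <- integer(m)
    for (i in seq_len(m)) {
      tmpl <- templates[[class[i]]]
      up_len <- switch(class[i],
                       unrecombined_5 = nchar(config$flank_5prime_up),
                       unrecombined_3 = nchar(config$flank_3prime_up),
                       recombined = nchar(config$flank_5prime_up))
      # read [s, s+L-1] must cover core (up_len+1 .. up_len+34) plus k bases
      s_min <- max(1L, up_len + 34L + k - L + 1L)
      s_max <- min(up_len + 1L - k, nchar(tmpl) - L + 1L)
      s <- if (s_max > s_min) {
        s_min + sample.int(s_max - s_min + 1L, 1L) - 1L
      } else s_min
      seq_i <- substring(tmpl, s, s + L - 1L)
      if (spec$per_base_error > 0) {
        hit <- which(stats::runif(L) < spec$per_base_error)
        if (length(hit)) {
          bases <- strsplit(seq_i, "", fixed = TRUE)[[1]]
          for (p in hit) {
            bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1L)
          }
          seq_i <- paste(bases, collapse = "")
          n_err[i] <- length(hit)
        }
      }
      if (stats::runif(1) < 0.5) {
        seq_i <- reverse_complement(seq_i)
        strand[i] <- "-"
      } else {
        strand[i] <- "+"
      }
      reads[i] <- seq_i
    }
    ids <- sprintf("read_%05d", seq_len(m))
    names(reads) <- ids
    truth <- data.frame(read_id = ids, class = class, cell = cell,
                        strand = strand, n_errors = n_err,
                        stringsAsFactors = FALSE)
    counts <- c(unrecombined_5 = sum(class == "unrecombined_5"),
                unrecombined_3 = sum(class == "unrecombined_3"),
                recombined = sum(class == "recombined"))
    structure(
      list(reads = reads, truth = truth, class_counts = counts,
           config = config, spec = spec),
      class = "loxp_sim"
    )
  })
}

#' Write reads as FASTQ
#'
#' Four-line records with a constant high base quality (`I`, Q40); the
#' junction classifier ignores qualities.
#'
#' @param reads named character vector of sequences (names become read ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%05d", seq_along(reads))
  rec <- paste0("@", ids, "\n", reads, "\n+\n",
                strrep("I", nchar(reads)))
  writeLines(rec, path)
  invisible(path)
}
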