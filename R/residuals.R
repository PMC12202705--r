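# Analytic Pearson residuals for UMI counts under a CV-parameterized
# negative-binomial null, and per-gene z-standardization.

#' Analytic Pearson residuals for a UMI count matrix
#'
#' Under the null that gene `g` makes up a constant fraction of every
#' cell's transcriptome, the expected count is
#' `mu_gc = (gene total_g * cell total_c) / grand total`, and the count
#' variance under biological noise with coefficient of variation `c` is
#' `mu + c^2 mu^2` (negative binomial with overdispersion
#' `theta = 1 / c^2`). The residual is
#' `r_gc = (x_gc - mu_gc) / sqrt(mu_gc + mu_gc^2 / theta)`, clipped to
#' `±clip_bound` (default `sqrt(n_cells)`) so single outlier counts cannot
#' dominate downstream scores.
#'
#' Genes (and cells) with zero totals have undefined residuals and are
#' removed with a warning.
#'
#' @param counts genes x cells matrix of non-negative counts; dense matrix
#'   or any `Matrix` sparse matrix (absent entries are zeros).
#' @param cv biological coefficient of variation `c` (> 0). The study
#'   datasets this mirrors used 0.55 or 0.65 depending on genotype.
#' @param clip_bound clipping bound for `|r|`; default `sqrt(ncol(counts))`.
#' @return an object of class `residual_matrix`: list with `residuals`
#'   (dense genes x cells matrix), `mu` (expected means), `model`
#'   (`cv`, `theta`, `clip_bound`), and `n_clipped`.
#' @references Lause, Berens & Kobak (2021) Genome Biology 22:258
#'   (analytic Pearson residuals for UMI data).
#' @examples
#' x <- matrix(rpois(600, 5), nrow = 20)
#' res <- pearson_residuals(x, cv = 0.55)
#' range(res$residuals)
#' @export
pearson_residuals <- function(counts, cv, clip_bound = NULL) {
  cv <- check_scalar(cv, "cv", lower = 0, lower_open = TRUE)
  x <- as.matrix(counts)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("need at least 2 genes and 2 cells", call. = FALSE)
  }
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  gene_tot <- rowSums(x)
  if (all(gene_tot == 0)) stop("all-zero count matrix", call. = FALSE)
  if (any(gene_tot == 0)) {
    warning(sum(gene_tot == 0), " gene(s) with zero total removed",
            call. = FALSE)
    x <- x[gene_tot > 0, , drop = FALSE]
    gene_tot <- gene_tot[gene_tot > 0]
  }
  cell_tot <- colSums(x)
  if (any(cell_tot == 0)) {
    warning(sum(cell_tot == 0), " cell(s) with zero total removed",
            call. = FALSE)
    x <- x[, cell_tot > 0, drop = FALSE]
    gene_tot <- rowSums(x)
    cell_tot <- cell_tot[cell_tot > 0]
  }
  if (is.null(clip_bound)) clip_bound <- sqrt(ncol(x))
  clip_bound <- check_scalar(clip_bound, "clip_bound", lower = 0,
                             lower_open = TRUE)
  theta <- 1 / cv^2
  mu <- outer(gene_tot, cell_tot) / sum(gene_tot)
  r <- (x - mu) / sqrt(mu + mu^2 / theta)
  n_clipped <- sum(abs(r) > clip_bound)
  r[r > clip_bound] <- clip_bound
  r[r < -clip_bound] <- -clip_bound
  structure(
    list(residuals = r, mu = mu,
         model = list(cv = cv, theta = theta, clip_bound = clip_bound),
         n_clipped = n_clipped),
    class = "residual_matrix"
  )
}

#' @export
print.residual_matrix <- function(x, ...) {
  cat(sprintf(
    "Pearson residual matrix: %d genes x %d cells (cv = %.3g, theta = %.3g, clip = %.3g, %d clipped)\n",
    nrow(x$residuals), ncol(x$residuals), x$model$cv, x$model$theta,
    x$model$clip_bound, x$n_clipped
  ))
  invisible(x)
}

#' Standardize residuals per gene into z-scores
#'
#' Centers and scales each gene's residuals across cells using the sample
#' (`n - 1`) standard deviation. Genes with zero variance carry no
#' information and are dropped with a warning.
#'
#' @param residuals a [residual_matrix][pearson_residuals()] or a plain
#'   genes x cells numeric matrix.
#' @return genes x cells matrix of z-scores (per-gene mean 0, SD 1), with
#'   attribute `dropped_genes` naming removed zero-variance genes.
#' @export
standardize_residuals <- function(residuals) {
  r <- if (inherits(residuals, "residual_matrix")) {
    residuals$residuals
  } else as.matrix(residuals)
  if (ncol(r) < 2L) stop("need at least 2 cells to standardize",
                         call. = FALSE)
  m <- rowMeans(r)
  s <- sqrt(rowSums((r - m)^2) / (ncol(r) - 1L))
  zero_var <- s <= .Machine$double.eps^0.5 * pmax(abs(m), 1)
  if (all(zero_var)) {
    stop("every gene has zero residual variance; nothing to standardize",
         call. = FALSE)
  }
  dropped <- rownames(r)[zero_var]
  if (is.null(dropped) && any(zero_var)) dropped <- which(zero_var)
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance gene(s) dropped from ",
            "z-standardization", call. = FALSE)
    r <- r[!zero_var, , drop = FALSE]
    m <- m[!zero_var]
    s <- s[!zero_var]
  }
  z <- (r - m) / s
  attr(z, "dropped_genes") <- if (any(zero_var)) dropped else character(0)
  z
}

#' Moment estimate of the biological coefficient of variation
#'
#' Convenience estimator (not part of the canonical scoring procedure):
#' under the noise model the per-gene variance satisfies
#' `v = m + c^2 m^2`, so `c^2` is estimated as the median of
#' `(v_g - m_g) / m_g^2` over genes with mean above `min_mean`. Intended
#' for matrices with roughly uniform per-cell depth; depth variation
#' inflates the estimate.
#'
#' @param counts genes x cells count matrix.
#' @param min_mean include genes with mean count above this (default 0.5).
#' @return estimated `c` (non-negative scalar).
#' @export
estimate_cv <- function(counts, min_mean = 0.5) {
  x <- as.matrix(counts)
  m <- rowMeans(x)
  v <- apply(x, 1, stats::var)
  keep <- m > min_mean
  if (!any(keep)) stop("no genes with mean above 'min_mean'", call. = FALSE)
  c2 <- stats::median((v[keep] - m[keep]) / m[keep]^2)
  sqrt(max(c2, 0))
}
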