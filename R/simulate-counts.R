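# Negative-binomial UMI count simulator with planted cell-type signatures.

#' Specify a synthetic UMI count matrix
#'
#' Counts follow the overdispersed model assumed by the residual pipeline:
#' `x ~ NegativeBinomial(mean mu, variance mu + c^2 mu^2)` where `c` is the
#' biological coefficient of variation (overdispersion `theta = 1/c^2`).
#' Cells belong to discrete types; a planted signature multiplies the mean
#' of its genes by `2^log2fc` in one type, and per-type means are
#' renormalized so every cell keeps the same expected depth (fold changes
#' are compositional, as in real UMI data).
#'
#' @param n_genes,n_cells matrix dimensions.
#' @param biological_cv biological coefficient of variation `c` (> 0).
#' @param type_proportions named simplex of cell-type proportions
#'   (default a single `"background"` type).
#' @param planted_signatures list of `list(cell_type =, genes =, log2fc =)`
#'   entries; `genes` may be indices or names from the simulated universe
#'   (`gene0001`, ...).
#' @param baseline_gene_means positive relative expression levels, length
#'   `n_genes`; default drawn log-normal(0, 1).
#' @param depth_per_cell expected total UMI count per cell (default 2000).
#' @param depth_sdlog log-normal spread of per-cell depth around
#'   `depth_per_cell` (default 0: constant depth, so the marginal count
#'   variance is exactly `mu + c^2 mu^2`).
#' @param seed integer RNG seed.
#' @return an object of class `counts_spec`.
#' @export
counts_spec <- function(n_genes, n_cells, biological_cv,
                        type_proportions = c(background = 1),
                        planted_signatures = list(),
                        baseline_gene_means = NULL,
                        depth_per_cell = 2000,
                        depth_sdlog = 0,
                        seed = 1L) {
  n_genes <- check_scalar(n_genes, "n_genes", lower = 2, integer = TRUE)
  n_cells <- check_scalar(n_cells, "n_cells", lower = 2, integer = TRUE)
  biological_cv <- check_scalar(biological_cv, "biological_cv",
                                lower = 0, lower_open = TRUE)
  depth_per_cell <- check_scalar(depth_per_cell, "depth_per_cell",
                                 lower = 0, lower_open = TRUE)
  depth_sdlog <- check_scalar(depth_sdlog, "depth_sdlog", lower = 0)
  seed <- check_scalar(seed, "seed", integer = TRUE)
  if (is.null(names(type_proportions)) || any(type_proportions <= 0)) {
    stop("'type_proportions' must be a named vector of positive weights",
         call. = FALSE)
  }
  if (abs(sum(type_proportions) - 1) > 1e-6) {
    stop("'type_proportions' must sum to 1", call. = FALSE)
  }
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  if (!is.null(baseline_gene_means)) {
    stopifnot(length(baseline_gene_means) == n_genes,
              all(baseline_gene_means > 0))
  }
  planted_signatures <- lapply(planted_signatures, function(sig) {
    stopifnot(all(c("cell_type", "genes", "log2fc") %in% names(sig)))
    if (!sig$cell_type %in% names(type_proportions)) {
      stop("planted signature targets unknown cell type '", sig$cell_type,
           "'", call. = FALSE)
    }
    genes <- sig$genes
    if (is.numeric(genes)) {
      if (any(genes < 1 | genes > n_genes)) {
        stop("planted signature gene indices outside the gene universe",
             call. = FALSE)
      }
      genes <- gene_ids[genes]
    } else if (!all(genes %in% gene_ids)) {
      stop("planted signature genes must belong to the simulated universe",
           call. = FALSE)
    }
    list(cell_type = sig$cell_type, genes = genes,
         log2fc = check_scalar(sig$log2fc, "log2fc"))
  })
  structure(
    list(n_genes = n_genes, n_cells = n_cells,
         biological_cv = biological_cv,
         type_proportions = type_proportions,
         planted_signatures = planted_signatures,
         baseline_gene_means = baseline_gene_means,
         depth_per_cell = depth_per_cell,
         depth_sdlog = depth_sdlog,
         seed = seed, gene_ids = gene_ids),
    class = "counts_spec"
  )
}

#' Simulate a UMI count matrix with planted signatures
#'
#' @param spec a [counts_spec()].
#' @return a list of class `counts_sim`:
#'   \describe{
#'     \item{counts}{`dgCMatrix`, genes x cells, non-negative integers.}
#'     \item{features,barcodes}{gene and cell identifiers.}
#'     \item{labels}{data frame of per-cell type labels.}
#'     \item{signatures}{named list of planted gene sets (GMT-ready).}
#'     \item{truth}{baseline means, per-type expected means (`mu_by_type`),
#'       per-cell depths, type labels, and the spec.}
#'   }
#' @examples
#' sim <- simulate_count_matrix(counts_spec(
#'   n_genes = 100, n_cells = 300, biological_cv = 0.55,
#'   type_proportions = c(background = 0.8, planted = 0.2),
#'   planted_signatures = list(
#'     list(cell_type = "planted", genes = 1:20, log2fc = 1)
#'   ),
#'   seed = 3
#' ))
#' dim(sim$counts)
#' @export
simulate_count_matrix <- function(spec) {
  stopifnot(inherits(spec, "counts_spec"))
  G <- spec$n_genes
  n <- spec$n_cells
  theta <- 1 / spec$biological_cv^2
  types <- names(spec$type_proportions)

  with_seed(spec$seed, {
    baseline <- spec$baseline_gene_means
    if (is.null(baseline)) baseline <- stats::rlnorm(G, 0, 1)

    # per-type relative expression, renormalized to the same expected depth
    weight <- matrix(baseline, nrow = G, ncol = length(types),
                     dimnames = list(spec$gene_ids, types))
    for (sig in spec$planted_signatures) {
      idx <- match(sig$genes, spec$gene_ids)
      weight[idx, sig$cell_type] <-
        weight[idx, sig$cell_type] * 2^sig$log2fc
    }
    prop <- sweep(weight, 2, colSums(weight), "/")

    label <- sample(types, n, replace = TRUE,
                    prob = spec$type_proportions)
    depth <- if (spec$depth_sdlog > 0) {
      spec$depth_per_cell *
        stats::rlnorm(n, -spec$depth_sdlog^2 / 2, spec$depth_sdlog)
    } else rep(spec$depth_per_cell, n)

    mu_by_type <- prop * spec$depth_per_cell
    x <- matrix(0L, nrow = G, ncol = n)
    for (ty in types) {
      cells <- which(label == ty)
      if (!length(cells)) next
      mu <- outer(prop[, ty], depth[cells])
      draws <- if (theta > 1e8) {
        stats::rpois(length(mu), lambda = mu)
      } else {
        stats::rnbinom(length(mu), mu = mu, size = theta)
      }
      x[, cells] <- draws
    }
    barcodes <- sprintf("cell%05d", seq_len(n))
    dimnames(x) <- list(spec$gene_ids, barcodes)

    signatures <- list()
    for (sig in spec$planted_signatures) {
      signatures[[paste0("sig_", sig$cell_type)]] <- sig$genes
    }
    structure(
      list(counts = methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE),
                                            "CsparseMatrix"), "dMatrix"),
           features = spec$gene_ids,
           barcodes = barcodes,
           labels = data.frame(barcode = barcodes, cell_type = label,
                               stringsAsFactors = FALSE),
           signatures = signatures,
           truth = list(baseline = baseline, mu_by_type = mu_by_type,
                        depth = depth, cell_type = label, spec = spec)),
      class = "counts_sim"
    )
  })
}

#' Write a simulated counts dataset to a directory
#'
#' Emits the 10x-style trio `matrix.mtx` / `features.tsv` / `barcodes.tsv`,
#' a `labels.tsv` with per-cell types, a `signatures.gmt` with the planted
#' gene sets (if any), and a `truth.json` sidecar recording the seed, CV,
#' labels and planted signatures.
#'
#' @param sim a [counts_sim][simulate_count_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "counts_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(sim$counts, file.path(dir, "matrix.mtx"))
  writeLines(sim$features, file.path(dir, "features.tsv"))
  writeLines(sim$barcodes, file.path(dir, "barcodes.tsv"))
  utils::write.table(sim$labels, file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(sim$signatures)) {
    write_gmt(sim$signatures, file.path(dir, "signatures.gmt"))
  }
  spec <- sim$truth$spec
  jsonlite::write_json(
    list(seed = spec$seed, biological_cv = spec$biological_cv,
         depth_per_cell = spec$depth_per_cell,
         type_proportions = as.list(spec$type_proportions),
         planted_signatures = spec$planted_signatures,
         cell_type = sim$truth$cell_type),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a counts dataset written by [write_counts_dataset()]
#'
#' @param dir dataset directory.
#' @return list with `counts` (`dgCMatrix` with dimnames), `labels`
#'   (data frame or `NULL`), `signatures` (list or `NULL`).
#' @export
read_counts_dataset <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  features <- readLines(file.path(dir, "features.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(counts) <- list(features, barcodes)
  labels_path <- file.path(dir, "labels.tsv")
  labels <- if (file.exists(labels_path)) {
    utils::read.delim(labels_path, stringsAsFactors = FALSE)
  }
  gmt_path <- file.path(dir, "signatures.gmt")
  signatures <- if (file.exists(gmt_path)) read_gmt(gmt_path)
  list(counts = counts, labels = labels, signatures = signatures)
}
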