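# Gene-signature membership scores and cluster-centroid distances.

#' Read / write gene sets in GMT format
#'
#' Reading is delegated to [fgsea::gmtPathways()]. Writing emits one
#' tab-separated line per set: name, description, genes.
#'
#' @param path GMT file path.
#' @param sets named list of character gene vectors.
#' @param description description field written for every set.
#' @return `read_gmt` returns a named list of character vectors;
#'   `write_gmt` returns `path` invisibly.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, description = "melkin") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Per-cell membership scores for gene signatures
#'
#' The membership score of a cell for a signature is the unweighted mean,
#' over the signature genes present in the matrix, of that cell's per-gene
#' z-scored residuals. A high score means the cell's expression deviates
#' from the dataset-wide expectation in the same direction as the
#' signature. Gene identifiers are matched case-insensitively; an optional
#' symbol map (e.g. human to mouse) is applied to the signature first.
#' Missing genes are reported, never imputed.
#'
#' @param z genes x cells z-score matrix from [standardize_residuals()].
#' @param signatures a character vector of gene identifiers (one
#'   signature), or a named list of such vectors (e.g. from [read_gmt()]).
#' @param symbol_map optional data frame with columns `from` and `to`;
#'   signature genes matching `from` (case-insensitively) are translated
#'   to `to` before matching against the matrix.
#' @return a data frame with column `cell` and one score column per
#'   signature, carrying attributes `n_genes_used` (named integer vector)
#'   and `genes_missing` (named list of unmatched identifiers).
#' @examples
#' z <- matrix(rnorm(50), 5, 10,
#'             dimnames = list(paste0("g", 1:5), paste0("c", 1:10)))
#' membership_score(z, list(top = c("g1", "g2")))
#' @export
membership_score <- function(z, signatures, symbol_map = NULL) {
  z <- as.matrix(z)
  if (is.null(rownames(z))) {
    stop("'z' must have gene identifiers as row names", call. = FALSE)
  }
  if (!is.list(signatures)) signatures <- list(signature = signatures)
  if (is.null(names(signatures))) {
    names(signatures) <- paste0("signature_", seq_along(signatures))
  }
  key <- toupper(rownames(z))
  used <- integer(0)
  missing <- list()
  out <- data.frame(cell = colnames(z) %||% seq_len(ncol(z)),
                    stringsAsFactors = FALSE)
  for (nm in names(signatures)) {
    genes <- unique(as.character(signatures[[nm]]))
    if (!is.null(symbol_map)) {
      stopifnot(all(c("from", "to") %in% names(symbol_map)))
      hit <- match(toupper(genes), toupper(symbol_map$from))
      genes[!is.na(hit)] <- symbol_map$to[hit[!is.na(hit)]]
    }
    idx <- match(toupper(genes), key)
    found <- !is.na(idx)
    if (!any(found)) {
      stop("signature '", nm, "' shares no genes with the matrix; ",
           "missing: ", paste(genes, collapse = ", "), call. = FALSE)
    }
    out[[nm]] <- colMeans(z[idx[found], , drop = FALSE])
    used[nm] <- sum(found)
    missing[[nm]] <- genes[!found]
  }
  attr(out, "n_genes_used") <- used
  attr(out, "genes_missing") <- missing
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Euclidean distances between cluster centroids in embedding space
#'
#' Each cluster's centroid is the mean of its cells' coordinates over the
#' first `n_dims` embedding dimensions (e.g. the top 10 principal
#' components, or the top 30 integrated dimensions); the result is the
#' symmetric matrix of pairwise Euclidean distances between centroids.
#'
#' @param embedding cells x dims numeric matrix (or data frame).
#' @param labels per-cell cluster labels, length `nrow(embedding)`.
#' @param n_dims number of leading dimensions to use (default all).
#' @return symmetric distance matrix over cluster labels (zero diagonal).
#' @examples
#' emb <- rbind(matrix(0, 5, 2), matrix(rep(c(3, 4), each = 5), 5, 2))
#' cluster_centroid_distances(emb, rep(c("a", "b"), each = 5))
#' @export
cluster_centroid_distances <- function(embedding, labels, n_dims = NULL) {
  emb <- as.matrix(embedding)
  storage.mode(emb) <- "double"
  if (length(labels) != nrow(emb)) {
    stop("'labels' must have one entry per embedding row", call. = FALSE)
  }
  if (is.null(n_dims)) n_dims <- ncol(emb)
  n_dims <- check_scalar(n_dims, "n_dims", lower = 1, integer = TRUE)
  if (n_dims > ncol(emb)) {
    stop("n_dims (", n_dims, ") exceeds available dimensions (",
         ncol(emb), ")", call. = FALSE)
  }
  labels <- as.factor(labels)
  empty <- setdiff(levels(labels), unique(as.character(labels)))
  if (length(empty)) {
    warning("cluster(s) with no cells excluded: ",
            paste(empty, collapse = ", "), call. = FALSE)
    labels <- droplevels(labels)
  }
  if (nlevels(labels) < 2L) {
    stop("need at least 2 non-empty clusters", call. = FALSE)
  }
  emb <- emb[, seq_len(n_dims), drop = FALSE]
  centroids <- rowsum(emb, labels) / as.vector(table(labels))
  as.matrix(stats::dist(centroids))
}
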