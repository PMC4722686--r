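#' Kernels over genes and the joint input-output kernel
#'
#' Each feature source contributes a linear (dot-product) kernel between
#' gene feature vectors. Kernels are cosine-normalized so that the diagonal
#' is 1, then combined by addition across sources. The structured model uses
#' the joint kernel K((x1,y1),(x2,y2)) = K_X(x1,x2) * K_Y(y1,y2), the dot
#' product in the tensor-product feature space.
#'
#' @name kernels
NULL

#' Construct a kernel matrix
#'
#' @param values symmetric numeric matrix with identical gene row/col names.
#' @param normalized whether the kernel has been cosine-normalized.
#' @return an object of class `kernel_matrix`.
#' @export
kernel_matrix <- function(values, normalized = FALSE) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values))) stop("kernel matrix needs gene names")
  if (max(abs(values - t(values))) > 1e-8 * max(1, max(abs(values)))) {
    stop("kernel matrix is not symmetric")
  }
  values <- (values + t(values)) / 2
  colnames(values) <- rownames(values)
  structure(values, normalized = isTRUE(normalized),
            class = c("kernel_matrix", "matrix", "array"))
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix: %d genes, normalized=%s\n",
              nrow(x), isTRUE(attr(x, "normalized"))))
  invisible(x)
}

#' Linear kernel of a feature matrix
#'
#' Entry (i, j) is the dot product of the feature rows of genes i and j.
#'
#' @param X a [feature_matrix()] or plain matrix with gene rownames.
#' @return an unnormalized [kernel_matrix()].
#' @export
linear_kernel <- function(X) {
  if (nrow(X) == 0L || ncol(X) == 0L) stop("empty feature matrix")
  kernel_matrix(tcrossprod(unclass(X)), normalized = FALSE)
}

#' Cosine-normalize a kernel
#'
#' Entry (i, j) becomes K(i,j) / sqrt(K(i,i) K(j,j)), giving unit diagonal.
#' Genes with zero diagonal (all-zero feature rows in this source) get their
#' row and column set to 0 with diagonal 1, so they are neutral under
#' additive combination. Idempotent.
#'
#' @param K a [kernel_matrix()].
#' @param quiet suppress the zero-diagonal message.
#' @return a normalized [kernel_matrix()].
#' @export
normalize_kernel <- function(K, quiet = TRUE) {
  d <- diag(K)
  zero <- d <= 0
  if (any(zero) && !quiet) {
    message(sprintf("normalize_kernel: %d genes with zero self-similarity zeroed", sum(zero)))
  }
  s <- ifelse(zero, 1, 1 / sqrt(d))
  V <- unclass(K) * tcrossprod(s)
  V[zero, ] <- 0
  V[, zero] <- 0
  diag(V) <- 1
  kernel_matrix(V, normalized = TRUE)
}

#' Combine kernels by (weighted) addition
#'
#' All kernels must be on the identical gene list and normalized. Default
#' weights are all 1 (plain addition of per-source kernels).
#'
#' @param Ks list of normalized [kernel_matrix()] objects.
#' @param weights optional numeric vector, one per kernel.
#' @return a [kernel_matrix()] (not marked normalized: its diagonal is the
#'   sum of weights).
#' @export
combine_kernels <- function(Ks, weights = NULL) {
  if (inherits(Ks, "kernel_matrix")) Ks <- list(Ks)
  if (length(Ks) == 0L) stop("no kernels to combine")
  if (is.null(weights)) weights <- rep.int(1, length(Ks))
  stopifnot(length(weights) == length(Ks))
  genes <- rownames(Ks[[1L]])
  for (K in Ks) {
    if (!identical(rownames(K), genes)) stop("kernels are on different gene lists")
    if (!isTRUE(attr(K, "normalized"))) stop("combine_kernels expects normalized kernels")
  }
  V <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  for (k in seq_along(Ks)) V <- V + weights[[k]] * unclass(Ks[[k]])
  out <- kernel_matrix(V, normalized = length(Ks) == 1L && weights[[1L]] == 1)
  out
}

#' Joint input-output kernel value
#'
#' The joint kernel of two input-output pairs is the product of the
#' input-space and output-space kernel values; works elementwise on
#' conforming arrays.
#'
#' @param kx input-space kernel value(s) K_X(x1, x2).
#' @param ky output-space kernel value(s) K_Y(y1, y2).
#' @return `kx * ky`.
#' @export
joint_kernel <- function(kx, ky) kx * ky

#' Write a kernel matrix as dense TSV
#'
#' Header row of gene ids; values at 12 significant digits (round-trip
#' stable).
#'
#' @param K a [kernel_matrix()].
#' @param path output path.
#' @export
write_kernel_tsv <- function(K, path) {
  genes <- rownames(K)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", genes), collapse = "\t"), con)
  for (i in seq_along(genes)) {
    vals <- formatC(unclass(K)[i, ], digits = 12, format = "g")
    writeLines(paste(c(genes[[i]], vals), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a kernel matrix written by [write_kernel_tsv()]
#'
#' @param path input path.
#' @param normalized mark the result as normalized.
#' @return a [kernel_matrix()].
#' @export
read_kernel_tsv <- function(path, normalized = FALSE) {
  lines <- readLines(path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]][-1L]
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  genes <- vapply(rows, `[[`, "", 1L)
  V <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(length(header))))
  dimnames(V) <- list(genes, header)
  if (!identical(genes, header)) stop("kernel TSV row/column gene mismatch")
  kernel_matrix(V, normalized = normalized)
}
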