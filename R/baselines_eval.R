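#' Binary-SVM baseline, metrics, cross-validation and ablation
#'
#' The baseline trains one kernel binary SVM per ontology term on the same
#' combined input kernel as the structured model. Term-centric performance
#' is the macro AUC (mean of per-term ROC AUCs); protein-centric
#' performance is precision/recall per gene and F-max over a score
#' threshold grid (CAFA convention).
#'
#' @name baselines_eval
NULL

# Biasless kernel C-SVM dual: min 1/2 a' Q a - e' a, 0 <= a <= C,
# Q_ij = y_i y_j K_ij. Solved by coordinate descent (exact per-coordinate
# minimization), which converges for PSD Q.
.svm_dual <- function(K, y, C = 1, tol = 1e-8, max_sweeps = 2000L) {
  n <- length(y)
  a <- numeric(n)
  Q <- (y %o% y) * K
  dq <- diag(Q)
  grad <- rep.int(-1, n)                       # Q a - e
  for (sweep in seq_len(max_sweeps)) {
    delta_max <- 0
    for (i in seq_len(n)) {
      if (dq[[i]] <= 1e-12) next
      d <- -grad[[i]] / dq[[i]]
      new_a <- min(max(a[[i]] + d, 0), C)
      d <- new_a - a[[i]]
      if (abs(d) > 0) {
        a[[i]] <- new_a
        grad <- grad + d * Q[, i]
        delta_max <- max(delta_max, abs(d))
      }
    }
    if (delta_max < tol) break
  }
  a
}

#' Train per-term binary SVMs and score held-out genes
#'
#' One linear-kernel (precomputed) binary SVM per term, C-SVM with hinge
#' loss. Terms with fewer than one positive or one negative training gene
#' are skipped (their score column is NA, logged when `quiet = FALSE`).
#'
#' @param Kx_train [kernel_matrix()] over training genes.
#' @param truth_train binary training gene x term matrix.
#' @param Kx_cross kernel values, test genes in rows, training genes in
#'   columns.
#' @param C regularization constant (default 1).
#' @param quiet suppress skip messages.
#' @return matrix of decision values, test genes x terms (NA columns for
#'   skipped terms), with attribute `skipped`.
#' @export
train_binary_svms <- function(Kx_train, truth_train, Kx_cross, C = 1, quiet = TRUE) {
  terms <- colnames(truth_train)
  out <- matrix(NA_real_, nrow(Kx_cross), ncol(truth_train),
                dimnames = list(rownames(Kx_cross), terms))
  skipped <- character(0)
  K <- unclass(Kx_train)
  for (t in seq_along(terms)) {
    yb <- ifelse(truth_train[, t] > 0, 1, -1)
    if (length(unique(yb)) < 2L) {
      skipped <- c(skipped, terms[[t]])
      next
    }
    a <- .svm_dual(K, yb, C = C)
    out[, t] <- as.numeric(unclass(Kx_cross) %*% (a * yb))
  }
  if (!quiet && length(skipped) > 0L) {
    message(sprintf("skipped %d single-class terms", length(skipped)))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney statistic: the probability that a random positive scores
#' above a random negative, with ties contributing 1/2. Returns NA when the
#' labels are single-class.
#'
#' @param scores numeric score vector.
#' @param labels binary (0/1) truth vector.
#' @return AUC in \[0, 1\], or NA for single-class input.
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Score tables
#'
#' Genes x terms grids of confidence scores and matching binary truth.
#'
#' @param scores numeric matrix, genes x terms.
#' @param truth binary matrix of identical shape and dimnames.
#' @return an object of class `score_table`.
#' @export
score_table <- function(scores, truth) {
  stopifnot(identical(dim(scores), dim(truth)),
            identical(dimnames(scores), dimnames(truth)))
  structure(list(scores = scores, truth = truth), class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table: %d genes x %d terms\n", nrow(x$scores), ncol(x$scores)))
  invisible(x)
}

#' Macro (term-averaged) AUC
#'
#' Unweighted mean of per-term AUCs over terms with a defined AUC (at least
#' one positive and one negative gene, and a non-NA score column).
#'
#' @param table a [score_table()].
#' @return macro AUC.
#' @export
macro_auc <- function(table) {
  per_term <- per_term_auc(table)
  vals <- per_term$auc[!is.na(per_term$auc)]
  if (length(vals) == 0L) stop("no term with a defined AUC")
  mean(vals)
}

#' Per-term AUC table
#'
#' @param table a [score_table()].
#' @return data.frame with columns `term`, `frequency` (positive genes),
#'   `auc`.
#' @export
per_term_auc <- function(table) {
  terms <- colnames(table$scores)
  aucs <- vapply(seq_along(terms), function(t) {
    s <- table$scores[, t]
    ok <- !is.na(s)          # genes scored for this term (e.g. term not
    if (!any(ok)) return(NA_real_)   # skipped in that gene's fold)
    auc(s[ok], table$truth[ok, t])
  }, 0)
  data.frame(term = terms, frequency = colSums(table$truth), auc = aucs,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Protein-centric precision and recall
#'
#' Per gene: precision = |pred n truth| / |pred| (NA when nothing is
#' predicted), recall = |pred n truth| / |truth|. Genes with empty truth
#' sets are excluded.
#'
#' @param pred named list of predicted term sets.
#' @param truth named list of true term sets (same genes).
#' @return data.frame with columns `gene`, `precision`, `recall`.
#' @export
protein_centric_pr <- function(pred, truth) {
  genes <- names(truth)[vapply(truth, length, 1L) > 0L]
  res <- lapply(genes, function(g) {
    p <- pred[[g]]
    tp <- length(intersect(p, truth[[g]]))
    data.frame(gene = g,
               precision = if (length(p) == 0L) NA_real_ else tp / length(p),
               recall = tp / length(truth[[g]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Protein-centric F-max
#'
#' For each threshold t on the grid, a gene's predicted set is the terms
#' scoring >= t; precision is averaged over genes with at least one
#' prediction, recall over all genes with non-empty truth (CAFA
#' convention); F(t) is the harmonic mean of the two averages and F-max the
#' maximum over the grid.
#'
#' @param table a [score_table()].
#' @param thresholds optional numeric grid; default 101 points spanning the
#'   observed finite score range.
#' @return F-max value.
#' @export
fmax <- function(table, thresholds = NULL) {
  S <- table$scores
  S[!is.finite(S)] <- min(S[is.finite(S)], 0) - 1
  if (is.null(thresholds)) {
    rng <- range(S)
    thresholds <- if (rng[[1L]] == rng[[2L]]) rng[[1L]] else
      seq(rng[[1L]], rng[[2L]], length.out = 101L)
  }
  keep <- rowSums(table$truth) > 0
  S <- S[keep, , drop = FALSE]
  Tr <- table$truth[keep, , drop = FALSE]
  best <- 0
  for (t in thresholds) {
    P <- S >= t
    npred <- rowSums(P)
    tp <- rowSums(P & Tr == 1)
    covered <- npred > 0
    if (!any(covered)) next
    prec <- mean(tp[covered] / npred[covered])
    rec <- mean(tp / rowSums(Tr == 1))
    if (prec + rec > 0) best <- max(best, 2 * prec * rec / (prec + rec))
  }
  best
}

#' Seeded balanced cross-validation folds
#'
#' Random gene-level partition into k folds whose sizes differ by at most
#' one; deterministic for a given seed (the global RNG state is preserved).
#'
#' @param genes character vector of gene ids.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return a `fold_plan`: list with `fold` (named integer vector), `k`,
#'   `seed`.
#' @export
make_folds <- function(genes, k = 5L, seed = 42L) {
  if (k < 2L) stop("k must be at least 2")
  if (length(genes) < k) stop("fewer genes than folds")
  perm <- with_seed(seed, sample.int(length(genes)))
  fold <- stats::setNames(rep_len(seq_len(k), length(genes))[order(perm)], genes)
  # rep_len over a permutation: sizes differ by <= 1
  structure(list(fold = fold, k = k, seed = seed), class = "fold_plan")
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Drop grouping terms before metric computation
#'
#' Removes the listed term columns from both scores and truth (terms used
#' only for grouping, e.g. onset/pace-of-progression umbrella terms, are
#' ignored when computing performance). Unknown terms trigger a warning and
#' are ignored.
#'
#' @param table a [score_table()].
#' @param grouping character vector of term ids to drop.
#' @return a [score_table()] without those columns.
#' @export
exclude_grouping_terms <- function(table, grouping) {
  unknown <- setdiff(grouping, colnames(table$scores))
  if (length(unknown) > 0L) {
    warning(sprintf("ignoring %d unknown grouping terms", length(unknown)))
  }
  keep <- !(colnames(table$scores) %in% grouping)
  score_table(table$scores[, keep, drop = FALSE], table$truth[, keep, drop = FALSE])
}

#' Leave-one-source-out ablation
#'
#' For each source s, the percent change in macro AUC when s is left out,
#' relative to the macro AUC with all sources:
#' 100 * (AUC_without_s - AUC_all) / AUC_all.
#'
#' @param sources character vector of source names (>= 2).
#' @param evaluate function taking a character vector of included sources
#'   and returning a macro AUC.
#' @return list with `auc_all` and `deltas` (data.frame: source,
#'   auc_without, pct_change).
#' @export
leave_one_source_out <- function(sources, evaluate) {
  if (length(sources) < 2L) stop("need at least two sources for ablation")
  auc_all <- evaluate(sources)
  if (auc_all == 0) stop("macro AUC with all sources is zero")
  rows <- lapply(sources, function(s) {
    a <- evaluate(setdiff(sources, s))
    data.frame(source = s, auc_without = a,
               pct_change = 100 * (a - auc_all) / auc_all,
               stringsAsFactors = FALSE)
  })
  list(auc_all = auc_all, deltas = do.call(rbind, rows))
}

#' Two-sided paired t-test p-value
#'
#' Textbook statistic t = mean(d) / (sd(d) / sqrt(n)) on the paired
#' differences, with Student-t reference distribution on n - 1 degrees of
#' freedom. Returns NA when the differences have zero variance.
#'
#' @param a,b equal-length numeric vectors (e.g. per-term AUCs of two
#'   methods).
#' @return p-value, or NA for zero-variance differences.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  s <- stats::sd(d)
  if (s == 0) return(NA_real_)
  t_stat <- mean(d) / (s / sqrt(length(d)))
  2 * stats::pt(-abs(t_stat), df = length(d) - 1L)
}
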