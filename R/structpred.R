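#' Structured SVM over a candidate-label catalog
#'
#' The model scores input-output pairs with a compatibility function
#' f(x, y) that is linear in the joint (tensor-product) feature space, and
#' predicts the catalog label maximizing it. Training maximizes the margin
#' between the compatibility of the true label and every other candidate,
#' rescaled by the Hamming loss (margin-rescaled structured SVM), by
#' n-slack cutting-plane optimization with exhaustive loss-augmented
#' inference over the finite catalog.
#'
#' In dual form, with joint kernel K((x,y),(x',y')) = K_X(x,x') K_Y(y,y')
#' and one dual weight alpha(i, yhat) per (training gene, candidate) pair,
#'
#'   f(x, y) = sum_{i, yhat} alpha(i, yhat) K_X(x_i, x)
#'             (K_Y(y_i, y) - K_Y(yhat, y)).
#'
#' @name structpred
NULL

#' Build the candidate-label catalog
#'
#' The candidate set is the collection of distinct label vectors observed in
#' the training annotations (the biologically realized term combinations),
#' deduplicated and ordered lexicographically on the 0/1 pattern for
#' determinism.
#'
#' @param train_labels list of character vectors (term sets), or a binary
#'   gene x term matrix.
#' @param terms term order for the label vectors.
#' @return an object of class `candidate_catalog`: a binary matrix, one row
#'   per distinct label.
#' @export
build_catalog <- function(train_labels, terms) {
  if (is.matrix(train_labels)) {
    Y <- train_labels[, terms, drop = FALSE]
  } else {
    if (length(train_labels) == 0L) stop("empty training label set")
    Y <- matrix(0, length(train_labels), length(terms),
                dimnames = list(NULL, terms))
    for (i in seq_along(train_labels)) {
      Y[i, intersect(train_labels[[i]], terms)] <- 1
    }
  }
  if (nrow(Y) == 0L) stop("empty training label set")
  key <- apply(Y, 1L, paste, collapse = "")
  Y <- Y[!duplicated(key), , drop = FALSE]
  Y <- Y[order(apply(Y, 1L, paste, collapse = "")), , drop = FALSE]
  rownames(Y) <- NULL
  structure(Y, class = c("candidate_catalog", "matrix", "array"))
}

#' @export
print.candidate_catalog <- function(x, ...) {
  cat(sprintf("candidate_catalog: %d labels over %d terms\n", nrow(x), ncol(x)))
  invisible(x)
}

# index of each training label row in the catalog (labels must all occur)
.catalog_index <- function(labels, catalog) {
  key_cat <- apply(catalog, 1L, paste, collapse = "")
  key_lab <- apply(labels, 1L, paste, collapse = "")
  idx <- match(key_lab, key_cat)
  if (anyNA(idx)) stop("training label missing from catalog")
  idx
}

#' Train the margin-rescaled structured SVM
#'
#' n-slack cutting-plane: for each training gene the most-violated candidate
#' under loss-augmented inference (exhaustive over the catalog) is added to
#' a working set whenever it violates its margin constraint by more than
#' `epsilon` beyond the current slack, and the dual QP restricted to the
#' working sets is re-solved by blockwise pairwise coordinate ascent.
#' At termination every constraint
#'   f(x_i, y_i) >= f(x_i, yhat) + Hamming(y_i, yhat) - xi_i - epsilon
#' holds over the full catalog.
#'
#' @param Kx [kernel_matrix()] over the training genes (combined across
#'   sources, per-source normalized).
#' @param labels binary gene x term matrix of true (expanded, filtered)
#'   annotations; rownames are gene ids.
#' @param catalog a [build_catalog()] result over the same term order.
#' @param C regularization constant (> 0); per-gene dual mass is capped at C.
#' @param epsilon convergence tolerance on margin violations (> 0).
#' @param max_passes cap on outer cutting-plane passes.
#' @param quiet suppress the iteration-cap warning.
#' @return an object of class `structured_model`.
#' @export
train_structured <- function(Kx, labels, catalog, C = 1, epsilon = 0.01,
                             max_passes = 100L, quiet = FALSE) {
  if (C <= 0) stop("C must be positive")
  if (epsilon <= 0) stop("epsilon must be positive")
  stopifnot(nrow(labels) == nrow(Kx))
  n <- nrow(labels)
  L <- nrow(catalog)
  KX <- unclass(Kx)
  Ky_cat <- tcrossprod(unclass(catalog))           # L x L label kernel
  y_idx <- .catalog_index(labels, catalog)
  M <- Ky_cat[y_idx, , drop = FALSE]               # n x L: K_Y(y_i, cat_c)
  rs_cat <- rowSums(catalog)
  # Hamming loss Delta[i, c] = |y_i| + |cat_c| - 2 y_i . cat_c
  Delta <- outer(rs_cat[y_idx], rs_cat, "+") - 2 * M
  alpha <- matrix(0, n, L)
  work <- vector("list", n)                        # working set per gene
  fmat <- function() {
    # f(x_i, cat_c) for all i, c: S = diag(rowSums(alpha)) M - alpha Ky_cat
    S <- rowSums(alpha) * M - alpha %*% Ky_cat
    KX %*% S
  }
  inner_solve <- function(tol, sweeps = 200L) {
    # Gauss-Seidel over per-gene blocks. Within a block only row i of the
    # compatibility matrix is needed, so local updates are O(L); the
    # cross-block rank-1 update is flushed once per block visit.
    Fm <- fmat()
    for (sweep in seq_len(sweeps)) {
      moved <- FALSE
      for (i in seq_len(n)) {
        W <- work[[i]]
        if (length(W) == 0L) next
        nW <- length(W)
        # block Hessian: J((i,c1),(i,c2)) = Kx[i,i] (y_i - c1).(y_i - c2)
        Dif <- matrix(labels[i, ], nW, ncol(catalog), byrow = TRUE) -
          catalog[W, , drop = FALSE]
        H <- KX[i, i] * tcrossprod(Dif)
        # only f(x_i, .) at the true label and the working candidates is
        # needed inside the block; fv = (f_i[true], f_i[W])
        idx <- c(y_idx[i], W)
        B <- Ky_cat[idx, idx, drop = FALSE]
        fv <- Fm[i, idx]
        a_i <- alpha[i, W]
        dvec <- numeric(nW)        # net alpha change per working candidate
        bump_local <- function(j, d) {
          a_i[j] <<- a_i[j] + d
          dvec[j] <<- dvec[j] + d
          fv <<- fv + d * KX[i, i] * (B[1L, ] - B[j + 1L, ])
        }
        for (rep in seq_len(20L * nW)) {
          g <- Delta[i, W] - (fv[1L] - fv[-1L])   # constraint violations
          budget <- C - sum(a_i)
          j1 <- which.max(g)
          sup <- which(a_i > 1e-12)
          if (budget > 1e-12 && g[j1] > tol) {
            h <- H[j1, j1]
            d <- if (h <= 1e-12) budget else min(g[j1] / h, budget)
            if (d <= 0) break
            bump_local(j1, d)
          } else if (length(sup) > 0L) {
            j2 <- sup[which.min(g[sup])]
            if (budget <= 1e-12 && j1 != j2 && g[j1] - g[j2] > tol) {
              # transfer dual mass from the least- to the most-violated candidate
              h <- H[j1, j1] - 2 * H[j1, j2] + H[j2, j2]
              d <- if (h <= 1e-12) a_i[j2] else min((g[j1] - g[j2]) / h, a_i[j2])
              if (d <= 0) break
              bump_local(j1, d)
              bump_local(j2, -d)
            } else if (g[j2] < -tol) {
              # support vector with negative gradient: shrink it
              h <- H[j2, j2]
              d <- if (h <= 1e-12) a_i[j2] else min(-g[j2] / h, a_i[j2])
              if (d <= 0) break
              bump_local(j2, -d)
            } else break
          } else break
        }
        if (any(dvec != 0)) {
          alpha[i, W] <<- a_i
          row_delta <- sum(dvec) * M[i, ] -
            as.numeric(dvec %*% Ky_cat[W, , drop = FALSE])
          Fm <- Fm + tcrossprod(KX[, i], row_delta)
          moved <- TRUE
        }
      }
      if (!moved) break
    }
  }
  converged <- FALSE
  for (pass in seq_len(max_passes)) {
    Fm <- fmat()
    viol_all <- Delta - (Fm[cbind(seq_len(n), y_idx)] - Fm)   # n x L violations
    viol_all[cbind(seq_len(n), y_idx)] <- 0
    xi <- pmax(0, apply(viol_all, 1L, max))
    # slack implied by current working set (QP optimum): max violation there
    xi_ws <- vapply(seq_len(n), function(i) {
      W <- work[[i]]
      if (length(W) == 0L) 0 else max(0, max(viol_all[i, W]))
    }, 0)
    added <- FALSE
    for (i in seq_len(n)) {
      c_star <- which.max(viol_all[i, ])
      if (viol_all[i, c_star] > xi_ws[[i]] + epsilon && !(c_star %in% work[[i]])) {
        work[[i]] <- c(work[[i]], c_star)
        added <- TRUE
      }
    }
    if (!added) { converged <- TRUE; break }
    inner_solve(tol = epsilon / 2)
  }
  if (!converged && !quiet) {
    warning("cutting-plane iteration cap reached; returning best-so-far model")
  }
  Fm <- fmat()
  viol_all <- Delta - (Fm[cbind(seq_len(n), y_idx)] - Fm)
  viol_all[cbind(seq_len(n), y_idx)] <- 0
  # the QP slack: max violation over each gene's working-set constraints;
  # the full-catalog audit checks no constraint exceeds it by > epsilon
  slack <- vapply(seq_len(n), function(i) {
    W <- work[[i]]
    if (length(W) == 0L) 0 else max(0, max(viol_all[i, W]))
  }, 0)
  structure(
    list(alpha = alpha, catalog = catalog, labels = labels,
         train_genes = rownames(labels), terms = colnames(catalog),
         y_idx = y_idx, C = C, epsilon = epsilon, slack = slack,
         converged = converged,
         # cached expansion: f(x, cat) = t(S) %*% Kx(train, x)
         S = rowSums(alpha) * M - alpha %*% Ky_cat),
    class = "structured_model")
}

#' @export
print.structured_model <- function(x, ...) {
  cat(sprintf(
    "structured_model: %d training genes, catalog %d labels x %d terms, C=%g, converged=%s\n",
    length(x$train_genes), nrow(x$catalog), length(x$terms), x$C, x$converged))
  invisible(x)
}

#' Compatibility scores of a query gene against every catalog label
#'
#' @param model a [train_structured()] model.
#' @param kx_col input-kernel values between the query gene and each
#'   training gene, in training order.
#' @return numeric vector of f(x, y) over catalog rows.
#' @export
catalog_scores <- function(model, kx_col) {
  kx_col <- as.numeric(kx_col)
  if (length(kx_col) != length(model$train_genes)) {
    stop("kernel column length does not match training genes")
  }
  as.numeric(crossprod(model$S, kx_col))
}

#' Compatibility function f(x, y)
#'
#' Dual expansion of the margin-rescaled structured SVM with the product
#' joint kernel: a sum over stored (training gene, candidate) weights of
#' alpha * K_X(x_i, x) * (K_Y(y_i, y) - K_Y(yhat, y)). `y` may be any
#' binary label vector over the model's term order, not only catalog rows.
#'
#' @param model a [train_structured()] model.
#' @param kx_col input-kernel values of the query vs training genes.
#' @param y binary label vector over `model$terms`.
#' @return numeric compatibility score.
#' @export
compatibility <- function(model, kx_col, y) {
  y <- as.numeric(y)
  if (length(y) != length(model$terms)) stop("label dimension mismatch")
  kx_col <- as.numeric(kx_col)
  if (length(kx_col) != length(model$train_genes)) {
    stop("kernel column length does not match training genes")
  }
  ky_true <- as.numeric(model$labels %*% y)        # K_Y(y_i, y)
  ky_cat <- as.numeric(model$catalog %*% y)        # K_Y(cat_c, y)
  per_gene <- rowSums(model$alpha) * ky_true - as.numeric(model$alpha %*% ky_cat)
  sum(kx_col * per_gene)
}

#' Predict the label of a query gene
#'
#' Argmax of the compatibility function over the candidate catalog; ties
#' broken by lowest catalog index. The result is hierarchically consistent
#' by catalog construction.
#'
#' @param model a [train_structured()] model.
#' @param kx_col input-kernel values of the query vs training genes.
#' @return list with `label` (binary vector over terms), `terms` (character
#'   vector of predicted terms), `index` (catalog row), `score`.
#' @export
predict_structured <- function(model, kx_col) {
  sc <- catalog_scores(model, kx_col)
  idx <- which.max(sc)                             # which.max: lowest index on ties
  label <- model$catalog[idx, ]
  list(label = label, terms = model$terms[label == 1], index = idx,
       score = sc[[idx]])
}

#' Per-term confidence scores
#'
#' The confidence of term t for a query gene is the compatibility margin
#' between the best catalog label containing t and the best catalog label
#' not containing t:
#'
#'   conf(t) = max over y containing t of f(x, y)
#'           - max over y not containing t of f(x, y).
#'
#' Subtracting the second max cancels the gene-specific scale of the
#' compatibility function, so confidences are comparable across genes (the
#' property term-centric AUC needs). Terms absent from every catalog label
#' get -Inf (ranked last); terms present in every label get +Inf. Scores
#' are monotone along the hierarchy: labels are hierarchically consistent,
#' so labels containing a child also contain its parent (first max over a
#' superset) and labels missing the parent also miss the child (second max
#' over a subset).
#'
#' @param model a [train_structured()] model.
#' @param kx_col input-kernel values of the query vs training genes.
#' @return named numeric vector over `model$terms`.
#' @export
term_confidence <- function(model, kx_col) {
  sc <- catalog_scores(model, kx_col)
  out <- vapply(seq_along(model$terms), function(t) {
    has <- model$catalog[, t] == 1
    a <- if (any(has)) max(sc[has]) else -Inf
    b <- if (any(!has)) max(sc[!has]) else -Inf
    a - b
  }, 0)
  stats::setNames(out, model$terms)
}

#' Serialize a structured model to a text file
#'
#' JSON container holding the term order, catalog bitmaps (as 0/1 strings),
#' training gene ids, labels, dual weights as sparse triplets, and the
#' hyperparameters. Round-trips through [read_structured_model()].
#'
#' @param model a [train_structured()] model.
#' @param path output path.
#' @export
write_structured_model <- function(model, path) {
  nz <- which(model$alpha != 0, arr.ind = TRUE)
  payload <- list(
    terms = model$terms,
    catalog = apply(model$catalog, 1L, paste, collapse = ""),
    train_genes = model$train_genes,
    labels = apply(model$labels, 1L, paste, collapse = ""),
    alpha = list(i = as.integer(nz[, 1L]), j = as.integer(nz[, 2L]),
                 x = as.numeric(model$alpha[nz])),
    C = model$C, epsilon = model$epsilon, slack = as.numeric(model$slack),
    converged = model$converged)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a structured model written by [write_structured_model()]
#'
#' @param path input path.
#' @return a `structured_model`.
#' @export
read_structured_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  bits <- function(strs) {
    do.call(rbind, lapply(strs, function(s) as.numeric(strsplit(s, "")[[1L]])))
  }
  catalog <- bits(p$catalog)
  colnames(catalog) <- p$terms
  catalog <- structure(catalog, class = c("candidate_catalog", "matrix", "array"))
  labels <- bits(p$labels)
  dimnames(labels) <- list(p$train_genes, p$terms)
  alpha <- matrix(0, nrow(labels), nrow(catalog))
  if (length(p$alpha$i) > 0L) {
    alpha[cbind(p$alpha$i, p$alpha$j)] <- p$alpha$x
  }
  y_idx <- .catalog_index(labels, catalog)
  Ky_cat <- tcrossprod(unclass(catalog))
  M <- Ky_cat[y_idx, , drop = FALSE]
  structure(
    list(alpha = alpha, catalog = catalog, labels = labels,
         train_genes = p$train_genes, terms = p$terms, y_idx = y_idx,
         C = p$C, epsilon = p$epsilon, slack = p$slack,
         converged = isTRUE(p$converged),
         S = rowSums(alpha) * M - alpha %*% Ky_cat),
    class = "structured_model")
}
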