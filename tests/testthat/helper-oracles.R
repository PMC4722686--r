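# Independent oracles used across the suite. These deliberately use naive
# algorithms (edge expansion, pair counting, double loops) so they share no
# code path with the implementation they check.

# transitive closure of the parent relation by repeated boolean matrix
# multiplication; returns list term -> ancestor set
closure_oracle <- function(parents) {
  terms <- names(parents)
  A <- matrix(FALSE, length(terms), length(terms), dimnames = list(terms, terms))
  for (t in terms) A[t, parents[[t]]] <- TRUE
  R <- A
  repeat {
    R2 <- R | ((R %*% A) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  lapply(stats::setNames(terms, terms), function(t) sort(terms[R[t, ]]))
}

# reachability from a root over child edges (BFS on an explicit edge list)
reachable_oracle <- function(parents, root) {
  edges <- do.call(rbind, lapply(names(parents), function(t) {
    if (length(parents[[t]]) == 0L) NULL else cbind(parents[[t]], t)
  }))
  seen <- root
  repeat {
    nxt <- unique(edges[edges[, 1L] %in% seen, 2L])
    new <- setdiff(nxt, seen)
    if (length(new) == 0L) break
    seen <- c(seen, new)
  }
  sort(seen)
}

# AUC by explicit pair counting with half-credit ties
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# a small random parent map (independent of the package generator)
rand_parents <- function(n, seed, max_parents = 3L) {
  set.seed(seed)
  ids <- sprintf("N%03d", seq_len(n))
  parents <- stats::setNames(vector("list", n), ids)
  parents[[ids[[1L]]]] <- character(0)
  for (i in seq_len(n)[-1L]) {
    k <- sample.int(min(max_parents, i - 1L), 1L)
    parents[[ids[[i]]]] <- ids[sample.int(i - 1L, k)]
  }
  parents
}

# random hierarchically consistent label matrix over a DAG
rand_labels <- function(dag, n_genes, seed, terms = setdiff(dag$terms, dag$root)) {
  set.seed(seed)
  leaves <- dag$terms[vapply(dag$children[dag$terms], length, 1L) == 0L]
  ann <- stats::setNames(vector("list", n_genes), sprintf("g%03d", seq_len(n_genes)))
  for (g in names(ann)) {
    ann[[g]] <- leaves[sample.int(length(leaves), min(sample(1:3, 1L), length(leaves)))]
  }
  ex <- propagate_true_path(annotation_set(ann), dag)
  label_matrix(ex, terms)
}

# tiny OBO fixture text
obo_chain <- c(
  "format-version: 1.2", "",
  "[Term]", "id: R0", "name: root", "",
  "[Term]", "id: A1", "name: mid", "is_a: R0 ! root", "",
  "[Term]", "id: B2", "name: leaf", "is_a: A1 ! mid")
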