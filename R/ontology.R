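#' Ontology DAGs and hierarchically consistent annotation sets
#'
#' An `ontology_dag` is the is-a graph of one subontology: a set of term
#' identifiers, a parent map (is-a edges only), a single root, and per-term
#' name and depth metadata. Depth of the root is 0 and depth of any other
#' term is 1 + the minimum depth over its parents.
#'
#' @name ontology
NULL

#' Construct and validate an ontology DAG
#'
#' @param parents named list mapping each term to a character vector of its
#'   is-a parents (the root maps to an empty vector). Every referenced parent
#'   must itself be a list entry.
#' @param names optional named character vector of human-readable term names.
#' @return An object of class `ontology_dag` with elements `terms` (sorted),
#'   `parents`, `children`, `root`, `name`, `depth`.
#' @export
ontology_dag <- function(parents, names = NULL) {
  terms <- sort(base::names(parents))
  if (length(terms) == 0L) stop("ontology has no terms")
  parents <- lapply(parents[terms], function(p) sort(unique(as.character(p))))
  for (t in terms) {
    p <- parents[[t]]
    missing <- setdiff(p, terms)
    if (length(missing) > 0L) {
      stop(sprintf("term %s references missing parent %s", t, missing[[1L]]))
    }
  }
  roots <- terms[vapply(parents, length, 1L) == 0L]
  if (length(roots) != 1L) {
    stop(sprintf("expected exactly one root term, found %d", length(roots)))
  }
  # Kahn topological sort doubles as the cycle check
  indeg <- vapply(parents, length, 1L)
  children <- .invert_parent_map(parents, terms)
  queue <- roots
  seen <- 0L
  depth <- stats::setNames(rep.int(NA_integer_, length(terms)), terms)
  depth[roots] <- 0L
  while (length(queue) > 0L) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[t]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(terms)) {
    bad <- terms[indeg > 0L][[1L]]
    stop(sprintf("cycle detected in ontology involving edge into term %s", bad))
  }
  # depths via relaxation in topological order
  topo <- .topological_order(parents, children, roots)
  for (t in topo) {
    if (t == roots) next
    depth[[t]] <- 1L + min(depth[parents[[t]]])
  }
  nm <- stats::setNames(rep.int(NA_character_, length(terms)), terms)
  if (!is.null(names)) nm[base::names(names)] <- unname(names)
  structure(
    list(terms = terms, parents = parents, children = children,
         root = roots, name = nm, depth = depth),
    class = "ontology_dag")
}

.invert_parent_map <- function(parents, terms) {
  children <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) children[[t]] <- character(0)
  for (t in terms) {
    for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  }
  children
}

.topological_order <- function(parents, children, root) {
  indeg <- vapply(parents, length, 1L)
  queue <- root
  out <- character(0)
  while (length(queue) > 0L) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    out <- c(out, t)
    for (ch in children[[t]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  out
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("ontology_dag: %d terms, root %s, max depth %d\n",
              length(x$terms), x$root, max(x$depth)))
  invisible(x)
}

#' Parse an OBO 1.2 ontology
#'
#' Reads `[Term]` stanzas; only `is_a` lines become edges and stanzas marked
#' `is_obsolete: true` are skipped. All other relationship types are ignored.
#'
#' @param path path to an OBO file, or a character vector of OBO lines.
#' @return an [ontology_dag()].
#' @export
parse_obo <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- trimws(lines)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0L) stop("no [Term] stanzas found")
  bounds <- c(stanza_starts, length(lines) + 1L)
  parents <- list()
  names_vec <- character(0)
  for (k in seq_along(stanza_starts)) {
    chunk <- lines[(bounds[[k]] + 1L):(bounds[[k + 1L]] - 1L)]
    # a stanza ends at the next bracketed header
    hdr <- grep("^\\[", chunk)
    if (length(hdr) > 0L) chunk <- chunk[seq_len(hdr[[1L]] - 1L)]
    get <- function(tag) {
      v <- chunk[startsWith(chunk, paste0(tag, ":"))]
      trimws(sub(paste0("^", tag, ":"), "", v))
    }
    id <- get("id")
    if (length(id) == 0L) next
    id <- id[[1L]]
    if (any(tolower(get("is_obsolete")) == "true")) next
    isa <- get("is_a")
    # strip trailing "! name" comments and any qualifier after whitespace
    isa <- vapply(isa, function(s) trimws(strsplit(s, "!", fixed = TRUE)[[1L]][1L]), "")
    isa <- vapply(isa, function(s) strsplit(s, "[[:space:]]+")[[1L]][1L], "")
    nm <- get("name")
    parents[[id]] <- unique(unname(isa[nzchar(isa)]))
    if (length(nm) > 0L) names_vec[[id]] <- nm[[1L]]
  }
  ontology_dag(parents, names = names_vec)
}

#' Extract the induced subontology under a root term
#'
#' Returns the DAG induced on the given term and all its descendants; edges
#' to terms outside that set are dropped.
#'
#' @param dag an [ontology_dag()].
#' @param root term identifier to use as the new root.
#' @return an [ontology_dag()].
#' @export
subontology <- function(dag, root) {
  if (!root %in% dag$terms) stop(sprintf("unknown root term %s", root))
  keep <- character(0)
  queue <- root
  while (length(queue) > 0L) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    if (t %in% keep) next
    keep <- c(keep, t)
    queue <- c(queue, dag$children[[t]])
  }
  parents <- lapply(stats::setNames(keep, keep), function(t) {
    intersect(dag$parents[[t]], keep)
  })
  parents[[root]] <- character(0)
  ontology_dag(parents, names = dag$name[keep])
}

#' Ancestors of a term
#'
#' All terms on any directed is-a path from `term` to the root, excluding
#' the term itself, including the root.
#'
#' @param dag an [ontology_dag()].
#' @param term a term identifier present in the DAG.
#' @return character vector of ancestor term identifiers (sorted).
#' @export
ancestors <- function(dag, term) {
  if (!term %in% dag$terms) stop(sprintf("unknown term %s", term))
  out <- character(0)
  queue <- dag$parents[[term]]
  while (length(queue) > 0L) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    if (t %in% out) next
    out <- c(out, t)
    queue <- c(queue, dag$parents[[t]])
  }
  sort(out)
}

# ancestor sets for every term at once (used by propagation); list keyed by term
.ancestor_closure <- function(dag) {
  topo <- .topological_order(dag$parents, dag$children, dag$root)
  anc <- stats::setNames(vector("list", length(dag$terms)), dag$terms)
  for (t in topo) {
    ps <- dag$parents[[t]]
    anc[[t]] <- sort(unique(c(ps, unlist(anc[ps], use.names = FALSE))))
  }
  anc
}

#' Annotation sets
#'
#' An `annotation_set` maps genes to sets of ontology terms and records
#' whether the sets have been expanded by the true-path rule (annotation with
#' a term implies annotation with every ancestor of that term).
#'
#' @param annotations named list: gene id -> character vector of term ids.
#' @param expanded logical; whether the sets are true-path-expanded.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(annotations, expanded = FALSE) {
  stopifnot(is.list(annotations))
  if (is.null(names(annotations)) || anyDuplicated(names(annotations))) {
    stop("annotations must be a uniquely named list keyed by gene")
  }
  annotations <- lapply(annotations, function(x) sort(unique(as.character(x))))
  structure(list(annotations = annotations[order(names(annotations))],
                 expanded = isTRUE(expanded)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d genes, %d distinct terms, expanded=%s\n",
              length(x$annotations),
              length(unique(unlist(x$annotations, use.names = FALSE))),
              x$expanded))
  invisible(x)
}

#' Expand annotations by the true-path rule
#'
#' Replaces every gene's term set by its union with all ancestors of its
#' terms. Idempotent and monotone.
#'
#' @param ann an [annotation_set()].
#' @param dag an [ontology_dag()] containing every annotated term.
#' @return an expanded [annotation_set()].
#' @export
propagate_true_path <- function(ann, dag) {
  all_terms <- unique(unlist(ann$annotations, use.names = FALSE))
  missing <- setdiff(all_terms, dag$terms)
  if (length(missing) > 0L) {
    stop(sprintf("annotated term %s not in ontology", missing[[1L]]))
  }
  anc <- .ancestor_closure(dag)
  expanded <- lapply(ann$annotations, function(ts) {
    sort(unique(c(ts, unlist(anc[ts], use.names = FALSE))))
  })
  annotation_set(expanded, expanded = TRUE)
}

#' Filter annotation terms by gene support and drop root terms
#'
#' Removes terms annotated to fewer than `min_genes` genes and any term in
#' `drop_roots` from every gene's set, then drops genes whose set becomes
#' empty. Requires the annotations to be expanded so that ancestor counts
#' dominate descendant counts (filtering then preserves hierarchical
#' consistency).
#'
#' @param ann an expanded [annotation_set()].
#' @param dag an [ontology_dag()].
#' @param min_genes minimum number of annotated genes for a term to survive.
#' @param drop_roots terms removed unconditionally (the subontology root by
#'   default).
#' @return list with `ann` (the filtered [annotation_set()]) and `terms`
#'   (retained terms, sorted lexicographically).
#' @export
filter_terms <- function(ann, dag, min_genes = 10L, drop_roots = dag$root) {
  if (min_genes < 1L) stop("min_genes must be >= 1")
  if (!ann$expanded) stop("filter_terms requires a true-path-expanded annotation_set")
  counts <- table(unlist(ann$annotations, use.names = FALSE))
  keep <- setdiff(names(counts)[counts >= min_genes], drop_roots)
  filtered <- lapply(ann$annotations, function(ts) intersect(ts, keep))
  filtered <- filtered[vapply(filtered, length, 1L) > 0L]
  if (length(filtered) == 0L) stop("no genes left after term filtering")
  retained <- sort(unique(unlist(filtered, use.names = FALSE)))
  list(ann = annotation_set(filtered, expanded = TRUE), terms = retained)
}

#' Test hierarchical consistency of a term set
#'
#' TRUE iff for every term in the set, every ancestor of that term is also
#' in the set, ignoring the terms listed in `ignore` (the dropped
#' subontology root by default, matching [filter_terms()]).
#'
#' @param label character vector of term identifiers.
#' @param dag an [ontology_dag()].
#' @param ignore terms whose presence is not required (default the root).
#' @return logical scalar.
#' @export
is_consistent <- function(label, dag, ignore = dag$root) {
  label <- unique(as.character(label))
  if (length(label) == 0L) return(TRUE)
  if (!all(label %in% dag$terms)) {
    stop(sprintf("term %s not in ontology", setdiff(label, dag$terms)[[1L]]))
  }
  for (t in label) {
    req <- setdiff(ancestors(dag, t), ignore)
    if (!all(req %in% label)) return(FALSE)
  }
  TRUE
}

#' Read a gene-term annotation table
#'
#' Two tab-separated columns, `gene<TAB>term`, one pair per line; lines
#' starting with `#` are comments.
#'
#' @param path file path.
#' @param id_map optional named character vector mapping input gene ids to
#'   canonical ids (identity for ids not listed).
#' @return a raw (unexpanded) [annotation_set()].
#' @export
read_annotations <- function(path, id_map = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop(sprintf("no annotation rows in %s", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad) > 0L) stop(sprintf("malformed annotation line %d in %s", bad[[1L]], path))
  genes <- vapply(parts, `[[`, "", 1L)
  if (!is.null(id_map)) genes <- .map_ids(genes, id_map)
  terms <- vapply(parts, `[[`, "", 2L)
  annotation_set(split(terms, genes), expanded = FALSE)
}

#' Write a gene-term annotation table
#'
#' @param ann an [annotation_set()].
#' @param path output file path.
#' @export
write_annotations <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in names(ann$annotations)) {
    for (t in ann$annotations[[g]]) writeLines(paste(g, t, sep = "\t"), con)
  }
  invisible(path)
}

.map_ids <- function(ids, id_map) {
  hit <- ids %in% names(id_map)
  ids[hit] <- unname(id_map[ids[hit]])
  ids
}

#' Convert an annotation set to a binary label matrix
#'
#' @param ann an [annotation_set()].
#' @param terms term order for the columns (lexicographic by convention).
#' @return binary matrix, genes in rows (sorted), terms in columns.
#' @export
label_matrix <- function(ann, terms) {
  genes <- names(ann$annotations)
  Y <- matrix(0, length(genes), length(terms), dimnames = list(genes, terms))
  for (g in genes) {
    hit <- intersect(ann$annotations[[g]], terms)
    Y[g, hit] <- 1
  }
  Y
}
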