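#' Per-gene feature matrices from heterogeneous sources
#'
#' Genes are characterized by four families of features: binary interaction
#' indicators from protein-network unions, binary GO-term indicators from
#' curated (non-computational) annotations, sentence co-occurrence word
#' counts from the literature, and binary disease-variant indicators from a
#' two-hop gene-disease-variant join.
#'
#' @name datasources
NULL

#' Construct a feature matrix
#'
#' Rows follow the master gene list; all-zero feature columns are dropped
#' (logged via message when `quiet = FALSE`).
#'
#' @param values numeric matrix with gene rownames and feature colnames.
#' @param source_tag one of `"network"`, `"go"`, `"literature"`, `"variant"`.
#' @param quiet suppress the dropped-column message.
#' @return an object of class `feature_matrix` (a matrix with attributes).
#' @export
feature_matrix <- function(values, source_tag, quiet = TRUE) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            ncol(values) == 0L || !is.null(colnames(values)))
  source_tag <- match.arg(source_tag, c("network", "go", "literature", "variant"))
  zero <- colSums(abs(values)) == 0
  if (any(zero)) {
    if (!quiet) message(sprintf("dropping %d all-zero %s feature columns", sum(zero), source_tag))
    values <- values[, !zero, drop = FALSE]
  }
  structure(values, source_tag = source_tag, class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s]: %d genes x %d features\n",
              attr(x, "source_tag"), nrow(x), ncol(x)))
  invisible(x)
}

#' Read an undirected edge list
#'
#' Tab-separated `gene_a<TAB>gene_b[<TAB>score]`. Pairs are order-normalized
#' and deduplicated; self-loops are dropped. The network name is taken from
#' the file stem.
#'
#' @param path file path.
#' @param min_score optional confidence threshold; edges with a third column
#'   below it are dropped. Default `-Inf` (any listed edge counts).
#' @param id_map optional named character vector remapping gene ids.
#' @return an `edge_set`: data.frame with columns `a`, `b` and a `name`
#'   attribute.
#' @export
read_edge_list <- function(path, min_score = -Inf, id_map = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  score <- vapply(parts, function(p) {
    if (length(p) >= 3L) suppressWarnings(as.numeric(p[[3L]])) else Inf
  }, 0)
  keep <- is.na(score) | score >= min_score
  a <- a[keep]; b <- b[keep]
  if (!is.null(id_map)) { a <- .map_ids(a, id_map); b <- .map_ids(b, id_map) }
  edge_set(a, b, name = sub("\\.[^.]*$", "", basename(path)))
}

#' Construct an edge set from endpoint vectors
#'
#' @param a,b character vectors of endpoints.
#' @param name network name.
#' @return an `edge_set` data.frame.
#' @export
edge_set <- function(a, b, name = "network") {
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  df <- unique(data.frame(a = lo, b = hi, stringsAsFactors = FALSE))
  df <- df[order(df$a, df$b), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "name") <- name
  class(df) <- c("edge_set", "data.frame")
  df
}

#' Binary network interaction features
#'
#' The union of all given networks yields one binary column per interactor
#' gene (component i is 1 iff the row gene interacts with gene i in the
#' combined network; the diagonal convention is 0). When `per_network` is
#' TRUE and more than one network is supplied, an additional binary block
#' per named network is appended (per-evidence networks kept separate).
#' Edges touching genes outside the master list are skipped (count logged).
#'
#' @param edge_sets list of [edge_set()] objects.
#' @param genes master gene list (row order of the result).
#' @param per_network append one block per individual network.
#' @param quiet suppress skip-count messages.
#' @return a [feature_matrix()] with `source_tag = "network"`.
#' @export
build_network_features <- function(edge_sets, genes, per_network = length(edge_sets) > 1L,
                                   quiet = TRUE) {
  if (inherits(edge_sets, "edge_set")) edge_sets <- list(edge_sets)
  blocks <- list()
  adj_from <- function(df, prefix) {
    inside <- df$a %in% genes & df$b %in% genes
    if (!quiet && any(!inside)) {
      message(sprintf("%s: skipped %d edges touching unknown genes", prefix, sum(!inside)))
    }
    df <- df[inside, , drop = FALSE]
    A <- matrix(0, length(genes), length(genes),
                dimnames = list(genes, paste0(prefix, ":", genes)))
    if (nrow(df) > 0L) {
      A[cbind(df$a, paste0(prefix, ":", df$b))] <- 1
      A[cbind(df$b, paste0(prefix, ":", df$a))] <- 1
    }
    A
  }
  all_a <- unlist(lapply(edge_sets, `[[`, "a"), use.names = FALSE)
  all_b <- unlist(lapply(edge_sets, `[[`, "b"), use.names = FALSE)
  union_edges <- edge_set(all_a, all_b, name = "union")
  U <- adj_from(union_edges, "net:union")
  if (sum(U) == 0) stop("empty network union: no edges among master genes")
  blocks[["union"]] <- U
  if (per_network) {
    for (es in edge_sets) {
      nm <- attr(es, "name")
      blocks[[nm]] <- adj_from(es, paste0("net:", nm))
    }
  }
  feature_matrix(do.call(cbind, blocks), "network", quiet = quiet)
}

#' Read a GO annotation file (GAF 2.x)
#'
#' Lines starting with `!` are headers; rows with fewer than 7 columns are
#' skipped (count logged). Columns used: 2 (gene/protein id), 5 (GO id),
#' 7 (evidence code).
#'
#' @param path file path.
#' @param id_map optional named character vector remapping gene ids.
#' @param quiet suppress the skipped-row message.
#' @return data.frame with columns `gene`, `go_id`, `evidence`.
#' @export
read_gaf <- function(path, id_map = NULL, quiet = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, length, 1L) >= 7L
  if (!quiet && any(!ok)) message(sprintf("skipped %d malformed GAF rows", sum(!ok)))
  parts <- parts[ok]
  gene <- vapply(parts, `[[`, "", 2L)
  if (!is.null(id_map)) gene <- .map_ids(gene, id_map)
  data.frame(gene = gene,
             go_id = vapply(parts, `[[`, "", 5L),
             evidence = vapply(parts, `[[`, "", 7L),
             stringsAsFactors = FALSE)
}

#' Binary GO indicator features
#'
#' One indicator column per GO term; annotations carrying an excluded
#' evidence code (computationally inferred, default IEA) are dropped before
#' construction.
#'
#' @param gaf data.frame from [read_gaf()].
#' @param genes master gene list.
#' @param excluded_evidence evidence codes to drop (default `"IEA"`).
#' @return a [feature_matrix()] with `source_tag = "go"`.
#' @export
build_go_features <- function(gaf, genes, excluded_evidence = "IEA") {
  gaf <- gaf[!(gaf$evidence %in% excluded_evidence) & gaf$gene %in% genes, , drop = FALSE]
  terms <- sort(unique(gaf$go_id))
  X <- matrix(0, length(genes), length(terms), dimnames = list(genes, terms))
  if (nrow(gaf) > 0L) X[cbind(gaf$gene, gaf$go_id)] <- 1
  feature_matrix(X, "go")
}

#' Read a gene-word co-occurrence table
#'
#' Tab-separated `gene<TAB>word<TAB>count` triples.
#'
#' @param path file path.
#' @param id_map optional named character vector remapping gene ids.
#' @return data.frame with columns `gene`, `word`, `count`.
#' @export
read_cooccurrence <- function(path, id_map = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad) > 0L) stop(sprintf("malformed co-occurrence line %d in %s", bad[[1L]], path))
  gene <- vapply(parts, `[[`, "", 1L)
  if (!is.null(id_map)) gene <- .map_ids(gene, id_map)
  data.frame(gene = gene,
             word = vapply(parts, `[[`, "", 2L),
             count = as.numeric(vapply(parts, `[[`, "", 3L)),
             stringsAsFactors = FALSE)
}

# shared bag-of-words assembly; returns the count matrix after lower-casing,
# stopword removal and the strict document-frequency cut
.bow_counts <- function(cooccur, genes, max_doc_freq, stopwords) {
  if (max_doc_freq <= 0 || max_doc_freq > 1) stop("max_doc_freq must be in (0, 1]")
  if (any(cooccur$count < 0)) stop("co-occurrence counts must be non-negative")
  cooccur$word <- tolower(cooccur$word)
  cooccur <- cooccur[!(cooccur$word %in% tolower(stopwords)), , drop = FALSE]
  cooccur <- cooccur[cooccur$gene %in% genes & cooccur$count > 0, , drop = FALSE]
  # aggregate duplicate (gene, word) rows
  key <- paste(cooccur$gene, cooccur$word, sep = "\r")
  agg <- tapply(cooccur$count, key, sum)
  gw <- strsplit(names(agg), "\r", fixed = TRUE)
  gene <- vapply(gw, `[[`, "", 1L)
  word <- vapply(gw, `[[`, "", 2L)
  cnt <- as.numeric(agg)
  # document frequency: fraction of master genes with count > 0, strict cut
  df_count <- table(word)
  keep_words <- names(df_count)[df_count / length(genes) < max_doc_freq]
  sel <- word %in% keep_words
  words <- sort(unique(word[sel]))
  X <- matrix(0, length(genes), length(words), dimnames = list(genes, words))
  if (any(sel)) X[cbind(gene[sel], word[sel])] <- cnt[sel]
  X
}

#' Literature bag-of-words features
#'
#' Raw same-sentence co-occurrence counts. Words are lower-cased, stopwords
#' removed, and a word is retained iff the fraction of master genes it
#' co-occurs with is strictly below `max_doc_freq` (the low-frequency filter).
#'
#' @param cooccur data.frame from [read_cooccurrence()].
#' @param genes master gene list.
#' @param max_doc_freq strict document-frequency cutoff in (0, 1]; default
#'   0.01 (words present in less than 1\% of the genes).
#' @param stopwords character vector of words to remove.
#' @return a [feature_matrix()] with `source_tag = "literature"`.
#' @export
build_bow_features <- function(cooccur, genes, max_doc_freq = 0.01,
                               stopwords = character(0)) {
  X <- .bow_counts(cooccur, genes, max_doc_freq, stopwords)
  feature_matrix(X, "literature")
}

#' Document-frequency-normalized bag-of-words features
#'
#' Each retained count is divided by the number of distinct genes the word
#' co-occurs with (an IDF-like weighting).
#'
#' @inheritParams build_bow_features
#' @return a [feature_matrix()] with `source_tag = "literature"`.
#' @export
build_bow_normalized <- function(cooccur, genes, max_doc_freq = 0.01,
                                 stopwords = character(0)) {
  X <- .bow_counts(cooccur, genes, max_doc_freq, stopwords)
  df <- colSums(X > 0)
  df[df == 0] <- 1
  feature_matrix(sweep(X, 2L, df, "/"), "literature")
}

#' Read a two-column pair table
#'
#' Tab-separated pairs (`gene<TAB>disease` or `disease<TAB>variant`).
#'
#' @param path file path.
#' @param id_map optional named character vector remapping first-column ids.
#' @return data.frame with columns `from`, `to`.
#' @export
read_pairs <- function(path, id_map = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad) > 0L) stop(sprintf("malformed pair line %d in %s", bad[[1L]], path))
  from <- vapply(parts, `[[`, "", 1L)
  if (!is.null(id_map)) from <- .map_ids(from, id_map)
  unique(data.frame(from = from, to = vapply(parts, `[[`, "", 2L),
                    stringsAsFactors = FALSE))
}

#' Binary disease-variant features
#'
#' For each gene, its associated diseases are collected and the variants of
#' all those diseases form its indicator vector (a two-hop join, i.e. the
#' boolean product of the gene-disease and disease-variant relations).
#' Genes with no disease associations get all-zero rows.
#'
#' @param gene_disease data.frame with columns `from` (gene), `to` (disease).
#' @param disease_variant data.frame with columns `from` (disease), `to`
#'   (variant).
#' @param genes master gene list.
#' @return a [feature_matrix()] with `source_tag = "variant"`.
#' @export
build_variant_features <- function(gene_disease, disease_variant, genes) {
  variants <- sort(unique(disease_variant$to))
  X <- matrix(0, length(genes), length(variants), dimnames = list(genes, variants))
  dv <- split(disease_variant$to, disease_variant$from)
  gd <- split(gene_disease$to, gene_disease$from)
  for (g in intersect(genes, names(gd))) {
    vs <- unique(unlist(dv[gd[[g]]], use.names = FALSE))
    if (length(vs) > 0L) X[g, vs] <- 1
  }
  feature_matrix(X, "variant")
}

#' Read a two-column gene id mapping table
#'
#' @param path TSV with columns `from<TAB>to`.
#' @return named character vector usable as `id_map` in the readers.
#' @export
read_id_map <- function(path) {
  pairs <- read_pairs(path)
  stats::setNames(pairs$to, pairs$from)
}
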