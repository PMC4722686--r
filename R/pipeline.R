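#' End-to-end pipeline: load, featurize, cross-validate, report
#'
#' Ties the modules together: parse the ontology, true-path-expand and
#' filter the annotations, build per-source feature matrices and
#' cosine-normalized linear kernels, run five-fold cross-validation of the
#' structured model against per-term binary SVMs, and report term-centric
#' and protein-centric metrics plus leave-one-source-out ablation.
#'
#' @name pipeline
NULL

#' Run configuration
#'
#' @param ontology path to the OBO file.
#' @param annotations path to the gene-term TSV.
#' @param network character vector of edge-list TSV paths.
#' @param gaf path to the GAF file.
#' @param literature path to the gene-word-count TSV.
#' @param gene_disease,disease_variant paths to the pair TSVs.
#' @param sources enabled feature sources.
#' @param subontology_root optional term id; restrict to its descendants.
#' @param min_genes term filter threshold (default 10).
#' @param folds number of CV folds (default 5).
#' @param seed fold/partition seed.
#' @param C,epsilon structured-SVM hyperparameters.
#' @param binary_C binary-baseline regularization constant.
#' @param max_doc_freq literature document-frequency cutoff. The 1\% cutoff
#'   used on genome-scale corpora removes every shared word on a desk-scale
#'   fixture, so pipelines default to 0.5 here.
#' @param stopwords character vector of stopwords.
#' @param excluded_evidence GO evidence codes to exclude (default IEA).
#' @param grouping_terms terms ignored during metric computation.
#' @param id_map optional named character vector remapping gene ids.
#' @param out_dir report output directory (NULL = no files written).
#' @return a `run_config` list.
#' @export
run_config <- function(ontology, annotations, network = character(0),
                       gaf = NULL, literature = NULL, gene_disease = NULL,
                       disease_variant = NULL,
                       sources = c("network", "go", "literature", "variant"),
                       subontology_root = NULL, min_genes = 10L, folds = 5L,
                       seed = 42L, C = 1, epsilon = 0.01, binary_C = 1,
                       max_doc_freq = 0.5, stopwords = character(0),
                       excluded_evidence = "IEA", grouping_terms = character(0),
                       id_map = NULL, out_dir = NULL) {
  sources <- match.arg(sources, c("network", "go", "literature", "variant"),
                       several.ok = TRUE)
  structure(list(ontology = ontology, annotations = annotations,
                 network = network, gaf = gaf, literature = literature,
                 gene_disease = gene_disease, disease_variant = disease_variant,
                 sources = sources, subontology_root = subontology_root,
                 min_genes = as.integer(min_genes), folds = as.integer(folds),
                 seed = as.integer(seed), C = C, epsilon = epsilon,
                 binary_C = binary_C, max_doc_freq = max_doc_freq,
                 stopwords = stopwords, excluded_evidence = excluded_evidence,
                 grouping_terms = grouping_terms, id_map = id_map,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run configuration for a synthetic fixture directory
#'
#' @param dir directory written by [generate_fixture()].
#' @param ... overrides passed to [run_config()].
#' @return a `run_config`.
#' @export
fixture_config <- function(dir, ...) {
  run_config(
    ontology = file.path(dir, "ontology.obo"),
    annotations = file.path(dir, "annotations.tsv"),
    network = file.path(dir, c("network_ppi.tsv", "network_coexpr.tsv")),
    gaf = file.path(dir, "go.gaf"),
    literature = file.path(dir, "literature.tsv"),
    gene_disease = file.path(dir, "gene_disease.tsv"),
    disease_variant = file.path(dir, "disease_variant.tsv"),
    ...)
}

#' Load and preprocess a dataset per a run configuration
#'
#' Parses the ontology (optionally restricted to a subontology), expands
#' annotations by the true-path rule, applies the min-gene term filter with
#' root removal, builds the enabled feature sources on the master gene
#' list, and returns per-source normalized kernels.
#'
#' @param cfg a [run_config()].
#' @return list with `dag`, `ann`, `terms`, `genes`, `labels` (binary
#'   matrix), `features` (per-source [feature_matrix()]), `kernels`
#'   (per-source normalized [kernel_matrix()]).
#' @export
load_dataset <- function(cfg) {
  dag <- parse_obo(cfg$ontology)
  if (!is.null(cfg$subontology_root)) dag <- subontology(dag, cfg$subontology_root)
  ann <- read_annotations(cfg$annotations, id_map = cfg$id_map)
  ann <- annotation_set(lapply(ann$annotations, intersect, x = dag$terms))
  ann$annotations <- ann$annotations[vapply(ann$annotations, length, 1L) > 0L]
  ann <- propagate_true_path(ann, dag)
  flt <- filter_terms(ann, dag, min_genes = cfg$min_genes, drop_roots = dag$root)
  genes <- names(flt$ann$annotations)
  feats <- list()
  if ("network" %in% cfg$sources) {
    edge_sets <- lapply(cfg$network, read_edge_list, id_map = cfg$id_map)
    feats$network <- build_network_features(edge_sets, genes)
  }
  if ("go" %in% cfg$sources) {
    feats$go <- build_go_features(read_gaf(cfg$gaf, id_map = cfg$id_map), genes,
                                  excluded_evidence = cfg$excluded_evidence)
  }
  if ("literature" %in% cfg$sources) {
    feats$literature <- build_bow_features(
      read_cooccurrence(cfg$literature, id_map = cfg$id_map), genes,
      max_doc_freq = cfg$max_doc_freq, stopwords = cfg$stopwords)
  }
  if ("variant" %in% cfg$sources) {
    feats$variant <- build_variant_features(
      read_pairs(cfg$gene_disease, id_map = cfg$id_map),
      read_pairs(cfg$disease_variant), genes)
  }
  kernels <- lapply(feats, function(X) normalize_kernel(linear_kernel(X)))
  list(dag = dag, ann = flt$ann, terms = flt$terms, genes = genes,
       labels = label_matrix(flt$ann, flt$terms), features = feats,
       kernels = kernels)
}

# intersect(lapply(...)) helper is used with reversed args above
#' Pooled cross-validated scores for both methods
#'
#' For each fold, trains the structured model (catalog from that fold's
#' training labels only) and the per-term binary SVMs on the training
#' genes, and scores the held-out genes. Held-out scores are pooled across
#' folds into one genes x terms table per method; no test gene's label ever
#' enters its own fold's catalog or training kernel.
#'
#' @param K combined [kernel_matrix()] over all genes.
#' @param labels binary gene x term matrix.
#' @param plan a [make_folds()] plan over the same genes.
#' @param C,epsilon structured-SVM hyperparameters.
#' @param binary_C binary-SVM regularization.
#' @param methods subset of `c("structured", "binary")`.
#' @return list of [score_table()]s (one per method) plus `predictions`
#'   (named list of predicted term sets from the structured argmax).
#' @export
cv_scores <- function(K, labels, plan, C = 1, epsilon = 0.01, binary_C = 1,
                      methods = c("structured", "binary")) {
  genes <- rownames(labels)
  stopifnot(identical(rownames(K), genes), identical(names(plan$fold), genes))
  terms <- colnames(labels)
  struct_scores <- matrix(NA_real_, length(genes), length(terms),
                          dimnames = list(genes, terms))
  binary_scores <- struct_scores
  predictions <- stats::setNames(vector("list", length(genes)), genes)
  for (f in seq_len(plan$k)) {
    test <- genes[plan$fold == f]
    train <- setdiff(genes, test)
    K_tr <- kernel_matrix(unclass(K)[train, train, drop = FALSE],
                          normalized = isTRUE(attr(K, "normalized")))
    K_cross <- unclass(K)[test, train, drop = FALSE]
    Y_tr <- labels[train, , drop = FALSE]
    if ("structured" %in% methods) {
      catalog <- build_catalog(Y_tr, terms)
      model <- train_structured(K_tr, Y_tr, catalog, C = C, epsilon = epsilon,
                                quiet = TRUE)
      for (g in test) {
        kxc <- K_cross[g, ]
        struct_scores[g, ] <- term_confidence(model, kxc)
        predictions[[g]] <- predict_structured(model, kxc)$terms
      }
    }
    if ("binary" %in% methods) {
      binary_scores[test, ] <- train_binary_svms(K_tr, Y_tr, K_cross, C = binary_C)
    }
  }
  out <- list(predictions = predictions)
  if ("structured" %in% methods) out$structured <- score_table(struct_scores, labels)
  if ("binary" %in% methods) out$binary <- score_table(binary_scores, labels)
  out
}

#' Full evaluation run
#'
#' Loads the dataset, cross-validates the structured model and the binary
#' baseline on the combined kernel, computes macro AUC, per-term AUCs,
#' protein-centric precision/recall and F-max, a paired t-test between the
#' two methods' per-term AUCs, and (with at least two sources) the
#' leave-one-source-out ablation. Optionally writes `per_term.tsv`,
#' `summary.json` and `manifest.json` to `cfg$out_dir`.
#'
#' @param cfg a [run_config()].
#' @param ablation run the leave-one-source-out protocol (default TRUE when
#'   more than one source is enabled).
#' @return results list (invisibly also written to disk when `out_dir` is
#'   set).
#' @export
run_evaluation <- function(cfg, ablation = length(cfg$sources) > 1L) {
  data <- load_dataset(cfg)
  plan <- make_folds(data$genes, k = cfg$folds, seed = cfg$seed)
  combined <- function(srcs) combine_kernels(data$kernels[srcs])
  cv <- cv_scores(combined(cfg$sources), data$labels, plan, C = cfg$C,
                  epsilon = cfg$epsilon, binary_C = cfg$binary_C)
  strip <- function(tab) {
    if (length(cfg$grouping_terms) > 0L)
      exclude_grouping_terms(tab, cfg$grouping_terms) else tab
  }
  st <- strip(cv$structured)
  bt <- strip(cv$binary)
  per_term_s <- per_term_auc(st)
  per_term_b <- per_term_auc(bt)
  both <- !is.na(per_term_s$auc) & !is.na(per_term_b$auc)
  truth_sets <- apply(data$labels, 1L, function(r) colnames(data$labels)[r == 1],
                      simplify = FALSE)
  res <- list(
    config = cfg,
    n_genes = length(data$genes), n_terms = length(data$terms),
    macro_auc = c(structured = macro_auc(st), binary = macro_auc(bt)),
    per_term = data.frame(
      term = per_term_s$term,
      name = unname(data$dag$name[per_term_s$term]),
      frequency = per_term_s$frequency,
      depth = unname(data$dag$depth[per_term_s$term]),
      auc_structured = per_term_s$auc,
      auc_binary = per_term_b$auc, stringsAsFactors = FALSE),
    fmax = c(structured = fmax(st), binary = fmax(bt)),
    protein_pr = protein_centric_pr(cv$predictions, truth_sets),
    p_value = if (sum(both) >= 2L)
      paired_ttest(per_term_s$auc[both], per_term_b$auc[both]) else NA_real_,
    predictions = cv$predictions)
  if (ablation && length(cfg$sources) > 1L) {
    res$ablation <- leave_one_source_out(cfg$sources, function(srcs) {
      cvk <- cv_scores(combined(srcs), data$labels, plan, C = cfg$C,
                       epsilon = cfg$epsilon, methods = "structured")
      macro_auc(strip(cvk$structured))
    })
  }
  if (!is.null(cfg$out_dir)) write_report(res, cfg$out_dir)
  res
}

#' Write evaluation reports
#'
#' `per_term.tsv` mirrors the per-term tables (name, frequency, depth,
#' AUC); `summary.json` carries macro AUCs, F-max, the paired-test p-value
#' and ablation deltas; `manifest.json` records the configuration and seed
#' verbatim.
#'
#' @param res a [run_evaluation()] result.
#' @param dir output directory.
#' @export
write_report <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pt <- res$per_term
  num <- vapply(pt, is.numeric, TRUE)
  pt[num] <- lapply(pt[num], function(x) formatC(x, digits = 12, format = "g"))
  utils::write.table(pt, file.path(dir, "per_term.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary <- list(
    n_genes = res$n_genes, n_terms = res$n_terms,
    macro_auc_structured = unname(res$macro_auc[["structured"]]),
    macro_auc_binary = unname(res$macro_auc[["binary"]]),
    fmax_structured = unname(res$fmax[["structured"]]),
    fmax_binary = unname(res$fmax[["binary"]]),
    p_value_structured_vs_binary = res$p_value)
  if (!is.null(res$ablation)) {
    summary$ablation <- list(auc_all = res$ablation$auc_all,
                             deltas = res$ablation$deltas)
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- res$config
  cfg$id_map <- NULL
  jsonlite::write_json(list(config = unclass(cfg), seed = cfg$seed,
                            tool = "ontostruct"),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
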