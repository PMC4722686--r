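#' Synthetic desk-scale fixtures
#'
#' Generates a complete synthetic data set in the exact file dialects the
#' loaders consume: a random single-root is-a DAG, hierarchically
#' consistent gene annotations, and four feature sources whose
#' informativeness about the labels is tunable via per-source signal
#' strengths. Identical config + seed produces byte-identical files.
#'
#' @name synthetic
NULL

#' Simulation configuration
#'
#' @param n_terms number of ontology terms including the root (default 40).
#' @param max_parents maximum is-a parents drawn per non-root term.
#' @param n_genes number of genes (default 120).
#' @param mean_leaf_annotations Poisson mean of leaf terms drawn per gene
#'   (at least one is always drawn).
#' @param signal_strength per-source informativeness in \[0, 1\]; scalar or
#'   named vector over `network`, `go`, `literature`, `variant`.
#' @param noise flip/background rate in \[0, 1\].
#' @param vocab_size literature vocabulary size (signal + background words).
#' @param n_diseases,n_variants sizes of the disease/variant layer.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_terms = 40L, max_parents = 3L, n_genes = 120L,
                       mean_leaf_annotations = 3, signal_strength = 0.75,
                       noise = 0.05, vocab_size = 150L, n_diseases = 15L,
                       n_variants = 60L, seed = 1L) {
  src <- c("network", "go", "literature", "variant")
  if (length(signal_strength) == 1L && is.null(names(signal_strength))) {
    signal_strength <- stats::setNames(rep.int(signal_strength, 4L), src)
  }
  stopifnot(all(src %in% names(signal_strength)),
            all(signal_strength >= 0 & signal_strength <= 1),
            noise >= 0, noise <= 1, n_terms >= 3L, n_genes >= 1L,
            max_parents >= 1L, mean_leaf_annotations > 0,
            vocab_size >= 1L, n_diseases >= 1L, n_variants >= 1L)
  structure(list(n_terms = as.integer(n_terms), max_parents = as.integer(max_parents),
                 n_genes = as.integer(n_genes),
                 mean_leaf_annotations = mean_leaf_annotations,
                 signal_strength = signal_strength[src], noise = noise,
                 vocab_size = as.integer(vocab_size),
                 n_diseases = as.integer(n_diseases),
                 n_variants = as.integer(n_variants), seed = as.integer(seed)),
            class = "sim_config")
}

.term_id <- function(i) sprintf("PH:%07d", i)
.gene_id <- function(i) sprintf("G%04d", i)

#' Generate a random single-root is-a DAG
#'
#' Term i > 1 draws between 1 and `max_parents` parents uniformly among the
#' earlier terms, so the graph is acyclic by construction with
#' `PH:0000001` as the unique root.
#'
#' @param cfg a [sim_config()].
#' @return an [ontology_dag()].
#' @export
generate_dag <- function(cfg) {
  with_seed(cfg$seed, {
    ids <- .term_id(seq_len(cfg$n_terms))
    parents <- stats::setNames(vector("list", cfg$n_terms), ids)
    parents[[ids[[1L]]]] <- character(0)
    for (i in seq_len(cfg$n_terms)[-1L]) {
      np <- sample.int(min(cfg$max_parents, i - 1L), 1L)
      parents[[ids[[i]]]] <- ids[sample.int(i - 1L, np)]
    }
    ontology_dag(parents,
                 names = stats::setNames(paste("synthetic term", seq_len(cfg$n_terms)), ids))
  })
}

#' Generate hierarchically consistent annotations
#'
#' Each gene draws Poisson(`mean_leaf_annotations`) leaf terms (minimum 1)
#' and the set is true-path expanded, so every label is consistent by
#' construction.
#'
#' @param dag an [ontology_dag()].
#' @param cfg a [sim_config()].
#' @return an expanded [annotation_set()].
#' @export
generate_annotations <- function(dag, cfg) {
  leaves <- dag$terms[vapply(dag$children[dag$terms], length, 1L) == 0L]
  raw <- with_seed(cfg$seed + 1L, {
    out <- stats::setNames(vector("list", cfg$n_genes), .gene_id(seq_len(cfg$n_genes)))
    for (g in names(out)) {
      k <- max(1L, stats::rpois(1L, cfg$mean_leaf_annotations))
      out[[g]] <- leaves[sample.int(length(leaves), min(k, length(leaves)))]
    }
    out
  })
  propagate_true_path(annotation_set(raw), dag)
}

.jaccard_matrix <- function(Y) {
  inter <- tcrossprod(Y)
  sz <- rowSums(Y)
  un <- outer(sz, sz, "+") - inter
  J <- inter / pmax(un, 1)
  diag(J) <- 1
  J
}

#' Generate the four feature sources
#'
#' * network: two edge lists (`ppi`, `coexpr`); the probability of an edge
#'   between two genes is `noise + signal * Jaccard(label_i, label_j)` --
#'   interacting genes tend to share phenotype labels.
#' * go: one indicator feature per ontology term, set with probability
#'   `signal` for genes annotated with the term, and flipped on with
#'   probability `noise` otherwise; emitted as a GAF with experimental
#'   evidence, plus pure-noise IEA rows the loader must discard.
#' * literature: one signal word per term with Poisson(1 + 2*signal)
#'   same-sentence counts for annotated genes, plus background words with
#'   Poisson(noise) counts.
#' * variant: diseases are latent label-set clusters (prototype genes);
#'   each gene links to its most similar prototype's disease with
#'   probability `signal`, otherwise to a random disease; variants hang off
#'   diseases.
#'
#' @param ann an expanded [annotation_set()].
#' @param dag an [ontology_dag()].
#' @param cfg a [sim_config()].
#' @return list with elements `network` (list of [edge_set()]), `gaf`,
#'   `cooccur`, `gene_disease`, `disease_variant` data frames.
#' @export
generate_features <- function(ann, dag, cfg) {
  genes <- names(ann$annotations)
  Y <- label_matrix(ann, setdiff(dag$terms, dag$root))
  sig <- cfg$signal_strength
  with_seed(cfg$seed + 2L, {
    J <- .jaccard_matrix(Y)
    p_edge <- pmin(cfg$noise + sig[["network"]] * J^2, 1)  # matrix arg first: pmin keeps dims
    nets <- lapply(c(ppi = "ppi", coexpr = "coexpr"), function(nm) {
      up <- which(upper.tri(p_edge), arr.ind = TRUE)
      draw <- stats::runif(nrow(up)) < p_edge[up] / 2   # each net carries half
      edge_set(genes[up[draw, 1L]], genes[up[draw, 2L]], name = nm)
    })

    # GO-like indicators: latent GO term j mirrors ontology term j
    go_ids <- sprintf("GO:%07d", seq_len(ncol(Y)))
    # annotated genes carry the indicator at rate >= the background rate, so
    # signal 0 degenerates to pure background noise (no anti-correlation)
    on_p <- pmax(sig[["go"]], cfg$noise) * Y + cfg$noise * (1 - Y)
    hit <- matrix(stats::runif(length(on_p)) < on_p, nrow(Y), ncol(Y))
    gaf_rows <- which(hit, arr.ind = TRUE)
    gaf <- data.frame(gene = genes[gaf_rows[, 1L]], go_id = go_ids[gaf_rows[, 2L]],
                      evidence = "EXP", stringsAsFactors = FALSE)
    # computational (IEA) decoy rows: random, must be excluded by the loader
    n_iea <- max(1L, round(0.1 * nrow(gaf)))
    gaf <- rbind(gaf, data.frame(
      gene = genes[sample.int(length(genes), n_iea, replace = TRUE)],
      go_id = go_ids[sample.int(length(go_ids), n_iea, replace = TRUE)],
      evidence = "IEA", stringsAsFactors = FALSE))
    gaf <- gaf[order(gaf$gene, gaf$go_id, gaf$evidence), , drop = FALSE]

    # literature: signal words per term + background vocabulary
    sig_words <- sprintf("term%03dword", seq_len(ncol(Y)))
    n_bg <- max(0L, cfg$vocab_size - length(sig_words))
    bg_words <- if (n_bg > 0L) sprintf("background%03d", seq_len(n_bg)) else character(0)
    lit <- list()
    lam_sig <- 1 + 2 * sig[["literature"]]
    for (i in seq_along(genes)) {
      ts <- which(Y[i, ] == 1)
      if (sig[["literature"]] > 0 && length(ts) > 0L) {
        cnt <- stats::rpois(length(ts), lam_sig)
        keep <- cnt > 0
        if (any(keep)) {
          lit[[length(lit) + 1L]] <- data.frame(
            gene = genes[[i]], word = sig_words[ts[keep]], count = cnt[keep],
            stringsAsFactors = FALSE)
        }
      }
      if (n_bg > 0L) {
        bcnt <- stats::rpois(n_bg, max(cfg$noise, 0.02))
        bkeep <- bcnt > 0
        if (any(bkeep)) {
          lit[[length(lit) + 1L]] <- data.frame(
            gene = genes[[i]], word = bg_words[bkeep], count = bcnt[bkeep],
            stringsAsFactors = FALSE)
        }
      }
    }
    cooccur <- if (length(lit) > 0L) do.call(rbind, lit) else
      data.frame(gene = character(0), word = character(0), count = numeric(0))
    cooccur <- cooccur[order(cooccur$gene, cooccur$word), , drop = FALSE]

    # variants: diseases as label-set clusters around prototype genes
    protos <- sample.int(length(genes), cfg$n_diseases)
    dis_ids <- sprintf("DIS:%04d", seq_len(cfg$n_diseases))
    simil <- (Y %*% t(Y[protos, , drop = FALSE])) /
      pmax(outer(rowSums(Y), rowSums(Y[protos, , drop = FALSE]), pmax), 1)
    gd <- data.frame(from = character(0), to = character(0))
    for (i in seq_along(genes)) {
      d <- if (stats::runif(1L) < sig[["variant"]]) which.max(simil[i, ]) else
        sample.int(cfg$n_diseases, 1L)
      gd <- rbind(gd, data.frame(from = genes[[i]], to = dis_ids[[d]],
                                 stringsAsFactors = FALSE))
    }
    var_ids <- sprintf("VAR:%05d", seq_len(cfg$n_variants))
    dv <- data.frame(from = dis_ids[1L + (seq_len(cfg$n_variants) - 1L) %% cfg$n_diseases],
                     to = var_ids, stringsAsFactors = FALSE)
    dv <- dv[order(dv$from, dv$to), , drop = FALSE]

    list(network = nets, gaf = gaf, cooccur = cooccur,
         gene_disease = gd, disease_variant = dv)
  })
}

#' Write a DAG as OBO 1.2
#'
#' @param dag an [ontology_dag()].
#' @param path output path.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", "ontology: synthetic-phenotype"), con)
  for (t in dag$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t),
                 paste0("name: ", dag$name[[t]])), con)
    for (p in sort(dag$parents[[t]])) {
      writeLines(paste0("is_a: ", p, " ! ", dag$name[[p]]), con)
    }
  }
  invisible(path)
}

#' Generate and write a complete fixture directory
#'
#' Emits `ontology.obo`, `annotations.tsv`, `network_ppi.tsv`,
#' `network_coexpr.tsv`, `go.gaf`, `literature.tsv`, `gene_disease.tsv`,
#' `disease_variant.tsv` and `manifest.json` (config + seed).
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the in-memory `dag`, `ann`, `features`
#'   and the file `paths`.
#' @export
generate_fixture <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dag <- generate_dag(cfg)
  ann <- generate_annotations(dag, cfg)
  feats <- generate_features(ann, dag, cfg)
  paths <- list(
    ontology = file.path(dir, "ontology.obo"),
    annotations = file.path(dir, "annotations.tsv"),
    network = c(file.path(dir, "network_ppi.tsv"), file.path(dir, "network_coexpr.tsv")),
    gaf = file.path(dir, "go.gaf"),
    literature = file.path(dir, "literature.tsv"),
    gene_disease = file.path(dir, "gene_disease.tsv"),
    disease_variant = file.path(dir, "disease_variant.tsv"),
    manifest = file.path(dir, "manifest.json"))
  write_obo(dag, paths$ontology)
  write_annotations(ann, paths$annotations)
  for (k in seq_along(feats$network)) {
    es <- feats$network[[k]]
    writeLines(paste(es$a, es$b, sep = "\t"), paths$network[[k]])
  }
  gaf <- feats$gaf
  gaf_lines <- vapply(seq_len(nrow(gaf)), function(i) {
    f <- rep("", 17L)
    f[[1L]] <- "SYN"; f[[2L]] <- gaf$gene[[i]]; f[[3L]] <- gaf$gene[[i]]
    f[[5L]] <- gaf$go_id[[i]]; f[[7L]] <- gaf$evidence[[i]]; f[[9L]] <- "P"
    f[[12L]] <- "protein"; f[[13L]] <- "taxon:9606"; f[[14L]] <- "20150101"
    f[[15L]] <- "SYN"
    paste(f, collapse = "\t")
  }, "")
  writeLines(c("!gaf-version: 2.1", gaf_lines), paths$gaf)
  writeLines(paste(feats$cooccur$gene, feats$cooccur$word,
                   format(feats$cooccur$count, trim = TRUE, scientific = FALSE),
                   sep = "\t"), paths$literature)
  writeLines(paste(feats$gene_disease$from, feats$gene_disease$to, sep = "\t"),
             paths$gene_disease)
  writeLines(paste(feats$disease_variant$from, feats$disease_variant$to, sep = "\t"),
             paths$disease_variant)
  jsonlite::write_json(list(config = unclass(cfg), generator = "ontostruct-synthetic"),
                       paths$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dag = dag, ann = ann, features = feats, paths = paths))
}
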