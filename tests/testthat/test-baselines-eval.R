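test_that("binary SVM matches a high-precision box-QP oracle", {
  # 6 points in 2D, 2 terms; biasless dual: min 1/2 a'Qa - e'a, 0 <= a <= C
  set.seed(2)
  X <- rbind(matrix(rnorm(6, 2), 3, 2), matrix(rnorm(6, -2), 3, 2))
  rownames(X) <- sprintf("g%d", 1:6)
  truth <- cbind(t1 = c(1, 1, 1, 0, 0, 0), t2 = c(0, 1, 1, 0, 0, 1))
  rownames(truth) <- rownames(X)
  K <- kernel_matrix(tcrossprod(X))
  scores <- train_binary_svms(K, truth, unclass(K), C = 1)
  for (t in 1:2) {
    yb <- ifelse(truth[, t] > 0, 1, -1)
    Q <- (yb %o% yb) * unclass(K)
    qp <- optim(rep(0.5, 6), fn = function(a) 0.5 * sum(a * (Q %*% a)) - sum(a),
                gr = function(a) as.numeric(Q %*% a) - 1,
                method = "L-BFGS-B", lower = 0, upper = 1,
                control = list(maxit = 500, factr = 1e3))
    oracle_scores <- as.numeric(unclass(K) %*% (qp$par * yb))
    expect_equal(unname(scores[, t]), oracle_scores, tolerance = 1e-6)
  }
  # separable toy: positives above negatives
  expect_true(min(scores[truth[, 1] == 1, 1]) > max(scores[truth[, 1] == 0, 1]))
  # degenerate single-class term is skipped
  truth3 <- cbind(truth, t3 = rep(1, 6))
  s3 <- train_binary_svms(K, truth3, unclass(K), C = 1)
  expect_true(all(is.na(s3[, "t3"])))
  expect_equal(attr(s3, "skipped"), "t3")
})

test_that("auc matches the pair-counting oracle, including ties", {
  expect_equal(auc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(1, 2, 3, 4), c(1, 1, 0, 0)), 0)
  expect_true(is.na(auc(1:4, c(1, 1, 1, 1))))
  set.seed(8)
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    scores <- sample(1:6, n, TRUE)          # heavy ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) %in% c(0, n)) next
    expect_equal(auc(scores, labels), auc_oracle(scores, labels))
  }
  # invariance under strictly monotone transforms
  set.seed(9)
  s <- rnorm(40); l <- rbinom(40, 1, 0.5)
  expect_equal(auc(exp(s), l), auc(s, l))
  expect_equal(auc(rank(s), l), auc(s, l))
})

test_that("macro_auc averages defined per-term AUCs", {
  truth <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0), c = rep(1, 4))
  rownames(truth) <- sprintf("g%d", 1:4)
  scores <- cbind(a = c(9, 8, 1, 2), b = c(5, 6, 7, 8), c = rnorm(4))
  rownames(scores) <- rownames(truth)
  tab <- score_table(scores, truth)
  # a: AUC 1, b: AUC 0.25, c: undefined (no negatives) -> skipped
  expect_equal(macro_auc(tab), mean(c(1, 0.25)))
  # perfect self-scores give 1.0
  tab2 <- score_table(truth + 0, truth)
  expect_equal(macro_auc(tab2), 1.0)
  # loop-and-average oracle on a random table
  set.seed(10)
  S <- matrix(rnorm(60), 10, 6, dimnames = list(sprintf("g%d", 1:10), letters[1:6]))
  Tr <- matrix(rbinom(60, 1, 0.4), 10, 6, dimnames = dimnames(S))
  vals <- c()
  for (t in 1:6) {
    a <- auc_oracle(S[, t], Tr[, t])
    if (!is.na(a)) vals <- c(vals, a)
  }
  expect_equal(macro_auc(score_table(S, Tr)), mean(vals))
})

test_that("protein-centric precision/recall follow set arithmetic", {
  # 8 predicted terms all correct out of 13 true: precision 1.0, recall 0.62
  pred <- list(p1 = sprintf("t%02d", 1:8))
  truth <- list(p1 = sprintf("t%02d", 1:13))
  pr <- protein_centric_pr(pred, truth)
  expect_equal(pr$precision, 1.0)
  expect_equal(round(pr$recall, 2), 0.62)
  # pred == truth
  pr2 <- protein_centric_pr(list(g = c("a", "b")), list(g = c("a", "b")))
  expect_equal(c(pr2$precision, pr2$recall), c(1, 1))
  # random sets vs oracle
  set.seed(12)
  for (rep in 1:10) {
    p <- sample(letters, sample(0:8, 1))
    t <- sample(letters, sample(1:8, 1))
    pr3 <- protein_centric_pr(list(g = p), list(g = t))
    tp <- length(intersect(p, t))
    expect_equal(pr3$recall, tp / length(t))
    if (length(p) > 0) expect_equal(pr3$precision, tp / length(p)) else
      expect_true(is.na(pr3$precision))
  }
  # genes with empty truth are excluded
  pr4 <- protein_centric_pr(list(g1 = "a", g2 = "b"),
                            list(g1 = "a", g2 = character(0)))
  expect_equal(pr4$gene, "g1")
})

test_that("fmax equals the per-threshold scan oracle", {
  truth <- matrix(rbinom(50, 1, 0.4), 10, 5,
                  dimnames = list(sprintf("g%d", 1:10), letters[1:5]))
  truth[rowSums(truth) == 0, 1] <- 1
  # scores that reproduce truth exactly at some threshold
  tab <- score_table(truth + 0, truth)
  expect_equal(fmax(tab), 1.0)

  set.seed(13)
  S <- matrix(rnorm(50), 10, 5, dimnames = dimnames(truth))
  tab2 <- score_table(S, truth)
  grid <- seq(min(S), max(S), length.out = 51)
  oracle <- 0
  for (th in grid) {
    precs <- c(); tps <- c(); szs <- c()
    for (g in 1:10) {
      p <- colnames(S)[S[g, ] >= th]
      t <- colnames(truth)[truth[g, ] == 1]
      tp <- length(intersect(p, t))
      if (length(p) > 0) precs <- c(precs, tp / length(p))
      tps <- c(tps, tp / length(t))
    }
    if (length(precs) == 0) next
    pr <- mean(precs); rc <- mean(tps)
    if (pr + rc > 0) oracle <- max(oracle, 2 * pr * rc / (pr + rc))
  }
  expect_equal(fmax(tab2, thresholds = grid), oracle)
  # F-max dominates F at every grid point by construction
  expect_gte(fmax(tab2), fmax(tab2, thresholds = grid[25]))
})

test_that("make_folds partitions genes into balanced seeded folds", {
  genes <- sprintf("g%03d", 1:10)
  plan <- make_folds(genes, k = 5, seed = 1)
  expect_equal(as.integer(sort(table(plan$fold))), rep(2L, 5))
  expect_identical(plan$fold, make_folds(genes, k = 5, seed = 1)$fold)
  expect_false(identical(plan$fold, make_folds(genes, k = 5, seed = 2)$fold))
  g103 <- sprintf("g%03d", 1:103)
  sizes <- as.integer(sort(table(make_folds(g103, 5, 7)$fold)))
  expect_equal(sizes, c(20L, 20L, 21L, 21L, 21L))
  expect_error(make_folds(genes, k = 1), "at least 2")
})

test_that("grouping-term exclusion drops the right columns", {
  S <- matrix(rnorm(40), 10, 4, dimnames = list(sprintf("g%d", 1:10),
                                                c("onset", "pace", "t1", "t2")))
  Tr <- matrix(rbinom(40, 1, 0.5), 10, 4, dimnames = dimnames(S))
  tab <- score_table(S, Tr)
  expect_identical(exclude_grouping_terms(tab, character(0)), tab)
  out <- exclude_grouping_terms(tab, c("onset", "pace"))
  expect_equal(colnames(out$scores), c("t1", "t2"))
  expect_warning(exclude_grouping_terms(tab, "ghost"), "unknown")
})

test_that("leave-one-source-out computes percent change per source", {
  aucs <- c(all = 0.8, no_a = 0.72, no_b = 0.8, no_c = 0.85)
  evaluate <- function(srcs) {
    miss <- setdiff(c("a", "b", "c"), srcs)
    if (length(miss) == 0) aucs[["all"]] else aucs[[paste0("no_", miss)]]
  }
  res <- leave_one_source_out(c("a", "b", "c"), evaluate)
  expect_equal(res$auc_all, 0.8)
  expect_equal(res$deltas$pct_change[res$deltas$source == "a"], -10)
  expect_equal(res$deltas$pct_change[res$deltas$source == "b"], 0)
  expect_equal(res$deltas$pct_change[res$deltas$source == "c"], 6.25)
  expect_error(leave_one_source_out("a", evaluate), "two sources")
})

test_that("paired t-test matches the quadrature oracle", {
  expect_true(is.na(paired_ttest(1:5, 1:5)))
  expect_lt(paired_ttest(1:20 + 10, 1:20 + rnorm(20, 0, 1e-4)), 1e-10)
  set.seed(14)
  for (rep in 1:8) {
    n <- sample(5:25, 1)
    a <- rnorm(n); b <- rnorm(n)
    d <- a - b
    t_stat <- mean(d) / (sd(d) / sqrt(n))
    dens <- function(x) {
      gamma((n) / 2) / (sqrt((n - 1) * pi) * gamma((n - 1) / 2)) *
        (1 + x^2 / (n - 1))^(-n / 2)
    }
    tail_mass <- integrate(dens, abs(t_stat), Inf, rel.tol = 1e-10)$value
    expect_equal(paired_ttest(a, b), 2 * tail_mass, tolerance = 1e-7)
  }
})
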