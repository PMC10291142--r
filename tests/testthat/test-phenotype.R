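test_that("PCA scores are centered, ordered, and shaped as requested", {
  set.seed(1)
  # rank-1 matrix: one component carries all variance
  u <- rnorm(30); v <- rnorm(5)
  x1 <- outer(u, v)
  s1 <- top_principal_components(x1, 1)
  expect_equal(attr(s1, "explained_variance")[1], 1, tolerance = 1e-10)

  # two orthogonal blocks separate on PC1
  blocks <- rbind(matrix(rnorm(200, 5), 20), matrix(rnorm(200, -5), 20))
  s2 <- top_principal_components(blocks, 2)
  lab <- rep(c(1, 2), each = 20)
  expect_true(abs(cor(s2[, 1], lab)) > 0.95)
  expect_equal(unname(colMeans(s2)), c(0, 0), tolerance = 1e-10)
  ev <- attr(s2, "explained_variance")
  expect_true(all(diff(ev) <= 0))

  x42 <- matrix(rnorm(50 * 42), 50)
  expect_equal(dim(top_principal_components(x42, 12)), c(50L, 12L))
  expect_error(top_principal_components(x42, 43), "exceeds")

  # deterministic sign convention: repeated calls identical
  expect_identical(top_principal_components(x42, 3), top_principal_components(x42, 3))
})

test_that("tSNE embedding preserves strong cluster separation deterministically", {
  set.seed(5)
  n <- 100
  x <- rbind(matrix(rnorm(n * 42, 0), n), matrix(rnorm(n * 42, 10), n))
  rownames(x) <- paste0("s", seq_len(2 * n))
  e1 <- tsne_embed(x, seed = 1, perplexity = 20)
  e2 <- tsne_embed(x, seed = 1, perplexity = 20)
  expect_identical(e1, e2)

  lab <- rep(1:2, each = n)
  sil <- cluster::silhouette(lab, dist(as.matrix(e1[, c("tsne1", "tsne2")])))
  expect_gt(mean(sil[, "sil_width"]), 0.5)

  expect_error(tsne_embed(x[1:10, ], perplexity = 30), "perplexity")
})

test_that("SNN clustering recovers well-separated mixtures", {
  set.seed(2)
  blob <- function(center, n = 40) sweep(matrix(rnorm(n * 5), n), 2, center, `+`)
  x <- rbind(blob(c(0, 0, 0, 0, 0)), blob(c(10, 0, 0, 0, 0)),
             blob(c(0, 10, 0, 0, 0)))
  truth <- rep(1:3, each = 40)
  labels <- knn_cluster(x, k_neighbors = 15, resolution = 0.8, seed = 1)
  expect_equal(nlevels(labels), 3)
  expect_gt(mclust::adjustedRandIndex(labels, truth), 0.9)

  expect_identical(knn_cluster(x, k_neighbors = 15, seed = 1),
                   knn_cluster(x, k_neighbors = 15, seed = 1))

  expect_warning(one <- knn_cluster(matrix(1, 10, 3), k_neighbors = 3),
                 "single cluster")
  expect_equal(nlevels(one), 1)
  expect_error(knn_cluster(x, k_neighbors = 1000), "smaller")
})

test_that("cluster count does not decrease with resolution", {
  set.seed(3)
  x <- rbind(matrix(rnorm(200), 40), matrix(rnorm(200, 8), 40))
  counts <- vapply(c(0.2, 0.8, 2.5), function(res)
    nlevels(knn_cluster(x, k_neighbors = 10, resolution = res, seed = 1)),
    integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("cluster reports tally composition and stage enrichment", {
  meta <- data.frame(
    cancer_type = rep(c("A", "B"), each = 20),
    group = rep(c("tumor", "normal"), 20),
    stage = c(rep(c("I", "II"), 10), rep("IV", 20)),
    stringsAsFactors = FALSE)

  # single cluster: proportions equal the global stage distribution
  # (one cluster cannot support a stage enrichment test)
  expect_warning(rep1 <- cluster_stage_distribution(factor(rep(1, 40)), meta),
                 "skipped")
  expect_equal(unname(rep1$stage_proportions[1, "IV"]), 0.5)

  # constructed: cluster 2 holds all stage-IV samples
  labels <- factor(ifelse(meta$stage == "IV", 2, 1))
  rep2 <- cluster_stage_distribution(labels, meta)
  expect_equal(unname(rep2$stage_proportions["2", "IV"]), 1)
  expect_true(which.max(rep2$stage_proportions[, "IV"]) == 2)
  expect_lt(rep2$stage_test$p.value, 0.001)

  # missing stage metadata: NA tally, no test, warning
  meta_na <- meta; meta_na$stage <- NA_character_
  expect_warning(rep3 <- cluster_stage_distribution(labels, meta_na), "skipped")
  expect_null(rep3$stage_test)
  expect_true(all(rep3$stage_table[, !is.na(colnames(rep3$stage_table))] == 0))

  expect_error(cluster_stage_distribution(factor(1:3), meta), "cover")
})

test_that("ssGSEA scores match the brute-force running-sum oracle", {
  genes <- c("g1", "g2", "g3", "g4")
  expr <- matrix(c(4, 3, 2, 1), 4, 1, dimnames = list(genes, "s1"))
  sets <- list(top2 = c("g1", "g2"), mid = c("g2", "g3"))

  # alpha = 0 hand enumeration for {g1,g2}: steps 1/2-0, 1-0, 1-1/2, 1-1 -> 2
  es0 <- ssgsea_scores(expr, sets, alpha = 0)
  expect_equal(unname(es0[1, "top2"]), 2)
  for (a in c(0, 0.75, 1)) {
    es <- ssgsea_scores(expr, sets, alpha = a)
    for (s in names(sets))
      expect_equal(unname(es[1, s]),
                   ssgsea_oracle(expr[, 1], genes, sets[[s]], a))
  }
})

test_that("ssGSEA is rank-invariant and handles boundary sets", {
  set.seed(9)
  expr <- matrix(rexp(50 * 4), 50, 4,
                 dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  sets <- list(a = paste0("g", 1:10), b = paste0("g", 30:50),
               all = paste0("g", 1:50))
  es <- ssgsea_scores(expr, sets)
  # strictly increasing transform leaves scores unchanged
  es_t <- ssgsea_scores(exp(expr) + 3, sets)
  expect_equal(es, es_t, ignore_attr = TRUE)
  # the all-gene set dominates every other set within each sample
  expect_true(all(es[, "all"] >= apply(es[, c("a", "b")], 1, max)))
  expect_true(all(is.finite(es)))

  expect_warning(es_na <- ssgsea_scores(expr, list(none = c("x1", "x2"))), "overlap")
  expect_true(all(is.na(es_na[, "none"])))
})

test_that("flux-enrichment correlations behave at the extremes and under null", {
  set.seed(4)
  n <- 500
  flux <- matrix(rnorm(n * 3), n, 3,
                 dimnames = list(paste0("s", 1:n), paste0("M", 1:3)))
  scores <- cbind(same = flux[, 1], anti = -flux[, 2]^3,
                  noise = rnorm(n))
  rownames(scores) <- rownames(flux)
  co <- flux_stress_correlation(flux, scores)
  expect_equal(unname(co["M1", "same"]), 1)
  expect_equal(unname(co["M2", "anti"]), -1)
  expect_lt(abs(median(co[, "noise"])), 0.1)
  expect_true(all(co >= -1 & co <= 1))

  expect_error(flux_stress_correlation(flux[1:2, ], scores[1:2, , drop = FALSE]),
               "3 shared")
})

test_that("GMT files round-trip", {
  sets <- list(s1 = c("a", "b"), s2 = c("c", "d", "e"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  expect_equal(read_gmt(f), sets)
})
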