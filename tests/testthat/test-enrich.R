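toy_collection <- function() {
  gene_set_collection(list(
    list(term_id = "A", term_name = "a", namespace = "BP",
         genes = c("g1", "g2", "g3", "g4", "g5")),
    list(term_id = "B", term_name = "b", namespace = "MF",
         genes = c("g6", "g7")),
    list(term_id = "C", term_name = "c", namespace = "BP",
         genes = c("g9", "g10"))))
}

test_that("ORA reproduces the closed-form hypergeometric example", {
  universe <- paste0("g", 1:10)
  res <- ora(paste0("g", 1:4), universe, toy_collection(), min_size = 2)
  # term A: N=10, K=5, n=4, k=4 -> C(5,4) C(5,0) / C(10,4) = 5/210
  a <- res[res$term_id == "A", ]
  expect_equal(a$p_value, 5 / 210, tolerance = 1e-12)
  expect_equal(a$overlap, 4)
  # zero overlap gives p = 1
  expect_equal(res$p_value[res$term_id == "B"], 1)
  # BH applied within namespace: B is alone in MF
  expect_equal(res$p_fdr[res$term_id == "B"], 1)
  bp <- res[res$namespace == "BP", ]
  expect_equal(sort(bp$p_fdr), sort(bh_adjust(bp$p_value)))
})

test_that("ORA matches exhaustive enumeration on small universes", {
  set.seed(3)
  for (i in 1:40) {
    N <- sample(4:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 hyper_upper_enum(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("ORA enforces universe, size bounds and empty input", {
  universe <- paste0("g", 1:10)
  expect_error(ora("gX", universe, toy_collection()), "subset")
  expect_warning(res <- ora(character(), universe, toy_collection()),
                 "empty DE list")
  expect_equal(nrow(res), 0)
  # min_size = 3 drops the two 2-gene terms
  res2 <- ora(paste0("g", 1:4), universe, toy_collection(), min_size = 3)
  expect_identical(res2$term_id, "A")
  # members outside the universe are ignored before sizing
  res3 <- ora("g1", paste0("g", 1:6), toy_collection(), min_size = 2)
  expect_false("C" %in% res3$term_id)
})

test_that("random-forest importance is deterministic and ignores flat genes", {
  gen <- generate_expression(sim_config(n_genes = 300, n_de = 30, seed = 6))
  col <- preprocess_intensity(gen$table)
  flat <- col
  flat$values[1, ] <- 5  # constant gene cannot split anything
  a <- rf_importance(flat, gen$design, n_trees = 300, seed = 42)
  b <- rf_importance(flat, gen$design, n_trees = 300, seed = 42)
  expect_identical(a$importance, b$importance)
  expect_equal(a$importance[1], 0)
  expect_true(all(a$importance >= 0))
  expect_error(rf_importance(col, gen$design[1:2, ], n_trees = 10),
               "absent from design")
})

test_that("planted genes dominate importance when the design permits", {
  # at 4 samples/group the noise-gene rank-tie fraction is small enough
  # for planted separators to rise above the null importance tail
  gen <- generate_expression(sim_config(n_genes = 2000, n_de = 100,
                                        n_per_group = 4, seed = 5))
  col <- preprocess_intensity(gen$table)
  imp <- rf_importance(col, gen$design, n_trees = 1000, seed = 14)
  planted <- gen$truth$de_genes$R_vs_C$gene
  pl <- imp$importance[imp$gene %in% planted]
  un <- imp$importance[!imp$gene %in% planted]
  expect_gt(median(pl), quantile(un, 0.95))
})

test_that("term aggregation is a plain mean over mapped genes", {
  imp <- structure(data.frame(gene = c("g1", "g2", "g3"),
                              importance = c(0.4, 0.1, 0.7)),
                   class = c("gini_importance", "data.frame"))
  coll <- gene_set_collection(list(
    list(term_id = "T1", term_name = "t", namespace = "BP",
         genes = c("g1", "g2")),
    list(term_id = "T2", term_name = "t", namespace = "BP", genes = "g3"),
    list(term_id = "T3", term_name = "t", namespace = "BP",
         genes = c("g2", "g1", "g1", "gX"))))
  tr <- aggregate_terms(imp, coll)
  expect_equal(tr$score[tr$term_id == "T1"], 0.25)
  expect_equal(tr$score[tr$term_id == "T2"], 0.7)
  # duplicated members and unmapped genes do not change the mean
  expect_equal(tr$score[tr$term_id == "T3"], 0.25)
  expect_equal(tr$n_mapped[tr$term_id == "T3"], 2)
  # terms with no mapped genes are excluded
  coll2 <- gene_set_collection(list(
    list(term_id = "T4", term_name = "t", namespace = "BP", genes = "gZ")))
  expect_message(tr2 <- aggregate_terms(imp, coll2), "no mapped genes")
  expect_null(tr2)
  # constant importance scores every term identically
  imp$importance <- rep(0.3, 3)
  expect_equal(unique(aggregate_terms(imp, coll)$score), 0.3)
})

test_that("permutation p-values respect their bounds and exact ties", {
  imp <- structure(data.frame(gene = paste0("g", 1:40),
                              importance = runif(40)),
                   class = c("gini_importance", "data.frame"))
  # term = entire universe: every permutation ties, p = 1
  expect_equal(permutation_p(mean(imp$importance), 40, imp,
                             n_perm = 200, seed = 1), 1)
  # add-one lower bound
  p <- permutation_p(max(imp$importance), 1, imp, n_perm = 200, seed = 2)
  expect_gte(p, 1 / 201)
  expect_error(permutation_p(0.5, 41, imp, n_perm = 10), "exceeds")
})

test_that("permutation p is super-uniform under a null importance vector", {
  set.seed(50)
  hits <- vapply(1:2000, function(i) {
    scores <- rexp(60)
    imp <- structure(data.frame(gene = paste0("g", 1:60),
                                importance = scores),
                     class = c("gini_importance", "data.frame"))
    idx <- sample.int(60, 6)
    permutation_p(mean(scores[idx]), 6, imp, n_perm = 99,
                  seed = i) <= 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.07)
})

test_that("planted enriched terms earn small permutation p at n = 4/group", {
  cfg <- sim_config(n_genes = 2000, n_de = 100, n_per_group = 4, seed = 8)
  gen <- generate_expression(cfg)
  col <- preprocess_intensity(gen$table)
  gs <- generate_genesets(cfg, gen$truth)
  imp <- rf_importance(col, gen$design, n_trees = 1000, seed = 18)
  tr <- aggregate_terms(imp, gs$collection)
  tr <- add_permutation_p(tr, imp, n_perm = 1000, seed = 4)
  enr <- tr$term_id %in% gs$enriched_terms
  expect_true(all(tr$p_value[enr] <= 0.01))
  # and they outrank every null term by score
  expect_gt(min(tr$score[enr]), max(tr$score[!enr]))
})

test_that("gene/term selection applies the strict filters", {
  terms <- data.frame(
    term_id = c("T1", "T2", "T3", "T4", "T5"),
    term_name = "t",
    namespace = c("BP", "BP", "BP", "MF", "BP"),
    score = 1,
    n_mapped = c(10, 9, 10, 10, 15),
    p_value = c(0.001, 0.001, 0.01, 0.001, 0.0099),
    stringsAsFactors = FALSE)
  imp <- structure(data.frame(gene = sprintf("g%04d", 1:1200),
                              importance = c(rep(2, 600), rep(1, 600))),
                   class = c("gini_importance", "data.frame"))
  sel <- filter_and_select(terms, imp, n_top = 1000)
  # T2: count 9 < 10; T3: p = 0.01 not < 0.01; T4: not BP
  expect_setequal(sel$terms$term_id, c("T1", "T5"))
  expect_length(sel$genes, 1000)
  # ties broken by gene id: all 600 high scorers then lowest 400 ids
  expect_identical(sel$genes[1:600], sprintf("g%04d", 1:600))
  expect_identical(sel$genes[601:1000], sprintf("g%04d", 601:1000))
  expect_warning(sel2 <- filter_and_select(terms, imp[1:500, ],
                                           n_top = 1000), "selecting all")
  expect_length(sel2$genes, 500)
})
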