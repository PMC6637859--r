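test_that("group-means OLS reproduces hand-computed fits", {
  x <- rbind(G1 = c(1, 1, 2, 2, 4, 4),
             G2 = c(0, 2, 1, 1, 1, 1))
  colnames(x) <- make_design()$sample_id
  fit <- fit_models(collapsed_table(x), make_design())
  expect_identical(fit$df_residual, 3L)
  expect_equal(unname(fit$coefficients["G1", ]), c(1, 2, 4))
  expect_equal(fit$s2[["G1"]], 0)
  # C:(0,2) contributes (0-1)^2 + (2-1)^2 = 2 to the RSS
  expect_equal(fit$s2[["G2"]], 2 / 3)
})

test_that("residual variance is unbiased on simulated data", {
  set.seed(99)
  n <- 10000
  x <- matrix(rnorm(n * 6, 8, 1), n, 6,
              dimnames = list(sprintf("G%05d", 1:n), make_design()$sample_id))
  fit <- fit_models(collapsed_table(x), make_design())
  expect_gt(mean(fit$s2), 0.9)
  expect_lt(mean(fit$s2), 1.1)
})

test_that("zero residual df is rejected with a moderation hint", {
  x <- matrix(rnorm(30), 10, 3,
              dimnames = list(sprintf("G%02d", 1:10), c("C_1", "S_1", "R_1")))
  d <- data.frame(sample_id = c("C_1", "S_1", "R_1"),
                  group = c("C", "S", "R"))
  expect_warning(expect_error(fit_models(collapsed_table(x), d),
                              "moderation cannot rescue"))
})

test_that("trigamma inversion reproduces its target", {
  for (target in c(1e-4, 0.01, 0.5, 0.9348, 5, 100)) {
    x <- spacecord:::trigamma_inverse(target)
    expect_lt(abs(trigamma(x) - target), 1e-9)
  }
  expect_identical(spacecord:::trigamma_inverse(0), Inf)
})

test_that("homogeneous variances give an infinite prior df", {
  fit <- structure(list(s2 = rep(2, 500), df_residual = 3L),
                   class = "de_fit")
  prior <- estimate_prior(fit)
  expect_identical(prior$d0, Inf)
  expect_equal(prior$s02,
               exp(log(2) - digamma(1.5) + log(1.5)))
})

test_that("prior estimation agrees with limma on heteroscedastic data", {
  set.seed(7)
  n <- 2000
  sig <- sqrt(4 / rchisq(n, 4))
  x <- matrix(rnorm(n * 6, 0, rep(sig, 6)), n, 6,
              dimnames = list(sprintf("G%04d", 1:n),
                              make_design()$sample_id)) + 8
  fit <- fit_models(collapsed_table(x), make_design())
  prior <- estimate_prior(fit)
  grp <- factor(make_design()$group, levels = c("C", "S", "R"))
  dm <- stats::model.matrix(~ 0 + grp)
  colnames(dm) <- levels(grp)
  eb <- limma::eBayes(limma::contrasts.fit(
    limma::lmFit(x, dm),
    limma::makeContrasts(R_vs_C = R - C, levels = dm)))
  expect_equal(prior$d0, eb$df.prior, tolerance = 1e-8)
  expect_equal(prior$s02, eb$s2.prior, tolerance = 1e-8)
  st <- moderate_and_test(fit, prior)
  s <- st[st$contrast == "R_vs_C", ]
  expect_equal(s$t, unname(eb$t[, 1]), tolerance = 1e-10)
  expect_equal(s$p_value, unname(eb$p.value[, 1]), tolerance = 1e-10)
})

test_that("moderation limits recover ordinary t and full shrinkage", {
  set.seed(12)
  x <- matrix(rnorm(600, 5, 1), 100, 6,
              dimnames = list(sprintf("G%03d", 1:100),
                              make_design()$sample_id))
  fit <- fit_models(collapsed_table(x), make_design())
  # d0 = 0: no moderation, ordinary t on d df
  st0 <- moderate_and_test(fit, list(d0 = 0, s02 = 1))
  s <- st0[st0$contrast == "R_vs_C", ]
  lfc <- fit$coefficients[, "R"] - fit$coefficients[, "C"]
  t_ord <- lfc / sqrt(fit$s2 * (1 / 2 + 1 / 2))
  expect_equal(s$t, unname(t_ord), tolerance = 1e-12)
  expect_equal(s$p_value, unname(2 * pt(-abs(t_ord), df = 3)),
               tolerance = 1e-12)
  # d0 = Inf: posterior variance is s02 for every gene, normal p-values
  stI <- moderate_and_test(fit, list(d0 = Inf, s02 = 0.5))
  sI <- stI[stI$contrast == "R_vs_C", ]
  expect_equal(sI$t, unname(lfc / sqrt(0.5)), tolerance = 1e-12)
  expect_equal(sI$p_value, unname(2 * pnorm(-abs(sI$t))), tolerance = 1e-12)
})

test_that("posterior variance lies between gene and prior variance", {
  set.seed(5)
  x <- matrix(rnorm(1200, 6, 1.5), 200, 6,
              dimnames = list(sprintf("G%03d", 1:200),
                              make_design()$sample_id))
  fit <- fit_models(collapsed_table(x), make_design())
  prior <- estimate_prior(fit)
  d <- fit$df_residual
  s2p <- if (is.infinite(prior$d0)) rep(prior$s02, 200) else
    (prior$d0 * prior$s02 + d * fit$s2) / (prior$d0 + d)
  expect_true(all(s2p >= pmin(fit$s2, prior$s02) - 1e-12))
  expect_true(all(s2p <= pmax(fit$s2, prior$s02) + 1e-12))
  st <- moderate_and_test(fit, prior)
  expect_true(all(st$p_fdr >= st$p_value - 1e-15))
  expect_true(all(st$p_value >= 0 & st$p_fdr <= 1))
})

test_that("BH adjustment matches hand computations and the oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.03, 0.5)), c(0.015, 0.045, 0.5))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")

  set.seed(41)
  for (i in 1:25) {
    p <- runif(sample(2:200, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_stepup_oracle(p), tolerance = 1e-14)
    expect_equal(bh_adjust(p), bh_stepup_literal(p), tolerance = 1e-14)
    # monotonicity in the raw p-values
    o <- order(p)
    expect_true(all(diff(bh_adjust(p)[o]) >= -1e-15))
  }
})

test_that("DE calls use strict inequalities at both cutoffs", {
  stats <- data.frame(
    gene = c("g1", "g2", "g3", "g4", "g5"),
    contrast = "R_vs_C",
    logFC = c(3, 2, -3, 2.5, -2.5),
    t = 1, p_value = 0.001,
    p_fdr = c(0.05, 0.01, 0.049, 0.01, 0.02),
    stringsAsFactors = FALSE)
  calls <- call_de(stats)
  # g1: p_fdr exactly 0.05 -> excluded; g2: logFC exactly 2 -> excluded
  expect_identical(calls$R_vs_C$up, "g4")
  expect_identical(calls$R_vs_C$down, c("g3", "g5"))
  expect_equal(calls$summary$n_up, 1L)
  expect_equal(calls$summary$n_down, 2L)
  expect_error(call_de(stats, lfc_thresh = -1), "positive")
})

test_that("DE recovery is invariant to gene and within-group column order", {
  gen <- generate_expression(sim_config(n_genes = 800, n_de = 60, seed = 3))
  col <- preprocess_intensity(gen$table)
  run <- function(tab) {
    fit <- fit_models(tab, gen$design)
    call_de(moderate_and_test(fit, estimate_prior(fit)))$summary
  }
  base <- run(col)
  shuf <- spacecord:::subset_probes(col, sample(nrow(col$values)))
  expect_equal(run(shuf), base)
  # swap the two samples within each group
  swap <- c(2, 1, 4, 3, 6, 5)
  col_swap <- intensity_table(col$values[, swap], col$probe_id,
                              col$gene_symbol, col$is_control,
                              state = "collapsed", log2 = TRUE)
  expect_equal(run(col_swap), base)
})

test_that("volcano and top-k tables are consistent with the statistics", {
  set.seed(88)
  x <- matrix(rnorm(900, 8, 1), 150, 6,
              dimnames = list(sprintf("G%03d", 1:150),
                              make_design()$sample_id))
  x[1:5, 5:6] <- x[1:5, 5:6] + 5
  fit <- fit_models(collapsed_table(x), make_design())
  st <- moderate_and_test(fit, estimate_prior(fit))
  v <- volcano_table(st, "R_vs_C")
  expect_identical(v$gene, sort(v$gene))
  # -log10 mapping of the raw p-value
  i <- match("G001", v$gene)
  p <- st$p_value[st$contrast == "R_vs_C" & st$gene == "G001"]
  expect_equal(v$neg_log10_p[i], -log10(p))
  calls <- call_de(st)
  expect_setequal(v$gene[v$de],
                  c(calls$R_vs_C$up, calls$R_vs_C$down))

  # top-k returns exactly the k smallest min-across-contrast p_fdr
  best <- tapply(st$p_fdr, st$gene, min)
  k10 <- top_k_table(st, 10)
  expect_true(max(best[k10]) <= min(best[setdiff(names(best), k10)]))
  expect_warning(allg <- top_k_table(st, 200), "exceeds")
  expect_length(allg, 150)
})

test_that("degenerate zero posterior variance is flagged with p = 0", {
  x <- rbind(G1 = c(1, 1, 1, 1, 5, 5),
             G2 = c(1, 1, 1, 1, 1, 1))
  colnames(x) <- make_design()$sample_id
  fit <- fit_models(collapsed_table(x), make_design())
  st <- moderate_and_test(fit, list(d0 = 0, s02 = 1))
  s <- st[st$contrast == "R_vs_C" & st$gene == "G1", ]
  expect_true(s$degenerate)
  expect_identical(s$p_value, 0)
})
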