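quant_of <- function(exon_expr, psi = NULL, gene_expr = NULL, id = "E") {
  n <- length(exon_expr)
  psi <- psi %||% rep(0.5, n)
  structure(list(event_id = id, gene_id = "G",
                 sample_id = sprintf("s%d", seq_len(n)), psi = psi,
                 psi_defined = !is.na(psi), exon_expr = exon_expr,
                 gene_expr = gene_expr %||% (exon_expr * 2)),
            class = "event_quant")
}

test_that("variability filter applies the expression, prevalence and ratio criteria", {
  f <- variability_filter(quant_of(rep(25, 10)))
  expect_equal(f$expressed_fraction, 1)
  expect_equal(f$mean_expr, 25)
  expect_equal(f$p95_p5_ratio, 1)
  expect_false(f$passed)   # constant vector fails the ratio

  f2 <- variability_filter(quant_of(c(rep(0, 6), rep(100, 4))))
  expect_equal(f2$expressed_fraction, 0.4)
  expect_false(f2$passed)
  ## zero 5th percentile -> undefined ratio -> fail
  expect_true(is.na(f2$p95_p5_ratio))

  ## lognormal sample: all three criteria recomputed independently
  set.seed(5)
  x <- rlnorm(100, log(50), 0.6)
  f3 <- variability_filter(quant_of(x))
  q <- sort(x)
  lin_q <- function(p) {
    h <- (100 - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    q[lo] + (h - lo) * (q[hi] - q[lo])
  }
  expect_equal(f3$p95_p5_ratio, lin_q(0.95) / lin_q(0.05))
  expect_equal(f3$mean_expr, sum(x) / 100)
  expect_equal(f3$expressed_fraction, sum(x >= 1) / 100)
  expect_equal(f3$passed,
               f3$expressed_fraction >= 0.5 && f3$mean_expr >= 20 &&
                 f3$p95_p5_ratio >= 2)
})

test_that("the expression~psi regression recovers exact lines and degenerates safely", {
  q <- quant_of(rep(10, 3), psi = c(0, 0.5, 1), gene_expr = c(0, 1, 2))
  fit <- fit_expression_psi(q)
  expect_equal(fit$beta1, 2)
  expect_equal(fit$beta0, 0)
  expect_equal(fit$r2, 1)
  fit2 <- fit_expression_psi(quant_of(rep(10, 3), psi = c(0, 0.5, 1),
                                      gene_expr = c(2, 1, 0)))
  expect_equal(fit2$beta1, -2)
  expect_equal(fit2$r2, 1)
  ## constant psi or too few samples -> degenerate, never an error
  expect_true(fit_expression_psi(quant_of(1:5, psi = rep(0.4, 5)))$degenerate)
  expect_true(fit_expression_psi(quant_of(1:2, psi = c(0.1, 0.9)))$degenerate)
})

test_that("slope estimate sits in its standard-error band and p matches a permutation oracle", {
  set.seed(21)
  n <- 50
  psi <- runif(n)
  y <- 10 + 5 * psi + rnorm(n)
  fit <- fit_expression_psi(quant_of(rep(30, n), psi = psi, gene_expr = y))
  se_analytic <- 1 / sqrt(sum((psi - mean(psi))^2))  # sigma = 1 by design
  expect_lt(abs(fit$beta1 - 5), 4 * se_analytic)

  ## weak-effect case: two-sided slope p agrees with a permutation oracle
  set.seed(22)
  y2 <- 10 + 0.8 * psi + rnorm(n)
  fit2 <- fit_expression_psi(quant_of(rep(30, n), psi = psi, gene_expr = y2))
  B <- 4000
  t_obs <- abs(fit2$beta1)
  exceed <- 0
  for (b in seq_len(B)) {
    yp <- sample(y2)
    bp <- coef(lm(yp ~ psi))[2]
    if (abs(bp) >= t_obs) exceed <- exceed + 1
  }
  p_perm <- exceed / B
  se_mc <- sqrt(p_perm * (1 - p_perm) / B) + 1e-3
  expect_lt(abs(fit2$p_slope - p_perm), 4 * se_mc + 0.02)
})

test_that("BH adjustment is the step-up procedure and is order invariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(8)
  p <- runif(20)
  o <- sample(20)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("event labels follow the UHP/DHP/type-0 rule table", {
  filt <- list(p95_p5_ratio = 3, passed = TRUE)
  fit <- list(beta1 = 4, r2 = 0.6, gene_p95_p5_ratio = 3, degenerate = FALSE)
  expect_equal(classify_event(fit, 0.01, filt), "UHP")
  fit$beta1 <- -4
  expect_equal(classify_event(fit, 0.01, filt), "DHP")
  expect_equal(classify_event(fit, 0.7, filt), "TYPE0")
  expect_equal(classify_event(fit, 0.2, list(p95_p5_ratio = 3, passed = TRUE)),
               "INDETERMINATE")  # between the two rule sets
  ## degenerate fit is always indeterminate
  expect_equal(classify_event(list(degenerate = TRUE, gene_p95_p5_ratio = 3),
                              NA_real_, filt), "INDETERMINATE")
  ## low R2 blocks a UHP call even at small adjusted p
  fit2 <- list(beta1 = 4, r2 = 0.3, gene_p95_p5_ratio = 3, degenerate = FALSE)
  expect_equal(classify_event(fit2, 0.01, filt), "INDETERMINATE")
  ## gene-scope ratio criterion can be selected
  th <- default_thresholds(); th$ratio_scope <- "gene"
  fit3 <- list(beta1 = 4, r2 = 0.9, gene_p95_p5_ratio = 1.5, degenerate = FALSE)
  expect_equal(classify_event(fit3, 0.01, filt, th), "INDETERMINATE")
})

test_that("gene labels aggregate exon labels with purity rules", {
  cl <- data.table::data.table(
    gene_id = c("g1", "g1", "g2", "g2", "g3", "g4"),
    label = c("UHP", "INDETERMINATE", "UHP", "TYPE0", "INDETERMINATE", "DHP"))
  lg <- label_genes(cl)
  expect_equal(lg[lg$gene_id == "g1", ]$gene_label, "UHP_GENE")
  expect_equal(lg[lg$gene_id == "g2", ]$gene_label, "MIXED")
  expect_equal(lg[lg$gene_id == "g3", ]$gene_label, "NONE")
  expect_equal(lg[lg$gene_id == "g4", ]$gene_label, "DHP_GENE")
})

test_that("cross-group consistency counts multi-group events and conflicts", {
  mk <- function(ids, labels, grp)
    data.table::data.table(event_id = ids, gene_id = "g", group = grp,
                           label = labels)
  r1 <- mk(c("e1", "e2"), c("UHP", "UHP"), "t1")
  r2 <- mk(c("e1", "e2"), c("UHP", "DHP"), "t2")
  rep <- consistency_report(list(r1, r2))
  expect_equal(rep$n_multi_group, 2)
  expect_equal(rep$n_conflicts, 1)
  expect_equal(rep$n_consistent, 1)
  ## cross-tabulation against a replication dataset
  rep2 <- consistency_report(list(r1, r2), other = mk("e1", "UHP", "sra"))
  expect_equal(unname(rep2$cross_tab["UHP", "UHP"]), 1L)
})

test_that("multi-group synthetic runs have conflicts matching a pairwise oracle and zero sign flips", {
  cfg <- sim_config(n_genes = 40, n_samples = 120, n_groups = 3, seed = 33)
  ann <- simulate_annotation(cfg)
  expr <- simulate_expression(cfg, ann)
  events <- collapse_equivalent_events(find_cassette_events(ann$models))
  runs <- lapply(sprintf("g%d", 1:3), function(g) {
    keep <- names(expr$sample_groups)[expr$sample_groups == g]
    classify_events(quantify_events(expr$mat[, keep], events), group = g)
  })
  rep <- consistency_report(runs)
  ## pairwise brute-force conflict count
  pooled <- data.table::rbindlist(runs)
  pooled <- pooled[pooled$label %in% c("UHP", "DHP"), ]
  conflicts <- 0
  for (e in unique(pooled$event_id)) {
    labs <- pooled$label[pooled$event_id == e]
    if (length(labs) >= 2 && length(unique(labs)) > 1) conflicts <- conflicts + 1
  }
  expect_equal(rep$n_conflicts, conflicts)
  ## planted classes are shared across groups: no sign flips may occur
  expect_equal(rep$n_conflicts, 0)
})

test_that("slope-versus-mean regression returns the generative coefficient", {
  mu <- c(10, 20, 40, 80, 160)
  expect_equal(slope_vs_mean_expression(mu, mu)$coefficient, 1)
  expect_equal(slope_vs_mean_expression(2 * mu, mu)$coefficient, 2)
  expect_error(slope_vs_mean_expression(mu, rep(5, 5)), "constant")
})
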