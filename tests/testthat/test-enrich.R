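test_that("the delta statistic is the difference of hit percentages", {
  hit <- c(rep(1, 163), rep(0, 337), rep(1, 86), rep(0, 414))
  lab <- c(rep("UHP_GENE", 500), rep("TYPE0_GENE", 500))
  d <- delta_statistic(hit, lab, "UHP_GENE", "TYPE0_GENE")
  expect_equal(d$prop_focus, 32.6)
  expect_equal(d$prop_ref, 17.2)
  expect_equal(d$delta, 15.4)
  ## identical patterns -> 0; empty class -> error
  expect_equal(delta_statistic(c(1, 0, 1, 0), c("A", "A", "B", "B"), "A", "B")$delta, 0)
  expect_error(delta_statistic(1, "A", "A", "B"), "non-empty")
  ## random fixture vs direct proportion arithmetic
  set.seed(30)
  h <- rbinom(20, 1, 0.4)
  l <- sample(c("A", "B"), 20, TRUE, prob = c(0.6, 0.4))
  d2 <- delta_statistic(h, l, "A", "B")
  expect_equal(d2$delta, 100 * mean(h[l == "A"]) - 100 * mean(h[l == "B"]))
})

test_that("exhaustive permutation p-values equal full enumeration", {
  hit <- c(1, 0, 1, 0)
  lab <- c("F", "F", "T", "T")
  r <- permutation_pvalue(hit, lab, "F", "T", exhaustive = TRUE)
  expect_equal(r$delta, 0)
  expect_equal(r$n_replicates, 6)
  expect_equal(r$p_emp, 1 / 6)
  ## maximal observed statistic -> p 0
  r2 <- permutation_pvalue(c(1, 1, 0, 0), lab, "F", "T", exhaustive = TRUE)
  expect_equal(r2$delta, 100)
  expect_equal(r2$p_emp, 0)
  expect_error(permutation_pvalue(rep(1, 13), rep(c("F", "T"), c(6, 7)),
                                  "F", "T", exhaustive = TRUE), "12 units")

  ## random small fixtures, including a third lumped class, vs the oracle
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    h <- rbinom(n, 1, 0.5)
    l <- sample(c("F", "T", "O"), n, TRUE)
    if (sum(l == "F") == 0 || sum(l == "T") == 0) next
    got <- permutation_pvalue(h, l, "F", "T", exhaustive = TRUE)
    expect_equal(got$p_emp, oracle_perm_pvalue(h, l, "F", "T"))
  }
})

test_that("Monte-Carlo permutation p-values are reproducible and consistent with exhaustive", {
  hit <- c(1, 0, 1, 0)
  lab <- c("F", "F", "T", "T")
  mc1 <- permutation_pvalue(hit, lab, "F", "T", n_perm = 10000, seed = 99)
  mc2 <- permutation_pvalue(hit, lab, "F", "T", n_perm = 10000, seed = 99)
  expect_identical(mc1$p_emp, mc2$p_emp)   # bit-reproducible given seed
  p_true <- 1 / 6
  se <- sqrt(p_true * (1 - p_true) / 10000)
  expect_lt(abs(mc1$p_emp - p_true), 3 * se)
})

test_that("null permutation p-values are super-uniform (tie-inclusive convention)", {
  ## with a discrete statistic the strict-inequality p undershoots by the tie
  ## mass; the tie-inclusive variant carries the distribution-free guarantee
  set.seed(55)
  n_perm <- 200
  alpha <- 0.1
  hits_below <- 0
  n_data <- 150
  for (rep in 1:n_data) {
    h <- rbinom(16, 1, 0.5)
    l <- rep(c("F", "T"), each = 8)
    p <- permutation_pvalue(h, l, "F", "T", n_perm = n_perm)$p_emp_inclusive
    if (p <= alpha) hits_below <- hits_below + 1
  }
  bound <- alpha + 1 / n_perm
  mc_slack <- 3 * sqrt(bound * (1 - bound) / n_data)
  expect_lte(hits_below / n_data, bound + mc_slack)
  ## and the strict variant never exceeds the inclusive one
  pp <- permutation_pvalue(rbinom(16, 1, 0.5), rep(c("F", "T"), each = 8),
                           "F", "T", n_perm = 500, seed = 2)
  expect_lte(pp$p_emp, pp$p_emp_inclusive)
})

test_that("motif screening finds planted factors, flags tiny effects, and spares nulls", {
  set.seed(61)
  labels <- setNames(rep(c("UHP_GENE", "TYPE0_GENE"), each = 200),
                     sprintf("u%03d", 1:400))
  sim <- simulate_hits(labels, seed = 61, n_factors = 6, base_prob = 0.15,
                       planted_delta = 15, n_planted = 2)
  scr <- motif_screen(sim$hits, labels,
                      comparisons = list(c("UHP_GENE", "TYPE0_GENE")),
                      n_perm = 2000, seed = 7)
  planted <- scr[scr$factor_id %in% c("FACTOR001", "FACTOR002"), ]
  expect_true(all(planted$p_bonf < 0.05))
  expect_true(all(planted$delta > 5))
  null_rows <- scr[!(scr$factor_id %in% c("FACTOR001", "FACTOR002")), ]
  expect_true(all(null_rows$p_emp > 0.001 | abs(null_rows$delta) < 5))

  ## a 0.3-point delta is excluded regardless of p
  h <- cbind(F1 = c(rep(1, 303), rep(0, 697), rep(1, 300), rep(0, 700)))
  rownames(h) <- sprintf("g%04d", 1:2000)
  lab2 <- setNames(rep(c("UHP_GENE", "TYPE0_GENE"), each = 1000), rownames(h))
  scr2 <- motif_screen(h, lab2, comparisons = list(c("UHP_GENE", "TYPE0_GENE")),
                       n_perm = 50, seed = 1)
  expect_equal(scr2$delta, 0.3)
  expect_true(scr2$excluded)
})

test_that("GO over-representation matches the combinatorial formula", {
  classes <- setNames(c(rep("UHP", 4), rep("TYPE0", 6)), sprintf("i%02d", 1:10))
  ann <- data.frame(isoform_id = sprintf("i%02d", 1:5), go_id = "GO:0000001")
  res <- go_hypergeometric(ann, classes, min_focus = 4)
  expect_equal(res$p, 6 / 252, tolerance = 1e-12)
  expect_equal(res$coverage, 4 / 5)
  ## below the minimum focus count the term is skipped
  expect_equal(nrow(go_hypergeometric(ann, classes, min_focus = 5)), 0L)
  ## unclassed isoforms are ignored with a message
  ann2 <- rbind(ann, data.frame(isoform_id = "ghost", go_id = "GO:0000001"))
  expect_message(res2 <- go_hypergeometric(ann2, classes, min_focus = 4),
                 "without class")
  expect_equal(res2$p, res$p)
})

test_that("GO p-values equal the factorial oracle on random small universes", {
  set.seed(71)
  for (rep in 1:30) {
    N <- sample(10:30, 1)
    K <- sample(5:(N - 1), 1)
    classes <- setNames(sample(c(rep("UHP", K), rep("TYPE0", N - K))),
                        sprintf("i%03d", 1:N))
    n_term <- sample(5:N, 1)
    members <- sample(names(classes), n_term)
    ann <- data.frame(isoform_id = members, go_id = "GO:X")
    k <- sum(classes[members] == "UHP")
    res <- go_hypergeometric(ann, classes, min_focus = 1)
    expect_equal(res$p, oracle_hyper_upper(N, K, n_term, k), tolerance = 1e-10)
  }
})

test_that("planted GO terms rank first", {
  set.seed(81)
  classes <- setNames(sample(c("UHP", "DHP", "TYPE0"), 300, TRUE,
                             prob = c(0.3, 0.3, 0.4)), sprintf("iso%03d", 1:300))
  go <- simulate_go(classes, seed = 81, n_terms = 25, n_planted = 2,
                    planted_coverage = 0.8)
  res <- go_hypergeometric(go$annotations, classes)
  expect_true(all(res$go_id[1:2] %in% go$truth$go_id[go$truth$planted]))
  expect_true(all(res$adj_p[1:2] < 0.05))
})

test_that("psi-marker correlations follow the textbook formula", {
  psi <- rbind(e1 = seq(0.1, 0.9, length.out = 9),
               e2 = 1 - seq(0.1, 0.9, length.out = 9))
  marker <- seq(2, 18, length.out = 9)
  r <- psi_marker_correlation(psi, marker)
  expect_equal(r$r, c(1, -1))
  set.seed(91)
  pm <- matrix(runif(30), 3, 10, dimnames = list(c("a", "b", "c"), NULL))
  mk <- rnorm(10)
  rr <- psi_marker_correlation(pm, mk)
  for (i in 1:3) {
    x <- pm[i, ]
    want <- sum((x - mean(x)) * (mk - mean(mk))) /
      sqrt(sum((x - mean(x))^2) * sum((mk - mean(mk))^2))
    expect_equal(rr$r[i], want, tolerance = 1e-12)
  }
  ## constant psi is flagged undefined
  pm2 <- rbind(const = rep(0.5, 10))
  expect_false(psi_marker_correlation(pm2, mk)$defined)
})

test_that("hit matrices round-trip through TSV", {
  set.seed(95)
  labels <- setNames(sample(c("UHP_GENE", "TYPE0_GENE"), 12, TRUE),
                     sprintf("u%02d", 1:12))
  hits <- matrix(rbinom(36, 1, 0.3), 12, 3,
                 dimnames = list(names(labels), c("fA", "fB", "fC")))
  path <- tempfile(fileext = ".tsv")
  write_hits_tsv(hits, labels, path)
  back <- read_hits_tsv(path)
  expect_equal(back$hits, hits)
  expect_equal(back$labels, labels)
})
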