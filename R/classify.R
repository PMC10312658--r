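## Variability filtering, expression~psi regression, and UHP/DHP/type-0
## classification.

#' Default classification thresholds
#'
#' * `min_expressed_fraction` (0.5): exon must be expressed (>= 1 unit) in at
#'   least this fraction of samples.
#' * `min_mean` (20): minimum mean exon expression, in the matrix's units.
#' * `min_ratio` (2): minimum 95th/5th percentile expression ratio, both for
#'   the variability filter and for the significance criteria.
#' * `alpha` (0.05): maximum BH-adjusted p for a UHP/DHP call (inclusive).
#' * `type0_min_p` (0.5): minimum BH-adjusted p for a type-0 call (inclusive).
#' * `min_r2` (0.5): minimum coefficient of determination for a UHP/DHP call.
#' * `ratio_scope` (`"exon"`): which 95/5 ratio the UHP/DHP/type-0 criteria
#'   use — the exon-level ratio (default) or `"gene"` for the gene-level one.
#'   Both ratios are always computed and reported.
#'
#' @return A named list of thresholds.
#' @export
default_thresholds <- function() {
  list(min_expressed_fraction = 0.5, min_mean = 20, min_ratio = 2,
       alpha = 0.05, type0_min_p = 0.5, min_r2 = 0.5, ratio_scope = "exon")
}

#' Expression-variability filter for one event
#'
#' An event passes when its exon expression is at least 1 unit in at least
#' half the samples, has mean at least 20 units, and has a 95th/5th
#' percentile ratio of at least 2 (linear-interpolation percentiles; the
#' ratio is undefined, hence a fail, when the 5th percentile is zero).
#'
#' @param quant An [event_psi()] result.
#' @param thresholds See [default_thresholds()].
#' @return A list: `event_id`, `expressed_fraction`, `mean_expr`,
#'   `p95_p5_ratio`, `passed`.
#' @export
variability_filter <- function(quant, thresholds = default_thresholds()) {
  x <- quant$exon_expr
  check_that(length(x) >= 1L, "variability_filter: no samples")
  frac <- mean(x >= 1)
  mean_expr <- mean(x)
  ratio <- percentile_ratio(x)
  passed <- frac >= thresholds$min_expressed_fraction &&
    mean_expr >= thresholds$min_mean &&
    !is.na(ratio) && ratio >= thresholds$min_ratio
  list(event_id = quant$event_id, expressed_fraction = frac,
       mean_expr = mean_expr, p95_p5_ratio = ratio, passed = passed)
}

#' Ordinary least squares of gene expression on psi
#'
#' Fits `Y(g) ~ beta0 + beta1 * psi` over the samples where psi is defined
#' (undefined samples are dropped pairwise). The slope p-value is the
#' two-sided t test with `n_used - 2` degrees of freedom; R^2 is
#' `1 - SSres/SStot`. Fewer than 3 usable samples, or constant psi or
#' constant expression, yields a degenerate fit (flagged, never an error):
#' such events are classified INDETERMINATE downstream.
#'
#' @param quant An [event_psi()] result.
#' @return A list: `event_id`, `beta0`, `beta1`, `p_slope`, `r2`, `n_used`,
#'   `gene_p95_p5_ratio`, `degenerate`.
#' @export
fit_expression_psi <- function(quant) {
  ok <- quant$psi_defined & !is.na(quant$gene_expr)
  psi <- quant$psi[ok]
  y <- quant$gene_expr[ok]
  gene_ratio <- percentile_ratio(y)
  base <- list(event_id = quant$event_id, beta0 = NA_real_, beta1 = NA_real_,
               p_slope = NA_real_, r2 = NA_real_, n_used = sum(ok),
               gene_p95_p5_ratio = gene_ratio, degenerate = TRUE)
  if (sum(ok) < 3L || stats::var(psi) == 0 || stats::var(y) == 0) return(base)
  fit <- lm(y ~ psi)
  sm <- suppressWarnings(summary(fit))  # noiseless fixtures fit perfectly
  base$beta0 <- unname(coef(fit)[1])
  base$beta1 <- unname(coef(fit)[2])
  base$p_slope <- sm$coefficients[2, 4]
  base$r2 <- sm$r.squared
  base$degenerate <- FALSE
  base
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p-values, monotone in rank order and capped at 1. The
#' adjustment is applied within one sample group (tissue) at a time by
#' [classify_events()].
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  check_that(is.numeric(p), "p-values must be numeric")
  pp <- p[!is.na(p)]
  check_that(all(pp >= 0 & pp <= 1), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Classify one event from its fit, adjusted p, and filter decision
#'
#' UHP: adjusted p <= alpha, R^2 >= 0.5, 95/5 expression ratio >= 2 and
#' beta1 > 0 (higher inclusion predicts higher expression). DHP: the same
#' with beta1 < 0. TYPE0: adjusted p >= 0.5 with ratio >= 2 and the
#' variability filter passed — variable expression with strong evidence of
#' no coupling. Anything else, including degenerate fits, is INDETERMINATE.
#'
#' @param fit A [fit_expression_psi()] result.
#' @param adj_p BH-adjusted slope p-value for this event.
#' @param filter A [variability_filter()] result.
#' @param thresholds See [default_thresholds()].
#' @return One of `"UHP"`, `"DHP"`, `"TYPE0"`, `"INDETERMINATE"`.
#' @export
classify_event <- function(fit, adj_p, filter, thresholds = default_thresholds()) {
  ratio <- if (identical(thresholds$ratio_scope, "gene"))
    fit$gene_p95_p5_ratio else filter$p95_p5_ratio
  ratio_ok <- !is.na(ratio) && ratio >= thresholds$min_ratio
  if (!fit$degenerate && !is.na(adj_p)) {
    sig <- adj_p <= thresholds$alpha && !is.na(fit$r2) &&
      fit$r2 >= thresholds$min_r2 && ratio_ok
    if (sig && fit$beta1 > 0) return("UHP")
    if (sig && fit$beta1 < 0) return("DHP")
  }
  if (!is.na(adj_p) && adj_p >= thresholds$type0_min_p && ratio_ok &&
      isTRUE(filter$passed)) return("TYPE0")
  "INDETERMINATE"
}

#' Classify all events of one sample group
#'
#' Applies the variability filter, fits the expression~psi regression for
#' every filter-passing event, adjusts the slope p-values with
#' Benjamini-Hochberg within the group, and assigns labels. Events failing
#' the filter are retained in the output (label INDETERMINATE, `analyzed =
#' FALSE`) but do not enter the regression or the BH family.
#'
#' @param quants Named list of [event_psi()] results.
#' @param group Group label (tissue, donor, or dataset) recorded per row.
#' @param thresholds See [default_thresholds()].
#' @return A `data.table`, one row per event: ids, group, filter fields, fit
#'   fields, `adj_p`, `analyzed`, `label`.
#' @export
classify_events <- function(quants, group = "group1",
                            thresholds = default_thresholds()) {
  filters <- lapply(quants, variability_filter, thresholds = thresholds)
  analyzed <- vapply(filters, `[[`, TRUE, "passed")
  fits <- lapply(seq_along(quants), function(i) {
    if (analyzed[i]) fit_expression_psi(quants[[i]])
    else list(event_id = quants[[i]]$event_id, beta0 = NA_real_,
              beta1 = NA_real_, p_slope = NA_real_, r2 = NA_real_,
              n_used = NA_integer_,
              gene_p95_p5_ratio = percentile_ratio(quants[[i]]$gene_expr),
              degenerate = TRUE)
  })
  p_raw <- vapply(fits, `[[`, 0, "p_slope")
  adj <- rep(NA_real_, length(fits))
  in_family <- analyzed & !is.na(p_raw)
  adj[in_family] <- bh_adjust(p_raw[in_family])
  labels <- vapply(seq_along(fits), function(i) {
    if (!analyzed[i]) return("INDETERMINATE")
    classify_event(fits[[i]], adj[i], filters[[i]], thresholds)
  }, "")
  data.table(
    event_id = vapply(quants, `[[`, "", "event_id"),
    gene_id = vapply(quants, `[[`, "", "gene_id"),
    group = group,
    expressed_fraction = vapply(filters, `[[`, 0, "expressed_fraction"),
    mean_expr = vapply(filters, `[[`, 0, "mean_expr"),
    exon_p95_p5_ratio = vapply(filters, `[[`, 0, "p95_p5_ratio"),
    filter_passed = analyzed,
    n_used = vapply(fits, function(f) as.integer(f$n_used), 0L),
    beta0 = vapply(fits, `[[`, 0, "beta0"),
    beta1 = vapply(fits, `[[`, 0, "beta1"),
    p = p_raw,
    adj_p = adj,
    r2 = vapply(fits, `[[`, 0, "r2"),
    gene_p95_p5_ratio = vapply(fits, `[[`, 0, "gene_p95_p5_ratio"),
    analyzed = analyzed,
    label = labels
  )
}

#' Gene-level labels from classified events
#'
#' A gene is a UHP gene when it has at least one UHP exon and no DHP or
#' type-0 exon; DHP and type-0 genes symmetrically. Genes with labeled exons
#' of conflicting classes are MIXED; genes whose exons are all INDETERMINATE
#' are NONE.
#'
#' @param classified Output of [classify_events()].
#' @return A `data.table`: `gene_id`, `gene_label`.
#' @export
label_genes <- function(classified) {
  classified[, {
    n_uhp <- sum(label == "UHP"); n_dhp <- sum(label == "DHP")
    n_t0 <- sum(label == "TYPE0")
    lab <- if (n_uhp > 0 && n_dhp == 0 && n_t0 == 0) "UHP_GENE"
    else if (n_dhp > 0 && n_uhp == 0 && n_t0 == 0) "DHP_GENE"
    else if (n_t0 > 0 && n_uhp == 0 && n_dhp == 0) "TYPE0_GENE"
    else if (n_uhp + n_dhp + n_t0 > 0) "MIXED"
    else "NONE"
    .(gene_label = lab)
  }, by = gene_id]
}

#' Cross-group consistency of UHP/DHP assignments
#'
#' Counts events labeled UHP or DHP in two or more groups, how many of those
#' carry the same label everywhere, and how many conflict (UHP in one group,
#' DHP in another). Optionally cross-tabulates labels against a second result
#' set (replication in an external dataset).
#'
#' @param results_by_group List of [classify_events()] outputs (>= 2 groups).
#' @param other Optional single [classify_events()] output to cross-tabulate
#'   against the pooled labels of `results_by_group`.
#' @return A list: `n_multi_group`, `n_consistent`, `n_conflicts`,
#'   `per_event` (event-level label summary), and `cross_tab` when `other`
#'   is given.
#' @export
consistency_report <- function(results_by_group, other = NULL) {
  check_that(length(results_by_group) >= 2L, "need at least 2 groups")
  pooled <- rbindlist(results_by_group)[label %in% c("UHP", "DHP")]
  per_event <- pooled[, .(
    n_groups = .N, n_uhp = sum(label == "UHP"), n_dhp = sum(label == "DHP")
  ), by = event_id]
  multi <- per_event[n_groups >= 2L]
  conflicts <- multi[n_uhp > 0L & n_dhp > 0L]
  out <- list(
    n_multi_group = nrow(multi),
    n_consistent = nrow(multi) - nrow(conflicts),
    n_conflicts = nrow(conflicts),
    per_event = per_event
  )
  if (!is.null(other)) {
    mine <- rbindlist(results_by_group)[, .(
      label = if (any(label == "UHP") && any(label == "DHP")) "CONFLICT"
      else if (any(label == "UHP")) "UHP"
      else if (any(label == "DHP")) "DHP"
      else if (any(label == "TYPE0")) "TYPE0" else "INDETERMINATE"
    ), by = event_id]
    shared <- merge(mine, other[, .(event_id, other_label = label)],
                    by = "event_id")
    out$cross_tab <- table(this = shared$label, other = shared$other_label)
  }
  out
}

#' Regression slope versus mean gene expression
#'
#' Across UHP/DHP events, regresses the fitted expression~psi slope on the
#' gene's mean expression level. Under a multiplicative coupling model the
#' slope equals the gene's baseline mean, so the coefficient is close to 1.
#'
#' @param beta1 Fitted slopes, one per event.
#' @param mean_expr Mean gene expression per event (same order).
#' @return A list: `coefficient`, `se`, `ci` (95 percent), `n`.
#' @export
slope_vs_mean_expression <- function(beta1, mean_expr) {
  ok <- !is.na(beta1) & !is.na(mean_expr)
  check_that(sum(ok) >= 3L, "need at least 3 fits")
  check_that(stats::var(mean_expr[ok]) > 0,
             "mean expression is constant: coefficient undefined")
  fit <- lm(beta1[ok] ~ mean_expr[ok])
  sm <- suppressWarnings(summary(fit))  # exact-line inputs fit perfectly
  est <- sm$coefficients[2, 1]
  se <- sm$coefficients[2, 2]
  tq <- stats::qt(0.975, df = sum(ok) - 2)
  list(coefficient = unname(est), se = unname(se),
       ci = unname(c(est - tq * se, est + tq * se)), n = sum(ok))
}

#' Write per-group classification results to TSV
#'
#' @param classified Output of [classify_events()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_classified_tsv <- function(classified, file) {
  fwrite(classified, file, sep = "\t")
  invisible(file)
}
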