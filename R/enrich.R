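## Label-permutation enrichment of binding-factor hits, isoform-level GO
## over-representation, and psi-versus-marker correlation.

#' Difference of hit proportions between two gene classes
#'
#' The enrichment statistic: the percentage of focus-class units with a hit
#' minus the percentage of reference-class units with a hit, in percentage
#' points. With 32.6 percent of UHP promoters and 17.2 percent of type-0
#' promoters carrying a TATA box, delta is 15.4.
#'
#' @param hit Binary (0/1) vector, one entry per unit.
#' @param labels Class label per unit.
#' @param focus,ref The two classes compared (e.g. `"UHP_GENE"`,
#'   `"TYPE0_GENE"`).
#' @return A list: `delta`, `prop_focus`, `prop_ref` (percentages).
#' @export
delta_statistic <- function(hit, labels, focus, ref) {
  check_that(length(hit) == length(labels), "hit and labels lengths differ")
  nf <- sum(labels == focus); nr <- sum(labels == ref)
  check_that(nf > 0L && nr > 0L, "both classes must be non-empty (%s: %d, %s: %d)",
             focus, nf, ref, nr)
  pf <- 100 * sum(hit[labels == focus]) / nf
  pr <- 100 * sum(hit[labels == ref]) / nr
  list(delta = pf - pr, prop_focus = pf, prop_ref = pr)
}

#' Empirical p-value by label permutation
#'
#' Class labels are shuffled without replacement (class sizes preserved) and
#' the statistic recomputed as delta-prime; the empirical p-value is the
#' proportion of replicates with delta-prime strictly greater than the
#' observed delta, so ties count against significance. In exhaustive mode
#' (at most 12 units) all distinct label assignments are enumerated instead
#' of sampling. Runs are bit-reproducible given `(seed, n_perm)`.
#'
#' @param hit Binary vector per unit.
#' @param labels Class label per unit.
#' @param focus,ref Compared classes.
#' @param n_perm Number of Monte-Carlo permutations (ignored when
#'   `exhaustive`).
#' @param seed Integer seed for the Monte-Carlo draw.
#' @param exhaustive Enumerate all distinct assignments (requires <= 12
#'   units).
#' @return A list: `delta`, `p_emp` (strict-inequality convention),
#'   `p_emp_inclusive` (replicates with delta-prime >= delta; the variant
#'   with guaranteed super-uniformity under the null when the statistic is
#'   discrete), `n_replicates`, `method`.
#' @export
permutation_pvalue <- function(hit, labels, focus, ref, n_perm = 10000L,
                               seed = NULL, exhaustive = FALSE) {
  obs <- delta_statistic(hit, labels, focus, ref)$delta
  nf <- sum(labels == focus); nr <- sum(labels == ref)
  delta_of <- function(lab) {
    100 * sum(hit[lab == focus]) / nf - 100 * sum(hit[lab == ref]) / nr
  }
  if (exhaustive) {
    check_that(length(labels) <= 12L,
               "exhaustive enumeration limited to 12 units, got %d", length(labels))
    assigns <- enumerate_label_assignments(labels)
    deltas <- vapply(assigns, delta_of, 0)
    list(delta = obs, p_emp = mean(deltas > obs),
         p_emp_inclusive = mean(deltas >= obs - 1e-9),
         n_replicates = length(deltas), method = "exhaustive")
  } else {
    check_that(n_perm >= 1L, "n_perm must be at least 1")
    if (!is.null(seed)) set.seed(seed)
    exceed <- 0L; ge <- 0L
    for (b in seq_len(n_perm)) {
      dp <- delta_of(sample(labels))
      if (dp > obs) exceed <- exceed + 1L
      if (dp >= obs - 1e-9) ge <- ge + 1L
    }
    list(delta = obs, p_emp = exceed / n_perm, p_emp_inclusive = ge / n_perm,
         n_replicates = n_perm, method = "monte carlo")
  }
}

## All distinct assignments of the multiset of labels to positions.
enumerate_label_assignments <- function(labels) {
  classes <- sort(unique(labels))
  counts <- as.integer(table(factor(labels, levels = classes)))
  n <- length(labels)
  recurse <- function(open, ci) {
    if (ci == length(classes)) {
      lab <- rep(classes[ci], n)
      return(list(list(pos = open, lab = lab)))
    }
    k <- counts[ci]
    picks <- if (k == 0L) list(integer(0)) else
      asplit(utils::combn(open, k), 2L)
    out <- list()
    for (p in picks) {
      p <- as.integer(p)
      for (sub in recurse(setdiff(open, p), ci + 1L)) {
        sub$lab[p] <- classes[ci]
        out[[length(out) + 1L]] <- sub
      }
    }
    out
  }
  lapply(recurse(seq_len(n), 1L), `[[`, "lab")
}

#' Screen all factors for class-enrichment of hits
#'
#' For every factor and every class comparison (by default UHP vs type-0,
#' DHP vs type-0, and UHP vs DHP where the classes are populated), computes
#' the observed delta, a label-permutation empirical p-value, and a
#' Bonferroni correction over all tests actually performed. Tests whose
#' observed effect is below the reporting floor (absolute delta under 0.5
#' percentage points, or relative difference under 5 percent of the larger
#' proportion) are flagged `excluded`, not dropped.
#'
#' @param hits Binary matrix, units x factors, with unit row names and
#'   factor column names.
#' @param labels Named class-label vector (names = unit ids) or unnamed
#'   vector aligned with `hits` rows.
#' @param comparisons List of `c(focus, ref)` pairs.
#' @param n_perm Permutations per test.
#' @param seed Integer seed; one permutation stream is drawn per comparison
#'   so results are reproducible given `(seed, n_perm)`.
#' @param min_abs_delta,min_rel_delta Exclusion floor (percentage points,
#'   fraction).
#' @return A `data.table`: `factor_id`, `focus`, `ref`, `prop_focus`,
#'   `prop_ref`, `delta`, `p_emp`, `p_bonf`, `excluded`.
#' @export
motif_screen <- function(hits, labels,
                         comparisons = list(c("UHP_GENE", "TYPE0_GENE"),
                                            c("DHP_GENE", "TYPE0_GENE"),
                                            c("UHP_GENE", "DHP_GENE")),
                         n_perm = 10000L, seed = 1L,
                         min_abs_delta = 0.5, min_rel_delta = 0.05) {
  hits <- as.matrix(hits)
  if (!is.null(names(labels)) && !is.null(rownames(hits)))
    labels <- labels[rownames(hits)]
  labels <- unname(labels)
  check_that(length(labels) == nrow(hits), "labels must cover every hit-matrix row")
  comparisons <- Filter(function(cc) sum(labels == cc[1]) > 0 &&
                          sum(labels == cc[2]) > 0, comparisons)
  set.seed(seed)
  res <- list()
  for (cc in comparisons) {
    focus <- cc[1]; ref <- cc[2]
    nf <- sum(labels == focus); nr <- sum(labels == ref)
    pf <- 100 * colSums(hits[labels == focus, , drop = FALSE]) / nf
    pr <- 100 * colSums(hits[labels == ref, , drop = FALSE]) / nr
    obs <- pf - pr
    exceed <- integer(ncol(hits))
    for (b in seq_len(n_perm)) {
      lab <- sample(labels)
      dp <- 100 * colSums(hits[lab == focus, , drop = FALSE]) / nf -
        100 * colSums(hits[lab == ref, , drop = FALSE]) / nr
      exceed <- exceed + (dp > obs)
    }
    rel <- ifelse(pmax(pf, pr) > 0, abs(obs) / pmax(pf, pr), 0)
    res[[length(res) + 1L]] <- data.table(
      factor_id = colnames(hits), focus = focus, ref = ref,
      prop_focus = unname(pf), prop_ref = unname(pr), delta = unname(obs),
      p_emp = unname(exceed / n_perm),
      excluded = abs(unname(obs)) < min_abs_delta | unname(rel) < min_rel_delta
    )
  }
  out <- rbindlist(res)
  out[, p_bonf := pmin(1, p_emp * .N)]
  out[]
}

#' Isoform-level GO over-representation of UHP isoforms
#'
#' Hypergeometric upper-tail test per GO term: the population is all classed
#' isoforms (UHP, DHP or type-0), successes are the UHP isoforms, and each
#' term draws its annotated classed isoforms. Terms with fewer than 5 UHP
#' isoforms annotated are skipped; Bonferroni correction runs over the
#' tested terms. Coverage is the proportion of a term's classed isoforms
#' that are UHP.
#'
#' @param annotations `data.frame` with columns `isoform_id`, `go_id`.
#' @param isoform_classes Named vector isoform_id -> class (`"UHP"`,
#'   `"DHP"`, `"TYPE0"`).
#' @param focus Class tested for over-representation, default `"UHP"`.
#' @param min_focus Minimum focus-class isoforms per term (default 5).
#' @return A `data.table` sorted by p: `go_id`, `n_term`, `k_uhp`,
#'   `coverage`, `p`, `adj_p`.
#' @export
go_hypergeometric <- function(annotations, isoform_classes, focus = "UHP",
                              min_focus = 5L) {
  ann <- as.data.table(annotations)
  setnames(ann, 1:2, c("isoform_id", "go_id"))
  check_that(length(isoform_classes) >= 1L, "need at least one classed isoform")
  unclassed <- setdiff(unique(ann$isoform_id), names(isoform_classes))
  if (length(unclassed) > 0L) {
    message(sprintf("go_hypergeometric: %d annotated isoform(s) without class ignored",
                    length(unclassed)))
    ann <- ann[isoform_id %in% names(isoform_classes)]
  }
  N <- length(isoform_classes)
  K <- sum(isoform_classes == focus)
  ann <- unique(ann)
  per_term <- ann[, .(
    n_term = .N,
    k_uhp = sum(isoform_classes[isoform_id] == focus)
  ), by = go_id]
  tested <- per_term[k_uhp >= min_focus]
  if (nrow(tested) == 0L)
    return(data.table(go_id = character(), n_term = integer(),
                      k_uhp = integer(), coverage = numeric(),
                      p = numeric(), adj_p = numeric()))
  tested[, coverage := k_uhp / n_term]
  tested[, p := phyper(k_uhp - 1L, K, N - K, n_term, lower.tail = FALSE)]
  tested[, adj_p := pmin(1, p * .N)]
  setorder(tested, p)
  tested[]
}

#' Pearson correlation between event psi and a marker gene's expression
#'
#' Per event, the correlation is computed over samples where psi is defined
#' and the marker value is present; events with fewer than 3 usable pairs or
#' a constant psi or marker are flagged undefined.
#'
#' @param psi_mat Events x samples matrix of psi values (NA = undefined).
#' @param marker Per-sample marker expression (same column order).
#' @return A `data.table`: `event_id`, `n`, `r`, `defined`.
#' @export
psi_marker_correlation <- function(psi_mat, marker) {
  check_that(ncol(psi_mat) == length(marker),
             "marker length must equal the sample count")
  res <- lapply(seq_len(nrow(psi_mat)), function(i) {
    ok <- !is.na(psi_mat[i, ]) & !is.na(marker)
    x <- psi_mat[i, ok]; y <- marker[ok]
    if (sum(ok) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
      data.table(event_id = rownames(psi_mat)[i], n = sum(ok), r = NA_real_,
                 defined = FALSE)
    else
      data.table(event_id = rownames(psi_mat)[i], n = sum(ok), r = cor(x, y),
                 defined = TRUE)
  })
  rbindlist(res)
}

#' Read a hit-matrix TSV
#'
#' Expected layout: `unit_id`, `label`, then one 0/1 column per factor.
#'
#' @param file Path to the TSV.
#' @return A list: `hits` (binary matrix with unit row names), `labels`
#'   (named vector).
#' @export
read_hits_tsv <- function(file) {
  dt <- fread(file, sep = "\t", header = TRUE)
  check_that(ncol(dt) >= 3L, "hit matrix needs unit_id, label and >= 1 factor column")
  hits <- as.matrix(dt[, -(1:2)])
  check_that(all(hits %in% c(0, 1)), "hit matrix entries must be 0/1")
  rownames(hits) <- dt[[1]]
  list(hits = hits, labels = setNames(dt[[2]], dt[[1]]))
}

#' Write a hit matrix and labels as TSV
#'
#' @param hits Binary matrix, units x factors.
#' @param labels Named label vector.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_hits_tsv <- function(hits, labels, file) {
  dt <- data.table(unit_id = rownames(hits),
                   label = unname(labels[rownames(hits)]))
  dt <- cbind(dt, as.data.table(hits))
  fwrite(dt, file, sep = "\t")
  invisible(file)
}
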