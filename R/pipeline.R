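## End-to-end per-group orchestration and summary aggregation.

#' Run the full analysis for one sample group
#'
#' Executes event discovery, collapsing, quantification and classification
#' for the samples of one group: cassette events are found in the gene
#' models, equivalent events are collapsed, per-sample psi is computed from
#' the expression matrix, and events are classified UHP/DHP/TYPE0/
#' INDETERMINATE. The classified table is augmented with annotation-derived
#' characterization columns (representative exon length, flanking-intron
#' lengths, transcripts per gene, inclusion proportion, inclusion-transcript
#' biotypes). A failing event is logged and skipped, never aborts the run.
#'
#' @param models Transcript models from [parse_gtf()].
#' @param mat Expression matrix from [read_gct()].
#' @param group Group label; when `sample_groups` is given, only its samples
#'   are used.
#' @param sample_groups Optional named vector sample_id -> group label.
#' @param thresholds See [default_thresholds()].
#' @param events Optional precomputed collapsed event table (skips
#'   rediscovery).
#' @return A list: `classified` (event table with labels and
#'   characterization columns), `events`, `summary` (named counts: analyzed,
#'   per-label totals).
#' @export
run_group_analysis <- function(models, mat, group = "group1",
                               sample_groups = NULL,
                               thresholds = default_thresholds(),
                               events = NULL) {
  if (!is.null(sample_groups)) {
    keep <- intersect(colnames(mat), names(sample_groups)[sample_groups == group])
    check_that(length(keep) > 0L, "group %s has no samples in the matrix", group)
    mat <- mat[, keep, drop = FALSE]
  }
  if (is.null(events))
    events <- collapse_equivalent_events(find_cassette_events(models))
  quants <- list()
  for (i in seq_len(nrow(events))) {
    q <- tryCatch(event_psi(mat, events[i]), error = function(e) {
      message(sprintf("run_group_analysis: skipping event %s (%s)",
                      events$event_id[i], conditionMessage(e)))
      NULL
    })
    if (!is.null(q)) quants[[q$event_id]] <- q
  }
  classified <- classify_events(quants, group = group, thresholds = thresholds)
  classified <- merge(classified, characterize_events(events, models),
                      by = "event_id", sort = FALSE)
  counts <- c(
    n_events = nrow(events), n_quantified = length(quants),
    n_analyzed = sum(classified$analyzed),
    n_uhp = sum(classified$label == "UHP"),
    n_dhp = sum(classified$label == "DHP"),
    n_type0 = sum(classified$label == "TYPE0"),
    n_indeterminate = sum(classified$label == "INDETERMINATE"))
  list(classified = classified, events = events, summary = counts)
}

## Annotation-derived per-event characterization columns.
characterize_events <- function(events, models) {
  fl <- flanking_intron_lengths(events, models)
  tx_per_gene <- models[, .(transcripts_per_gene = uniqueN(transcript_id)),
                        by = gene_id]
  bt <- models[, .(biotype = biotype[1]), by = transcript_id]
  out <- events[, .(
    event_id,
    exon_length = end - start,
    inclusion_proportion = lengths(inclusion) /
      (lengths(inclusion) + lengths(exclusion)),
    inclusion_biotypes = vapply(inclusion, function(tx)
      paste(sort(bt[match(tx, transcript_id), biotype]), collapse = ","), "")
  )]
  out <- merge(out, fl, by = "event_id", sort = FALSE)
  gene_of <- events[, .(event_id, gene_id)]
  out <- merge(out, merge(gene_of, tx_per_gene, by = "gene_id")[, .(event_id, transcripts_per_gene)],
               by = "event_id", sort = FALSE)
  out
}

#' Aggregate per-group results into a run summary
#'
#' Computes the cross-group accounting: per-group class counts, the total
#' number of UHP/DHP identifications (with multiplicity across groups), the
#' unique coupled exons and their percentage of analyzed exons, genes with
#' at least one coupled exon and their percentage of classed genes, plus a
#' per-class characterization table (medians of exon length, flanking-intron
#' lengths, transcripts per gene and inclusion proportion, with rank-sum
#' p-values between classes) and per-class biotype fractions. Percentages
#' are one-decimal, rounded half away from zero, and always recompute
#' exactly from their component counts.
#'
#' Alternatively, pass precomputed `counts` (named list with
#' `coupled_exons`, `analyzed_exons`, `coupled_genes`, `classed_genes`) to
#' obtain just the percentage block from externally tabulated numbers.
#'
#' @param results List of [run_group_analysis()] outputs (or of classified
#'   tables).
#' @param counts Optional precomputed counts (see above).
#' @return A list of summary components; see details.
#' @export
aggregate_summary <- function(results = NULL, counts = NULL) {
  if (!is.null(counts)) {
    return(list(
      n_unique_coupled = counts$coupled_exons,
      n_analyzed = counts$analyzed_exons,
      coupled_exon_pct = prevalence_percent(counts$coupled_exons,
                                            counts$analyzed_exons),
      n_coupled_genes = counts$coupled_genes,
      n_classed_genes = counts$classed_genes,
      coupled_gene_pct = prevalence_percent(counts$coupled_genes,
                                            counts$classed_genes)))
  }
  check_that(length(results) >= 1L, "need at least one group result")
  tabs <- lapply(results, function(r) if (is.data.frame(r)) r else r$classified)
  pooled <- rbindlist(tabs, fill = TRUE)
  per_group <- pooled[, .(
    n_analyzed = sum(analyzed), n_uhp = sum(label == "UHP"),
    n_dhp = sum(label == "DHP"), n_type0 = sum(label == "TYPE0"),
    n_indeterminate = sum(label == "INDETERMINATE")), by = group]
  coupled <- pooled[label %in% c("UHP", "DHP")]
  n_identifications <- nrow(coupled)
  n_unique_coupled <- uniqueN(coupled$event_id)
  n_analyzed <- uniqueN(pooled[analyzed == TRUE, event_id])
  classed_genes <- unique(pooled[label %in% c("UHP", "DHP", "TYPE0"), gene_id])
  coupled_genes <- unique(coupled$gene_id)

  ## consensus class per unique event for the characterization table
  consensus <- pooled[label %in% c("UHP", "DHP", "TYPE0"), .(
    class = {
      u <- any(label == "UHP"); d <- any(label == "DHP")
      if (u && d) NA_character_
      else if (u) "UHP" else if (d) "DHP" else "TYPE0"
    }), by = event_id]
  consensus <- consensus[!is.na(class)]
  char_cols <- c("exon_length", "upstream_length", "downstream_length",
                 "transcripts_per_gene", "inclusion_proportion")
  first_rows <- pooled[!duplicated(event_id)]
  char <- merge(consensus, first_rows, by = "event_id")
  characterization <- char[, c(list(n = .N),
    lapply(.SD, function(v) median(as.numeric(v), na.rm = TRUE))),
    by = class, .SDcols = char_cols]
  pairs <- list(c("TYPE0", "UHP"), c("TYPE0", "DHP"), c("UHP", "DHP"))
  tests <- rbindlist(lapply(char_cols, function(fc) {
    rbindlist(lapply(pairs, function(pp) {
      x <- char[class == pp[1]][[fc]]; y <- char[class == pp[2]][[fc]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      p <- if (length(x) >= 1L && length(y) >= 1L)
        rank_sum_test(x, y)$p.value else NA_real_
      data.table(feature = fc, class_a = pp[1], class_b = pp[2], p = p)
    }))
  }))
  biotypes <- char[, .(biotype = unlist(strsplit(inclusion_biotypes, ","))),
                   by = class][, .(n = .N), by = .(class, biotype)]
  biotypes[, fraction := n / sum(n), by = class]

  list(per_group = per_group,
       n_identifications = n_identifications,
       n_unique_coupled = n_unique_coupled,
       n_analyzed = n_analyzed,
       coupled_exon_pct = prevalence_percent(n_unique_coupled, max(n_analyzed, 1L)),
       n_coupled_genes = length(coupled_genes),
       n_classed_genes = length(classed_genes),
       coupled_gene_pct = prevalence_percent(length(coupled_genes),
                                             max(length(classed_genes), 1L)),
       characterization = characterization,
       characterization_tests = tests,
       biotype_fractions = biotypes)
}
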