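## Seeded synthetic fixtures with planted structure: annotation, expression,
## occupancy tracks, hit matrices, and GO annotations. Every generator is a
## pure function of (config, seed), so emitted files are byte-identical
## across runs.

#' Simulation configuration
#'
#' Defines the study conditions emulated by the generators: a GTEx-like
#' transcripts x samples expression matrix in which each gene carries one
#' cassette-exon event whose inclusion level is positively (UHP), negatively
#' (DHP) or not at all (TYPE0) coupled to total gene expression.
#'
#' @param n_genes Number of genes (one planted cassette event each).
#' @param transcripts_per_gene Integer range `c(min, max)`, min >= 2; one
#'   transcript skips the cassette exon, the rest include it.
#' @param exons_per_transcript Integer range, min >= 3 (an internal exon must
#'   exist).
#' @param n_samples Samples per group.
#' @param n_groups Number of sample groups (tissues).
#' @param class_proportions Named proportions over UHP, DHP, TYPE0; must sum
#'   to 1.
#' @param effect_b Planted slope multiplier b: coupled events have expected
#'   expression `mu_g * (1 + b * psi)` (UHP) or `mu_g * (1 + b * (1 - psi))`
#'   (DHP), so the planted regression slope is `+/- mu_g * b`.
#' @param noise_sd Standard deviation of the multiplicative noise, as a
#'   fraction of the mean (truncated at -0.9 to keep values non-negative).
#' @param base_expr_log_mean,base_expr_log_sd Log-normal parameters of the
#'   per-gene baseline expression mu_g, in TPM-like units.
#' @param seed Integer seed governing every random draw.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 200L, transcripts_per_gene = c(2L, 3L),
                       exons_per_transcript = c(4L, 6L), n_samples = 400L,
                       n_groups = 1L,
                       class_proportions = c(UHP = 0.3, DHP = 0.3, TYPE0 = 0.4),
                       effect_b = 1, noise_sd = 0.1,
                       base_expr_log_mean = log(200), base_expr_log_sd = 0.6,
                       seed = 1L) {
  check_that(n_genes >= 1L && n_samples >= 1L && n_groups >= 1L,
             "counts must be positive")
  check_that(min(exons_per_transcript) >= 3L,
             "exons_per_transcript must be at least 3: no internal exon otherwise")
  check_that(min(transcripts_per_gene) >= 2L,
             "transcripts_per_gene must be at least 2")
  check_that(abs(sum(class_proportions) - 1) < 1e-9 &&
               all(c("UHP", "DHP", "TYPE0") %in% names(class_proportions)),
             "class_proportions must be named UHP/DHP/TYPE0 and sum to 1")
  structure(list(
    n_genes = as.integer(n_genes),
    transcripts_per_gene = as.integer(transcripts_per_gene),
    exons_per_transcript = as.integer(exons_per_transcript),
    n_samples = as.integer(n_samples), n_groups = as.integer(n_groups),
    class_proportions = class_proportions, effect_b = effect_b,
    noise_sd = noise_sd, base_expr_log_mean = base_expr_log_mean,
    base_expr_log_sd = base_expr_log_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

sample_range <- function(rng, n = 1L) {
  vals <- seq(min(rng), max(rng))
  vals[sample.int(length(vals), n, replace = TRUE)]
}

#' Simulate a multi-transcript gene annotation with planted cassette events
#'
#' Each gene gets one "full" transcript structure and one skip transcript
#' lacking a randomly chosen internal exon, so exactly one cassette event is
#' planted per gene; extra transcripts (up to the configured range) repeat
#' the full structure, which keeps the planted event set identical to the
#' discoverable event set under exact-coordinate cassette semantics. Gene
#' loci do not overlap. Transcript biotypes are planted tags drawn from the
#' common GENCODE categories.
#'
#' @param cfg A [sim_config()].
#' @return A list: `models` (exon table in [parse_gtf()] schema), `truth`
#'   (`data.table`: `event_id`, `gene_id`, `class`, `chrom`, `start`, `end`,
#'   `n_inclusion`, `skip_transcript`), `gtf` (character lines).
#' @export
simulate_annotation <- function(cfg) {
  set.seed(cfg$seed)
  cursor <- 10000L
  models <- vector("list", cfg$n_genes)
  truth <- vector("list", cfg$n_genes)
  biotypes <- c("protein_coding", "retained_intron", "lncRNA",
                "nonsense_mediated_decay")
  bt_prob <- c(0.6, 0.2, 0.1, 0.1)
  for (i in seq_len(cfg$n_genes)) {
    gene <- sprintf("GENE%04d", i)
    chrom <- "chrS"
    strand <- c("+", "-")[sample.int(2L, 1L)]
    n_exon <- sample_range(cfg$exons_per_transcript)
    exon_len <- sample_range(c(80L, 300L), n_exon)
    intron_len <- pmax(100L, as.integer(round(rlnorm(n_exon - 1L, log(600), 0.5))))
    starts <- cursor + cumsum(c(0L, exon_len[-n_exon] + intron_len))
    ends <- starts + exon_len
    cursor <- ends[n_exon] + 10000L
    internal <- 2:(n_exon - 1L)
    skip <- internal[sample.int(length(internal), 1L)]
    n_tx <- sample_range(cfg$transcripts_per_gene)
    cls <- names(cfg$class_proportions)[
      sample.int(3L, 1L, prob = cfg$class_proportions)]
    tx_ids <- sprintf("%s_T%d", gene, seq_len(n_tx))
    bts <- biotypes[sample.int(4L, n_tx, replace = TRUE, prob = bt_prob)]
    rows <- lapply(seq_len(n_tx), function(k) {
      idx <- if (k == n_tx) setdiff(seq_len(n_exon), skip) else seq_len(n_exon)
      data.table(transcript_id = tx_ids[k], gene_id = gene, chrom = chrom,
                 strand = strand, start = starts[idx], end = ends[idx],
                 biotype = bts[k])
    })
    models[[i]] <- rbindlist(rows)
    truth[[i]] <- data.table(
      event_id = sprintf("%s:%s:%d-%d", gene, chrom, starts[skip], ends[skip]),
      gene_id = gene, class = cls, chrom = chrom,
      start = starts[skip], end = ends[skip],
      n_inclusion = n_tx - 1L, skip_transcript = tx_ids[n_tx])
  }
  models <- rbindlist(models)
  setorder(models, gene_id, transcript_id, start, end)
  list(models = models, truth = rbindlist(truth), gtf = write_gtf(models))
}

#' Simulate transcript expression with planted expression-psi coupling
#'
#' Per sample and event, psi is drawn Uniform(0.1, 0.9); the gene's total
#' expression is `mu_g * (1 + b * psi)` for planted UHP events,
#' `mu_g * (1 + b * (1 - psi))` for DHP, and `mu_g` for TYPE0, each times a
#' multiplicative noise term `(1 + eps)` with `eps ~ Normal(0, noise_sd)`
#' truncated at -0.9. Inclusion transcripts share `Y * psi` equally and the
#' skip transcript carries `Y * (1 - psi)`, so the event's quantified psi
#' reproduces the drawn psi exactly and the planted regression slope is
#' `+/- mu_g * b`.
#'
#' @param cfg A [sim_config()].
#' @param ann Output of [simulate_annotation()].
#' @return A list: `mat` (transcripts x samples matrix), `sample_groups`
#'   (named vector sample -> group), `truth` (annotation truth plus `mu_g`
#'   and `planted_beta1`), `psi_true` (events x samples matrix).
#' @export
simulate_expression <- function(cfg, ann) {
  set.seed(cfg$seed + 1L)
  truth <- copy(ann$truth)
  n_ev <- nrow(truth)
  truth[, mu_g := rlnorm(n_ev, cfg$base_expr_log_mean, cfg$base_expr_log_sd)]
  truth[, planted_beta1 := fifelse(class == "UHP", cfg$effect_b * mu_g,
                            fifelse(class == "DHP", -cfg$effect_b * mu_g, 0))]
  samples <- as.vector(vapply(seq_len(cfg$n_groups), function(g)
    sprintf("g%d_s%04d", g, seq_len(cfg$n_samples)), character(cfg$n_samples)))
  groups <- setNames(rep(sprintf("g%d", seq_len(cfg$n_groups)),
                         each = cfg$n_samples), samples)
  S <- length(samples)
  psi <- matrix(runif(n_ev * S, 0.1, 0.9), nrow = n_ev,
                dimnames = list(truth$event_id, samples))
  eps <- matrix(pmax(rnorm(n_ev * S, 0, cfg$noise_sd), -0.9), nrow = n_ev)
  b <- cfg$effect_b
  coupling <- matrix(1, nrow = n_ev, ncol = S)
  is_uhp <- truth$class == "UHP"; is_dhp <- truth$class == "DHP"
  coupling[is_uhp, ] <- 1 + b * psi[is_uhp, , drop = FALSE]
  coupling[is_dhp, ] <- 1 + b * (1 - psi[is_dhp, , drop = FALSE])
  Y <- truth$mu_g * coupling * (1 + eps)

  tx_of_gene <- split(unique(ann$models$transcript_id),
                      sub("_T\\d+$", "", unique(ann$models$transcript_id)))
  rows <- vector("list", n_ev)
  for (i in seq_len(n_ev)) {
    txs <- tx_of_gene[[truth$gene_id[i]]]
    skip_tx <- truth$skip_transcript[i]
    inc_tx <- setdiff(txs, skip_tx)
    per_inc <- Y[i, ] * psi[i, ] / length(inc_tx)
    m <- rbind(matrix(rep(per_inc, length(inc_tx)), nrow = length(inc_tx),
                      byrow = TRUE),
               Y[i, ] * (1 - psi[i, ]))
    rownames(m) <- c(inc_tx, skip_tx)
    rows[[i]] <- m
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- samples
  list(mat = mat, sample_groups = groups, truth = truth, psi_true = psi)
}

#' Classified-exon table for occupancy simulations
#'
#' Pairs each gene's planted cassette exon (carrying its planted class) with
#' a second internal, constitutive exon of the same gene labeled TYPE0, so
#' per-gene focus-vs-type-0 occupancy ratios are defined. Genes without a
#' spare internal exon are dropped.
#'
#' @param ann Output of [simulate_annotation()].
#' @return A `data.table`: `gene_id`, `chrom`, `start`, `end`, `label`.
#' @export
occupancy_exon_table <- function(ann) {
  full <- ann$models[!duplicated(paste(gene_id, start, end))]
  rows <- lapply(seq_len(nrow(ann$truth)), function(i) {
    tr <- ann$truth[i]
    ex <- full[gene_id == tr$gene_id]
    setorder(ex, start)
    if (nrow(ex) < 3L) return(NULL)
    internal <- ex[2:(nrow(ex) - 1L)]
    spare <- internal[!(start == tr$start & end == tr$end)]
    if (nrow(spare) == 0L) return(NULL)
    rbind(
      data.table(gene_id = tr$gene_id, chrom = tr$chrom, start = tr$start,
                 end = tr$end, label = tr$class),
      data.table(gene_id = tr$gene_id, chrom = spare$chrom[1],
                 start = spare$start[1], end = spare$end[1], label = "TYPE0"))
  })
  rbindlist(rows)
}

#' Simulate ChIP peak tracks and nascent-read tracks with planted rates
#'
#' Peak counts per exon are Poisson with a per-bp rate scaled by a
#' class-specific ratio (defaults follow the occupancy pattern the package
#' is designed to detect: fewer peaks on coupled exons than on type-0
#' exons). Read counts per downstream intron are Poisson with class-specific
#' per-bp rates (coupled classes denser). Peaks are placed to overlap their
#' exon by at least one bp; reads fall inside their intron.
#'
#' @param exon_classes Table from [occupancy_exon_table()] (or equivalent).
#' @param introns Optional downstream-intron table (`event_id`, `gene_id`,
#'   `label`, `chrom`, `start`, `end`); when `NULL` no read track is
#'   generated.
#' @param seed Integer seed.
#' @param n_tracks Number of peak tracks (ChIP experiments).
#' @param peak_rate Baseline peaks per bp per track for TYPE0 exons.
#' @param peak_ratios Named class multipliers for the peak rate.
#' @param peak_width Peak width in bp.
#' @param read_rate Baseline reads per bp for TYPE0 downstream introns.
#' @param read_ratios Named class multipliers for the read rate.
#' @param read_width Read width in bp.
#' @return A list: `peaks` (list of interval tables) and `reads` (interval
#'   table or NULL).
#' @export
simulate_occupancy <- function(exon_classes, introns = NULL, seed = 1L,
                               n_tracks = 5L, peak_rate = 0.02,
                               peak_ratios = c(UHP = 0.86, DHP = 0.31, TYPE0 = 1),
                               peak_width = 150L, read_rate = 0.05,
                               read_ratios = c(UHP = 2, DHP = 1.5, TYPE0 = 1),
                               read_width = 50L) {
  set.seed(seed)
  ex <- as.data.table(exon_classes)
  peaks <- lapply(seq_len(n_tracks), function(t) {
    lam <- peak_rate * (ex$end - ex$start) * peak_ratios[ex$label]
    k <- rpois(nrow(ex), lam)
    idx <- rep(seq_len(nrow(ex)), k)
    if (length(idx) == 0L)
      return(data.table(chrom = character(), start = integer(), end = integer()))
    lo <- pmax(0L, ex$start[idx] - peak_width + 1L)
    hi <- ex$end[idx] - 1L
    ps <- lo + floor(runif(length(idx)) * (hi - lo + 1L))
    out <- data.table(chrom = ex$chrom[idx], start = as.integer(ps),
                      end = as.integer(ps + peak_width))
    setorder(out, chrom, start, end)
    out
  })
  reads <- NULL
  if (!is.null(introns)) {
    intr <- as.data.table(introns)
    lam <- read_rate * (intr$end - intr$start) * read_ratios[intr$label]
    k <- rpois(nrow(intr), lam)
    idx <- rep(seq_len(nrow(intr)), k)
    if (length(idx) > 0L) {
      w <- pmin(read_width, intr$end[idx] - intr$start[idx])
      lo <- intr$start[idx]
      hi <- intr$end[idx] - w
      rs <- lo + floor(runif(length(idx)) * (hi - lo + 1L))
      reads <- data.table(chrom = intr$chrom[idx], start = as.integer(rs),
                          end = as.integer(rs + w))
      setorder(reads, chrom, start, end)
    } else {
      reads <- data.table(chrom = character(), start = integer(), end = integer())
    }
  }
  list(peaks = peaks, reads = reads)
}

#' Simulate a binary hit matrix with planted proportion differences
#'
#' Each factor's hits are Bernoulli with a class-specific probability: the
#' first `n_planted` factors have their hit probability raised by
#' `planted_delta` percentage points in `planted_class` units; the rest are
#' null (same probability in every class).
#'
#' @param labels Named gene-class vector (`UHP_GENE`/`DHP_GENE`/
#'   `TYPE0_GENE`).
#' @param seed Integer seed.
#' @param n_factors Number of factors (columns).
#' @param base_prob Baseline hit probability.
#' @param planted_delta Planted difference in percentage points.
#' @param n_planted Number of planted factors.
#' @param planted_class Class receiving the raised probability.
#' @return A list: `hits` (binary matrix), `truth` (`data.table`:
#'   `factor_id`, `planted_delta`).
#' @export
simulate_hits <- function(labels, seed = 1L, n_factors = 20L, base_prob = 0.2,
                          planted_delta = 15, n_planted = 3L,
                          planted_class = "UHP_GENE") {
  set.seed(seed)
  n <- length(labels)
  factor_ids <- sprintf("FACTOR%03d", seq_len(n_factors))
  hits <- matrix(0L, nrow = n, ncol = n_factors,
                 dimnames = list(names(labels), factor_ids))
  for (j in seq_len(n_factors)) {
    pr <- rep(base_prob, n)
    if (j <= n_planted) pr[labels == planted_class] <- base_prob + planted_delta / 100
    hits[, j] <- rbinom(n, 1L, pr)
  }
  truth <- data.table(factor_id = factor_ids,
                      planted_delta = c(rep(planted_delta, n_planted),
                                        rep(0, n_factors - n_planted)))
  list(hits = hits, truth = truth)
}

#' Simulate isoform GO annotations with planted over-representation
#'
#' Null terms draw their members uniformly from all classed isoforms;
#' planted terms draw a `planted_coverage` fraction of their members from
#' the focus-class isoforms.
#'
#' @param isoform_classes Named vector isoform -> class (`UHP`, `DHP`,
#'   `TYPE0`).
#' @param seed Integer seed.
#' @param n_terms Total number of GO terms.
#' @param n_planted Number of planted terms (the first ones).
#' @param planted_coverage Fraction of planted-term members from the focus
#'   class.
#' @param term_size Range of term sizes.
#' @param focus Focus class, default `"UHP"`.
#' @return A list: `annotations` (`isoform_id`, `go_id`), `truth`
#'   (`go_id`, `planted`).
#' @export
simulate_go <- function(isoform_classes, seed = 1L, n_terms = 30L,
                        n_planted = 2L, planted_coverage = 0.8,
                        term_size = c(15L, 40L), focus = "UHP") {
  set.seed(seed)
  isoforms <- names(isoform_classes)
  focus_iso <- isoforms[isoform_classes == focus]
  other_iso <- isoforms[isoform_classes != focus]
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  rows <- lapply(seq_len(n_terms), function(j) {
    size <- sample_range(term_size)
    members <- if (j <= n_planted) {
      k <- min(round(planted_coverage * size), length(focus_iso))
      m <- min(size - k, length(other_iso))
      c(focus_iso[sample.int(length(focus_iso), k)],
        if (m > 0) other_iso[sample.int(length(other_iso), m)])
    } else {
      isoforms[sample.int(length(isoforms), min(size, length(isoforms)))]
    }
    data.table(isoform_id = members, go_id = terms[j])
  })
  list(annotations = rbindlist(rows),
       truth = data.table(go_id = terms, planted = seq_len(n_terms) <= n_planted))
}

#' Simulate hit matrix and GO annotations together
#'
#' Convenience wrapper over [simulate_hits()] and [simulate_go()] using one
#' seed.
#'
#' @param gene_labels Named gene-class vector.
#' @param isoform_classes Named isoform-class vector.
#' @param seed Integer seed.
#' @param ... Passed on to the two generators.
#' @return A list with components `hits` and `go`.
#' @export
simulate_hits_and_go <- function(gene_labels, isoform_classes, seed = 1L, ...) {
  dots <- list(...)
  hit_args <- dots[names(dots) %in% names(formals(simulate_hits))]
  go_args <- dots[names(dots) %in% names(formals(simulate_go))]
  list(hits = do.call(simulate_hits, c(list(labels = gene_labels, seed = seed),
                                       hit_args)),
       go = do.call(simulate_go, c(list(isoform_classes = isoform_classes,
                                        seed = seed + 1L), go_args)))
}

#' Map classed events to isoform classes
#'
#' Inclusion transcripts of each UHP, DHP or type-0 event receive the
#' event's label (an isoform "contains a UHP exon" when it is in the
#' inclusion set of a UHP event); conflicts resolve UHP > DHP > TYPE0.
#'
#' @param events Event table (with `inclusion` list-column).
#' @param classified Output of [classify_events()].
#' @return Named vector isoform_id -> class.
#' @export
classify_isoforms <- function(events, classified) {
  merged <- merge(events[, .(event_id, inclusion)],
                  classified[label %in% c("UHP", "DHP", "TYPE0"),
                             .(event_id, label)], by = "event_id")
  out <- character(0)
  for (lab in c("TYPE0", "DHP", "UHP")) {   # increasing priority
    iso <- unique(unlist(merged[label == lab, inclusion]))
    out[iso] <- lab
  }
  out
}

#' Write a complete synthetic study to disk
#'
#' Emits `annotation.gtf`, `expression.gct`, `peaks/peak_<k>.bed`,
#' `reads.bed`, `hits.tsv`, `go.tsv` and `truth.tsv` under `out_dir`, all
#' derived deterministically from the configuration's seed.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_study <- function(cfg, out_dir) {
  dir.create(file.path(out_dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  ann <- simulate_annotation(cfg)
  expr <- simulate_expression(cfg, ann)
  exon_classes <- occupancy_exon_table(ann)
  events <- collapse_equivalent_events(find_cassette_events(ann$models))
  introns <- downstream_intron_coords(events, ann$models,
                                      setNames(ann$truth$class, ann$truth$event_id))
  occ <- simulate_occupancy(exon_classes, introns, seed = cfg$seed + 2L)
  gene_labels <- setNames(paste0(ann$truth$class, "_GENE"), ann$truth$gene_id)
  iso_classes <- setNames(
    ann$truth$class[match(sub("_T\\d+$", "", unique(ann$models$transcript_id)),
                          ann$truth$gene_id)],
    unique(ann$models$transcript_id))
  hg <- simulate_hits_and_go(gene_labels, iso_classes, seed = cfg$seed + 3L)

  writeLines(ann$gtf, file.path(out_dir, "annotation.gtf"))
  write_gct(expr$mat, file.path(out_dir, "expression.gct"))
  for (k in seq_along(occ$peaks))
    write_bed(occ$peaks[[k]], file.path(out_dir, "peaks", sprintf("peak_%02d.bed", k)))
  if (!is.null(occ$reads)) write_bed(occ$reads, file.path(out_dir, "reads.bed"))
  write_hits_tsv(hg$hits$hits, gene_labels, file.path(out_dir, "hits.tsv"))
  fwrite(hg$go$annotations, file.path(out_dir, "go.tsv"), sep = "\t")
  fwrite(expr$truth, file.path(out_dir, "truth.tsv"), sep = "\t")
  invisible(list(ann = ann, expr = expr, occ = occ, hits = hg$hits, go = hg$go,
                 exon_classes = exon_classes, introns = introns))
}
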