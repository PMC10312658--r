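## Interval arithmetic over exons/introns and BED feature tracks, plus the
## rank tests used on occupancy ratios. All intervals are 0-based half-open.

#' Read a BED3+ interval track
#'
#' Browser and track lines are skipped. Only the first three columns (chrom,
#' start, end) are required; name, score and strand are kept when present.
#'
#' @param file Path to a BED file (plain or gzip).
#' @return A `data.table` with columns `chrom`, `start`, `end` (0-based
#'   half-open) and any of `name`, `score`, `strand` present in the file.
#' @export
read_bed <- function(file) {
  lines <- readLines(if (grepl("\\.gz$", file)) gzfile(file) else file)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.table(chrom = character(), start = integer(), end = integer()))
  dt <- fread(text = lines, sep = "\t", header = FALSE, fill = TRUE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  setnames(dt, cols[seq_len(min(ncol(dt), 6L))])
  dt <- dt[, seq_len(min(ncol(dt), 6L)), with = FALSE]
  check_that(all(dt$end > dt$start), "BED interval with end <= start")
  dt
}

#' Write an interval table as BED
#'
#' @param intervals `data.table` with `chrom`, `start`, `end` and optional
#'   further BED columns.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(intervals, file) {
  fwrite(intervals, file, sep = "\t", col.names = FALSE)
  invisible(file)
}

#' Count overlapping features per target interval
#'
#' A feature overlaps a target iff the two share at least one base pair on
#' the same chromosome; strand is ignored and half-open abutment ([100,200)
#' vs [200,300)) does not count. These are the semantics of
#' `bedtools intersect` with default parameters.
#'
#' @param features Interval table (`chrom`, `start`, `end`).
#' @param targets Interval table.
#' @return Integer vector of feature counts, one per row of `targets`.
#' @export
count_overlaps <- function(features, targets) {
  out <- integer(nrow(targets))
  if (nrow(targets) == 0L || nrow(features) == 0L) return(out)
  for (ch in unique(targets$chrom)) {
    ti <- which(targets$chrom == ch)
    fi <- which(features$chrom == ch)
    if (length(fi) == 0L) next
    tr <- IRanges::IRanges(start = targets$start[ti] + 1L, end = targets$end[ti])
    fr <- IRanges::IRanges(start = features$start[fi] + 1L, end = features$end[fi])
    out[ti] <- IRanges::countOverlaps(tr, fr)
  }
  out
}

#' Per-gene peak-occupancy ratio between exon classes
#'
#' For each gene that has at least one type-0 exon and one exon of the focus
#' class, peak-to-exon overlap counts are summed over all experiments and
#' divided by the summed exon length of the class within the gene
#' ("bindings per base pair"); the ratio is focus-class density over type-0
#' density. Genes whose type-0 density is zero get an undefined ratio and
#' are flagged.
#'
#' @param peak_tracks A list of interval tables, one per ChIP experiment.
#' @param exon_classes `data.table` with `gene_id`, `chrom`, `start`, `end`,
#'   `label` (one row per classified exon; labels `"UHP"`, `"DHP"`,
#'   `"TYPE0"`).
#' @param focus_class `"UHP"` or `"DHP"`.
#' @param ref_class Reference class, default `"TYPE0"`.
#' @return A `data.table`: `gene_id`, `focus_class`, `per_bp_focus`,
#'   `per_bp_type0`, `ratio`, `excluded`.
#' @export
chip_ratio_per_gene <- function(peak_tracks, exon_classes,
                                focus_class = "UHP", ref_class = "TYPE0") {
  if (is.data.frame(peak_tracks)) peak_tracks <- list(peak_tracks)
  ex <- as.data.table(exon_classes)
  counts <- Reduce(`+`, lapply(peak_tracks, count_overlaps, targets = ex))
  ex[, n_peaks := counts]
  ex[, len := end - start]
  keep <- ex[label %in% c(focus_class, ref_class)]
  res <- keep[, {
    f <- label == focus_class
    r <- label == ref_class
    if (any(f) && any(r)) {
      pf <- sum(n_peaks[f]) / sum(len[f])
      pr <- sum(n_peaks[r]) / sum(len[r])
      .(per_bp_focus = pf, per_bp_type0 = pr,
        ratio = if (pr > 0) pf / pr else NA_real_, excluded = pr == 0)
    } else .(per_bp_focus = NA_real_, per_bp_type0 = NA_real_,
             ratio = NA_real_, excluded = NA)
  }, by = gene_id][!is.na(excluded)]
  res[, focus_class := focus_class]
  if (any(res$excluded))
    message(sprintf("chip_ratio_per_gene: %d gene(s) with zero %s density excluded",
                    sum(res$excluded), ref_class))
  setcolorder(res, c("gene_id", "focus_class"))
  res[]
}

#' Downstream-intron read density per event, normalized within gene
#'
#' Counts read intervals overlapping each event's downstream intron, divides
#' by intron length, then normalizes per gene by the sum over the gene's
#' scored events so that normalized densities sum to 1 within each gene.
#'
#' @param read_track Interval table of read alignments.
#' @param introns `data.table` with `event_id`, `gene_id`, `label`, `chrom`,
#'   `start`, `end` giving each event's downstream intron.
#' @return A `data.table`: `event_id`, `gene_id`, `label`, `reads_per_bp`,
#'   `normalized` (NA, flagged by message, for genes with zero total
#'   density).
#' @export
proseq_intron_density <- function(read_track, introns) {
  intr <- as.data.table(introns)
  check_that(all(intr$end > intr$start), "zero- or negative-length downstream intron")
  counts <- count_overlaps(read_track, intr)
  intr[, reads_per_bp := counts / (end - start)]
  intr[, gene_total := sum(reads_per_bp), by = gene_id]
  intr[, normalized := ifelse(gene_total > 0, reads_per_bp / gene_total, NA_real_)]
  if (anyNA(intr$normalized))
    message(sprintf("proseq_intron_density: %d gene(s) with zero read density",
                    uniqueN(intr[is.na(normalized), gene_id])))
  intr[, .(event_id, gene_id, label, reads_per_bp, normalized)]
}

#' Downstream-intron coordinates for classified events
#'
#' Picks, per event, the first inclusion transcript in lexicographic order
#' and returns the genomic gap just 3' (in transcription direction) of the
#' representative exon. Events whose exon is last in that transcript have no
#' downstream intron and are dropped.
#'
#' @param events Event table with `inclusion` list-column.
#' @param models Transcript models.
#' @param labels Optional named vector event_id -> class label to attach.
#' @return `data.table`: `event_id`, `gene_id`, `label`, `chrom`, `start`,
#'   `end`.
#' @export
downstream_intron_coords <- function(events, models, labels = NULL) {
  rows <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i]
    tx <- sort(ev$inclusion[[1]])[1]
    ex <- models[transcript_id == tx & chrom == ev$chrom]
    setorder(ex, start)
    j <- which(ex$start == ev$start & ex$end == ev$end)
    if (length(j) != 1L)
      stop(sprintf("event %s: representative exon not found in transcript %s",
                   ev$event_id, tx), call. = FALSE)
    if (ev$strand == "+") {
      if (j == nrow(ex)) return(NULL)
      data.table(event_id = ev$event_id, gene_id = ev$gene_id, chrom = ev$chrom,
                 start = ex$end[j], end = ex$start[j + 1L])
    } else {
      if (j == 1L) return(NULL)
      data.table(event_id = ev$event_id, gene_id = ev$gene_id, chrom = ev$chrom,
                 start = ex$end[j - 1L], end = ex$start[j])
    }
  })
  out <- rbindlist(rows)
  if (nrow(out) == 0L) return(out)
  out[, label := if (!is.null(labels)) unname(labels[event_id]) else NA_character_]
  setcolorder(out, c("event_id", "gene_id", "label", "chrom", "start", "end"))
  out[]
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney U test. When both groups have at most 20
#' observations the exact null distribution of the rank sum is computed by
#' dynamic-programming enumeration over subsets (midranks, so ties are
#' handled exactly); otherwise the normal approximation with tie-corrected
#' variance and continuity correction is used.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return A list: `U` (number of (x, y) pairs with x > y, counting ties as
#'   half), `p.value`, `method`.
#' @export
rank_sum_test <- function(x, y) {
  check_that(length(x) >= 1L && length(y) >= 1L, "both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2
  if (n1 <= 20L && n2 <= 20L) {
    s <- as.integer(round(2 * r))       # scaled midranks are integers
    total <- sum(s)
    ## f[j+1, t+1] = number of size-j subsets with scaled rank sum t
    f <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
    f[1, 1] <- 1
    for (si in s) {
      jmax <- n1
      f[2:(jmax + 1L), (si + 1L):(total + 1L)] <-
        f[2:(jmax + 1L), (si + 1L):(total + 1L)] +
        f[1:jmax, 1:(total - si + 1L)]
    }
    dist <- f[n1 + 1L, ]
    ncomb <- choose(n, n1)
    w2 <- as.integer(round(2 * w))
    p_le <- sum(dist[seq_len(w2 + 1L)]) / ncomb
    p_ge <- sum(dist[(w2 + 1L):(total + 1L)]) / ncomb
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nt <- table(c(x, y))
    sigma <- sqrt((n1 * n2 / 12) * ((n + 1) - sum(nt^3 - nt) / (n * (n - 1))))
    z <- u - mu
    z <- (z - sign(z) * 0.5) / sigma   # continuity correction
    p <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
    method <- "normal approximation with tie correction"
  }
  list(U = unname(u), p.value = p, method = method)
}

#' Wilcoxon signed-rank test of ratios against 1
#'
#' Tests whether a vector of positive ratios is centered at 1 by applying
#' the two-sided signed-rank test to the log ratios. Exact null distribution
#' (midrank convolution, tie-exact) for n <= 25 after dropping ratios equal
#' to 1; normal approximation with tie-corrected variance otherwise.
#'
#' @param ratios Positive numeric vector.
#' @return A list: `V` (signed-rank statistic), `p.value`, `n` (non-unit
#'   ratios used), `method`.
#' @export
ratio_vs_one_test <- function(ratios) {
  check_that(all(ratios > 0), "all ratios must be positive")
  d <- log(ratios)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(V = 0, p.value = 1, n = 0L, method = "degenerate"))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25L) {
    s <- as.integer(round(2 * r))
    total <- sum(s)
    g <- numeric(total + 1L)          # counts of sign patterns by scaled V
    g[1] <- 1
    for (si in s) {
      shifted <- c(numeric(si), g[seq_len(total + 1L - si)])
      g <- g + shifted
    }
    v2 <- as.integer(round(2 * v))
    p_le <- sum(g[seq_len(v2 + 1L)]) / 2^n
    p_ge <- sum(g[(v2 + 1L):(total + 1L)]) / 2^n
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- v - mu
    z <- (z - sign(z) * 0.5) / sigma
    p <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
    method <- "normal approximation"
  }
  list(V = unname(v), p.value = p, n = n, method = method)
}
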