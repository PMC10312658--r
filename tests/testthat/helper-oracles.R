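## Fixture builders and independent brute-force oracles used across tests.
## Every oracle here deliberately re-derives its quantity from first
## principles, without calling the package code path it checks.

gtf_line <- function(chrom, feature, start1, end1, strand, gene, tx,
                     biotype = NULL) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gene, tx)
  if (!is.null(biotype))
    attrs <- paste0(attrs, sprintf(' transcript_biotype "%s";', biotype))
  paste(chrom, "test", feature, start1, end1, ".", strand, ".", attrs,
        sep = "\t")
}

## Two-transcript toy gene: T1 = [101,200],[301,400],[501,600] (1-based),
## T2 skips the middle exon.
toy_gtf <- function(strand = "+") {
  c(gtf_line("chr1", "exon", 101, 200, strand, "G1", "T1"),
    gtf_line("chr1", "exon", 301, 400, strand, "G1", "T1"),
    gtf_line("chr1", "exon", 501, 600, strand, "G1", "T1"),
    gtf_line("chr1", "exon", 101, 200, strand, "G1", "T2"),
    gtf_line("chr1", "exon", 501, 600, strand, "G1", "T2"))
}

## A-B-C-D-E vs A-C-E gene (five 100 bp exons, 100 bp introns).
abcde_gtf <- function() {
  s <- c(101, 301, 501, 701, 901)
  c(vapply(1:5, function(i)
      gtf_line("chr2", "exon", s[i], s[i] + 99, "+", "G2", "t1"), ""),
    vapply(c(1, 3, 5), function(i)
      gtf_line("chr2", "exon", s[i], s[i] + 99, "+", "G2", "t2"), ""))
}

## Random toy gene: a pool of exon slots; each transcript includes a random
## subset. Returns a model table in parse_gtf() schema.
random_toy_gene <- function(gene = "GR", n_tx = NULL, n_slots = NULL) {
  n_slots <- n_slots %||% sample(3:6, 1)
  n_tx <- n_tx %||% sample(2:6, 1)
  starts <- cumsum(c(100L, rep(200L, n_slots - 1L)))
  ends <- starts + 100L
  rows <- lapply(seq_len(n_tx), function(k) {
    keep <- sort(sample(n_slots, sample(seq_len(n_slots), 1)))
    data.table::data.table(
      transcript_id = sprintf("%s_T%d", gene, k), gene_id = gene,
      chrom = "chrR", strand = "+", start = starts[keep], end = ends[keep],
      biotype = "protein_coding")
  })
  data.table::rbindlist(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Event-detection oracle: for every (exon key, transcript) pair, test
## membership directly and classify keys present in some but not all
## transcripts of the gene.
oracle_events <- function(models) {
  out <- list()
  for (g in unique(models$gene_id)) {
    gm <- models[models$gene_id == g, ]
    txs <- sort(unique(gm$transcript_id))
    keys <- unique(gm[, c("chrom", "start", "end", "strand")])
    for (i in seq_len(nrow(keys))) {
      inc <- character(0)
      for (tx in txs) {
        tm <- gm[gm$transcript_id == tx, ]
        has <- any(tm$chrom == keys$chrom[i] & tm$start == keys$start[i] &
                     tm$end == keys$end[i])
        if (has) inc <- c(inc, tx)
      }
      if (length(inc) > 0 && length(inc) < length(txs)) {
        out[[length(out) + 1]] <- list(
          gene = g, start = keys$start[i], end = keys$end[i],
          inclusion = sort(inc), exclusion = sort(setdiff(txs, inc)))
      }
    }
  }
  out
}

## All-pairs interval overlap oracle (half-open intervals).
oracle_overlap_counts <- function(features, targets) {
  vapply(seq_len(nrow(targets)), function(i) {
    sum(features$chrom == targets$chrom[i] &
          features$start < targets$end[i] &
          features$end > targets$start[i])
  }, 0L)
}

## Independent Benjamini-Hochberg step-up implementation.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

## Hypergeometric upper tail by the factorial formula (valid for N <= 170).
oracle_hyper_upper <- function(N, K, n, k) {
  ch <- function(a, b) {
    if (b < 0 || b > a) return(0)
    factorial(a) / (factorial(b) * factorial(a - b))
  }
  sum(vapply(k:min(K, n), function(j) ch(K, j) * ch(N - K, n - j), 0)) / ch(N, n)
}

## Full-enumeration permutation oracle for the delta statistic. For n <= 8
## units, enumerates all n! orderings of the label vector (equal-multiplicity
## multiset enumeration); for larger n, enumerates distinct focus/ref
## position assignments by nested combinations.
oracle_perm_pvalue <- function(hit, labels, focus, ref) {
  n <- length(labels)
  nf <- sum(labels == focus); nr <- sum(labels == ref)
  obs <- 100 * sum(hit[labels == focus]) / nf - 100 * sum(hit[labels == ref]) / nr
  delta_of <- function(lab)
    100 * sum(hit[lab == focus]) / nf - 100 * sum(hit[lab == ref]) / nr
  if (n <= 8) {
    perms <- all_permutations(n)
    deltas <- apply(perms, 1, function(idx) delta_of(labels[idx]))
    mean(deltas > obs)
  } else {
    other <- setdiff(unique(labels), c(focus, ref))
    deltas <- c()
    for (fpos in asplit(utils::combn(n, nf), 2)) {
      rest <- setdiff(seq_len(n), fpos)
      for (rpos in asplit(utils::combn(rest, nr), 2)) {
        lab <- rep(if (length(other)) other[1] else focus, n)
        lab[fpos] <- focus
        lab[as.integer(rpos)] <- ref
        deltas <- c(deltas, delta_of(lab))
      }
    }
    mean(deltas > obs)
  }
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

## Small planted one-gene study for pipeline tests.
one_gene_study <- function(class = "UHP", n_samples = 100, seed = 7,
                           noise_sd = 0.1, b = 1) {
  cfg <- psicoupler::sim_config(
    n_genes = 1, n_samples = n_samples, seed = seed, noise_sd = noise_sd,
    effect_b = b,
    class_proportions = stats::setNames(as.numeric(c("UHP", "DHP", "TYPE0") == class),
                                        c("UHP", "DHP", "TYPE0")))
  ann <- psicoupler::simulate_annotation(cfg)
  expr <- psicoupler::simulate_expression(cfg, ann)
  list(cfg = cfg, ann = ann, expr = expr)
}
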