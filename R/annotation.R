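## Gene-model parsing and cassette-exon event discovery.
##
## Internal coordinate convention: 0-based half-open intervals everywhere.
## GTF I/O converts from/to the format's 1-based inclusive coordinates at the
## boundary; BED files are already 0-based half-open and pass through as-is.

#' Parse transcript models from a GTF stream
#'
#' Reads a GENCODE-dialect GTF and returns one exon interval per row, grouped
#' by transcript. Only `exon` feature rows contribute intervals; `gene`,
#' `transcript`, `CDS` and all other feature types are ignored. GTF 1-based
#' inclusive coordinates are converted to 0-based half-open. The transcript
#' biotype is taken from the `transcript_biotype` (Ensembl) or
#' `transcript_type` (GENCODE) attribute and recorded as `"unknown"` when
#' neither is present.
#'
#' @param x Path to a GTF file (plain or gzip) or a character vector of GTF
#'   lines.
#' @return A `data.table` with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open), `biotype`, sorted by
#'   transcript and genomic coordinate. Within each transcript exons are
#'   validated to be non-overlapping.
#' @export
parse_gtf <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\t", x) && file.exists(x)) {
    readLines(if (grepl("\\.gz$", x)) gzfile(x) else x)
  } else {
    as.character(x)
  }
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_models())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1]
    stop(sprintf("malformed GTF line %d: expected 9 tab-delimited fields, found %d",
                 line_no[bad], nf[bad]), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  is_exon <- m[, 3] == "exon"
  if (!any(is_exon)) return(empty_models())
  m <- m[is_exon, , drop = FALSE]
  line_no <- line_no[is_exon]

  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start1) || anyNA(end1)) {
    bad <- which(is.na(start1) | is.na(end1))[1]
    stop(sprintf("malformed GTF line %d: non-numeric coordinates", line_no[bad]),
         call. = FALSE)
  }
  if (any(end1 < start1)) {
    bad <- which(end1 < start1)[1]
    stop(sprintf("invalid exon on GTF line %d: end (%d) < start (%d)",
                 line_no[bad], end1[bad], start1[bad]), call. = FALSE)
  }

  attr_field <- m[, 9]
  gid <- gtf_attr(attr_field, "gene_id")
  tid <- gtf_attr(attr_field, "transcript_id")
  if (anyNA(gid) || anyNA(tid)) {
    bad <- which(is.na(gid) | is.na(tid))[1]
    stop(sprintf("malformed GTF line %d: exon lacks gene_id or transcript_id",
                 line_no[bad]), call. = FALSE)
  }
  bt <- gtf_attr(attr_field, "transcript_biotype")
  bt2 <- gtf_attr(attr_field, "transcript_type")
  bt[is.na(bt)] <- bt2[is.na(bt)]
  bt[is.na(bt)] <- "unknown"

  models <- data.table(
    transcript_id = tid, gene_id = gid, chrom = m[, 1], strand = m[, 7],
    start = start1 - 1L, end = end1, biotype = bt
  )
  setorder(models, gene_id, transcript_id, start, end)
  validate_models(models)
  models[]
}

gtf_attr <- function(attrs, key) {
  pat <- paste0('(^|;)\\s*', key, '\\s+"([^"]*)"')
  mm <- regmatches(attrs, regexpr(pat, attrs))
  out <- rep(NA_character_, length(attrs))
  hit <- grepl(pat, attrs)
  out[hit] <- sub(pat, "\\2", regmatches(attrs, regexpr(pat, attrs)))
  out
}

empty_models <- function() {
  data.table(transcript_id = character(), gene_id = character(),
             chrom = character(), strand = character(),
             start = integer(), end = integer(), biotype = character())
}

validate_models <- function(models) {
  check_that(all(models$end > models$start), "exon intervals must have end > start")
  bad <- models[, {
    s <- sort(start); e <- end[order(start)]
    .(overlap = any(s[-1] < e[-length(e)]) && .N > 1L)
  }, by = transcript_id][overlap == TRUE]
  check_that(nrow(bad) == 0L, "overlapping exons within transcript %s",
             paste(head(bad$transcript_id, 3), collapse = ", "))
  invisible(models)
}

#' Write transcript models back to GTF
#'
#' Emits one `exon` feature row per interval, converting the internal 0-based
#' half-open coordinates back to GTF's 1-based inclusive convention.
#' `parse_gtf(write_gtf(models))` reproduces the interval set exactly.
#'
#' @param models A model table as returned by [parse_gtf()].
#' @param file Optional path; when `NULL` the GTF lines are returned invisibly
#'   as a character vector.
#' @return The GTF lines, invisibly.
#' @export
write_gtf <- function(models, file = NULL) {
  lines <- models[, sprintf(
    '%s\tpsicoupler\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
    chrom, start + 1L, end, strand, gene_id, transcript_id, biotype)]
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Find cassette-exon events in a gene's transcript models
#'
#' A cassette event is a unique exon key (chrom, start, end, strand) that is
#' present — by exact coordinate match — in at least one but not all
#' transcripts of its gene. The inclusion set is the transcripts containing
#' the key; the exclusion set is every other transcript of the gene,
#' including transcripts that do not span the locus at all. A transcript with
#' a longer, overlapping exon therefore counts as excluding. Genes with a
#' single transcript yield no events.
#'
#' @param models Transcript models from [parse_gtf()]; may contain one or
#'   several genes.
#' @return A `data.table` with one row per pre-collapse event: `event_id`,
#'   `gene_id`, `chrom`, `strand`, `start`, `end`, `n_exon_keys` (always 1
#'   here), and list-columns `exon_keys`, `inclusion`, `exclusion`.
#' @export
find_cassette_events <- function(models) {
  if (nrow(models) == 0L) return(empty_events())
  gene_tx <- models[, .(all_tx = list(sort(unique(transcript_id)))), by = gene_id]
  keys <- models[, .(inclusion = list(sort(unique(transcript_id)))),
                 by = .(gene_id, chrom, start, end, strand)]
  keys <- gene_tx[keys, on = "gene_id"]
  keys[, n_inc := lengths(inclusion)]
  keys[, n_all := lengths(all_tx)]
  ev <- keys[n_inc > 0L & n_inc < n_all]
  if (nrow(ev) == 0L) return(empty_events())
  ev[, exclusion := Map(setdiff, all_tx, inclusion)]
  ev[, event_id := sprintf("%s:%s:%d-%d", gene_id, chrom, start, end)]
  ev[, exon_keys := Map(function(ch, s, e, st)
    data.table(chrom = ch, start = s, end = e, strand = st),
    chrom, start, end, strand)]
  ev[, n_exon_keys := 1L]
  out <- ev[, .(event_id, gene_id, chrom, strand, start, end, n_exon_keys,
                exon_keys, inclusion, exclusion)]
  setorder(out, gene_id, chrom, start, end)
  out[]
}

empty_events <- function() {
  data.table(event_id = character(), gene_id = character(), chrom = character(),
             strand = character(), start = integer(), end = integer(),
             n_exon_keys = integer(), exon_keys = list(), inclusion = list(),
             exclusion = list())
}

#' Collapse events with identical inclusion/exclusion transcript sets
#'
#' When several exons of a gene are perfectly correlated with respect to
#' transcript structure (identical inclusion and exclusion sets), their
#' inclusion levels are mathematically identical, so the group is tested once:
#' the events are merged into a single event whose `exon_keys` is the union.
#' The representative exon is the key with the smallest start (ties broken by
#' smallest end) and supplies the event's coordinates and id. The operation is
#' idempotent.
#'
#' @param events Event table from [find_cassette_events()] (one gene or many).
#' @return A collapsed event table with the same schema.
#' @export
collapse_equivalent_events <- function(events) {
  if (nrow(events) == 0L) return(events)
  ev <- copy(events)
  ev[, sig := paste(gene_id,
                    vapply(inclusion, paste, "", collapse = ","),
                    vapply(exclusion, paste, "", collapse = ","), sep = "|")]
  out <- ev[, {
    keys <- rbindlist(exon_keys)
    setorder(keys, start, end)
    rep_key <- keys[1]
    .(event_id = sprintf("%s:%s:%d-%d", gene_id[1], rep_key$chrom,
                         rep_key$start, rep_key$end),
      gene_id = gene_id[1], chrom = rep_key$chrom, strand = rep_key$strand,
      start = rep_key$start, end = rep_key$end, n_exon_keys = nrow(keys),
      exon_keys = list(keys), inclusion = inclusion[1], exclusion = exclusion[1])
  }, by = sig][, sig := NULL]
  setorder(out, gene_id, chrom, start, end)
  out[]
}

#' Flanking-intron lengths of a cassette event
#'
#' For each inclusion transcript, the gap in bp between the representative
#' exon and its adjacent exon on each transcription side; "upstream" is the
#' 5' side in transcription direction, so on the minus strand it is the
#' higher-coordinate gap. The event-level value is the median across
#' inclusion transcripts in which the side exists; it is `NA` when the exon
#' is first (respectively last) in every inclusion transcript.
#'
#' @param events Collapsed or raw event table.
#' @param models The gene's transcript models.
#' @return A `data.table`: `event_id`, `upstream_length`, `downstream_length`.
#' @export
flanking_intron_lengths <- function(events, models) {
  if (nrow(events) == 0L)
    return(data.table(event_id = character(), upstream_length = numeric(),
                      downstream_length = numeric()))
  res <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i]
    gaps <- vapply(ev$inclusion[[1]], function(tx) {
      ex <- models[transcript_id == tx & chrom == ev$chrom]
      setorder(ex, start)
      j <- which(ex$start == ev$start & ex$end == ev$end)
      if (length(j) != 1L)
        stop(sprintf("event %s: representative exon not found in inclusion transcript %s",
                     ev$event_id, tx), call. = FALSE)
      left <- if (j > 1L) ex$start[j] - ex$end[j - 1L] else NA_real_
      right <- if (j < nrow(ex)) ex$start[j + 1L] - ex$end[j] else NA_real_
      c(left, right)
    }, numeric(2))
    left <- gaps[1, ]; right <- gaps[2, ]
    up <- if (ev$strand == "+") left else right
    dn <- if (ev$strand == "+") right else left
    med <- function(v) if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
    data.table(event_id = ev$event_id, upstream_length = med(up),
               downstream_length = med(dn))
  })
  rbindlist(res)
}

#' Write a cassette-event table to TSV
#'
#' @param events Event table.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_events_tsv <- function(events, file) {
  flat <- events[, .(
    event_id, gene_id, chrom, strand,
    representative_start = start, representative_end = end, n_exon_keys,
    inclusion_ids = vapply(inclusion, paste, "", collapse = ","),
    exclusion_ids = vapply(exclusion, paste, "", collapse = ","))]
  fwrite(flat, file, sep = "\t")
  invisible(file)
}
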