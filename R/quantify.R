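## Transcript-level expression input and per-sample psi quantification.

#' Read a GCT v1.2 expression matrix
#'
#' GCT layout: line 1 is the version tag `#1.2`, line 2 holds the row and
#' column counts, line 3 the header (`Name`, `Description`, then sample ids),
#' followed by one row per transcript. Gzip input is handled transparently.
#' A trailing version suffix on transcript ids (`ENST0000001.5`) is stripped
#' so ids match GTF transcript ids; the Description column is discarded.
#'
#' @param file Path to a `.gct` or `.gct.gz` file.
#' @return A numeric matrix, transcripts x samples, with transcript ids as
#'   row names and sample ids as column names.
#' @export
read_gct <- function(file) {
  con <- if (grepl("\\.gz$", file)) gzfile(file) else file(file)
  lines <- readLines(con)
  close(con)
  check_that(length(lines) >= 3L && trimws(lines[1]) == "#1.2",
             "not a GCT v1.2 file: first line must be '#1.2'")
  dims <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]]))
  check_that(length(dims) >= 2L && !anyNA(dims[1:2]),
             "malformed GCT dimension line: %s", lines[2])
  body <- fread(text = lines[-(1:2)], sep = "\t", header = TRUE,
                colClasses = list(character = 1:2))
  check_that(nrow(body) == dims[1],
             "GCT dimension line declares %d rows but body has %d", dims[1], nrow(body))
  check_that(ncol(body) - 2L == dims[2],
             "GCT dimension line declares %d samples but body has %d",
             dims[2], ncol(body) - 2L)
  ids <- sub("\\.\\d+$", "", body[[1]])
  check_that(!anyDuplicated(ids),
             "duplicate transcript id in GCT: %s", ids[anyDuplicated(ids)])
  mat <- as.matrix(body[, -(1:2)])
  mode(mat) <- "double"
  check_that(!any(mat < 0, na.rm = TRUE), "GCT contains negative expression values")
  rownames(mat) <- ids
  mat
}

#' Write an expression matrix as GCT v1.2
#'
#' @param mat Numeric matrix with transcript row names and sample column
#'   names.
#' @param file Output path; a `.gz` suffix triggers gzip compression.
#' @return The path, invisibly.
#' @export
write_gct <- function(mat, file) {
  con <- if (grepl("\\.gz$", file)) gzfile(file, "w") else file(file, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(mat), ncol(mat), sep = "\t")), con)
  header <- paste(c("Name", "Description", colnames(mat)), collapse = "\t")
  writeLines(header, con)
  body <- cbind(rownames(mat), rownames(mat),
                format(mat, trim = TRUE, scientific = FALSE, digits = 15))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(file)
}

#' Total gene expression Y(g)
#'
#' Per-sample sum of the expression of all transcripts assigned to the gene.
#' Transcripts listed but absent from the matrix contribute zero (a message
#' notes them); if none of the listed transcripts is present the gene is
#' missing and an error is raised.
#'
#' @param mat Expression matrix from [read_gct()].
#' @param transcripts Character vector of the gene's transcript ids.
#' @return Named numeric vector, one value per sample.
#' @export
gene_expression <- function(mat, transcripts) {
  present <- intersect(transcripts, rownames(mat))
  if (length(present) == 0L)
    stop("none of the gene's transcripts are present in the expression matrix",
         call. = FALSE)
  absent <- setdiff(transcripts, present)
  if (length(absent) > 0L)
    message(sprintf("gene_expression: %d transcript(s) absent from matrix, counted as 0: %s",
                    length(absent), paste(head(absent, 5), collapse = ", ")))
  colSums(mat[present, , drop = FALSE])
}

#' Per-sample percent spliced in for one cassette event
#'
#' For each sample, `ITinc` is the summed expression of the inclusion
#' transcripts and `ITexcl` that of the exclusion transcripts;
#' psi = ITinc / (ITinc + ITexcl), undefined (NA, flagged) where the
#' denominator is zero. Exon expression is `ITinc` and gene expression is
#' `ITinc + ITexcl` (the event's transcript sets partition the gene).
#'
#' @param mat Expression matrix from [read_gct()].
#' @param event One row of a cassette-event table.
#' @return An object of class `event_quant`: a list with `event_id`,
#'   `gene_id`, `sample_id`, `psi`, `psi_defined`, `exon_expr`, `gene_expr`.
#' @export
event_psi <- function(mat, event) {
  inc <- event$inclusion[[1]]
  exc <- event$exclusion[[1]]
  all_tx <- c(inc, exc)
  if (length(intersect(all_tx, rownames(mat))) == 0L)
    stop(sprintf("event %s: gene absent from expression matrix", event$event_id),
         call. = FALSE)
  row_sum <- function(ids) {
    present <- intersect(ids, rownames(mat))
    if (length(present) == 0L) return(rep(0, ncol(mat)))
    colSums(mat[present, , drop = FALSE])
  }
  it_inc <- row_sum(inc)
  it_exc <- row_sum(exc)
  denom <- it_inc + it_exc
  psi <- ifelse(denom > 0, it_inc / denom, NA_real_)
  structure(list(
    event_id = event$event_id, gene_id = event$gene_id,
    sample_id = colnames(mat), psi = psi, psi_defined = denom > 0,
    exon_expr = it_inc, gene_expr = denom
  ), class = "event_quant")
}

#' Quantify all events of an event table
#'
#' @param mat Expression matrix.
#' @param events Cassette-event table.
#' @return A named list of [event_psi()] results, one per event.
#' @export
quantify_events <- function(mat, events) {
  out <- lapply(seq_len(nrow(events)), function(i) event_psi(mat, events[i]))
  names(out) <- events$event_id
  out
}

#' Export event quantifications as long-format TSV
#'
#' @param quants List of `event_quant` objects.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_quant_tsv <- function(quants, file) {
  long <- rbindlist(lapply(quants, function(q)
    data.table(event_id = q$event_id, sample_id = q$sample_id, psi = q$psi,
               exon_expr = q$exon_expr, gene_expr = q$gene_expr)))
  fwrite(long, file, sep = "\t")
  invisible(file)
}
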