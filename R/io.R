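# Readers and writers for the standard plain-text interfaces: BED targets,
# TSV count matrices (rows keyed chrom:start-end), call tables, and SEG
# tracks. Gzipped files are accepted everywhere R's connections handle them.

#' Read a target BED file
#'
#' BED is 0-based half-open; columns 4+ may carry gc_fraction and kit_id
#' (name/score-style extras are read when present).
#'
#' @param path BED file (optionally gzipped).
#' @return target data frame sorted genomically.
#' @export
read_targets_bed <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "gc_fraction"
  if (ncol(df) >= 5) names(df)[5] <- "kit_id"
  df$chrom <- sub("^chr", "", as.character(df$chrom))
  order_genomic(df)
}

#' Write targets as BED
#'
#' @param targets target data frame.
#' @param path output path.
#' @export
write_targets_bed <- function(targets, path) {
  cols <- intersect(c("chrom", "start", "end", "gc_fraction", "kit_id"),
                    names(targets))
  write.table(targets[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a counts/coverage TSV matrix
#'
#' Rows keyed `chrom:start-end` in the first column, one column per sample.
#'
#' @param path TSV file (optionally gzipped).
#' @return numeric matrix with interval rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a counts/coverage matrix as TSV
#'
#' @param m matrix with interval rownames.
#' @param path output path.
#' @export
write_counts_tsv <- function(m, path) {
  df <- data.frame(interval = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a call table as TSV
#'
#' @param calls call data frame.
#' @param path output path.
#' @export
write_calls_tsv <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write calls as a SEG track
#'
#' Tab-delimited segmented-copy-number format consumed by genome browsers:
#' sample, chrom, start, end, number of windows/targets, seg value (the
#' caller's quality metric, signed by type).
#'
#' @param calls call data frame.
#' @param path output path.
#' @param track_name track header name.
#' @export
write_seg <- function(calls, path, track_name = "rdcnv") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('#track name="%s"', track_name), con)
  writeLines(paste("ID", "chrom", "loc.start", "loc.end", "num.mark",
                   "seg.mean", sep = "\t"), con)
  if (nrow(calls)) {
    segval <- ifelse(calls$type == "DEL", -abs(calls$quality),
                     abs(calls$quality))
    write.table(data.frame(calls$sample_id, calls$chrom, calls$start,
                           calls$end, calls$n_windows, segval),
                con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}
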