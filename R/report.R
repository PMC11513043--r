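# Nomenclature, summary tables and the packaged curated-results fixture.

#' CNV length
#'
#' Coordinates are 0-based half-open, so the length is simply `end - start`
#' (this convention reproduces the printed lengths of the curated results,
#' e.g. 32053731 - 31947661 = 106070).
#'
#' @param start,end interval bounds, `end > start`.
#' @return length in bp.
#' @export
cnv_length <- function(start, end) {
  if (any(end <= start)) stop("end must exceed start")
  end - start
}

#' HGVS-style CNV nomenclature
#'
#' Builds the uncertain-breakpoint genomic nomenclature used in clinical
#' CNV reporting on GRCh37 RefSeq accessions:
#' heterozygous deletions `ACC:g.(?_start)_(end_?)del`, duplications at
#' CN 3 (or hemizygous CN 2) `...dup`, complete losses `...[0]`, copy
#' numbers of four or more `...[cn]`, and whole-gonosome aneuploidies
#' `ACC:g.pter_qter[n]`.
#'
#' @param chrom chromosome ("1".."22", "X", "Y").
#' @param start,end interval bounds (ignored for aneuploidies).
#' @param type "DEL" or "DUP".
#' @param cn integer copy number (NA allowed for plain het calls).
#' @param aneuploidy TRUE for a whole-chromosome event.
#' @param accessions chromosome-to-accession map.
#' @return character nomenclature string.
#' @export
hgvs_name <- function(chrom, start, end, type, cn = NA_integer_,
                      aneuploidy = FALSE, accessions = NC_ACCESSIONS) {
  acc <- accessions[as.character(chrom)]
  if (any(is.na(acc))) stop("unmapped chromosome: ", chrom)
  if (length(aneuploidy) == 1L) aneuploidy <- rep(aneuploidy, length(acc))
  suffix <- ifelse(!is.na(cn) & cn == 0L, "[0]",
            ifelse(!is.na(cn) & cn >= 4L, sprintf("[%d]", cn),
            ifelse(type == "DEL", "del", "dup")))
  ifelse(aneuploidy,
         sprintf("%s:g.pter_qter[%d]", acc, cn),
         sprintf("%s:g.(?_%d)_(%d_?)%s", acc, start, end, suffix))
}

#' Read the packaged curated-results fixture
#'
#' The package ships, as a plain TSV, the published set of potentially
#' pathogenic CNVs from the Solve-RD exome re-analysis (103 CNV records -
#' 52 confirmed disease-causing, 25 partially explanatory including seven
#' gonosomal aneuploidies, 26 unvalidated candidates - plus the 8 SNVs that
#' form compound-heterozygous pairs with CNVs of the same individuals).
#' Nomenclature strings are kept exactly as printed, including a handful of
#' rows with typographical slips in the source table (missing punctuation;
#' one individual's two rows carry each other's chromosome accession).
#'
#' @param path fixture path (default: the installed copy).
#' @return data frame, one row per record.
#' @export
read_reported_cnvs <- function(path = system.file("extdata",
                                                  "reported_pathogenic_cnvs.tsv",
                                                  package = "rdcnv")) {
  read.delim(path, colClasses = "character", check.names = FALSE,
             na.strings = character())
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Summary table of retained calls
#'
#' Counts calls per caller and copy-number category (Long, CN 0-4, > 4),
#' with gonosomal sub-counts, plus a percentage-of-events row over the
#' grand total (half-up rounding to 2 decimals). Calls longer than
#' `long_bp` fall in "Long" regardless of copy number; calls without a copy
#' number count as CN 1 / CN 3 by type.
#'
#' @param calls call data frame.
#' @param long_bp long-CNV bound (bp).
#' @return list: `counts` (caller x category matrix), `gonosomal`
#'   (same shape, sex-chromosome subset), `percent` (category percentages),
#'   `total` (grand total).
#' @export
summarize_calls <- function(calls, long_bp = 500000) {
  categories <- c("Long", "0", "1", "2", "3", "4", ">4")
  callers <- c("clincnv", "conifer", "exomedepth")
  if (!nrow(calls)) {
    m <- matrix(0L, length(callers), length(categories),
                dimnames = list(callers, categories))
    return(list(counts = m, gonosomal = m,
                percent = setNames(rep(NA_real_, length(categories)),
                                   categories), total = 0L))
  }
  cn <- effective_cn(calls)
  cat <- ifelse((calls$end - calls$start) > long_bp, "Long",
                ifelse(cn > 4L, ">4", as.character(cn)))
  gono <- calls$chrom %in% c("X", "Y")
  counts <- table(factor(calls$caller, levels = callers),
                  factor(cat, levels = categories))
  gcounts <- table(factor(calls$caller[gono], levels = callers),
                   factor(cat[gono], levels = categories))
  tot <- sum(counts)
  pct <- round_half_up(100 * colSums(counts) / tot, 2)
  list(counts = unclass(counts), gonosomal = unclass(gcounts),
       percent = pct, total = tot)
}

#' Diagnostic yield
#'
#' Proportion of families with disease-causing variants, as a percentage to
#' one decimal (half-up).
#'
#' @param solved_families,total_families non-negative counts,
#'   `total_families > 0`.
#' @return percentage.
#' @export
diagnostic_yield <- function(solved_families, total_families) {
  if (total_families <= 0) stop("total_families must be positive")
  stopifnot(solved_families >= 0)
  round_half_up(100 * solved_families / total_families, 1)
}
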