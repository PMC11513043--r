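# Cohort-level triage: frequency filter, gene-panel restriction, six-class
# categorisation, SNV/CNV double-hit matching and per-ERN prioritisation.

#' Filtering thresholds
#'
#' Every numeric threshold of the triage stage, in one place. Defaults are
#' the working values of the re-analysis workflow: cohort frequency 1%
#' (strictly more than 1% of individuals with a similar-type call removes a
#' locus), long-CNV bound 500 kb, caller primary thresholds (z 1.75, log
#' likelihood 20, Bayes factor 15), 50% reciprocal overlap for "similar"
#' calls, and the ERN-specific rules:
#' * EURO-NMD: discard CN1 calls in genes with haploinsufficiency score
#'   > 90 or pLI < 0.1; discard CN1/CN3 log-likelihood < 30 calls;
#'   discard calls confined to recessive-only genes; discard blacklisted
#'   long calls.
#' * GENTURIS: tier 1 = called by more than one tool; tier 2 = single-tool
#'   calls at log likelihood >= 20 (ClinCNV) or BF >= 15 (ExomeDepth).
#' * ITHACA: discard low-QC/benign/blacklisted calls and deletions < 10 kb
#'   or duplications < 20 kb (except homozygous deletions and trio de novo
#'   calls); prioritise genes with validity score >= 3; keep >= 200 kb
#'   calls regardless of the gene list.
#' * RND: discard log likelihood < 30, prioritise > 200; keep all SVD-z
#'   calls; discard ExomeDepth calls under three targets or BF < 30 unless
#'   another caller overlaps.
#'
#' @param freq_threshold cohort carrier-fraction cutoff.
#' @param long_cnv_bp long-CNV length bound (bp).
#' @param conifer_z,clincnv_loglik,exomedepth_bf caller primary thresholds.
#' @param reciprocal_overlap fraction for "similar type of call".
#' @param euro_nmd,genturis,ithaca,rnd named lists of ERN thresholds.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(freq_threshold = 0.01, long_cnv_bp = 500000,
                          conifer_z = 1.75, clincnv_loglik = 20,
                          exomedepth_bf = 15, reciprocal_overlap = 0.5,
                          euro_nmd = list(hi_discard = 90, pli_discard = 0.1,
                                          loglik_discard = 30),
                          genturis = list(loglik = 20, bf = 15),
                          ithaca = list(min_del = 10000, min_dup = 20000,
                                        long_regardless = 200000,
                                        validity = 3),
                          rnd = list(loglik_discard = 30,
                                     loglik_priority = 200,
                                     min_targets = 3, bf_discard = 30)) {
  cfg <- list(freq_threshold = freq_threshold, long_cnv_bp = long_cnv_bp,
              conifer_z = conifer_z, clincnv_loglik = clincnv_loglik,
              exomedepth_bf = exomedepth_bf,
              reciprocal_overlap = reciprocal_overlap,
              euro_nmd = euro_nmd, genturis = genturis, ithaca = ithaca,
              rnd = rnd)
  stopifnot(all(unlist(cfg[c("freq_threshold", "long_cnv_bp", "conifer_z",
                             "clincnv_loglik", "exomedepth_bf",
                             "reciprocal_overlap")]) > 0))
  structure(cfg, class = "filter_config")
}

# Reciprocal-overlap carrier count: for each call, the number of distinct
# individuals (including its own) carrying a same-type call overlapping it
# reciprocally by >= frac.
reciprocal_carriers <- function(calls, frac = 0.5) {
  carriers <- integer(nrow(calls))
  for (key in unique(paste(calls$chrom, calls$type))) {
    idx <- which(paste(calls$chrom, calls$type) == key)
    ir <- IRanges::IRanges(start = calls$start[idx] + 1L, end = calls$end[idx])
    hits <- IRanges::findOverlaps(ir, ir)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    inter <- IRanges::width(IRanges::pintersect(ir[q], ir[s]))
    ok <- inter >= frac * IRanges::width(ir[q]) &
      inter >= frac * IRanges::width(ir[s])
    q <- q[ok]; s <- s[ok]
    sm <- calls$sample_id[idx]
    cnt <- vapply(split(sm[s], q), function(x) length(unique(x)), 1L)
    carriers[idx[as.integer(names(cnt))]] <- cnt
  }
  carriers
}

#' Cohort frequency filter
#'
#' A call is removed when strictly more than `freq_threshold` (default 1%)
#' of individuals in the whole sample carry a similar type of call - same
#' type (deletion vs duplication) with at least `reciprocal` reciprocal
#' overlap. The filter is caller-agnostic: calls from all callers and
#' samples are pooled before counting carriers.
#'
#' @param calls pooled call data frame.
#' @param n_individuals denominator (individuals in the whole sample).
#' @param freq_threshold carrier-fraction cutoff (exclusive).
#' @param reciprocal reciprocal-overlap fraction defining "similar".
#' @return list with `kept` and `removed` call data frames; both carry a
#'   `carrier_count` column.
#' @export
frequency_filter <- function(calls, n_individuals, freq_threshold = 0.01,
                             reciprocal = 0.5) {
  if (!nrow(calls)) return(list(kept = calls, removed = calls))
  calls$carrier_count <- reciprocal_carriers(calls, reciprocal)
  common <- calls$carrier_count > freq_threshold * n_individuals
  list(kept = calls[!common, , drop = FALSE],
       removed = calls[common, , drop = FALSE])
}

# Gene indices overlapping each call (>= 1 bp), as a list.
overlapping_genes <- function(calls, genes) {
  res <- vector("list", nrow(calls))
  for (chrom in unique(calls$chrom)) {
    ci <- which(calls$chrom == chrom)
    gi <- which(genes$chrom == chrom)
    if (!length(gi)) next
    ir_c <- IRanges::IRanges(calls$start[ci] + 1L, calls$end[ci])
    ir_g <- IRanges::IRanges(genes$start[gi] + 1L, genes$end[gi])
    hits <- IRanges::findOverlaps(ir_c, ir_g)
    for (h in seq_along(S4Vectors::queryHits(hits))) {
      q <- S4Vectors::queryHits(hits)[h]
      res[[ci[q]]] <- c(res[[ci[q]]], gi[S4Vectors::subjectHits(hits)[h]])
    }
  }
  res
}

gene_in_ern <- function(genes, ern) {
  vapply(strsplit(genes$ern_lists, ","), function(x) ern %in% x, TRUE)
}

#' Restrict calls to an ERN gene panel
#'
#' A call is kept when it overlaps at least part (1 bp) of a gene on the
#' ERN's list, or when it is a long CNV (> `long_bp`), which is kept
#' regardless of gene content. On chromosome Y only long calls survive (no
#' ERN panel contains Y genes).
#'
#' @param calls call data frame.
#' @param genes gene panel data frame.
#' @param ern one of "EURO-NMD", "GENTURIS", "ITHACA", "RND".
#' @param long_bp long-CNV bound (exclusive, bp).
#' @return kept calls.
#' @export
gene_list_filter <- function(calls, genes, ern, long_bp = 500000) {
  if (!nrow(calls)) return(calls)
  panel <- genes[gene_in_ern(genes, ern), , drop = FALSE]
  ov <- overlapping_genes(calls, panel)
  in_panel <- lengths(ov) > 0L
  long <- (calls$end - calls$start) > long_bp
  keep <- ifelse(calls$chrom == "Y", long, in_panel | long)
  calls[keep, , drop = FALSE]
}

#' Categorise calls into the six interpretation classes
#'
#' Classes, in precedence order (the broadest evidence wins):
#' LONG (> `long_bp`), GONOSOMAL (chrX/Y), HOM_DEL (autosomal CN 0),
#' HIGH_CN (CN >= 4), DOUBLE_HIT (heterozygous deletion paired with a
#' pathogenic heterozygous SNV in the same biallelic-disease gene and
#' sample), HET_AD (CN 1 or CN 3 overlapping an autosomal-dominant gene).
#' Calls without a copy number (SVD z caller) count as CN 1 (DEL) or CN 3
#' (DUP). Calls fitting no class return `NA` and are dropped from
#' interpretation upstream.
#'
#' @param calls call data frame.
#' @param genes gene panel.
#' @param snv candidate-SNV table (may be empty) for double hits.
#' @param long_bp long-CNV bound (bp).
#' @return character vector of class labels (NA = unclassified).
#' @export
classify_calls <- function(calls, genes, snv = NULL, long_bp = 500000) {
  if (!nrow(calls)) return(character())
  cn <- effective_cn(calls)
  long <- (calls$end - calls$start) > long_bp
  gono <- calls$chrom %in% c("X", "Y")
  hom_del <- !gono & cn == 0L
  high_cn <- cn >= 4L
  dh <- rep(FALSE, nrow(calls))
  if (!is.null(snv) && nrow(snv)) {
    pairs <- double_hit_match(calls, snv, genes)
    dh[pairs$call_index] <- TRUE
  }
  ov <- overlapping_genes(calls, genes[genes$inheritance == "AD", , drop = FALSE])
  het_ad <- cn %in% c(1L, 3L) & lengths(ov) > 0L
  out <- rep(NA_character_, nrow(calls))
  out[het_ad] <- "HET_AD"
  out[dh] <- "DOUBLE_HIT"
  out[high_cn] <- "HIGH_CN"
  out[hom_del] <- "HOM_DEL"
  out[gono] <- "GONOSOMAL"
  out[long] <- "LONG"
  out
}

# Copy number used for classing: SVD z calls carry none, so deletions count
# as CN 1 and duplications as CN 3.
effective_cn <- function(calls) {
  cn <- calls$copy_number
  ifelse(is.na(cn), ifelse(calls$type == "DEL", 1L, 3L), cn)
}

#' Match compound-heterozygous SNV/CNV double hits
#'
#' A pair is emitted when a heterozygous CNV deletion and a flagged
#' (pathogenic or high-impact) heterozygous SNV share sample and gene, and
#' the gene's inheritance is biallelic (AR). Homozygous deletions are
#' already explanatory alone and never pair.
#'
#' @param calls call data frame.
#' @param snv SNV table: sample_id, gene_id, zygosity, pathogenic,
#'   high_impact.
#' @param genes gene panel.
#' @return data frame: call_index, sample_id, gene_id, snv_index.
#' @export
double_hit_match <- function(calls, snv, genes) {
  empty <- data.frame(call_index = integer(), sample_id = character(),
                      gene_id = character(), snv_index = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(calls) || is.null(snv) || !nrow(snv)) return(empty)
  cn <- effective_cn(calls)
  het_del <- calls$type == "DEL" & cn == 1L & !calls$chrom %in% c("X", "Y")
  ar <- genes[genes$inheritance == "AR", , drop = FALSE]
  if (!nrow(ar)) return(empty)
  ov <- overlapping_genes(calls, ar)
  snv_ok <- snv$zygosity %in% c("heterozygous", "het") &
    (isTRUE_vec(snv$pathogenic) | isTRUE_vec(snv$high_impact))
  rows <- list()
  for (i in which(het_del & lengths(ov) > 0L)) {
    gids <- ar$gene_id[ov[[i]]]
    j <- which(snv_ok & snv$sample_id == calls$sample_id[i] &
                 snv$gene_id %in% gids)
    for (jj in j) {
      rows[[length(rows) + 1L]] <- data.frame(
        call_index = i, sample_id = calls$sample_id[i],
        gene_id = snv$gene_id[jj], snv_index = jj, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

# Calls overlapping (>= 1 bp, same type) a call of a different caller.
called_by_other_tool <- function(calls) {
  out <- rep(FALSE, nrow(calls))
  key <- paste(calls$sample_id, calls$chrom, calls$type)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(unique(calls$caller[idx])) < 2L) next
    ir <- IRanges::IRanges(calls$start[idx] + 1L, calls$end[idx])
    hits <- IRanges::findOverlaps(ir, ir)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    diff_caller <- calls$caller[idx[q]] != calls$caller[idx[s]]
    out[idx[unique(q[diff_caller])]] <- TRUE
  }
  out
}

#' Apply an ERN prioritisation strategy
#'
#' Takes classified calls (after the frequency and gene-list filters) and
#' applies one ERN's discard/priority rules (see [filter_config()]).
#' Expected columns beyond the call schema: `class`, and optionally
#' `de_novo`, `blacklist`, `benign`, `low_qc` (missing flag columns are
#' treated as all-FALSE). Cross-caller support is computed internally.
#'
#' @param calls classified call data frame.
#' @param ern one of "EURO-NMD", "GENTURIS", "ITHACA", "RND".
#' @param genes gene panel (scores used by EURO-NMD and ITHACA).
#' @param config a [filter_config()].
#' @return `calls` with `discard` (logical), `discard_reason`, and `tier`
#'   ("tier1", "tier2", "priority", "retained") columns; discarded rows are
#'   kept in the table for audit.
#' @export
apply_ern_strategy <- function(calls, ern, genes, config = filter_config()) {
  if (!nrow(calls)) {
    calls$discard <- logical(); calls$discard_reason <- character()
    calls$tier <- character(); return(calls)
  }
  flag <- function(col) if (is.null(calls[[col]])) rep(FALSE, nrow(calls)) else
    isTRUE_vec(calls[[col]])
  blacklist <- flag("blacklist"); benign <- flag("benign"); low_qc <- flag("low_qc")
  de_novo <- flag("de_novo")
  cn <- effective_cn(calls)
  len <- calls$end - calls$start
  multi <- called_by_other_tool(calls)
  ov <- overlapping_genes(calls, genes)
  discard <- rep(FALSE, nrow(calls))
  reason <- rep("", nrow(calls))
  tier <- rep("retained", nrow(calls))
  set_discard <- function(which, why) {
    new <- which & !discard
    discard[new] <<- TRUE
    reason[new] <<- why
  }
  is_clin <- calls$caller == "clincnv"
  is_exo <- calls$caller == "exomedepth"
  if (ern == "EURO-NMD") {
    p <- config$euro_nmd
    tol <- vapply(seq_len(nrow(calls)), function(i) {
      g <- genes[ov[[i]], , drop = FALSE]
      nrow(g) > 0 && all(g$ddd_hi_score > p$hi_discard | g$pli < p$pli_discard)
    }, TRUE)
    set_discard(cn == 1L & calls$type == "DEL" & tol,
                "gene tolerant of heterozygous loss (HI/pLI)")
    set_discard(cn %in% c(1L, 3L) & is_clin & calls$quality < p$loglik_discard,
                sprintf("log likelihood < %g", p$loglik_discard))
    ar_only <- vapply(seq_len(nrow(calls)), function(i) {
      g <- genes[ov[[i]], , drop = FALSE]
      nrow(g) > 0 && all(g$inheritance == "AR")
    }, TRUE)
    set_discard(cn %in% c(1L, 3L) & ar_only & calls$class == "HET_AD",
                "recessive-only genes")
    set_discard(calls$class == "LONG" & blacklist, "blacklist region")
  } else if (ern == "GENTURIS") {
    p <- config$genturis
    set_discard(calls$class == "LONG" & blacklist, "blacklist region")
    tier[!discard & multi] <- "tier1"
    tier[!discard & !multi & is_clin & calls$quality >= p$loglik] <- "tier2"
    tier[!discard & !multi & is_exo & calls$quality >= p$bf] <- "tier2"
    set_discard(!multi & is_clin & calls$quality < p$loglik,
                sprintf("single-tool log likelihood < %g", p$loglik))
    set_discard(!multi & is_exo & calls$quality < p$bf,
                sprintf("single-tool BF < %g", p$bf))
  } else if (ern == "ITHACA") {
    p <- config$ithaca
    set_discard(low_qc, "low QC")
    set_discard(benign, "previously annotated benign")
    set_discard(blacklist, "blacklist region")
    exempt <- calls$class == "HOM_DEL" | (!is.na(de_novo) & de_novo)
    set_discard(calls$type == "DEL" & len < p$min_del & !exempt,
                sprintf("deletion < %g kb", p$min_del / 1000))
    set_discard(calls$type == "DUP" & len < p$min_dup & !exempt,
                sprintf("duplication < %g kb", p$min_dup / 1000))
    valid <- vapply(seq_len(nrow(calls)), function(i) {
      g <- genes[ov[[i]], , drop = FALSE]
      nrow(g) > 0 && any(g$validity_score >= p$validity)
    }, TRUE)
    tier[!discard & valid] <- "priority"
    tier[!discard & !valid & len >= p$long_regardless] <- "retained"
    set_discard(!valid & len < p$long_regardless & lengths(ov) == 0L,
                "no gene of interest and < 200 kb")
  } else if (ern == "RND") {
    p <- config$rnd
    set_discard(is_clin & calls$quality < p$loglik_discard,
                sprintf("log likelihood < %g", p$loglik_discard))
    tier[!discard & is_clin & calls$quality > p$loglik_priority] <- "priority"
    set_discard(is_exo & !multi &
                  (calls$n_windows < p$min_targets |
                     calls$quality < p$bf_discard),
                "ExomeDepth unsupported: < 3 targets or BF < 30")
  } else {
    stop("unknown ERN: ", ern)
  }
  calls$discard <- discard
  calls$discard_reason <- reason
  calls$tier <- ifelse(discard, "", tier)
  calls
}
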