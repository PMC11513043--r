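# SVD-based RPKM caller with iterative batch QC.
#
# RPKM values are standardised per target, the leading singular components
# (which absorb batch structure) are removed, and maximal runs of targets
# with residual z beyond +/-1.75 become duplication/deletion calls. A batch
# QC loop raises the number of removed components while the batch remains
# too noisy, and discards individual runaway samples.

#' SVD caller configuration
#'
#' @param n_components_removed starting number of singular components to
#'   remove; `NA` picks the elbow of the singular-value curve (maximum
#'   distance to the chord), clipped to \[3, 15\].
#' @param z_threshold call threshold on the residual z value (+/-).
#' @param max_calls_per_sample per-sample call count above which a batch is
#'   considered unresolved (QC loop).
#' @param median_calls_limit batch-median call count below which runaway
#'   samples are discarded rather than re-running.
#' @param max_components hard cap on removable components.
#' @return list of class `svd_config`.
#' @export
svd_config <- function(n_components_removed = NA_integer_,
                       z_threshold = 1.75, max_calls_per_sample = 30L,
                       median_calls_limit = 10L, max_components = 15L) {
  if (!is.na(n_components_removed))
    stopifnot(n_components_removed >= 3L, n_components_removed <= max_components)
  stopifnot(z_threshold > 0, max_calls_per_sample > 0, median_calls_limit > 0)
  structure(list(n_components_removed = n_components_removed,
                 z_threshold = z_threshold,
                 max_calls_per_sample = as.integer(max_calls_per_sample),
                 median_calls_limit = as.integer(median_calls_limit),
                 max_components = as.integer(max_components)),
            class = "svd_config")
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm[t, s] = count * 1e9 / (target_length_bp * total_sample_reads)`,
#' computed independently per enrichment kit (the function takes one kit's
#' matrix).
#'
#' @param counts targets x samples raw count matrix.
#' @param targets matching target data frame.
#' @return RPKM matrix.
#' @export
compute_rpkm <- function(counts, targets) {
  stopifnot(nrow(counts) == nrow(targets))
  totals <- colSums(counts)
  if (any(totals == 0)) stop("sample with zero total reads: ",
                             paste(colnames(counts)[totals == 0], collapse = ","))
  len <- targets$end - targets$start
  sweep(counts * 1e9 / len, 2L, totals, "/")
}

#' Remove leading singular components from standardised RPKM
#'
#' Each target row is standardised to zero mean and unit variance, the first
#' `k` singular components are subtracted, and the residual z-like matrix is
#' returned. The sign of each component is fixed (largest-absolute sample
#' loading positive) so decompositions are reproducible; `k = 0` returns the
#' standardised matrix unchanged.
#'
#' @param rpkm targets x samples RPKM matrix.
#' @param k number of components to remove (< min(dim)).
#' @return list: `z` (residual matrix), `d` (singular values),
#'   `standardized` (input after standardisation).
#' @export
svd_zrpkm <- function(rpkm, k) {
  if (k < 0 || k >= min(dim(rpkm))) stop("k out of range")
  mu <- rowMeans(rpkm)
  s <- apply(rpkm, 1L, sd)
  s[s < 1e-12] <- 1e-12
  z0 <- (rpkm - mu) / s
  sv <- svd(z0)
  # fixed sign convention: largest-|loading| entry of each right vector > 0
  for (i in seq_along(sv$d)) {
    piv <- which.max(abs(sv$v[, i]))
    if (sv$v[piv, i] < 0) { sv$v[, i] <- -sv$v[, i]; sv$u[, i] <- -sv$u[, i] }
  }
  z <- z0
  if (k > 0) {
    idx <- seq_len(k)
    z <- z0 - sv$u[, idx, drop = FALSE] %*%
      (sv$d[idx] * t(sv$v[, idx, drop = FALSE]))
  }
  dimnames(z) <- dimnames(rpkm)
  list(z = z, d = sv$d, standardized = z0)
}

# Elbow of the singular-value curve: maximum distance to the chord.
scree_elbow <- function(d, lo = 3L, hi = 15L) {
  n <- length(d)
  if (n < 3L) return(min(lo, n - 1L))
  chord <- d[1] + (d[n] - d[1]) * (seq_len(n) - 1) / (n - 1)
  min(max(which.max(chord - d), lo), hi, n - 1L)
}

#' Threshold residual z values into calls
#'
#' Maximal runs of consecutive targets (within a chromosome) with z above
#' `+threshold` become duplication calls and below `-threshold` deletion
#' calls; the quality is the extremal |z| in the run. No copy number is
#' estimated - the residual carries no absolute scale.
#'
#' @param z residual matrix from [svd_zrpkm()].
#' @param targets matching target data frame.
#' @param threshold z cutoff (default 1.75).
#' @return call data frame (copy_number `NA`, caller "conifer").
#' @export
call_from_zrpkm <- function(z, targets, threshold = 1.75) {
  stopifnot(nrow(z) == nrow(targets))
  out <- list()
  for (j in seq_len(ncol(z))) {
    state <- ifelse(z[, j] > threshold, 1L, ifelse(z[, j] < -threshold, -1L, 0L))
    grp <- cumsum(c(1L, diff(state) != 0L | diff(match(targets$chrom, CHROMS)) != 0L))
    for (g in split(seq_len(nrow(z)), grp)) {
      st <- state[g[1]]
      if (st == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        sample_id = colnames(z)[j], chrom = targets$chrom[g[1]],
        start = targets$start[g[1]], end = targets$end[g[length(g)]],
        copy_number = NA_integer_, type = if (st > 0L) "DUP" else "DEL",
        caller = "conifer", quality = max(abs(z[g, j])),
        n_windows = length(g), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_calls())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Iterative batch QC loop
#'
#' Runs SVD calling and applies the batch rules: if every sample has fewer
#' than `max_calls_per_sample` calls the batch is accepted; otherwise, if
#' the batch median is below `median_calls_limit`, runaway samples (more
#' than `max_calls_per_sample` calls) are discarded and the rest accepted;
#' otherwise one more component is removed and the batch rerun. The loop
#' also stops, flagged "unresolved", when `max_components` is exceeded.
#'
#' @param rpkm batch RPKM matrix.
#' @param targets matching target data frame.
#' @param config an [svd_config()].
#' @return list: `calls`, `discarded_samples`, `k` (final components
#'   removed), `status` ("clean", "discarded", or "unresolved").
#' @export
batch_qc_loop <- function(rpkm, targets, config = svd_config()) {
  k <- config$n_components_removed
  if (is.na(k)) {
    d <- svd(scale_rows(rpkm))$d
    k <- scree_elbow(d, 3L, config$max_components)
  }
  k <- max(3L, min(k, min(dim(rpkm)) - 1L))
  repeat {
    z <- svd_zrpkm(rpkm, k)$z
    calls <- call_from_zrpkm(z, targets, config$z_threshold)
    n_calls <- table(factor(calls$sample_id, levels = colnames(rpkm)))
    if (all(n_calls < config$max_calls_per_sample)) {
      return(list(calls = calls, discarded_samples = character(), k = k,
                  status = "clean"))
    }
    if (median(n_calls) < config$median_calls_limit) {
      bad <- names(n_calls)[n_calls > config$max_calls_per_sample]
      keep <- calls$sample_id %in% setdiff(colnames(rpkm), bad)
      return(list(calls = calls[keep, , drop = FALSE],
                  discarded_samples = bad, k = k, status = "discarded"))
    }
    if (k + 1L > min(config$max_components, min(dim(rpkm)) - 1L)) {
      return(list(calls = calls, discarded_samples = character(), k = k,
                  status = "unresolved"))
    }
    k <- k + 1L
  }
}

scale_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  s[s < 1e-12] <- 1e-12
  (m - mu) / s
}

#' Call CNVs with the SVD/RPKM workflow
#'
#' Applies the GC-extreme target filter, computes RPKM, and runs the batch
#' QC loop - on the autosomes with all samples together, and on chromosome
#' X separately per sex (sex-specific pools give accurate X calls); the Y
#' chromosome is not analysed by this caller.
#'
#' @param counts targets x samples raw count matrix (one kit).
#' @param targets matching target data frame.
#' @param metadata kit metadata (sex per sample).
#' @param config an [svd_config()].
#' @return list: `calls`, `discarded_samples`, `k` (per pool), `status`.
#' @export
conifer_call_cnvs <- function(counts, targets, metadata,
                              config = svd_config()) {
  gc <- remove_gc_extreme_targets(targets)
  keep_t <- rownames(targets) %in% rownames(gc$kept)
  tg <- gc$kept
  counts <- counts[keep_t, , drop = FALSE]
  # systematically poorly captured targets carry mostly shot noise and
  # produce spurious single-target z excursions; apply the cohort-level
  # low-coverage exclusion (normalised coverage < 0.3 in >= 90% of samples)
  # at target resolution before standardisation
  rel <- sweep(counts, 2L, pmax(apply(counts, 2L, median), 1), "/")
  low <- rowMeans(rel < 0.3) >= 0.9
  tg <- tg[!low, , drop = FALSE]
  counts <- counts[!low, , drop = FALSE]
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ,
                       drop = FALSE]
  pools <- list(autosomes = list(rows = tg$chrom %in% as.character(1:22),
                                 cols = rep(TRUE, ncol(counts))))
  for (sx in intersect(c("M", "F"), unique(metadata$sex))) {
    pools[[paste0("X_", sx)]] <- list(rows = tg$chrom == "X",
                                      cols = metadata$sex == sx)
  }
  all_calls <- list(); discarded <- character(); ks <- integer(); status <- character()
  for (nm in names(pools)) {
    p <- pools[[nm]]
    if (sum(p$rows) < 5L || sum(p$cols) < 5L) next
    rp <- compute_rpkm(counts[p$rows, p$cols, drop = FALSE],
                       tg[p$rows, , drop = FALSE])
    res <- batch_qc_loop(rp, tg[p$rows, , drop = FALSE], config)
    all_calls[[nm]] <- res$calls
    discarded <- union(discarded, res$discarded_samples)
    ks[nm] <- res$k
    status[nm] <- res$status
  }
  calls <- do.call(rbind, all_calls)
  if (is.null(calls)) calls <- empty_calls()
  calls <- calls[!calls$sample_id %in% discarded, , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls, discarded_samples = discarded, k = ks, status = status)
}
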