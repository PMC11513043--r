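# Reference-matched beta-binomial caller.
#
# For each test sample an aggregate reference is assembled from the most
# correlated samples in the batch; the test count at each target is
# modelled beta-binomial against test + reference totals, adjacent targets
# agreeing on a non-diploid state are merged, and segments are scored with
# a log10 Bayes factor against the diploid model. Observed/expected read
# ratios map segments to copy-number bins.

#' Select a correlation-matched reference set
#'
#' Candidates are ranked by Pearson correlation with the test sample;
#' members are added greedily while the correlation between the test sample
#' and the aggregated (summed) reference keeps improving by at least
#' `min_gain`, up to `max_members` members.
#'
#' @param test_id test sample (column name).
#' @param counts targets x samples count matrix for the batch.
#' @param max_members maximum reference members.
#' @param min_gain minimum correlation improvement to keep adding.
#' @return list: `test_sample_id`, `member_sample_ids`, `aggregate` (summed
#'   member counts), `correlation` (test vs aggregate).
#' @export
select_reference <- function(test_id, counts, max_members = 10L,
                             min_gain = 1e-4) {
  stopifnot(test_id %in% colnames(counts), ncol(counts) >= 2L)
  test <- counts[, test_id]
  cand <- setdiff(colnames(counts), test_id)
  rank_cor <- vapply(cand, function(s) {
    r <- suppressWarnings(cor(test, counts[, s]))
    if (is.na(r)) -1 else r
  }, 1.0)
  cand <- cand[order(-rank_cor)]
  members <- cand[1]
  agg <- counts[, cand[1]]
  best <- suppressWarnings(cor(test, agg))
  if (is.na(best)) best <- -1
  for (s in cand[-1]) {
    if (length(members) >= max_members) break
    r <- suppressWarnings(cor(test, agg + counts[, s]))
    if (!is.na(r) && r > best + min_gain) {
      members <- c(members, s)
      agg <- agg + counts[, s]
      best <- r
    }
  }
  list(test_sample_id = test_id, member_sample_ids = members,
       aggregate = agg, correlation = best)
}

#' Reference-correlation QC
#'
#' A test sample passes when its correlation with the aggregate reference
#' is at least 0.97; below that, depth profiles are too dissimilar for
#' reliable calling and the sample is excluded from this caller's output.
#'
#' @param reference a reference set from [select_reference()].
#' @param min_correlation inclusive pass threshold.
#' @return logical pass flag.
#' @export
exomedepth_qc <- function(reference, min_correlation = 0.97) {
  reference$correlation >= min_correlation
}

# Beta-binomial log pmf with mean p and intra-class correlation rho.
dbetabinom_log <- function(x, n, p, rho) {
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  if (rho < 1e-8) return(dbinom(x, n, p, log = TRUE))
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b)
}

# Method-of-moments overdispersion from presumed-diploid targets.
estimate_overdispersion <- function(x, n, p0) {
  ok <- n > 20
  if (sum(ok) < 10) return(0)
  z <- (x[ok] - n[ok] * p0[ok]) / sqrt(n[ok] * p0[ok] * (1 - p0[ok]))
  # trim CNV-affected targets before moment matching
  z <- z[abs(z) < quantile(abs(z), 0.95)]
  v <- var(z)
  nm <- mean(n[ok])
  rho <- (v - 1) / (nm - 1)
  min(max(rho, 0), 0.5)
}

#' Beta-binomial CNV calls with Bayes-factor scoring
#'
#' Per target, the test count `x` out of `x + r` (r = aggregate reference)
#' is modelled beta-binomial with expected proportion
#' `p_c = (c/ploidy * e) / (c/ploidy * e + r)` under copy number c, where
#' `e` is the expected test count from the reference profile. Adjacent
#' targets whose maximum-likelihood state agrees (and differs from the
#' baseline) merge into candidate segments; the segment score is the log10
#' likelihood ratio (Bayes factor) of the best alternative copy number
#' against the baseline, and calls with BF above `bf_threshold` are
#' retained. The observed/expected read ratio over the segment is mapped to
#' a copy-number bin via [oe_ratio_to_cn()] on diploid chromosomes.
#'
#' @param test test-sample count vector.
#' @param reference aggregate reference count vector.
#' @param targets matching target data frame.
#' @param sample_id test sample name (for the call table).
#' @param bf_threshold minimum Bayes factor (log10) for a call.
#' @param ploidy per-target baseline copy number of the test sample
#'   (default diploid everywhere).
#' @param cn_states modelled states.
#' @param cn0_floor effective copy number of the CN 0 state.
#' @param rho beta-binomial overdispersion; `NULL` estimates it by method
#'   of moments from presumed-diploid targets (binomial fallback with a
#'   warning when estimation fails).
#' @return call data frame (caller "exomedepth", quality = BF); the
#'   `copy_number` column carries the O/E bin (`NA` for bin "OTHER" and on
#'   non-diploid baselines).
#' @export
beta_binomial_calls <- function(test, reference, targets, sample_id = "test",
                                bf_threshold = 15, ploidy = NULL,
                                cn_states = 0:4, cn0_floor = 0.05,
                                rho = NULL) {
  stopifnot(length(test) == nrow(targets),
            length(reference) == nrow(targets))
  if (is.null(ploidy)) ploidy <- rep(2L, nrow(targets))
  tt <- sum(test); tr <- sum(reference)
  if (tr <= 0) stop("empty reference")
  e <- tt * reference / tr          # expected test count, baseline state
  n <- test + reference
  p0 <- e / (e + reference)
  if (is.null(rho)) {
    rho <- tryCatch(estimate_overdispersion(test, n, p0), error = function(err) {
      warning("overdispersion estimation failed; using binomial model")
      0
    })
  }
  usable <- n > 0 & reference > 0 & ploidy > 0
  states <- pmax(cn_states, cn0_floor)
  ll <- matrix(-Inf, nrow(targets), length(cn_states))
  for (i in seq_along(cn_states)) {
    f <- states[i] / ploidy
    p <- (f * e) / (f * e + reference)
    ll[usable, i] <- dbetabinom_log(test[usable], n[usable], p[usable], rho)
  }
  base_col <- match(ploidy, cn_states)
  ok <- usable & !is.na(base_col)
  mlstate <- cn_states[max.col(ll, ties.method = "first")]
  mlstate[!ok] <- ploidy[!ok]       # unusable targets stay at baseline
  alt <- mlstate != ploidy
  grp <- cumsum(c(1L, diff(match(targets$chrom, CHROMS)) != 0L |
                    diff(mlstate) != 0L | diff(as.integer(alt)) != 0L))
  out <- list()
  for (g in split(seq_len(nrow(targets)), grp)) {
    if (!alt[g[1]]) next
    st <- mlstate[g[1]]
    ll_alt <- sum(ll[g, match(st, cn_states)])
    ll_base <- sum(ll[cbind(g, base_col[g])])
    bf <- (ll_alt - ll_base) / log(10)
    if (!is.finite(bf) || bf <= bf_threshold) next
    oe <- sum(test[g]) / sum(e[g])
    diploid <- all(ploidy[g] == 2L)
    cn_bin <- if (diploid) oe_ratio_to_cn(sum(test[g]), sum(e[g])) else NA_character_
    out[[length(out) + 1L]] <- data.frame(
      sample_id = sample_id, chrom = targets$chrom[g[1]],
      start = targets$start[g[1]], end = targets$end[g[length(g)]],
      copy_number = if (!is.null(cn_bin) && !is.na(cn_bin) && cn_bin != "OTHER")
        as.integer(cn_bin) else NA_integer_,
      type = if (st < ploidy[g[1]]) "DEL" else "DUP",
      caller = "exomedepth", quality = bf, n_windows = length(g),
      oe_ratio = oe, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    res <- empty_calls()
    res$oe_ratio <- numeric()
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map an observed/expected read ratio to a copy-number bin
#'
#' The bins partition `[0, Inf)` on diploid chromosomes: `[0, 0.10)` likely
#' homozygous deletion (CN 0); `[0.10, 0.75)` heterozygous deletion (CN 1);
#' `[0.75, 1.25)` copy-number neutral (CN 2); `[1.25, 1.75)` heterozygous
#' duplication (CN 3); `[1.75, 2.25)` CN 4; `[2.25, Inf)` "OTHER". Lower
#' bounds are inclusive, upper bounds exclusive.
#'
#' @param observed observed read count (or sum over a segment).
#' @param expected expected read count (> 0).
#' @return character copy-number label: "0","1","2","3","4" or "OTHER".
#' @export
oe_ratio_to_cn <- function(observed, expected) {
  if (any(expected <= 0)) stop("expected must be positive")
  ratio <- observed / expected
  breaks <- c(0, 0.10, 0.75, 1.25, 1.75, 2.25, Inf)
  labels <- c("0", "1", "2", "3", "4", "OTHER")
  labels[findInterval(ratio, breaks, rightmost.closed = FALSE)]
}

#' Call CNVs with the reference-matched beta-binomial workflow
#'
#' For every sample: GC-extreme targets are removed, a correlation-matched
#' reference is selected (same-sex samples only for the gonosomes),
#' reference QC is applied (correlation >= 0.97 on the autosomes), and
#' beta-binomial Bayes-factor calls are produced with sex-adjusted baseline
#' ploidy on X and Y.
#'
#' @param counts targets x samples raw count matrix (one kit).
#' @param targets matching target data frame.
#' @param metadata kit metadata (sex per sample).
#' @param bf_threshold minimum Bayes factor.
#' @param max_members maximum reference-set size.
#' @return list: `calls`, `qc` (per-sample reference correlation and pass
#'   flag).
#' @export
exomedepth_call_cnvs <- function(counts, targets, metadata, bf_threshold = 15,
                                 max_members = 10L) {
  gc <- remove_gc_extreme_targets(targets)
  keep_t <- rownames(targets) %in% rownames(gc$kept)
  tg <- gc$kept
  counts <- counts[keep_t, , drop = FALSE]
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ,
                       drop = FALSE]
  auto <- tg$chrom %in% as.character(1:22)
  gono <- !auto
  qc <- data.frame(sample_id = colnames(counts), correlation = NA_real_,
                   pass = FALSE, stringsAsFactors = FALSE)
  calls <- list()
  for (j in seq_len(ncol(counts))) {
    sid <- colnames(counts)[j]
    ref <- select_reference(sid, counts[auto, , drop = FALSE],
                            max_members = max_members)
    qc$correlation[j] <- ref$correlation
    qc$pass[j] <- exomedepth_qc(ref)
    if (!qc$pass[j]) next
    res_a <- beta_binomial_calls(counts[auto, j], ref$aggregate,
                                 tg[auto, , drop = FALSE], sample_id = sid,
                                 bf_threshold = bf_threshold)
    res_g <- NULL
    same_sex <- metadata$sample_id[metadata$sex == metadata$sex[j]]
    if (any(gono) && length(same_sex) >= 3L) {
      refg <- select_reference(sid, counts[gono, same_sex, drop = FALSE],
                               max_members = max_members)
      pl <- baseline_ploidy(tg$chrom[gono], tg$start[gono], metadata$sex[j])
      res_g <- beta_binomial_calls(counts[gono, j], refg$aggregate,
                                   tg[gono, , drop = FALSE], sample_id = sid,
                                   bf_threshold = bf_threshold, ploidy = pl)
    }
    calls[[sid]] <- rbind(res_a, res_g)
  }
  calls <- if (length(calls)) do.call(rbind, calls) else {
    res <- empty_calls(); res$oe_ratio <- numeric(); res
  }
  rownames(calls) <- NULL
  list(calls = calls, qc = qc)
}
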