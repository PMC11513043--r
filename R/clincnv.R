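# Copy-number log-likelihood caller with maximum-subarray segmentation.
#
# Coverage profiles are clustered to absorb residual batch structure, each
# window is normalised by its cluster median (sex-stratified on the
# gonosomes), Gaussian log-likelihoods are evaluated in sqrt space for copy
# numbers 0..6, and calling finds, per chromosome, the contiguous segment
# with the highest summed evidence for an alternative copy number -
# iteratively, masking each accepted segment, until the best remaining
# segment falls below the log-likelihood threshold (default 20).

#' Cluster samples by global coverage profile
#'
#' Clustering works on the autosomal profile (sex must not define a batch);
#' windows in the top and bottom variance quintiles are dropped (polymorphic
#' and dead regions dominate them), profiles are smoothed with a rolling
#' median, embedded in two dimensions by PCA (deterministic), and
#' density-clustered with a minimum cluster size of 15; the clustering
#' radius is the 95th percentile of 15-nearest-neighbour distances, so any
#' group of mutually close samples clusters and isolated profiles become
#' noise.
#' Noise points and sub-minimum clusters are reassigned to the nearest
#' retained cluster centroid. Cohorts below the minimum size fall back to a
#' single cluster.
#'
#' @param m sqrt-stage windows x samples matrix.
#' @param min_cluster_size minimum retained cluster size.
#' @param smooth_window rolling-median window (odd).
#' @return data frame: sample_id, cluster_id, is_noise (noise before
#'   reassignment).
#' @export
cluster_samples <- function(m, min_cluster_size = 15L, smooth_window = 11L) {
  ns <- ncol(m)
  ids <- colnames(m)
  single <- function(noise = rep(FALSE, ns)) {
    data.frame(sample_id = ids, cluster_id = 1L, is_noise = noise,
               stringsAsFactors = FALSE)
  }
  if (ns < min_cluster_size) {
    warning("cohort smaller than the minimum cluster size; using one cluster")
    return(single())
  }
  # cluster on autosomal profile only: sex must not drive the batches
  auto <- !window_chrom(m) %in% c("X", "Y")
  ma <- if (any(auto)) m[auto, , drop = FALSE] else m
  v <- apply(ma, 1L, var)
  qs <- quantile(v, c(0.2, 0.8))
  keep <- v > qs[1] & v < qs[2]
  if (sum(keep) < 10L) keep <- rep(TRUE, nrow(ma))
  prof <- ma[keep, , drop = FALSE]
  k <- min(smooth_window, nrow(prof) - (1 - nrow(prof) %% 2))
  if (k >= 3) prof <- apply(prof, 2L, function(x) runmed(x, k))
  emb <- prcomp(t(prof), rank. = 2L)$x
  d <- as.matrix(dist(emb))
  # radius covering the minPts-NN distance of 95% of samples: any group of
  # >= minPts mutually close samples forms a cluster, the stragglers in the
  # top 5% become noise and are reassigned to the nearest centroid
  kd <- apply(d, 1L, function(r) sort(r)[min(min_cluster_size + 1L, ns)])
  eps <- quantile(kd, 0.95) * 1.001
  if (!is.finite(eps) || eps <= 0) eps <- median(kd) + 1e-9
  labels <- dbscan_labels(d, eps, minPts = min_cluster_size)
  # dissolve clusters under the minimum size into noise
  tab <- table(labels[labels > 0])
  small <- as.integer(names(tab)[tab < min_cluster_size])
  labels[labels %in% small] <- 0L
  if (!any(labels > 0)) return(single(noise = rep(TRUE, ns)))
  noise <- labels == 0L
  # relabel 1..K and assign noise to the nearest centroid
  lev <- sort(unique(labels[labels > 0]))
  labels <- match(labels, lev)
  cent <- vapply(seq_along(lev), function(ci)
    colMeans(emb[which(labels == ci), , drop = FALSE]), numeric(2L))
  for (i in which(is.na(labels))) {
    dc <- colSums((cent - emb[i, ])^2)
    labels[i] <- which.min(dc)
  }
  data.frame(sample_id = ids, cluster_id = labels, is_noise = noise,
             stringsAsFactors = FALSE)
}

# Classic density clustering on a precomputed distance matrix.
# Returns integer labels; 0 = noise.
dbscan_labels <- function(d, eps, minPts) {
  n <- nrow(d)
  labels <- rep(NA_integer_, n)
  cl <- 0L
  neighbours <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(neighbours, length, 1L) >= minPts
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- neighbours[[i]]
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (is.na(labels[j]) || labels[j] == 0L) {
        expand <- is.na(labels[j]) && core[j]
        labels[j] <- cl
        if (expand) queue <- c(queue, neighbours[[j]])
      }
    }
  }
  labels[is.na(labels)] <- 0L
  labels
}

window_chrom <- function(m) sub(":.*$", "", rownames(m))

# Shrink per-window sd estimates halfway (weight w) towards a smooth trend
# of sd against mean raw window coverage (lowess on log scale).
moderate_sd <- function(s, mu, w = 0.5) {
  if (w <= 0 || length(s) < 30L) return(s)
  ok <- is.finite(s) & s > 0 & is.finite(mu)
  if (sum(ok) < 30L) return(s)
  lt <- lowess(log(mu[ok] + 1), log(s[ok]), f = 0.3)
  trend <- exp(approx(lt$x, lt$y, xout = log(mu + 1), rule = 2,
                      ties = "ordered")$y)
  sqrt((1 - w) * s^2 + w * trend^2)
}

#' Normalise each window by its cluster median
#'
#' Each window of each sample is divided by that window's median over the
#' sample's cluster, bringing the cluster median of every window to 1. On
#' the gonosomes the median is taken over same-sex cluster members (falling
#' back to all same-sex samples when fewer than `min_sex_group`), so that a
#' baseline male X window also normalises to 1.
#'
#' @param m sqrt-stage windows x samples matrix (rownames `chrom:start-end`).
#' @param assignments cluster assignments from [cluster_samples()].
#' @param sex optional per-sample sex vector ("M"/"F", aligned to columns);
#'   enables gonosome stratification.
#' @param min_sex_group minimum same-sex cluster members before falling back
#'   to the whole cohort's same-sex samples.
#' @return normalised matrix, stage "cluster_normalized".
#' @export
normalize_by_cluster <- function(m, assignments, sex = NULL,
                                 min_sex_group = 5L) {
  stopifnot(identical(colnames(m), assignments$sample_id))
  chrom <- window_chrom(m)
  gono <- chrom %in% c("X", "Y")
  out <- m
  for (cl in unique(assignments$cluster_id)) {
    cols <- which(assignments$cluster_id == cl)
    med <- row_medians(m[, cols, drop = FALSE])
    med[med <= 0] <- 1e-9
    out[, cols] <- m[, cols, drop = FALSE] / med
    if (!is.null(sex) && any(gono)) {
      for (sx in unique(sex[cols])) {
        cc <- cols[sex[cols] == sx]
        pool <- if (length(cc) >= min_sex_group) cc else which(sex == sx)
        if (!length(pool)) next
        medg <- row_medians(m[gono, pool, drop = FALSE])
        medg[medg <= 0] <- 1e-9
        out[gono, cc] <- m[gono, cc, drop = FALSE] / medg
      }
    }
  }
  attr(out, "stage") <- "cluster_normalized"
  out
}

#' Per-window copy-number log-likelihoods for one sample
#'
#' In sqrt space a window at copy number c has expected normalised coverage
#' `sqrt(c / ploidy)`; the observed value is modelled as Gaussian around
#' that mean with a per-window standard deviation estimated robustly from
#' the cohort. The copy-number-0 mean is floored at `sqrt(cn0_floor)` to
#' avoid a degenerate zero-mean state.
#'
#' @param x normalised values for one sample (length = windows).
#' @param sd per-window standard deviations (floored at `min_sd`).
#' @param ploidy per-window baseline copy number for this sample.
#' @param cn_states copy-number states to model.
#' @param cn0_floor floor (in coverage units) for the CN = 0 state mean.
#' @param min_sd standard-deviation floor.
#' @return matrix windows x states (columns named by state).
#' @export
window_loglik <- function(x, sd, ploidy, cn_states = 0:6,
                          cn0_floor = 0.05, min_sd = 0.01) {
  sd <- pmax(sd, min_sd)
  ll <- matrix(NA_real_, length(x), length(cn_states),
               dimnames = list(NULL, as.character(cn_states)))
  for (i in seq_along(cn_states)) {
    c_eff <- pmax(cn_states[i], cn0_floor)
    mu <- sqrt(c_eff / ploidy)
    ll[, i] <- dnorm(x, mean = mu, sd = sd, log = TRUE)
  }
  ll
}

# Maximum-sum contiguous subarray with deterministic tie-breaking:
# highest sum, then longest, then leftmost. Returns list(sum, i, j) or NULL
# for empty input.
max_subarray <- function(x) {
  n <- length(x)
  if (!n) return(NULL)
  cs <- cumsum(x)
  prefix <- c(0, cs[-n])
  m <- cummin(prefix)
  # earliest index attaining the running minimum (strict improvement only,
  # so ties keep the earlier = longer segment)
  strict <- prefix < c(Inf, m[-n])
  strict[1] <- TRUE
  start_at <- cummax(ifelse(strict, seq_len(n), 0L))
  sums <- cs - m
  best <- max(sums)
  cand <- which(sums == best)
  starts <- start_at[cand]
  lens <- cand - starts + 1L
  pick <- cand[order(-lens, starts)][1]
  list(sum = best, i = start_at[pick], j = pick)
}

#' Segment per-window evidence by iterative maximum-subarray search
#'
#' For every alternative copy-number state, the per-window score is the
#' log-likelihood advantage over the baseline state. Per chromosome (with
#' the X pseudo-autosomal stub treated as its own block when ploidies
#' differ), the contiguous segment with the highest summed score over all
#' states is located; if its sum reaches `threshold` it is emitted as a
#' call, its windows are masked, and the search repeats. Ties are resolved
#' by segment length, then leftmost start, then lower state.
#'
#' @param ll windows x states log-likelihood matrix (from [window_loglik()]).
#' @param windows window data frame aligned to `ll` rows.
#' @param ploidy per-window baseline copy number for the sample.
#' @param threshold minimum summed log-likelihood ratio for a call.
#' @param cn_states states corresponding to `ll` columns.
#' @return data frame: chrom, start, end, copy_number, quality, n_windows.
#' @export
segment_max_subarray <- function(ll, windows, ploidy, threshold = 20,
                                 cn_states = as.integer(colnames(ll))) {
  stopifnot(nrow(ll) == nrow(windows), nrow(ll) == length(ploidy))
  groups <- paste0(windows$chrom, ".", ploidy)
  out <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    base_state <- as.character(ploidy[idx[1]])
    if (!base_state %in% colnames(ll)) next
    scores <- ll[idx, , drop = FALSE] - ll[idx, base_state]
    alt <- setdiff(colnames(ll), base_state)
    masked <- rep(FALSE, length(idx))
    repeat {
      best <- NULL
      runs <- split(which(!masked), cumsum(c(1L, diff(which(!masked)) != 1L)))
      if (!length(runs) || !length(runs[[1]])) break
      for (st in alt) {
        for (run in runs) {
          r <- max_subarray(scores[run, st])
          if (is.null(r)) next
          cand <- list(sum = r$sum, i = run[r$i], j = run[r$j],
                       state = as.integer(st))
          if (is.null(best) ||
              cand$sum > best$sum + 1e-12 ||
              (abs(cand$sum - best$sum) <= 1e-12 &&
               ((cand$j - cand$i) > (best$j - best$i) ||
                ((cand$j - cand$i) == (best$j - best$i) &&
                 (cand$i < best$i ||
                  (cand$i == best$i && cand$state < best$state)))))) {
            best <- cand
          }
        }
      }
      if (is.null(best) || best$sum < threshold) break
      wi <- idx[best$i]; wj <- idx[best$j]
      out[[length(out) + 1L]] <- data.frame(
        chrom = windows$chrom[wi], start = windows$start[wi],
        end = windows$end[wj], copy_number = best$state,
        quality = best$sum, n_windows = best$j - best$i + 1L,
        stringsAsFactors = FALSE)
      masked[best$i:best$j] <- TRUE
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      copy_number = integer(), quality = numeric(),
                      n_windows = integer(), stringsAsFactors = FALSE))
  }
  order_genomic(do.call(rbind, out))
}

#' Call CNVs with the log-likelihood segmentation workflow
#'
#' Runs the full per-kit workflow: GC-extreme target removal, sample
#' coverage QC, windowing, GC/library correction, exclusion of
#' systematically low windows, sqrt variance stabilisation, coverage-profile
#' clustering, cluster-median normalisation, per-window copy-number
#' log-likelihoods and iterative maximum-subarray segmentation.
#'
#' @param counts targets x samples raw count matrix.
#' @param targets matching target data frame (one kit).
#' @param metadata sample metadata (sex, family, depth) for the kit.
#' @param threshold minimum summed log-likelihood for a call (default 20).
#' @param cn_states modelled copy-number states.
#' @param window_size window width in bp.
#' @param apply_sample_qc drop samples failing coverage QC before calling.
#' @param min_sd per-window standard-deviation floor.
#' @param sd_moderation weight of the coverage-dependent variance trend in
#'   the moderated per-window spread (0 = raw per-window MAD).
#' @return list: `calls` (with sample_id, caller = "clincnv"), `clusters`,
#'   `coverage_qc`, `normalized` (cluster-normalised matrix), `windows`
#'   (retained windows), `ploidy` (windows x samples baseline matrix).
#' @export
clincnv_call_cnvs <- function(counts, targets, metadata, threshold = 20,
                              cn_states = 0:6, window_size = 120L,
                              apply_sample_qc = TRUE, min_sd = 0.01,
                              sd_moderation = 0.5) {
  gc <- remove_gc_extreme_targets(targets)
  keep_t <- rownames(targets) %in% rownames(gc$kept)
  tg <- gc$kept
  counts <- counts[keep_t, , drop = FALSE]
  qc <- sample_coverage_qc(depth_from_counts(counts, tg), tg)
  if (apply_sample_qc) {
    counts <- counts[, qc$pass, drop = FALSE]
    metadata <- metadata[metadata$sample_id %in% colnames(counts), ,
                         drop = FALSE]
  }
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ,
                       drop = FALSE]
  windows <- windowize(tg, window_size)
  wc <- window_coverage(counts, tg, windows)
  norm <- gc_and_library_correct(wc, windows)
  ex <- exclude_systematically_low(norm)
  if (length(ex$excluded_windows))
    windows <- windows[-ex$excluded_windows, , drop = FALSE]
  sq <- variance_stabilize(ex$kept)
  clusters <- cluster_samples(sq)
  cn <- normalize_by_cluster(sq, clusters, sex = metadata$sex)
  # robust per-window spread, estimated within cluster; gonosomal windows
  # use same-sex cluster members only (mirrors the normalisation pooling).
  # Raw per-window MADs from a few dozen samples are noisy, and windows with
  # underestimated spread generate spurious borderline segments, so each
  # window's variance is moderated halfway towards a coverage-dependent
  # trend (shot noise scales with mean coverage) fitted across windows.
  gono <- windows$chrom %in% c("X", "Y")
  mu_w <- rowMeans(wc)[rownames(cn)]
  sdmat <- matrix(NA_real_, nrow(cn), ncol(cn))
  for (cl in unique(clusters$cluster_id)) {
    cols <- which(clusters$cluster_id == cl)
    s <- row_mads(cn[, cols, drop = FALSE])
    sdmat[, cols] <- moderate_sd(s, mu_w, sd_moderation)
    if (any(gono)) {
      for (sx in unique(metadata$sex[cols])) {
        cc <- cols[metadata$sex[cols] == sx]
        pool <- if (length(cc) >= 5L) cc else which(metadata$sex == sx)
        if (length(pool) < 3L) next
        sg <- row_mads(cn[gono, pool, drop = FALSE])
        sdmat[gono, cc] <- moderate_sd(sg, mu_w[gono], sd_moderation)
      }
    }
  }
  calls <- vector("list", ncol(cn))
  ploidy_mat <- matrix(NA_integer_, nrow(cn), ncol(cn))
  for (j in seq_len(ncol(cn))) {
    sex <- metadata$sex[j]
    pl <- baseline_ploidy(windows$chrom, windows$start, sex)
    ploidy_mat[, j] <- pl
    ok <- pl > 0L
    ll <- window_loglik(cn[ok, j], sdmat[ok, j], pl[ok],
                        cn_states = cn_states, min_sd = min_sd)
    seg <- segment_max_subarray(ll, windows[ok, , drop = FALSE], pl[ok],
                                threshold = threshold, cn_states = cn_states)
    seg <- trim_segment_edges(seg, ll, windows[ok, , drop = FALSE], pl[ok],
                              cn_states = cn_states)
    if (nrow(seg)) {
      seg$sample_id <- colnames(cn)[j]
      calls[[j]] <- seg
    }
  }
  calls <- if (any(!vapply(calls, is.null, TRUE))) {
    do.call(rbind, calls[!vapply(calls, is.null, TRUE)])
  } else empty_calls()
  if (nrow(calls)) {
    sex <- metadata$sex[match(calls$sample_id, metadata$sample_id)]
    base <- baseline_ploidy(calls$chrom, calls$start, sex)
    calls$type <- ifelse(calls$copy_number < base, "DEL", "DUP")
    calls$caller <- "clincnv"
    calls <- calls[, c("sample_id", "chrom", "start", "end", "copy_number",
                       "type", "caller", "quality", "n_windows")]
    rownames(calls) <- NULL
  }
  list(calls = calls, clusters = clusters, coverage_qc = qc,
       normalized = cn, windows = windows, ploidy = ploidy_mat)
}

# Breakpoint refinement: windows at a segment's edges that contribute
# almost no evidence (score below eps) should not define the boundaries -
# weakly covered flanking windows otherwise stretch calls across hundreds
# of kb. Detection (the threshold test) already happened on the untrimmed
# segment; quality keeps the full maximum-subarray sum.
trim_segment_edges <- function(seg, ll, windows, ploidy, cn_states,
                               eps = 0.5) {
  if (!nrow(seg)) return(seg)
  for (r in seq_len(nrow(seg))) {
    idx <- which(windows$chrom == seg$chrom[r] &
                   windows$start >= seg$start[r] & windows$end <= seg$end[r])
    if (length(idx) < 2L) next
    st <- as.character(seg$copy_number[r])
    base <- as.character(ploidy[idx])
    sc <- ll[idx, st] - ll[cbind(idx, match(base, colnames(ll)))]
    lo <- 1L; hi <- length(idx)
    while (lo < hi && sc[lo] < eps) lo <- lo + 1L
    while (hi > lo && sc[hi] < eps) hi <- hi - 1L
    seg$start[r] <- windows$start[idx[lo]]
    seg$end[r] <- windows$end[idx[hi]]
    seg$n_windows[r] <- hi - lo + 1L
  }
  seg
}

#' Robust-regression sample QC on call counts
#'
#' The response is the 75th percentile, across chromosomes, of the
#' per-chromosome number of CNV calls (insensitive to one long CNV shredded
#' into many calls on a single chromosome); predictors are median read
#' depth, enrichment kit and ancestry label. A Huber-weighted robust linear
#' model is fitted and a sample fails QC when its response lies outside the
#' 99.5% prediction interval (robust residual scale).
#'
#' @param calls call data frame (sample_id, chrom).
#' @param metadata sample metadata (sample_id, median_depth, kit_id,
#'   ancestry_label); every sample is scored, with zero calls where absent.
#' @param level prediction-interval coverage.
#' @return data frame: sample_id, response, lower, upper, pass.
#' @export
sample_qc_regression <- function(calls, metadata, level = 0.995) {
  per_chrom <- table(factor(calls$sample_id, levels = metadata$sample_id),
                     factor(calls$chrom, levels = CHROMS))
  resp <- apply(per_chrom, 1L, quantile, probs = 0.75, names = FALSE)
  df <- data.frame(response = as.numeric(resp),
                   median_depth = metadata$median_depth,
                   kit_id = metadata$kit_id,
                   ancestry_label = metadata$ancestry_label,
                   stringsAsFactors = FALSE)
  terms <- c("median_depth",
             if (length(unique(df$kit_id)) > 1) "kit_id",
             if (length(unique(df$ancestry_label)) > 1) "ancestry_label")
  X <- model.matrix(stats::reformulate(terms), df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("dropping collinear predictors from the QC regression")
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  if (var(df$response) < 1e-12) {
    return(data.frame(sample_id = metadata$sample_id, response = df$response,
                      lower = df$response[1], upper = df$response[1],
                      pass = TRUE, stringsAsFactors = FALSE))
  }
  fit <- tryCatch(MASS::rlm(X, df$response, maxit = 100),
                  error = function(e) NULL)
  if (is.null(fit)) {
    fit <- lm(df$response ~ X - 1)
    pred <- as.numeric(fitted(fit))
    s <- sigma(fit)
  } else {
    pred <- as.numeric(X %*% coef(fit))
    s <- fit$s
  }
  if (!is.finite(s) || s < 1e-9) s <- max(mad(df$response - pred), 1e-9)
  z <- qnorm(1 - (1 - level) / 2)
  lower <- pred - z * s
  upper <- pred + z * s
  data.frame(sample_id = metadata$sample_id, response = df$response,
             lower = lower, upper = upper,
             pass = df$response >= lower & df$response <= upper,
             stringsAsFactors = FALSE)
}

#' Flag de novo calls from parental coverage evidence
#'
#' For trio probands, a call is de novo when both parents' mean normalised
#' coverage over the call interval is consistent with their own baseline
#' (within `tolerance` of 1 in sqrt space). With a missing parent the flag
#' is `NA` ("unknown").
#'
#' @param calls call data frame for probands.
#' @param metadata sample metadata with family relationships.
#' @param normalized cluster-normalised matrix from [clincnv_call_cnvs()].
#' @param windows matching retained-window data frame.
#' @param tolerance consistency band around baseline, in sqrt space.
#' @return `calls` with a logical `de_novo` column (NA = unknown).
#' @export
annotate_de_novo <- function(calls, metadata, normalized, windows,
                             tolerance = 0.2) {
  calls$de_novo <- NA
  if (!nrow(calls)) return(calls)
  for (r in seq_len(nrow(calls))) {
    fam <- metadata$family_id[metadata$sample_id == calls$sample_id[r]]
    if (!length(fam)) next
    parents <- metadata$sample_id[metadata$family_id == fam &
                                    metadata$relationship %in% c("mother", "father")]
    parents <- intersect(parents, colnames(normalized))
    if (length(parents) < 2L) { calls$de_novo[r] <- NA; next }
    win <- which(windows$chrom == calls$chrom[r] &
                   windows$start >= calls$start[r] &
                   windows$end <= calls$end[r])
    if (!length(win)) next
    consistent <- vapply(parents, function(p) {
      abs(mean(normalized[win, p]) - 1) <= tolerance
    }, TRUE)
    calls$de_novo[r] <- all(consistent)
  }
  calls
}
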