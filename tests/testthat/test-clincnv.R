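# Log-likelihood segmentation caller: clustering, cluster normalisation,
# likelihood evaluation, maximum-subarray segmentation, QC regression and
# de novo annotation.

test_that("clustering recovers simulated batches and handles edge cases", {
  coh <- small_cohort()
  res <- small_clincnv()
  meta <- coh$metadata
  cl <- res$clusters
  batch <- meta$batch_id[match(cl$sample_id, meta$sample_id)]
  # clusters align with batch labels (>= 95% agreement up to relabelling)
  tab <- table(cl$cluster_id, batch)
  expect_gte(sum(apply(tab, 1, max)) / sum(tab), 0.95)
  expect_true(all(table(cl$cluster_id) >= 15))
  # homogeneous cohort: a single cluster
  set.seed(1)
  m <- matrix(rnorm(200 * 30, 1, 0.05), 200, 30,
              dimnames = list(sprintf("1:%d-%d", 1:200, 2:201),
                              sprintf("s%02d", 1:30)))
  hom <- cluster_samples(m)
  expect_equal(length(unique(hom$cluster_id)), 1L)
  # below the minimum cluster size: fallback with a warning
  expect_warning(small <- cluster_samples(m[, 1:14]), "minimum")
  expect_equal(unique(small$cluster_id), 1L)
})

test_that("cluster normalisation brings cluster medians to one", {
  set.seed(2)
  m <- matrix(rlnorm(100 * 36, 0, 0.1), 100, 36,
              dimnames = list(sprintf("5:%d-%d", 1:100, 2:101),
                              sprintf("s%02d", 1:36)))
  asg <- data.frame(sample_id = colnames(m),
                    cluster_id = rep(1:2, each = 18), is_noise = FALSE)
  norm <- normalize_by_cluster(m, asg)
  for (cl in 1:2) {
    med <- apply(norm[, asg$cluster_id == cl], 1, median)
    expect_true(all(abs(med - 1) < 1e-12))
  }
  # a sample equal to the cluster median everywhere normalises to 1:
  # with an odd cluster built around the elementwise median of the others,
  # the inserted column IS the cluster median
  m2 <- cbind(med = apply(m[, 1:18], 1, median), m[, 1:18])
  colnames(m2) <- sprintf("t%02d", 1:19)
  asg2 <- data.frame(sample_id = colnames(m2), cluster_id = 1L,
                     is_noise = FALSE)
  norm2 <- normalize_by_cluster(m2, asg2)
  expect_true(all(abs(norm2[, 1] - 1) < 1e-12))
})

test_that("a spiked heterozygous deletion sits near sqrt(1/2) after the pipeline", {
  coh <- small_cohort()
  res <- small_clincnv()
  tr <- coh$truth
  tr <- tr[tr$copy_number == 1L & tr$chrom %in% as.character(1:22) &
             !tr$common_locus, ]
  vals <- c()
  for (i in seq_len(nrow(tr))) {
    if (!tr$sample_id[i] %in% colnames(res$normalized)) next
    wi <- which(res$windows$chrom == tr$chrom[i] &
                  res$windows$start >= tr$start[i] &
                  res$windows$end <= tr$end[i])
    vals <- c(vals, res$normalized[wi, tr$sample_id[i]])
  }
  expect_gt(length(vals), 20)
  expect_equal(median(vals), sqrt(0.5), tolerance = 0.03)
})

test_that("window log-likelihoods match a direct density oracle", {
  set.seed(3)
  x <- rnorm(50, 1, 0.1)
  sdv <- runif(50, 0.03, 0.2)
  pl <- rep(2L, 50)
  ll <- window_loglik(x, sdv, pl, cn_states = 0:6)
  for (c in 0:6) {
    mu <- sqrt(max(c, 0.05) / 2)
    expect_equal(ll[, as.character(c)], dnorm(x, mu, pmax(sdv, 0.01), log = TRUE),
                 tolerance = 1e-9)
  }
  # argmax behaviour at exact state means
  ll1 <- window_loglik(1, 0.05, 2L)
  expect_equal(colnames(ll1)[which.max(ll1)], "2")
  ll2 <- window_loglik(sqrt(0.5), 0.05, 2L)
  expect_equal(colnames(ll2)[which.max(ll2)], "1")
})

test_that("segmentation equals the brute-force oracle on random instances", {
  set.seed(4)
  for (rep in 1:60) {
    n <- sample(5:18, 1)
    x <- pmax(rnorm(n, 1, 0.25), 0)
    ll <- toy_loglik(x, sd = 0.12, states = 0:4)
    win <- data.frame(chrom = "1", start = seq_len(n) * 100L,
                      end = seq_len(n) * 100L + 50L)
    thr <- sample(c(3, 8, 20), 1)
    seg <- segment_max_subarray(ll, win, rep(2L, n), threshold = thr)
    scores <- ll[, setdiff(colnames(ll), "2"), drop = FALSE] - ll[, "2"]
    oracle <- oracle_segments(scores, thr)
    expect_equal(nrow(seg), length(oracle))
    if (length(oracle)) {
      ord <- order(vapply(oracle, function(o) o$i, 1L))
      oracle <- oracle[ord]
      seg <- seg[order(seg$start), ]
      for (k in seq_along(oracle)) {
        expect_equal(seg$start[k], win$start[oracle[[k]]$i])
        expect_equal(seg$end[k], win$end[oracle[[k]]$j])
        expect_equal(seg$copy_number[k], oracle[[k]]$state)
        expect_equal(unname(seg$quality[k]), unname(oracle[[k]]$sum),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("all-negative evidence yields no calls; threshold is monotone", {
  n <- 12L
  ll <- toy_loglik(rep(1, n), sd = 0.05, states = 0:4)
  win <- data.frame(chrom = "1", start = seq_len(n) * 100L,
                    end = seq_len(n) * 100L + 50L)
  seg <- segment_max_subarray(ll, win, rep(2L, n), threshold = 1)
  expect_equal(nrow(seg), 0L)
  # raising the threshold never adds calls
  x <- c(rep(1, 4), rep(sqrt(0.5), 5), rep(1, 4), rep(sqrt(1.5), 3))
  x <- x + rnorm(length(x), 0, 0.02)
  ll2 <- toy_loglik(x, sd = 0.06, states = 0:4)
  win2 <- data.frame(chrom = "1", start = seq_along(x) * 100L,
                     end = seq_along(x) * 100L + 50L)
  prev <- Inf
  for (thr in c(5, 20, 50, 200)) {
    k <- nrow(segment_max_subarray(ll2, win2, rep(2L, length(x)),
                                   threshold = thr))
    expect_lte(k, prev)
    prev <- k
  }
})

test_that("a spiked deletion is recovered with near-exact boundaries", {
  set.seed(6)
  n <- 40L
  x <- rep(1, n)
  x[15:24] <- sqrt(0.5)
  x <- x + rnorm(n, 0, 0.02)
  ll <- toy_loglik(x, sd = 0.05, states = 0:4)
  win <- data.frame(chrom = "7", start = seq_len(n) * 200L,
                    end = seq_len(n) * 200L + 100L)
  seg <- segment_max_subarray(ll, win, rep(2L, n), threshold = 20)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$copy_number, 1L)
  expect_lte(abs(seg$start - win$start[15]), 200L)
  expect_lte(abs(seg$end - win$end[24]), 200L)
})

test_that("calls on split half-cohorts agree on multi-window events", {
  # halves must each retain >= 15 samples per batch for clustering
  cfg <- sim_config(n_kits = 1L, targets_per_kit = 700L,
                    samples_per_kit = 72L, seed = 23L)
  coh <- simulate_cohort(cfg, snv_fraction = 0)
  meta <- coh$metadata
  idx <- order(meta$batch_id)
  half1 <- meta$sample_id[idx[seq(1, length(idx), 2)]]
  half2 <- meta$sample_id[idx[seq(2, length(idx), 2)]]
  tr <- coh$truth
  ntg <- mapply(function(ch, s, e)
    sum(coh$targets$chrom == ch & coh$targets$start < e & coh$targets$end > s),
    tr$chrom, tr$start, tr$end)
  eligible <- tr$chrom %in% as.character(1:22) & tr$copy_number < 2 &
    !tr$common_locus & ntg >= 3
  recs <- c()
  for (half in list(half1, half2)) {
    cc <- clincnv_call_cnvs(coh$counts$kit01[, half],
                            coh$targets,
                            meta[meta$sample_id %in% half, ])
    sub <- tr[eligible & tr$sample_id %in% half, ]
    recs <- c(recs, recovered(cc$calls, sub))
  }
  expect_gte(mean(recs), 0.85)
})

test_that("QC regression flags only genuine outlier samples", {
  meta <- data.frame(sample_id = sprintf("s%02d", 1:40),
                     median_depth = round(runif(40, 100, 200)),
                     kit_id = "kit01",
                     ancestry_label = rep(c("EUR", "AFR"), 20))
  # identical call counts: everyone passes
  calls <- data.frame(sample_id = rep(meta$sample_id, each = 2),
                      chrom = rep(c("1", "2"), 40))
  qc <- sample_qc_regression(calls, meta)
  expect_true(all(qc$pass))
  # one sample with 50x the typical call count fails
  set.seed(8)
  calls2 <- data.frame(
    sample_id = c(rep(meta$sample_id, each = 3),
                  rep("s01", 150)),
    chrom = c(rep(c("1", "2", "3"), 40),
              sample(as.character(1:22), 150, replace = TRUE)))
  qc2 <- sample_qc_regression(calls2, meta)
  expect_false(qc2$pass[qc2$sample_id == "s01"])
  expect_true(all(qc2$pass[qc2$sample_id != "s01"]))
  # a long CNV shredded into many calls on ONE chromosome does not fail:
  # the 75th-percentile response ignores a single extreme chromosome
  calls3 <- data.frame(
    sample_id = c(rep(meta$sample_id, each = 3), rep("s02", 60)),
    chrom = c(rep(c("1", "2", "3"), 40), rep("9", 60)))
  qc3 <- sample_qc_regression(calls3, meta)
  expect_true(qc3$pass[qc3$sample_id == "s02"])
})

test_that("de novo annotation distinguishes inherited from de novo calls", {
  coh <- small_cohort()
  res <- small_clincnv()
  meta <- coh$metadata
  tr <- coh$truth
  calls <- res$calls
  calls <- annotate_de_novo(calls, meta, res$normalized, res$windows)
  # calls matching de novo truth in trio probands flagged TRUE
  match_truth <- function(i, truth_sub) {
    any(truth_sub$sample_id == calls$sample_id[i] &
          truth_sub$chrom == calls$chrom[i] &
          truth_sub$start < calls$end[i] & truth_sub$end > calls$start[i])
  }
  trio_children <- meta$sample_id[meta$relationship == "proband" &
    meta$family_id %in% meta$family_id[meta$relationship == "mother"]]
  dn_truth <- tr[tr$de_novo & tr$chrom %in% as.character(1:22), ]
  inh_truth <- tr[!tr$de_novo & !tr$common_locus &
                    tr$sample_id %in% trio_children &
                    tr$chrom %in% as.character(1:22), ]
  dn_calls <- which(vapply(seq_len(nrow(calls)), match_truth, TRUE,
                           truth_sub = dn_truth) &
                      calls$sample_id %in% trio_children)
  inh_calls <- which(vapply(seq_len(nrow(calls)), match_truth, TRUE,
                            truth_sub = inh_truth) &
                       calls$sample_id %in% trio_children)
  expect_gt(length(dn_calls), 0)
  expect_true(all(calls$de_novo[dn_calls]))
  if (length(inh_calls)) expect_false(any(calls$de_novo[inh_calls],
                                          na.rm = FALSE))
  # duo: missing parent gives an unknown flag
  meta2 <- meta
  mothers <- meta2$relationship == "mother"
  duo_calls <- annotate_de_novo(calls[calls$sample_id %in% trio_children, ],
                                meta2[!mothers, ], res$normalized,
                                res$windows)
  expect_true(all(is.na(duo_calls$de_novo)))
})
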