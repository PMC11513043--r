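# Shared fixtures, built in code and cached for the test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Small single-kit cohort used across caller tests.
small_cohort <- function() {
  fixture("small_cohort", function() {
    cfg <- sim_config(n_kits = 1L, targets_per_kit = 800L,
                      samples_per_kit = 40L, seed = 7L)
    coh <- simulate_cohort(cfg, snv_fraction = 1)
    coh$config <- cfg
    coh
  })
}

# ClinCNV-style pipeline output on the small cohort.
small_clincnv <- function() {
  fixture("small_clincnv", function() {
    coh <- small_cohort()
    clincnv_call_cnvs(coh$counts$kit01, coh$targets, coh$metadata)
  })
}

# Reciprocal-overlap test between one interval and a table of intervals.
reciprocal_hit <- function(s1, e1, s2, e2, frac = 0.5) {
  ov <- pmin(e1, e2) - pmax(s1, s2)
  ov >= frac * (e1 - s1) & ov >= frac * (e2 - s2)
}

# Recovery of truth events by a call table (same sample, any overlap,
# matching direction).
recovered <- function(calls, truth_sub) {
  if (!nrow(truth_sub)) return(logical())
  mapply(function(sid, ch, s, e, cn) {
    any(calls$sample_id == sid & calls$chrom == ch &
          calls$start < e & calls$end > s &
          ((cn < 2) == (calls$type == "DEL")))
  }, truth_sub$sample_id, truth_sub$chrom, truth_sub$start, truth_sub$end,
  truth_sub$copy_number)
}

# Brute-force oracle for iterative maximum-subarray segmentation: enumerate
# every (state, i, j), apply the same tie-breaking (sum, then length, then
# leftmost, then lowest state), mask, repeat. Single chromosome.
oracle_segments <- function(scores, threshold) {
  n <- nrow(scores)
  states <- colnames(scores)
  masked <- rep(FALSE, n)
  out <- list()
  repeat {
    best <- NULL
    for (st in states) {
      for (i in seq_len(n)) {
        if (masked[i]) next
        acc <- 0
        for (j in i:n) {
          if (masked[j]) break
          acc <- acc + scores[j, st]
          cand <- list(sum = acc, i = i, j = j, state = as.integer(st))
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
    }
    if (is.null(best) || best$sum < threshold) break
    out[[length(out) + 1L]] <- best
    masked[best$i:best$j] <- TRUE
  }
  out
}

# Naive per-target copy-number oracle: count ratio against the cohort
# median, rescaled by the sample's own global ratio (library size), times
# the baseline, rounded.
naive_copy_number <- function(counts, sample_id, target_rows, ploidy = 2L) {
  med_all <- apply(counts, 1L, median)
  scale <- median(counts[, sample_id] / pmax(med_all, 1))
  r <- counts[target_rows, sample_id] / pmax(med_all[target_rows], 1)
  round(mean(r) / scale * ploidy)
}

# Synthetic window log-likelihood matrix for segmentation tests.
toy_loglik <- function(x, sd = 0.05, states = 0:4, ploidy = 2L) {
  window_loglik(x, rep(sd, length(x)), rep(ploidy, length(x)),
                cn_states = states)
}
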