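# Synthetic exome coverage cohorts with known ground truth.
#
# The simulator emulates the heterogeneity of a multi-centre exome
# compendium: several enrichment kits with their own target sets and depth
# distributions, smooth GC-dependent capture bias per kit, library-size
# variation, negative-binomial count noise, spiked CNVs of copy number 0-6
# from a single target up to whole gonosomes, parent-child trios with de
# novo events, and heterozygous SNVs paired with deletions on the other
# allele of recessive-disease genes.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic cohort generator. The seed fully
#' determines all outputs: every generator runs under a seed derived from
#' `seed` (plus a per-kit offset) and restores the caller's RNG state on
#' exit.
#'
#' @param n_kits number of enrichment kits (each with its own target set,
#'   bias curve and samples).
#' @param targets_per_kit targets simulated per kit.
#' @param samples_per_kit samples per kit.
#' @param mean_depth_range range (reads) from which per-sample median target
#'   depth is drawn uniformly.
#' @param gc_bias_strength non-negative scale of the per-kit multiplicative
#'   GC bias curve; 0 disables GC bias.
#' @param nb_dispersion negative-binomial dispersion (1/size); values below
#'   1e-8 fall back to Poisson noise.
#' @param cnv_rate_per_sample expected number of spiked rare CNVs per sample
#'   (Poisson).
#' @param cnv_length_distribution named probabilities over event sizes:
#'   `one` (1 target), `two_three` (2-3 targets), `multi` (4-10 targets),
#'   `long` (consecutive targets spanning > 500 kb), `chromosome` (whole
#'   chromosome; drawn on the gonosomes to emulate aneuploidies).
#' @param n_batches_per_kit sequencing batches within each kit; every batch
#'   carries its own systematic per-target bias (the cluster/batch structure
#'   that coverage-profile clustering and SVD component removal must
#'   absorb).
#' @param batch_effect_sd log-normal sd of the per-batch per-target
#'   multiplicative bias.
#' @param capture_sd log-normal sd of per-target capture efficiency (shared
#'   by all samples of a kit; real capture efficiencies span orders of
#'   magnitude, which is what makes same-kit coverage profiles correlate
#'   near 0.97-0.99).
#' @param fraction_trios fraction of samples organised into parent-child
#'   trios (the rest are singleton probands).
#' @param fraction_common_cnv_loci carrier fraction planted at each
#'   designated common-CNV locus (must exceed 0.01 for the cohort frequency
#'   filter to have true positives).
#' @param n_common_loci designated common-CNV loci per kit.
#' @param seed integer seed.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_kits = 2L,
                       targets_per_kit = 2000L,
                       samples_per_kit = 60L,
                       mean_depth_range = c(150, 250),
                       gc_bias_strength = 0.6,
                       nb_dispersion = 0.005,
                       cnv_rate_per_sample = 2,
                       cnv_length_distribution = c(one = 0.25, two_three = 0.3,
                                                   multi = 0.33, long = 0.09,
                                                   chromosome = 0.03),
                       n_batches_per_kit = 2L,
                       batch_effect_sd = 0.6,
                       capture_sd = 1.0,
                       fraction_trios = 0.2,
                       fraction_common_cnv_loci = 0.05,
                       n_common_loci = 3L,
                       seed = 1L) {
  stopifnot(n_kits >= 1, targets_per_kit >= 1, samples_per_kit >= 1,
            length(mean_depth_range) == 2, all(mean_depth_range > 0),
            gc_bias_strength >= 0, nb_dispersion >= 0,
            cnv_rate_per_sample >= 0, n_batches_per_kit >= 1,
            batch_effect_sd >= 0, capture_sd >= 0,
            fraction_trios >= 0, fraction_trios <= 1,
            fraction_common_cnv_loci >= 0, fraction_common_cnv_loci <= 1)
  need <- c("one", "two_three", "multi", "long", "chromosome")
  if (!all(need %in% names(cnv_length_distribution)))
    stop("cnv_length_distribution must name: ", paste(need, collapse = ", "))
  p <- cnv_length_distribution[need]
  cfg <- list(n_kits = as.integer(n_kits),
              targets_per_kit = as.integer(targets_per_kit),
              samples_per_kit = as.integer(samples_per_kit),
              mean_depth_range = as.numeric(mean_depth_range),
              gc_bias_strength = gc_bias_strength,
              nb_dispersion = nb_dispersion,
              cnv_rate_per_sample = cnv_rate_per_sample,
              cnv_length_distribution = p / sum(p),
              n_batches_per_kit = as.integer(n_batches_per_kit),
              batch_effect_sd = batch_effect_sd,
              capture_sd = capture_sd,
              fraction_trios = fraction_trios,
              fraction_common_cnv_loci = fraction_common_cnv_loci,
              n_common_loci = as.integer(n_common_loci),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Run expr under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}

kit_index <- function(kit_id) {
  if (is.numeric(kit_id)) return(as.integer(kit_id))
  as.integer(sub("^kit", "", kit_id))
}

kit_name <- function(i) sprintf("kit%02d", kit_index(i))

#' Generate an enrichment-kit target set
#'
#' Exon-like targets (60-300 bp) are placed sorted and non-overlapping on all
#' autosomes plus X and Y, proportionally to chromosome length, with a small
#' pseudo-autosomal stub forced onto Xp. GC fractions follow a Beta mixture
#' centred near 0.45 with a deliberate small tail above 0.8 so that the
#' GC-extreme target filter has work to do (well under 0.5% of targets).
#'
#' @param config a [sim_config()].
#' @param kit_id kit index or "kitNN" name.
#' @param gc_mixture either "default" or "degenerate" (all GC = 0.5; no mass
#'   above the 0.8 filter threshold).
#' @return data frame with columns chrom, start, end (0-based half-open),
#'   gc_fraction, kit_id, sorted genomically.
#' @export
generate_targets <- function(config, kit_id = 1L, gc_mixture = c("default", "degenerate")) {
  gc_mixture <- match.arg(gc_mixture)
  k <- kit_index(kit_id)
  with_seed(config$seed + 7919L * k, {
    n <- config$targets_per_kit
    # allocate targets to chromosomes by length; Y gets a reduced share
    w <- CHROM_LENGTHS
    w["Y"] <- w["Y"] * 0.4
    n_chr <- pmax(1L, round(n * w / sum(w)))
    # fix rounding drift on chromosome 1
    n_chr[1] <- n_chr[1] + (n - sum(n_chr))
    out <- vector("list", length(CHROMS))
    for (ci in seq_along(CHROMS)) {
      chrom <- CHROMS[ci]
      m <- n_chr[ci]
      lens <- sample(60:300, m, replace = TRUE)
      gaps <- pmax(200, round(rexp(m, rate = m / (CHROM_LENGTHS[ci] * 0.9))))
      starts <- cumsum(gaps) + cumsum(c(0L, head(lens, -1L)))
      if (chrom == "X") {
        # force a pseudo-autosomal stub: ~3% of X targets inside the PAR
        npar <- max(1L, ceiling(0.03 * m))
        par_lens <- lens[seq_len(npar)]
        par_starts <- sort(sample.int(PAR_BOUNDARY - 400L, npar)) +
          cumsum(c(0L, head(par_lens, -1L)))
        par_starts <- pmin(par_starts, PAR_BOUNDARY - par_lens - 1L)
        rest <- starts[-seq_len(npar)]
        rest <- PAR_BOUNDARY + 1e6 + rest
        starts <- c(sort(par_starts), rest)
      }
      out[[ci]] <- data.frame(chrom = chrom, start = as.integer(starts),
                              end = as.integer(starts + lens),
                              stringsAsFactors = FALSE)
    }
    tg <- do.call(rbind, out)
    if (gc_mixture == "degenerate") {
      tg$gc_fraction <- 0.5
    } else {
      gc <- rbeta(nrow(tg), 9, 11)
      n_tail <- max(1L, rbinom(1L, nrow(tg), 0.003))
      tail_idx <- sample.int(nrow(tg), n_tail)
      gc[tail_idx] <- runif(n_tail, 0.81, 0.92)
      tg$gc_fraction <- gc
    }
    tg$kit_id <- kit_name(k)
    tg <- order_genomic(tg)
    rownames(tg) <- NULL
    tg
  })
}

#' Generate sample metadata for one kit
#'
#' Builds families first: `fraction_trios` of the kit's samples are organised
#' into affected-proband + unaffected-parents trios, the remainder are
#' singleton affected probands. Each family therefore has at least one
#' affected member. Sexes are drawn at random; per-sample median depth is
#' uniform over `mean_depth_range`.
#'
#' @inheritParams generate_targets
#' @return data frame: sample_id, family_id, affected, sex, kit_id,
#'   relationship, ancestry_label, median_depth.
#' @export
generate_metadata <- function(config, kit_id = 1L) {
  k <- kit_index(kit_id)
  with_seed(config$seed + 7919L * k + 1L, {
    n <- config$samples_per_kit
    n_trio <- floor(config$fraction_trios * n / 3)
    rows <- list()
    sid <- 0L
    fid <- 0L
    new_id <- function() {
      sid <<- sid + 1L
      sprintf("S%02d_%03d", k, sid)
    }
    for (i in seq_len(n_trio)) {
      fid <- fid + 1L
      fam <- sprintf("F%02d_%03d", k, fid)
      child_sex <- sample(c("M", "F"), 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = c(new_id(), new_id(), new_id()),
        family_id = fam,
        affected = c(TRUE, FALSE, FALSE),
        sex = c(child_sex, "F", "M"),
        relationship = c("proband", "mother", "father"),
        stringsAsFactors = FALSE)
    }
    while (sid < n) {
      fid <- fid + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = new_id(), family_id = sprintf("F%02d_%03d", k, fid),
        affected = TRUE, sex = sample(c("M", "F"), 1L),
        relationship = "proband", stringsAsFactors = FALSE)
    }
    meta <- do.call(rbind, rows)
    meta$kit_id <- kit_name(k)
    meta$ancestry_label <- sample(c("EUR", "SAS", "AFR"), nrow(meta),
                                  replace = TRUE, prob = c(0.7, 0.15, 0.15))
    # parents share the child's ancestry label
    for (fam in unique(meta$family_id)) {
      i <- meta$family_id == fam
      meta$ancestry_label[i] <- meta$ancestry_label[i][1]
    }
    meta$median_depth <- round(runif(nrow(meta), config$mean_depth_range[1],
                                     config$mean_depth_range[2]))
    # whole families sequence in one batch
    fams <- unique(meta$family_id)
    fam_batch <- setNames(sprintf("batch%d", (seq_along(fams) - 1L) %%
                                    config$n_batches_per_kit + 1L), fams)
    meta$batch_id <- unname(fam_batch[meta$family_id])
    rownames(meta) <- NULL
    meta[, c("sample_id", "family_id", "affected", "sex", "kit_id",
             "relationship", "ancestry_label", "median_depth", "batch_id")]
  })
}

# Pick the copy number of a spiked event given the local baseline ploidy.
draw_copy_number <- function(ploidy) {
  if (ploidy == 1L) {
    # hemizygous region: loss -> 0, gain -> 2
    if (runif(1) < 0.5) 0L else 2L
  } else {
    if (runif(1) < 0.5) {
      if (runif(1) < 0.8) 1L else 0L
    } else {
      sample(c(3L, 4L, 5L, 6L), 1L, prob = c(0.7, 0.2, 0.07, 0.03))
    }
  }
}

#' Generate ground-truth CNV events
#'
#' Rare events are spiked per sample at a Poisson rate with sizes drawn from
#' `cnv_length_distribution`; all events are anchored on runs of consecutive
#' targets so they are visible to depth-of-coverage calling.
#' Whole-chromosome events are drawn on the gonosomes (aneuploidies). In
#' trios, each proband event is de novo with probability 1/2; otherwise the
#' identical event is copied into one parent. Designated common loci are
#' planted as the same-type event in `fraction_common_cnv_loci` of the kit's
#' samples.
#'
#' @param config a [sim_config()].
#' @param targets targets of the sample's kit, from [generate_targets()].
#' @param metadata kit metadata from [generate_metadata()].
#' @return data frame: sample_id, chrom, start, end, copy_number, de_novo,
#'   common_locus.
#' @export
generate_truth <- function(config, targets, metadata) {
  k <- kit_index(metadata$kit_id[1])
  with_seed(config$seed + 7919L * k + 2L, {
    tg <- targets
    auto <- which(tg$chrom %in% as.character(1:22))
    recs <- list()
    sex_of <- setNames(metadata$sex, metadata$sample_id)
    trio_children <- metadata$sample_id[metadata$relationship == "proband" &
      metadata$family_id %in% metadata$family_id[metadata$relationship == "mother"]]
    parent_of <- function(sample) {
      fam <- metadata$family_id[metadata$sample_id == sample]
      p <- metadata$sample_id[metadata$family_id == fam &
                                metadata$relationship %in% c("mother", "father")]
      if (length(p)) sample(p, 1L) else NA_character_
    }
    add_event <- function(sample, i0, i1, chrom, de_novo, common) {
      start <- tg$start[i0]; end <- tg$end[i1]
      ploidy <- baseline_ploidy(chrom, start, sex_of[[sample]])
      if (ploidy == 0L) return(NULL)   # no Y in females
      cn <- draw_copy_number(ploidy)
      data.frame(sample_id = sample, chrom = chrom, start = start, end = end,
                 copy_number = cn, de_novo = de_novo, common_locus = common,
                 stringsAsFactors = FALSE)
    }
    used_rare <- logical(nrow(tg))
    # --- common loci first: they claim their targets so rare events never
    # collide with them
    n_samp <- nrow(metadata)
    carriers_n <- max(2L, round(config$fraction_common_cnv_loci * n_samp))
    for (li in seq_len(config$n_common_loci)) {
      for (try in 1:25) {
        anchor <- sample(auto, 1L)
        chrom <- tg$chrom[anchor]
        idx_chr <- which(tg$chrom == chrom)
        pos <- match(anchor, idx_chr)
        span <- sample(2:4, 1L)
        if (pos + span - 1L > length(idx_chr)) pos <- length(idx_chr) - span + 1L
        i0 <- idx_chr[pos]; i1 <- idx_chr[pos + span - 1L]
        if (any(used_rare[i0:i1])) next
        used_rare[i0:i1] <- TRUE
        cn <- if (li %% 2L == 1L) 1L else 3L
        carriers <- sample(metadata$sample_id, carriers_n)
        for (s in carriers) {
          recs[[length(recs) + 1L]] <- data.frame(
            sample_id = s, chrom = chrom, start = tg$start[i0], end = tg$end[i1],
            copy_number = cn, de_novo = FALSE, common_locus = TRUE,
            stringsAsFactors = FALSE)
        }
        break
      }
    }
    # --- rare events, per sample; loci are kept unique across samples so
    # cohort recurrence comes only from the designated common loci
    for (s in metadata$sample_id) {
      n_ev <- rpois(1L, config$cnv_rate_per_sample)
      if (n_ev == 0) next
      cats <- sample(names(config$cnv_length_distribution), n_ev,
                     replace = TRUE, prob = config$cnv_length_distribution)
      for (cat in cats) {
        if (cat == "chromosome") {
          chrom <- if (sex_of[[s]] == "M") sample(c("X", "Y"), 1L) else "X"
          idx <- which(tg$chrom == chrom)
          if (chrom == "X" && sex_of[[s]] == "M")
            idx <- idx[tg$start[idx] >= PAR_BOUNDARY]  # keep baseline uniform
          if (!length(idx)) next
          ploidy <- baseline_ploidy(chrom, tg$start[idx[1]], sex_of[[s]])
          cn <- ploidy + sample(c(-1L, 1L), 1L)
          if (cn < 0L || (cn == 0L && ploidy == 1L && chrom == "X")) cn <- ploidy + 1L
          recs[[length(recs) + 1L]] <- data.frame(
            sample_id = s, chrom = chrom, start = tg$start[idx[1]],
            end = tg$end[idx[length(idx)]], copy_number = cn,
            de_novo = FALSE, common_locus = FALSE, stringsAsFactors = FALSE)
          next
        }
        span <- switch(cat,
                       one = 1L,
                       two_three = sample(2:3, 1L),
                       multi = sample(4:10, 1L),
                       long = NA_integer_)
        i0 <- i1 <- NA_integer_
        for (try in 1:25) {
          anchor <- sample(auto, 1L)
          chrom <- tg$chrom[anchor]
          idx_chr <- which(tg$chrom == chrom)
          if (!is.na(span) && span > length(idx_chr)) next
          pos <- match(anchor, idx_chr)
          if (is.na(span)) {
            # extend until the span exceeds 500 kb
            j <- pos
            while (j < length(idx_chr) &&
                   tg$end[idx_chr[j]] - tg$start[idx_chr[pos]] <= 5e5) j <- j + 1L
            if (tg$end[idx_chr[j]] - tg$start[idx_chr[pos]] <= 5e5) next
            c0 <- idx_chr[pos]; c1 <- idx_chr[j]
          } else {
            if (pos + span - 1L > length(idx_chr)) pos <- length(idx_chr) - span + 1L
            c0 <- idx_chr[pos]; c1 <- idx_chr[pos + span - 1L]
          }
          if (any(used_rare[c0:c1])) next
          i0 <- c0; i1 <- c1
          break
        }
        if (is.na(i0)) next
        used_rare[i0:i1] <- TRUE
        chrom <- tg$chrom[i0]
        de_novo <- s %in% trio_children && runif(1) < 0.5
        ev <- add_event(s, i0, i1, chrom, de_novo, FALSE)
        if (is.null(ev)) next
        recs[[length(recs) + 1L]] <- ev
        if (s %in% trio_children && !de_novo) {
          p <- parent_of(s)
          if (!is.na(p)) {
            pv <- ev
            pv$sample_id <- p
            # re-check the parent's ploidy (sex chromosomes)
            if (baseline_ploidy(ev$chrom, ev$start, sex_of[[p]]) ==
                baseline_ploidy(ev$chrom, ev$start, sex_of[[s]])) {
              recs[[length(recs) + 1L]] <- pv
            } else {
              recs[[length(recs)]]$de_novo <- TRUE  # uninheritable -> de novo
            }
          }
        }
      }
    }
    if (!length(recs)) {
      return(data.frame(sample_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        copy_number = integer(), de_novo = logical(),
                        common_locus = logical(), stringsAsFactors = FALSE))
    }
    truth <- do.call(rbind, recs)
    # drop duplicate/overlapping events within a sample (keep the first)
    keep <- rep(TRUE, nrow(truth))
    by_s <- split(seq_len(nrow(truth)), truth$sample_id)
    for (ii in by_s) {
      if (length(ii) < 2) next
      o <- ii[order(match(truth$chrom[ii], CHROMS), truth$start[ii])]
      for (j in seq_along(o)[-1]) {
        prev <- o[seq_len(j - 1L)]
        prev <- prev[keep[prev] & truth$chrom[prev] == truth$chrom[o[j]]]
        if (any(truth$end[prev] > truth$start[o[j]])) keep[o[j]] <- FALSE
      }
    }
    truth <- truth[keep, , drop = FALSE]
    rownames(truth) <- NULL
    truth
  })
}

# Smooth unimodal multiplicative GC bias curve for a kit.
gc_bias_curve <- function(gc, strength, kit) {
  if (strength <= 0) return(rep(1, length(gc)))
  k <- kit_index(kit)
  centre <- 0.40 + 0.15 * ((k * 0.37) %% 1)   # kit-specific optimum in [.40,.55]
  sharp <- strength * (2 + 4 * ((k * 0.61) %% 1))
  exp(-sharp * (gc - centre)^2)
}

#' Simulate per-target read counts
#'
#' Counts for sample s at target t are negative-binomial with mean
#' `depth_s * weight_t * gc_factor(gc_t, kit) * CN_st / ploidy_st`, where
#' `weight_t` is a log-normal target capture efficiency, ploidy is 2 on
#' autosomes and sex-dependent on the gonosomes (females carry no Y), and
#' `CN_st` comes from the overlapping truth record (baseline elsewhere). De
#' novo events exist only in the child because [generate_truth()] never
#' copies them to a parent.
#'
#' @param targets targets of one kit.
#' @param metadata metadata of the same kit.
#' @param truth ground-truth events from [generate_truth()] (may be empty).
#' @param config a [sim_config()].
#' @return integer matrix targets x samples, rownames `chrom:start-end`,
#'   with `attr(,"stage") == "raw"`.
#' @export
simulate_counts <- function(targets, metadata, truth, config) {
  if (nrow(truth) && !all(truth$chrom %in% CHROMS))
    stop("truth record on unknown chromosome: ",
         paste(setdiff(truth$chrom, CHROMS), collapse = ","))
  k <- kit_index(metadata$kit_id[1])
  with_seed(config$seed + 7919L * k + 3L, {
    nt <- nrow(targets); ns <- nrow(metadata)
    weight <- rlnorm(nt, 0, config$capture_sd)
    weight <- weight / mean(weight)
    gcfac <- gc_bias_curve(targets$gc_fraction, config$gc_bias_strength, k)
    base <- weight * gcfac
    batches <- if (is.null(metadata$batch_id)) rep("batch1", ns) else
      metadata$batch_id
    batch_eff <- lapply(setNames(nm = unique(batches)), function(b)
      rlnorm(nt, 0, config$batch_effect_sd))
    counts <- matrix(0L, nt, ns,
                     dimnames = list(interval_key(targets$chrom, targets$start,
                                                  targets$end),
                                     metadata$sample_id))
    for (j in seq_len(ns)) {
      sex <- metadata$sex[j]
      ploidy <- baseline_ploidy(targets$chrom, targets$start, sex)
      cn <- as.numeric(ploidy)
      tr <- truth[truth$sample_id == metadata$sample_id[j], , drop = FALSE]
      if (nrow(tr)) {
        for (r in seq_len(nrow(tr))) {
          hit <- targets$chrom == tr$chrom[r] &
            targets$start < tr$end[r] & targets$end > tr$start[r]
          cn[hit] <- tr$copy_number[r]
        }
      }
      mu <- metadata$median_depth[j] * base * batch_eff[[batches[j]]] *
        ifelse(ploidy > 0, cn / 2, 0)
      # hemizygous baseline: ploidy 1 regions at cn/2 of the diploid mean is
      # exactly the physical expectation (half the DNA), so cn/2 is used for
      # every region with ploidy > 0; ploidy-0 regions (female Y) stay at 0.
      if (config$nb_dispersion < 1e-8) {
        counts[, j] <- rpois(nt, mu)
      } else {
        counts[, j] <- rnbinom(nt, size = 1 / config$nb_dispersion, mu = mu)
      }
    }
    attr(counts, "stage") <- "raw"
    counts
  })
}

#' Generate a synthetic gene panel
#'
#' When `targets` are supplied, genes are built from runs of consecutive
#' targets (3-12 targets each, padded into the flanking gaps) so that spiked
#' CNVs always hit genes; chromosome Y carries no genes, matching the ERN
#' panels. ERN memberships are drawn to the requested list sizes (a gene may
#' sit on several lists); without targets a free-standing genome-wide panel
#' of `n_genes` intervals is produced.
#'
#' @param seed integer seed.
#' @param targets optional target data frame to anchor genes on.
#' @param n_genes number of genes when `targets` is NULL.
#' @param ern_sizes named ERN list sizes; defaults mirror the four curated
#'   panels (EURO-NMD 615, GENTURIS 230, ITHACA 1944, RND 1820), scaled down
#'   proportionally if fewer genes are available.
#' @return data frame: gene_id, symbol, chrom, start, end, ern_lists
#'   (comma-separated), inheritance (AD/AR/XL/other), pli, ddd_hi_score,
#'   validity_score.
#' @export
generate_genes <- function(seed = 1L, targets = NULL, n_genes = 3000L,
                           ern_sizes = c("EURO-NMD" = 615, "GENTURIS" = 230,
                                         "ITHACA" = 1944, "RND" = 1820)) {
  with_seed(seed + 104729L, {
    if (!is.null(targets)) {
      tg <- targets[targets$chrom != "Y", , drop = FALSE]
      rows <- list()
      gi <- 0L
      for (chrom in unique(tg$chrom)) {
        idx <- which(tg$chrom == chrom)
        i <- 1L
        while (i <= length(idx)) {
          span <- sample(3:12, 1L)
          j <- min(i + span - 1L, length(idx))
          gi <- gi + 1L
          rows[[gi]] <- data.frame(
            chrom = chrom,
            start = max(0L, tg$start[idx[i]] - 500L),
            end = tg$end[idx[j]] + 500L, stringsAsFactors = FALSE)
          i <- j + 1L
        }
      }
      genes <- do.call(rbind, rows)
    } else {
      chrom <- sample(c(as.character(1:22), "X"), n_genes, replace = TRUE,
                      prob = c(CHROM_LENGTHS[1:22], CHROM_LENGTHS["X"]))
      width <- round(runif(n_genes, 5e3, 2e5))
      start <- vapply(chrom, function(ch)
        sample.int(CHROM_LENGTHS[[ch]] - 2e5, 1L), 1L)
      genes <- data.frame(chrom = chrom, start = start,
                          end = start + width, stringsAsFactors = FALSE)
    }
    n <- nrow(genes)
    genes <- order_genomic(genes)
    genes$gene_id <- sprintf("G%05d", seq_len(n))
    genes$symbol <- sprintf("GENE%05d", seq_len(n))
    sizes <- pmax(round(ern_sizes * min(1, n / sum(ern_sizes))), 1L)
    membership <- rep("", n)
    for (ern in names(sizes)) {
      pick <- sample.int(n, min(sizes[[ern]], n))
      membership[pick] <- ifelse(membership[pick] == "", ern,
                                 paste(membership[pick], ern, sep = ","))
    }
    genes$ern_lists <- membership
    inh <- sample(c("AD", "AR", "other"), n, replace = TRUE,
                  prob = c(0.45, 0.35, 0.20))
    inh[genes$chrom == "X"] <- ifelse(runif(sum(genes$chrom == "X")) < 0.6,
                                      "XL", inh[genes$chrom == "X"])
    genes$inheritance <- inh
    genes$pli <- round(runif(n), 3)
    genes$ddd_hi_score <- round(runif(n, 0, 100), 2)
    genes$validity_score <- sample(0:4, n, replace = TRUE)
    rownames(genes) <- NULL
    genes[, c("gene_id", "symbol", "chrom", "start", "end", "ern_lists",
              "inheritance", "pli", "ddd_hi_score", "validity_score")]
  })
}

#' Generate heterozygous SNV partners for double-hit deletions
#'
#' For a chosen subset of heterozygous-deletion truth records that overlap a
#' biallelic-disease (AR) gene, emits one heterozygous, pathogenic/high-impact
#' SNV in the same gene and sample - the constructed compound-heterozygous
#' pairs that [double_hit_match()] must recover.
#'
#' @param truth truth records from [generate_truth()].
#' @param genes gene panel from [generate_genes()].
#' @param fraction fraction of eligible deletions given a partner (1 = all).
#' @param seed integer seed.
#' @return data frame: sample_id, gene_id, symbol, chrom, pos, zygosity,
#'   pathogenic, high_impact. Zero rows when `fraction` = 0.
#' @export
generate_snv_partners <- function(truth, genes, fraction = 0.5, seed = 1L) {
  empty <- data.frame(sample_id = character(), gene_id = character(),
                      symbol = character(), chrom = character(),
                      pos = integer(), zygosity = character(),
                      pathogenic = logical(), high_impact = logical(),
                      stringsAsFactors = FALSE)
  if (fraction <= 0 || !nrow(truth)) return(empty)
  dels <- truth[truth$copy_number == 1L & truth$chrom %in% as.character(1:22), ,
                drop = FALSE]
  if (!nrow(dels)) return(empty)
  ar <- genes[genes$inheritance == "AR", , drop = FALSE]
  if (!nrow(ar)) return(empty)
  with_seed(seed + 15485863L, {
    rows <- list()
    for (r in seq_len(nrow(dels))) {
      g <- ar[ar$chrom == dels$chrom[r] & ar$start < dels$end[r] &
                ar$end > dels$start[r], , drop = FALSE]
      if (!nrow(g)) next
      g <- g[1L, ]
      # place the SNV inside the gene, outside the deleted interval if room
      left <- g$start < dels$start[r]
      pos <- if (left) g$start + 5L else min(g$end - 5L, dels$end[r] + 5L)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = dels$sample_id[r], gene_id = g$gene_id, symbol = g$symbol,
        chrom = g$chrom, pos = as.integer(pos), zygosity = "heterozygous",
        pathogenic = TRUE, high_impact = TRUE, stringsAsFactors = FALSE)
    }
    if (!length(rows)) return(empty)
    snv <- do.call(rbind, rows)
    snv <- snv[!duplicated(paste(snv$sample_id, snv$gene_id)), , drop = FALSE]
    n_keep <- if (fraction >= 1) nrow(snv) else round(fraction * nrow(snv))
    if (n_keep < nrow(snv)) snv <- snv[sort(sample.int(nrow(snv), n_keep)), ,
                                       drop = FALSE]
    rownames(snv) <- NULL
    snv
  })
}

#' Simulate a complete multi-kit cohort
#'
#' Convenience wrapper running all generators for every kit.
#'
#' @param config a [sim_config()].
#' @param snv_fraction fraction of eligible heterozygous deletions in AR
#'   genes given an SNV partner.
#' @return list with elements `targets` (all kits, row-bound), `counts`
#'   (named list of per-kit matrices), `metadata`, `truth`, `genes`
#'   (derived from kit 1 targets), and `snv`.
#' @export
simulate_cohort <- function(config = sim_config(), snv_fraction = 0.5) {
  targets <- list(); counts <- list(); metas <- list(); truths <- list()
  for (k in seq_len(config$n_kits)) {
    tg <- generate_targets(config, k)
    meta <- generate_metadata(config, k)
    tr <- generate_truth(config, tg, meta)
    counts[[kit_name(k)]] <- simulate_counts(tg, meta, tr, config)
    targets[[k]] <- tg; metas[[k]] <- meta; truths[[k]] <- tr
  }
  targets <- do.call(rbind, targets)
  metadata <- do.call(rbind, metas)
  truth <- do.call(rbind, truths)
  genes <- generate_genes(config$seed, targets = targets[targets$kit_id == kit_name(1), ])
  snv <- generate_snv_partners(truth, genes, snv_fraction, config$seed)
  list(targets = targets, counts = counts, metadata = metadata,
       truth = truth, genes = genes, snv = snv)
}
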