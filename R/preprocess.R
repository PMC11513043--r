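# Per-kit coverage QC and normalisation shared by all three callers.
#
# Fixed pipeline order: GC-extreme target filter -> sample coverage QC ->
# kit cohort-size gate -> windowing -> GC/library correction ->
# systematically-low exclusion -> variance stabilisation. No operation mixes
# samples across kits; each function takes the targets/counts of one kit.

stage_of <- function(m) attr(m, "stage")

check_stage <- function(m, expected) {
  st <- stage_of(m)
  if (!is.null(st) && !st %in% expected)
    stop("matrix has stage '", st, "', expected ",
         paste(expected, collapse = "/"))
  invisible(TRUE)
}

#' Remove GC-extreme targets
#'
#' GC-rich targets amplify poorly and produce unreliable depth signal;
#' targets with a GC fraction strictly above `max_gc` (default 0.80) are
#' removed before any calling. A target at exactly 0.80 is kept.
#'
#' @param targets target data frame with a `gc_fraction` column.
#' @param max_gc exclusive upper GC bound.
#' @return list with `kept` and `removed` data frames, input order preserved.
#' @export
remove_gc_extreme_targets <- function(targets, max_gc = 0.80) {
  if (is.null(targets$gc_fraction) || anyNA(targets$gc_fraction))
    stop("targets must carry a complete gc_fraction column")
  drop <- targets$gc_fraction > max_gc
  list(kept = targets[!drop, , drop = FALSE],
       removed = targets[drop, , drop = FALSE])
}

#' Convert per-target read counts to mean depth of coverage
#'
#' Per-base depth is approximated by the per-target mean:
#' `count * read_length / target_length`.
#'
#' @param counts targets x samples count matrix.
#' @param targets matching target data frame.
#' @param read_length sequencing read length in bp.
#' @return depth matrix of the same shape.
#' @export
depth_from_counts <- function(counts, targets, read_length = 150) {
  stopifnot(nrow(counts) == nrow(targets))
  counts * (read_length / (targets$end - targets$start))
}

#' Sample-level coverage QC
#'
#' A sample passes when at least `min_fraction` (default 70%) of the target
#' region has a depth of coverage of at least `min_depth` reads (default 10,
#' boundary inclusive). The fraction is computed over target bases, with
#' per-base depth approximated by the per-target mean.
#'
#' @param depth targets x samples matrix of per-target mean depth
#'   (see [depth_from_counts()]).
#' @param targets matching target data frame (lengths weight the fraction).
#' @param min_depth depth threshold in reads.
#' @param min_fraction minimum passing fraction of target bases.
#' @return data frame: sample_id, frac_targets_ge_10x, pass, reason.
#' @export
sample_coverage_qc <- function(depth, targets, min_depth = 10,
                               min_fraction = 0.70) {
  if (nrow(targets) == 0L) stop("empty target set")
  stopifnot(nrow(depth) == nrow(targets))
  w <- targets$end - targets$start
  frac <- apply(depth >= min_depth, 2L, function(ok) sum(w[ok]) / sum(w))
  pass <- frac >= min_fraction
  data.frame(
    sample_id = colnames(depth),
    frac_targets_ge_10x = unname(frac),
    pass = unname(pass),
    reason = ifelse(pass, "",
                    sprintf("only %.1f%% of target bases at >=%dx",
                            100 * frac, min_depth)),
    stringsAsFactors = FALSE)
}

#' Kit cohort-size gate
#'
#' Kits whose available cohort is smaller than `min_samples` (default 30) are
#' excluded from calling: their control pool is too small for accurate CNV
#' identification.
#'
#' @param metadata sample metadata with a `kit_id` column.
#' @param min_samples minimum cohort size per kit (inclusive).
#' @return character vector of kept kit ids.
#' @export
kit_cohort_gate <- function(metadata, min_samples = 30L) {
  tab <- table(metadata$kit_id)
  names(tab)[tab >= min_samples]
}

#' Split targets into windows
#'
#' Each target is tiled by consecutive windows of at most `window_size` bp
#' (default 120), covering the target exactly; windows keep a pointer to
#' their parent target.
#'
#' @param targets sorted target data frame.
#' @param window_size maximum window width in bp.
#' @return data frame: chrom, start, end, gc_fraction, kit_id (if present),
#'   target_index (row in `targets`).
#' @export
windowize <- function(targets, window_size = 120L) {
  len <- targets$end - targets$start
  n_w <- pmax(1L, ceiling(len / window_size))
  ti <- rep(seq_len(nrow(targets)), n_w)
  off <- unlist(lapply(n_w, function(k) seq_len(k) - 1L), use.names = FALSE)
  ws <- targets$start[ti] + off * window_size
  we <- pmin(ws + window_size, targets$end[ti])
  out <- data.frame(chrom = targets$chrom[ti], start = as.integer(ws),
                    end = as.integer(we),
                    gc_fraction = targets$gc_fraction[ti],
                    target_index = ti, stringsAsFactors = FALSE)
  if (!is.null(targets$kit_id)) out$kit_id <- targets$kit_id[ti]
  out
}

#' Average read coverage per window
#'
#' Distributes each target's read count uniformly over its windows
#' (`count * window_length / target_length`), the window-level analogue of
#' average read coverage given per-target counts.
#'
#' @param counts targets x samples raw count matrix.
#' @param targets matching target data frame.
#' @param windows windows from [windowize()].
#' @return windows x samples matrix, stage "raw".
#' @export
window_coverage <- function(counts, targets, windows) {
  stopifnot(nrow(counts) == nrow(targets))
  tlen <- targets$end - targets$start
  wlen <- windows$end - windows$start
  m <- counts[windows$target_index, , drop = FALSE] *
    (wlen / tlen[windows$target_index])
  rownames(m) <- interval_key(windows$chrom, windows$start, windows$end)
  attr(m, "stage") <- "raw"
  m
}

# Assign each window to a GC bin of the given width, merging bins holding
# fewer than min_bin windows into their lower neighbour (the lowest bin
# merges upward).
gc_bins <- function(gc, bin_width = 0.05, min_bin = 10L) {
  b <- pmin(floor(gc / bin_width), floor(1 / bin_width) - 1L)
  lev <- sort(unique(b))
  counts <- table(factor(b, levels = lev))
  merged <- lev
  for (i in seq_along(lev)) {
    if (counts[i] < min_bin) {
      tgt <- if (i > 1) merged[i - 1L] else lev[min(i + 1L, length(lev))]
      counts[lev == tgt] <- counts[lev == tgt] + counts[i]
      merged[i] <- tgt
    }
  }
  # resolve chains (a bin merged into a bin that itself merged)
  repeat {
    nxt <- merged[match(merged, lev)]
    if (identical(nxt, merged)) break
    merged <- nxt
  }
  merged[match(b, lev)]
}

#' GC-content and library-size correction
#'
#' Within each sample, coverage is first scaled to a common library size
#' (division by the sample's median window coverage, robust to CNVs) and
#' then each window is divided by the median coverage of its GC bin (bins of
#' width `bin_width` in GC fraction; bins with fewer than `min_bin` windows
#' are merged with a neighbour). The result is normalised coverage with
#' per-GC-bin medians flat at 1, invariant to a sample's sequencing depth.
#'
#' @param m raw windows x samples coverage matrix (from [window_coverage()]).
#' @param windows matching window data frame with `gc_fraction`.
#' @param bin_width GC bin width.
#' @param min_bin minimum windows per GC bin before merging.
#' @return normalised matrix, stage "gc_corrected".
#' @export
gc_and_library_correct <- function(m, windows, bin_width = 0.05,
                                   min_bin = 10L) {
  check_stage(m, "raw")
  stopifnot(nrow(m) == nrow(windows))
  bins <- gc_bins(windows$gc_fraction, bin_width, min_bin)
  out <- m
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    lib <- median(v)
    if (lib <= 0) lib <- mean(v) + 1e-9
    v <- v / lib
    med <- tapply(v, bins, median)
    med[med <= 0] <- 1e-9
    out[, j] <- v / med[as.character(bins)]
  }
  attr(out, "stage") <- "gc_corrected"
  out
}

#' Exclude systematically poorly covered windows
#'
#' A window is excluded when at least `sample_fraction` (default 90%) of
#' samples show normalised coverage below `min_coverage` (default 0.3, i.e.
#' under 30% of typical coverage).
#'
#' @param m normalised (gc_corrected) windows x samples matrix.
#' @param min_coverage normalised-coverage floor.
#' @param sample_fraction fraction of samples that must be low.
#' @return list with `kept` (matrix) and `excluded_windows` (integer row
#'   indices of the excluded windows).
#' @export
exclude_systematically_low <- function(m, min_coverage = 0.3,
                                       sample_fraction = 0.9) {
  check_stage(m, c("gc_corrected", "raw"))
  low <- rowMeans(m < min_coverage)
  drop <- low >= sample_fraction
  kept <- m[!drop, , drop = FALSE]
  attr(kept, "stage") <- stage_of(m)
  list(kept = kept, excluded_windows = which(drop))
}

#' Variance stabilisation
#'
#' Element-wise square-root transform. For count-like data this
#' approximately decouples the variance from the mean (delta method:
#' Poisson counts give variance ~ 1/4).
#'
#' @param m non-negative matrix.
#' @return transformed matrix, stage "sqrt".
#' @export
variance_stabilize <- function(m) {
  if (any(m < 0)) stop("negative values cannot be variance-stabilised")
  out <- sqrt(m)
  attr(out, "stage") <- "sqrt"
  out
}
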