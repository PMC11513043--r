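# Cohort triage: frequency filter, gene-panel restriction, six classes,
# double-hit matching and the four ERN strategies.

mk_calls <- function(...) {
  rows <- list(...)
  base <- data.frame(sample_id = "s1", chrom = "1", start = 1000L,
                     end = 6000L, copy_number = 1L, type = "DEL",
                     caller = "clincnv", quality = 50, n_windows = 4L,
                     stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(rows, function(r) {
    row <- base
    for (nm in names(r)) row[[nm]] <- r[[nm]]
    row
  }))
  rownames(out) <- NULL
  out
}

mk_genes <- function(...) {
  rows <- list(...)
  base <- data.frame(gene_id = "G1", symbol = "GENE1", chrom = "1",
                     start = 500L, end = 8000L, ern_lists = "RND",
                     inheritance = "AD", pli = 0.5, ddd_hi_score = 50,
                     validity_score = 3L, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_along(rows), function(i) {
    row <- base
    row$gene_id <- sprintf("G%d", i)
    row$symbol <- sprintf("GENE%d", i)
    for (nm in names(rows[[i]])) row[[nm]] <- rows[[i]][[nm]]
    row
  }))
  rownames(out) <- NULL
  out
}

test_that("frequency filter removes strictly above 1% of individuals, by type", {
  locus <- function(sid, type = "DEL", start = 1000L, end = 6000L)
    list(sample_id = sid, type = type, start = start, end = end)
  # 3 of 200 individuals (1.5%) -> removed
  calls <- mk_calls(locus("s1"), locus("s2"), locus("s3"))
  ff <- frequency_filter(calls, 200)
  expect_equal(nrow(ff$removed), 3L)
  expect_equal(nrow(ff$kept), 0L)
  # 2 of 200 (exactly 1.0%) -> kept
  calls2 <- mk_calls(locus("s1"), locus("s2"))
  ff2 <- frequency_filter(calls2, 200)
  expect_equal(nrow(ff2$removed), 0L)
  # type-specific: a DEL where only DUPs are common survives
  calls3 <- mk_calls(locus("s1"), locus("s2", "DUP"), locus("s3", "DUP"),
                     locus("s4", "DUP"), locus("s5", "DUP"))
  ff3 <- frequency_filter(calls3, 200)
  expect_true("DEL" %in% ff3$kept$type)
  expect_equal(sort(unique(ff3$removed$type)), "DUP")
  # permuting sample order changes nothing
  perm <- calls3[sample(nrow(calls3)), ]
  ff4 <- frequency_filter(perm, 200)
  expect_equal(sort(paste(ff4$removed$sample_id, ff4$removed$type)),
               sort(paste(ff3$removed$sample_id, ff3$removed$type)))
})

test_that("reciprocal overlap is required in both directions", {
  big <- list(sample_id = "s1", start = 0L, end = 100000L)
  small1 <- list(sample_id = "s2", start = 1000L, end = 2000L)
  small2 <- list(sample_id = "s3", start = 1000L, end = 2000L)
  small3 <- list(sample_id = "s4", start = 1000L, end = 2000L)
  calls <- mk_calls(big, small1, small2, small3)
  ff <- frequency_filter(calls, 100)
  # the big call overlaps all three small ones, but not reciprocally
  expect_true("s1" %in% ff$kept$sample_id)
  expect_false("s2" %in% ff$kept$sample_id)
})

test_that("gene-list filter keeps 1 bp overlaps, long calls, and prunes Y", {
  genes <- mk_genes(list(start = 5999L, end = 9000L, ern_lists = "RND"))
  # 1 bp overlap with a listed gene
  calls <- mk_calls(list(start = 1000L, end = 6000L))
  expect_equal(nrow(gene_list_filter(calls, genes, "RND")), 1L)
  # gene desert
  calls2 <- mk_calls(list(start = 20000L, end = 25000L))
  expect_equal(nrow(gene_list_filter(calls2, genes, "RND")), 0L)
  # wrong ERN list
  expect_equal(nrow(gene_list_filter(calls, genes, "GENTURIS")), 0L)
  # 600 kb duplication with no listed gene survives as long
  calls3 <- mk_calls(list(start = 1000000L, end = 1600001L, type = "DUP",
                          copy_number = 3L))
  expect_equal(nrow(gene_list_filter(calls3, genes, "RND")), 1L)
  # chrY: only long calls survive
  ycalls <- mk_calls(list(chrom = "Y", start = 1000L, end = 6000L),
                     list(chrom = "Y", start = 1000000L, end = 1600001L))
  ygenes <- mk_genes(list(chrom = "Y", start = 500L, end = 8000L))
  kept <- gene_list_filter(ycalls, ygenes, "RND")
  expect_equal(nrow(kept), 1L)
  expect_gt(kept$end - kept$start, 500000)
})

test_that("the six classes are assigned with the documented precedence", {
  genes <- mk_genes(list(inheritance = "AD"),
                    list(start = 100000L, end = 110000L, inheritance = "AR"))
  snv <- data.frame(sample_id = "s1", gene_id = "G2", symbol = "GENE2",
                    chrom = "1", pos = 100100L, zygosity = "heterozygous",
                    pathogenic = TRUE, high_impact = TRUE)
  calls <- mk_calls(
    list(start = 1000L, end = 601001L),                      # LONG
    list(start = 1000L, end = 2000L, copy_number = 0L),      # HOM_DEL
    list(start = 1000L, end = 2000L),                        # HET_AD (AD gene)
    list(start = 1000L, end = 2000L, copy_number = 5L,
         type = "DUP"),                                      # HIGH_CN
    list(chrom = "X", start = 1000L, end = 2000L, type = "DUP",
         copy_number = 3L),                                  # GONOSOMAL
    list(start = 100000L, end = 101000L))                    # DOUBLE_HIT
  cls <- classify_calls(calls, genes, snv)
  expect_equal(cls, c("LONG", "HOM_DEL", "HET_AD", "HIGH_CN", "GONOSOMAL",
                      "DOUBLE_HIT"))
  # precedence: a long gonosomal homozygous deletion is LONG
  mix <- mk_calls(list(chrom = "X", start = 0L, end = 700000L,
                       copy_number = 0L))
  expect_equal(classify_calls(mix, genes, snv), "LONG")
  # gonosomal beats homozygous-deletion
  mix2 <- mk_calls(list(chrom = "X", start = 0L, end = 1000L,
                        copy_number = 0L))
  expect_equal(classify_calls(mix2, genes, snv), "GONOSOMAL")
  # SVD z calls class by sign (DEL -> CN1, DUP -> CN3)
  zcall <- mk_calls(list(copy_number = NA_integer_, caller = "conifer"))
  expect_equal(classify_calls(zcall, genes, snv), "HET_AD")
  # an autosomal CN2 segment fits no class
  neutral <- mk_calls(list(copy_number = 2L, start = 20000L, end = 21000L))
  expect_true(is.na(classify_calls(neutral, genes, snv)))
})

test_that("double-hit matching needs het deletion + het SNV in one AR gene", {
  genes <- mk_genes(list(inheritance = "AR"),
                    list(start = 100000L, end = 110000L, inheritance = "AD"))
  snv <- data.frame(sample_id = c("s1", "s1", "s2"),
                    gene_id = c("G1", "G2", "G1"),
                    symbol = c("GENE1", "GENE2", "GENE1"),
                    chrom = "1", pos = 600L,
                    zygosity = "heterozygous",
                    pathogenic = TRUE, high_impact = FALSE)
  # het DEL in the AR gene of the same sample: one pair
  calls <- mk_calls(list(start = 1000L, end = 2000L))
  dh <- double_hit_match(calls, snv, genes)
  expect_equal(nrow(dh), 1L)
  expect_equal(dh$gene_id, "G1")
  expect_equal(dh$sample_id, "s1")
  # the same CNV in an AD gene: no pair
  calls_ad <- mk_calls(list(start = 100000L, end = 101000L))
  expect_equal(nrow(double_hit_match(calls_ad, snv, genes)), 0L)
  # homozygous deletions never pair
  calls_hom <- mk_calls(list(start = 1000L, end = 2000L, copy_number = 0L))
  expect_equal(nrow(double_hit_match(calls_hom, snv, genes)), 0L)
  # non-pathogenic or homozygous SNVs do not pair
  snv2 <- snv; snv2$pathogenic <- FALSE; snv2$high_impact <- FALSE
  expect_equal(nrow(double_hit_match(calls, snv2, genes)), 0L)
  snv3 <- snv; snv3$zygosity <- "homozygous"
  expect_equal(nrow(double_hit_match(calls, snv3, genes)), 0L)
})

test_that("double-hit matching recovers exactly the simulator's pairs", {
  coh <- small_cohort()
  tr <- coh$truth
  dels <- tr[tr$copy_number == 1L & tr$chrom %in% as.character(1:22), ]
  calls <- data.frame(sample_id = dels$sample_id, chrom = dels$chrom,
                      start = dels$start, end = dels$end, copy_number = 1L,
                      type = "DEL", caller = "clincnv", quality = 50,
                      n_windows = 3L)
  dh <- double_hit_match(calls, coh$snv, coh$genes)
  expect_setequal(paste(dh$sample_id, dh$gene_id),
                  paste(coh$snv$sample_id, coh$snv$gene_id))
})

test_that("EURO-NMD discards loss-tolerant genes, weak and recessive-only calls", {
  genes <- mk_genes(list(ddd_hi_score = 95, ern_lists = "EURO-NMD"),
                    list(start = 20000L, end = 30000L, pli = 0.05,
                         ern_lists = "EURO-NMD"),
                    list(start = 50000L, end = 60000L, inheritance = "AR",
                         ern_lists = "EURO-NMD"),
                    list(start = 80000L, end = 90000L, pli = 0.9,
                         ddd_hi_score = 20, ern_lists = "EURO-NMD"))
  calls <- mk_calls(
    list(start = 1000L, end = 2000L),                       # HI 95 -> out
    list(start = 21000L, end = 22000L),                     # pLI .05 -> out
    list(start = 51000L, end = 52000L),                     # AR-only -> out
    list(start = 81000L, end = 82000L, quality = 25),       # loglik < 30 -> out
    list(start = 81000L, end = 82000L, quality = 40))       # retained
  calls$class <- c("HET_AD", "HET_AD", "HET_AD", "HET_AD", "HET_AD")
  res <- apply_ern_strategy(calls, "EURO-NMD", genes)
  expect_equal(res$discard, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_match(res$discard_reason[1], "HI/pLI")
  expect_match(res$discard_reason[4], "log likelihood")
})

test_that("GENTURIS tiers by multi-tool support and single-tool thresholds", {
  genes <- mk_genes(list(ern_lists = "GENTURIS"))
  calls <- mk_calls(
    list(start = 1000L, end = 2000L, quality = 5),                 # clincnv weak
    list(start = 1000L, end = 2000L, caller = "exomedepth",
         quality = 5),                                             # multi-tool
    list(start = 30000L, end = 31000L, quality = 25),              # clincnv only
    list(start = 40000L, end = 41000L, caller = "exomedepth",
         quality = 16),                                            # exo only
    list(start = 50000L, end = 51000L, caller = "exomedepth",
         quality = 10))                                            # exo weak
  calls$class <- "HET_AD"
  res <- apply_ern_strategy(calls, "GENTURIS", genes)
  expect_equal(res$tier[1:2], c("tier1", "tier1"))
  expect_equal(res$tier[3:4], c("tier2", "tier2"))
  expect_true(res$discard[5])
})

test_that("ITHACA applies size cut-offs with de novo and homozygous exemptions", {
  genes <- mk_genes(list(ern_lists = "ITHACA", validity_score = 4L),
                    list(start = 50000L, end = 60000L, ern_lists = "ITHACA",
                         validity_score = 1L))
  calls <- mk_calls(
    list(start = 1000L, end = 9000L),                         # 8 kb DEL -> out
    list(start = 1000L, end = 9000L),                         # 8 kb de novo -> kept
    list(start = 1000L, end = 9000L, copy_number = 0L),       # hom del -> kept
    list(start = 1000L, end = 16000L, type = "DUP",
         copy_number = 3L),                                   # 15 kb DUP -> out
    list(start = 51000L, end = 63000L),                       # low validity
    list(start = 1000000L, end = 1250000L))                   # >= 200 kb
  calls$class <- c("HET_AD", "HET_AD", "HOM_DEL", "HET_AD", "HET_AD", "HET_AD")
  calls$de_novo <- c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  res <- apply_ern_strategy(calls, "ITHACA", genes)
  expect_true(res$discard[1])
  expect_false(res$discard[2])
  expect_false(res$discard[3])
  expect_true(res$discard[4])
  expect_false(res$discard[5])
  expect_equal(res$tier[5], "retained")   # low validity, not prioritised
  expect_equal(res$tier[2], "priority")   # validity 4 gene
  expect_false(res$discard[6])
  # blacklist and benign flags discard
  calls$blacklist <- c(FALSE, TRUE, rep(FALSE, 4))
  res2 <- apply_ern_strategy(calls, "ITHACA", genes)
  expect_true(res2$discard[2])
})

test_that("RND filters by tool metrics with cross-tool rescue", {
  genes <- mk_genes(list(ern_lists = "RND"))
  calls <- mk_calls(
    list(start = 1000L, end = 2000L, quality = 25),             # loglik<30 -> out
    list(start = 30000L, end = 31000L, quality = 250),          # priority
    list(start = 50000L, end = 51000L, caller = "conifer",
         quality = 1.9, copy_number = NA_integer_),             # kept (no metric)
    list(start = 70000L, end = 71000L, caller = "exomedepth",
         quality = 40, n_windows = 2L),                         # <3 targets -> out
    list(start = 90000L, end = 91000L, caller = "exomedepth",
         quality = 20, n_windows = 5L),                         # BF<30 -> out
    list(start = 110000L, end = 111000L, caller = "exomedepth",
         quality = 40, n_windows = 2L),                         # rescued below
    list(start = 110000L, end = 111000L, caller = "clincnv",
         quality = 100))                                        # overlapping
  calls$class <- "HET_AD"
  res <- apply_ern_strategy(calls, "RND", genes)
  expect_true(res$discard[1])
  expect_equal(res$tier[2], "priority")
  expect_false(res$discard[3])
  expect_true(res$discard[4])
  expect_true(res$discard[5])
  expect_false(res$discard[6])   # overlapped by another caller
  expect_error(apply_ern_strategy(calls, "NOT-AN-ERN", genes), "unknown ERN")
})
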