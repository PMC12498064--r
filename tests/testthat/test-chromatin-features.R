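test_that("OCR locality follows the strand-aware TSS-3kb/TTS window", {
  genes <- data.table::data.table(chrom = "chr1", start = 10000L,
                                  end = 20000L, strand = "+",
                                  gene_id = "g1")
  peaks <- data.table::data.table(chrom = "chr1",
                                  start = c(6000L, 9500L, 20500L),
                                  end = c(6500L, 10200L, 21000L))
  got <- classify_ocrs(peaks, genes)
  # window is [7000, 20000): upstream peak distal, straddling peak local,
  # downstream-of-TTS peak distal
  expect_equal(got$locality, c("distal", "local", "distal"))
  # minus-strand gene: window is [start, end + 3000)
  genes_m <- data.table::data.table(chrom = "chr1", start = 10000L,
                                    end = 20000L, strand = "-",
                                    gene_id = "g1")
  got_m <- classify_ocrs(peaks, genes_m)
  expect_equal(got_m$locality, c("distal", "local", "local"))
  # empty gene list: everything distal
  expect_true(all(classify_ocrs(peaks,
                                genes[0])$locality == "distal"))
  # unknown strand warns and is treated as plus
  genes_u <- data.table::copy(genes); genes_u$strand <- "."
  expect_warning(got_u <- classify_ocrs(peaks, genes_u), "strand")
  expect_equal(got_u$locality, got$locality)
})

test_that("peak enrichment is signal minus background per base", {
  sig <- data.table::data.table(chrom = "chr1", start = 0L, end = 1000L,
                                value = 5)
  bg <- data.table::data.table(chrom = "chr1", start = 0L, end = 1000L,
                               value = 2)
  region <- data.table::data.table(chrom = "chr1", start = 100L, end = 300L)
  expect_equal(peak_enrichment(sig, bg, region), 3)
  expect_equal(peak_enrichment(sig, sig, region), 0)
  expect_error(peak_enrichment(sig, bg,
                               data.table::data.table(chrom = "chr1",
                                                      start = 900L,
                                                      end = 1200L)),
               "outside")
  # planted peaks enrich over methylation background; random regions do not
  cfg <- sim_config(n_chroms = 1, chrom_length_bp = 4e6, bin_size_bp = 4e4,
                    genes_per_chrom = 40, seed = 5)
  tr <- make_genome(cfg)
  tk <- simulate_tracks(tr, cfg, "control")
  pk <- tk$peaks$ATAC[1:10, c("chrom", "start", "end")]
  enr <- peak_enrichment(tk$tracks$ATAC, tk$tracks$methylation, pk)
  expect_true(all(enr > 1))
  set.seed(9)
  rnd_start <- as.integer(seq(1e5, 3.9e6, length.out = 20)) + 13L
  rnd <- data.table::data.table(chrom = "chr1", start = rnd_start,
                                end = rnd_start + 400L)
  enr_rnd <- peak_enrichment(tk$tracks$ATAC, tk$tracks$ATAC, rnd)
  expect_true(all(abs(enr_rnd) < 1e-9))
})

test_that("differential regions gate on the stated fold-change and FDR rules", {
  # identical tables: nothing significant
  A <- matrix(rpois(200, 50), ncol = 2)
  d0 <- differential_regions(A, A, c(1e6, 1e6), c(1e6, 1e6))
  expect_equal(sum(d0$significant), 0)
  # CPM ~100 vs ~12.5: log2 (101/13.5) = 2.90 > 0.5
  A1 <- matrix(c(99, 100, 101, 100, 99, 101), ncol = 3, byrow = TRUE)
  B1 <- matrix(c(12, 12.5, 13, 12.5, 12, 13), ncol = 3, byrow = TRUE)
  # embed in a null background so BH has something to adjust over
  An <- rbind(A1, matrix(rpois(300, 50), ncol = 3))
  Bn <- rbind(B1, matrix(rpois(300, 50), ncol = 3))
  d1 <- differential_regions(An, Bn, rep(1e6, 3), rep(1e6, 3))
  expect_equal(d1$log2fc[1], log2(101 / 13.5), tolerance = 1e-6)
  expect_true(d1$significant[1])
  expect_equal(d1$direction[1], "A-enriched")
  # single replicates fall back to the exact count test
  d2 <- differential_regions(matrix(c(200, 50)), matrix(c(40, 50)),
                             1e6, 1e6)
  expect_true(d2$significant[1])
  expect_false(d2$significant[2])
})

test_that("differential-region and DEG null error rates are controlled", {
  set.seed(31)
  fp_dar <- replicate(3, {
    A <- matrix(rpois(3000, 60), ncol = 3)
    B <- matrix(rpois(3000, 60), ncol = 3)
    d <- differential_regions(A, B, rep(1e6, 3), rep(1e6, 3))
    mean(d$significant)
  })
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lte(mean(fp_dar), 0.05 + 2 * se)
  # DEG null: generator with no planted effects
  cfg0 <- sim_config(n_chroms = 1, chrom_length_bp = 4e6, bin_size_bp = 4e4,
                     genes_per_chrom = 1000, n_flipped_blocks = 0,
                     deg_fold = 1, seed = 41)
  tr0 <- make_genome(cfg0)
  fp_deg <- sapply(1:3, function(k) {
    cfg_k <- cfg0; cfg_k$seed <- 41L + k
    dg <- deg_call(simulate_expression(tr0, cfg_k, 3))
    mean(dg$call != "ns")
  })
  se_deg <- sqrt(0.01 * 0.99 / 1000)
  expect_lte(mean(fp_deg), 0.01 + 2 * se_deg)
})

test_that("DEG calling recovers planted folds and classes expression levels", {
  fx_cfg <- sim_config(n_chroms = 2, chrom_length_bp = 5e6,
                       bin_size_bp = 4e4, genes_per_chrom = 500, seed = 51)
  tr <- make_genome(fx_cfg)
  dg <- deg_call(simulate_expression(tr, fx_cfg, 3))
  planted <- tr$planted_deg$gene_id
  called <- dg$gene_id[dg$call != "ns"]
  expect_gte(mean(planted %in% called), 0.9)
  expect_lte(mean(!(called %in% planted)), 0.05)
  # class gates on constructed rows
  tbl <- data.table::data.table(
    gene_id = c("hi", "same", "low"),
    control_1 = c(300, 120, 0.5), control_2 = c(290, 121, 0.6),
    treatment_1 = c(310, 120, 0.2), treatment_2 = c(305, 119, 0.15))
  out <- deg_call(tbl)
  expect_equal(out$class_a, c("high", "high", "non-expressed"))
  expect_equal(out$class_b, c("high", "high", "non-expressed"))
  expect_equal(out$call[2], "ns")
})

test_that("histone four-case classification and precedence", {
  regions <- data.table::data.table(chrom = "chr1",
                                    start = c(0, 1000, 2000, 3000, 4000) * 10L,
                                    end = c(0, 1000, 2000, 3000, 4000) * 10L + 500L)
  pk <- function(starts) data.table::data.table(
    chrom = "chr1", start = starts, end = starts + 500L)
  peaksets <- list(
    H3K4me3 = pk(c(20000, 30000)),          # regions 3 and 4
    H3K9ac = pk(c(20000, 40000)),           # regions 3 and 5
    H3K27me3 = pk(c(0)))                    # region 1
  got <- classify_histone_cases(regions, peaksets)
  # region 1: K27 only -> Case 1; region 2: nothing -> Case 2;
  # region 3: K4+K9 -> Case 3; region 4: K4 only -> Case 3 (active);
  # region 5: K9 only -> Case 4
  expect_equal(got$case, c(1L, 2L, 3L, 3L, 4L))
  # precedence: full K27 cover beats partial active cover
  mixed <- data.table::data.table(chrom = "chr1", start = 0L, end = 1000L)
  ps <- list(H3K4me3 = pk(0)[, .(chrom, start, end = 100L)],
             H3K9ac = pk(integer(0)),
             H3K27me3 = data.table::data.table(chrom = "chr1", start = 0L,
                                               end = 1000L))
  expect_equal(classify_histone_cases(mixed, ps)$case, 1L)
  # active dominance when K27 touch is marginal
  ps2 <- list(H3K4me3 = data.table::data.table(chrom = "chr1", start = 0L,
                                               end = 900L),
              H3K9ac = data.table::data.table(chrom = "chr1", start = 0L,
                                              end = 900L),
              H3K27me3 = data.table::data.table(chrom = "chr1", start = 950L,
                                                end = 1000L))
  expect_equal(classify_histone_cases(mixed, ps2)$case, 3L)
})

test_that("enhancer calls exclude promoter windows and track differential marks", {
  genes <- data.table::data.table(chrom = "chr1", start = 50000L,
                                  end = 60000L, strand = "+",
                                  gene_id = "g1")
  regions <- data.table::data.table(chrom = "chr1",
                                    start = c(48000L, 20000L),
                                    end = c(48500L, 20500L))
  peaksets <- list(H3K4me3 = regions[1:2], H3K9ac = regions[1:2],
                   H3K27me3 = regions[0])
  cases <- classify_histone_cases(regions, peaksets)
  enh <- call_enhancers(cases, genes)
  # region at 48 kb is inside the TSS +/- 3 kb window -> excluded;
  # region at 20 kb (10 kb+ from the TSS) retained
  expect_equal(enh$start, 20000L)
  # enhancer set is disjoint from all promoter windows
  prom <- gene_promoter_window(genes)
  expect_equal(sum(chromarch:::overlaps_any(enh$chrom, enh$start, enh$end,
                                            prom)), 0)
  # synthetic condition-specific K9ac gains surface as B-gains
  dr <- data.table::data.table(chrom = "chr1", start = 19900L, end = 20600L,
                               significant = TRUE, direction = "B-enriched")
  de <- differential_enhancers(enh, list(H3K9ac = dr))
  expect_equal(de$status_H3K9ac, "B-gain")
})

test_that("metaprofiles are anchored, strand-flipped and NA-padded at edges", {
  # constant track -> flat profile
  trk <- data.table::data.table(chrom = "chr1", start = 0L, end = 100000L,
                                value = 2.5)
  anchors <- data.table::data.table(chrom = "chr1", pos = c(30000L, 60000L),
                                    strand = c("+", "+"))
  mp <- metaprofile(trk, anchors, flank_bp = 3000, bin_bp = 50)
  expect_true(all(abs(mp$profile - 2.5) < 1e-9))
  expect_equal(length(mp$profile), 120)
  # single asymmetric bump: mirror-symmetric between strands (oracle:
  # direct indexing of the track)
  bump <- data.table::data.table(chrom = "chr1",
                                 start = c(0L, 30000L, 30500L),
                                 end = c(30000L, 30500L, 100000L),
                                 value = c(0, 8, 0))
  a_plus <- data.table::data.table(chrom = "chr1", pos = 30000L, strand = "+")
  a_minus <- data.table::data.table(chrom = "chr1", pos = 30500L, strand = "-")
  mp_p <- metaprofile(bump, a_plus, flank_bp = 2000, bin_bp = 50)
  mp_m <- metaprofile(bump, a_minus, flank_bp = 2000, bin_bp = 50)
  # both anchors sit at the gene-oriented upstream edge of the bump, so
  # after the internal strand flip the profiles coincide
  expect_equal(mp_p$profile, mp_m$profile, tolerance = 1e-9)
  expect_equal(max(mp_p$profile), 8)
  # direct-indexing oracle for the + profile
  expect_equal(unname(mp_p$profile[41:50]), rep(8, 10))
  expect_true(all(mp_p$profile[1:40] == 0))
  # anchor near the chromosome start: NA padding, excluded from means
  a_edge <- data.table::data.table(chrom = "chr1", pos = 1000L, strand = "+")
  mp_e <- metaprofile(trk, a_edge, flank_bp = 3000, bin_bp = 50)
  expect_true(any(is.na(mp_e$matrix)))
})

test_that("strong differential regions agree with an independent limma analysis", {
  set.seed(77)
  n <- 200
  lamA <- rep(60, n); lamB <- rep(60, n)
  up <- 1:10; dn <- 11:20
  lamA[up] <- 480; lamB[dn] <- 480   # 8-fold planted effects
  A <- sapply(1:3, function(i) rpois(n, lamA))
  B <- sapply(1:3, function(i) rpois(n, lamB))
  got <- differential_regions(A, B, rep(1e6, 3), rep(1e6, 3))
  # independent route: limma moderated t on the same log-CPM matrix
  logcpm <- log2(cbind(A, B) + 1)   # equal library sizes
  design <- cbind(intercept = 1, condB = rep(c(0, 1), each = 3))
  fit <- limma::eBayes(limma::lmFit(logcpm, design))
  tt <- limma::topTable(fit, coef = "condB", number = n, sort.by = "none")
  limma_sig <- which(tt$adj.P.Val < 0.05 & abs(tt$logFC) > 0.5)
  welch_sig <- which(got$significant)
  # the two routes use different variance models (per-region Welch vs
  # moderated), so demand near-agreement: no false positives on either
  # route and at most two planted effects missed by either
  expect_true(all(welch_sig %in% c(up, dn)))
  expect_true(all(limma_sig %in% c(up, dn)))
  expect_gte(length(welch_sig), 18)
  expect_gte(length(limma_sig), 18)
  expect_lte(length(setdiff(union(welch_sig, limma_sig),
                            intersect(welch_sig, limma_sig))), 2)
  # directions agree on every called region
  expect_true(all(got$direction[up] == "A-enriched"))
  expect_true(all(got$direction[dn] == "B-enriched"))
  expect_true(all(tt$logFC[up] < 0) && all(tt$logFC[dn] > 0))
})
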