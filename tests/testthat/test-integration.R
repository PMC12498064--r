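test_that("switched-bin gene association matches enumeration", {
  sw_tab <- data.table::data.table(
    chrom = "chr1", bin = 0:3, start = (0:3) * 1000L, end = (1:4) * 1000L,
    label_control = c("A", "B", "A", "B"),
    label_treatment = c("A", "A", "A", "B"),
    pattern = c("A2A", "B2A", "A2A", "B2B"))
  switches <- structure(list(table = sw_tab,
                             counts = c(A2A = 2, A2B = 0, B2A = 1, B2B = 1,
                                        "NA" = 0)), class = "SwitchTable")
  genes <- data.table::data.table(
    chrom = "chr1", start = c(1100L, 1500L, 3200L), end = c(1300L, 1800L, 3600L),
    strand = "+", gene_id = c("d1", "d2", "n1"))
  degs <- data.table::data.table(gene_id = c("d1", "d2", "n1"),
                                 call = c("A-enriched", "B-enriched", "ns"),
                                 q = c(1e-4, 1e-3, 0.5), fc = c(4, 3, 1))
  got <- genes_in_switched_bins(switches, genes, degs)
  expect_setequal(got$genes$gene_id, c("d1", "d2"))
  expect_true(all(got$genes$pattern == "B2A"))
  expect_equal(got$counts[pattern == "B2A"]$n_deg, 2)
  # no switched bins -> empty
  sw0 <- switches
  sw0$table$pattern <- "A2A"
  expect_equal(nrow(genes_in_switched_bins(sw0, genes, degs)$genes), 0)
})

test_that("planted flip-coupled DEGs are recovered through the switch association", {
  fx <- fixture("comp")
  dens <- gene_density_track(fx$truth$genes, fx$map_control)
  trkA <- call_compartments(fx$map_control, dens)
  trkB <- call_compartments(fx$map_treatment, dens)
  sw <- classify_switches(trkA, trkB)
  dg <- deg_call(simulate_expression(fx$truth, fx$cfg, 3))
  got <- genes_in_switched_bins(sw, fx$truth$genes, dg)
  # genes whose TSS block flipped are planted DEGs; the association must
  # contain the DEG subset of genes inside recovered switched bins
  flip_genes <- with(fx$truth, {
    gw <- gr_from_bed_test(genes)
    fb <- gr_from_bed_test(data.table::data.table(
      chrom = flipped_blocks$chrom,
      start = flipped_blocks$start_bin * fx$cfg$bin_size_bp,
      end = flipped_blocks$end_bin * fx$cfg$bin_size_bp))
    genes$gene_id[GenomicRanges::countOverlaps(gw, fb) > 0]
  })
  expect_gte(mean(flip_genes %in% got$genes$gene_id), 0.9)
})

test_that("dOCR-gene links equal a brute-force anchors-by-dOCRs oracle", {
  for (seed in 1:25) {
    fx <- random_link_fixture(seed)
    got <- docr_gene_loops(fx$loops, fx$ocrs, fx$genes)
    ig <- fx$loops[fx$loops$class == "intergenic-gene"]
    docrs <- fx$ocrs[fx$ocrs$locality == "distal"]
    if (nrow(ig) == 0) {
      expect_equal(got$n_intergenic_anchors, 0L)
      next
    }
    # oracle: double loop over intergenic anchors x dOCRs
    linked <- logical(nrow(ig))
    for (i in seq_len(nrow(ig))) {
      s <- if (ig$anchor1_gene[i]) ig$start2[i] else ig$start1[i]
      e <- if (ig$anchor1_gene[i]) ig$end2[i] else ig$end1[i]
      linked[i] <- any(docrs$start < e & docrs$end > s)
    }
    expect_equal(got$n_intergenic_anchors, nrow(ig))
    expect_equal(got$n_linked_anchors, sum(linked))
    expect_equal(sort(got$per_loop$loop[got$per_loop$linked]),
                 sort(ig$name[linked]))
    expect_equal(got$anchored_fraction,
                 round(100 * sum(linked) / nrow(ig), 1))
  }
})

test_that("anchored fraction pools per-tissue counts the way totals do", {
  expect_equal(pooled_pct(c(223, 487), c(6455, 10878)), 4.1)
  expect_equal(pooled_pct(0, 100), 0)
  expect_error(pooled_pct(1, 0), "positive")
})

test_that("dOCR activity classing follows openness and flanking H3K27me3", {
  docrs <- data.table::data.table(chrom = "chr1",
                                  start = c(1000L, 20000L, 50000L, 80000L),
                                  end = c(1400L, 20400L, 50400L, 80400L),
                                  ocr_id = sprintf("d%d", 1:4))
  atac <- data.table::data.table(chrom = "chr1", start = 900L, end = 1500L,
                                 significant = TRUE, direction = "A-enriched")
  # K27 weaker in B = A-enriched K27 region; 1 kb from dOCR 2
  k27 <- data.table::data.table(chrom = "chr1", start = 21400L, end = 22000L,
                                significant = TRUE, direction = "A-enriched")
  got <- classify_docr_activity(docrs, atac, k27, flank_bp = 2000L)
  expect_equal(got$activity, c("A-active", "B-active", "static", "static"))
  # conflict: both directions -> static with flag
  atac2 <- rbind(atac, data.table::data.table(chrom = "chr1", start = 900L,
                                              end = 1500L, significant = TRUE,
                                              direction = "B-enriched"))
  got2 <- classify_docr_activity(docrs, atac2, k27[0], flank_bp = 2000L)
  expect_equal(got2$activity[1], "static")
  expect_true(got2$conflict[1])
  # antisymmetry under swapping the condition labels
  swap <- function(dr) {
    dr <- data.table::copy(dr)
    dr[, direction := ifelse(direction == "A-enriched", "B-enriched",
                             "A-enriched")]
    dr
  }
  got_sw <- classify_docr_activity(docrs, swap(atac), swap(k27),
                                   flank_bp = 2000L)
  expect_equal(got_sw$activity,
               ifelse(got$activity == "A-active", "B-active",
                      ifelse(got$activity == "B-active", "A-active",
                             "static")))
})

test_that("active-dOCR loop participation percentages match the printed arithmetic", {
  activity <- data.table::data.table(ocr_id = sprintf("d%d", 1:964),
                                     activity = "A-active")
  activity$activity[13:964] <- "A-active"
  links <- list(links = data.table::data.table(docr = sprintf("d%d", 1:12)))
  got <- active_docr_loop_rate(activity, links, "A-active")
  expect_equal(got$percent, 1.2)
  expect_equal(got$n_active, 964L)
  # all in links -> 100%
  links_all <- list(links = data.table::data.table(docr = activity$ocr_id))
  expect_equal(active_docr_loop_rate(activity, links_all, "A-active")$percent,
               100)
  # zero active dOCRs -> undefined with flag
  none <- active_docr_loop_rate(activity[0], links, "A-active")
  expect_true(none$undefined)
  expect_true(is.na(none$percent))
})

test_that("TFBS anchor categories match hand enumeration and sum correctly", {
  per_loop <- data.table::data.table(
    loop = c("L1", "L2"), chrom = "chr1",
    ig_start = c(0L, 100000L), ig_end = c(10000L, 110000L),
    gene_start = c(50000L, 200000L), gene_end = c(60000L, 210000L),
    n_docrs = 1L, linked = TRUE)
  links <- structure(list(per_loop = per_loop), class = "DocrGeneLinks")
  motifs <- data.table::data.table(
    chrom = "chr1",
    start = c(500L, 55000L, 105000L, 205000L, 300000L),
    end = c(520L, 55020L, 105020L, 205020L, 300020L),
    motif = c("m1", "m1", "m2", "m2", "m2"))
  got <- tfbs_loop_categories(motifs, links)
  # m1: on L1 both anchors -> Joint; m2: on L2 both anchors -> Joint;
  # the motif off all anchors is not counted
  expect_equal(got$per_link[motif == "m1" & loop == "L1"]$category,
               "Joint TFBS")
  expect_equal(got$per_link[motif == "m2" & loop == "L2"]$category,
               "Joint TFBS")
  expect_equal(nrow(got$per_link), 2)
  # one-sided occurrences
  motifs2 <- data.table::data.table(chrom = "chr1",
                                    start = c(500L, 55000L),
                                    end = c(520L, 55020L),
                                    motif = c("mA", "mB"))
  got2 <- tfbs_loop_categories(motifs2, links)
  expect_equal(got2$per_link[motif == "mA"]$category, "dOCR TFBS")
  expect_equal(got2$per_link[motif == "mB"]$category, "Local TFBS")
  # counts per motif sum to the per-link rows
  expect_equal(sum(got2$counts$N), nrow(got2$per_link))
})

test_that("enhancer-gene links equal a brute-force triple-loop oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    loops <- mk_loopset(data.table::data.table(
      chrom1 = "chr1", start1 = (s1 <- sample(seq(0, 3e5, by = 1e4), 8)),
      end1 = s1 + 1e4,
      chrom2 = "chr1", start2 = (s2 <- s1 + sample(seq(1e5, 2e5, by = 1e4),
                                                   8, replace = TRUE)),
      end2 = s2 + 1e4))
    genes <- data.table::data.table(
      chrom = "chr1", start = sample(seq(0, 5e5, by = 500), 20))
    genes$end <- genes$start + 3000L
    genes$strand <- sample(c("+", "-"), 20, replace = TRUE)
    genes$gene_id <- sprintf("g%d", 1:20)
    enh <- data.table::data.table(
      chrom = "chr1", start = sample(seq(0, 5e5, by = 100), 15))
    enh$end <- enh$start + 600L
    enh$region_id <- sprintf("e%d", 1:15)
    enh$status_H3K9ac <- sample(c("A-gain", "B-gain", "static"), 15,
                                replace = TRUE)
    got <- enhancer_gene_links(enh, loops, genes)
    # oracle: triple loop over enhancers x loops x genes
    prom <- gene_promoter_window(genes)
    want <- list()
    for (e in seq_len(nrow(enh))) for (l in seq_len(nrow(loops))) {
      on1 <- enh$start[e] < loops$end1[l] & enh$end[e] > loops$start1[l]
      on2 <- enh$start[e] < loops$end2[l] & enh$end[e] > loops$start2[l]
      for (g in seq_len(nrow(prom))) {
        p_on1 <- prom$start[g] < loops$end1[l] & prom$end[g] > loops$start1[l]
        p_on2 <- prom$start[g] < loops$end2[l] & prom$end[g] > loops$start2[l]
        if ((on1 && p_on2) || (on2 && p_on1)) {
          want[[length(want) + 1]] <- paste(enh$region_id[e], loops$name[l],
                                            prom$gene_id[g])
        }
      }
    }
    got_keys <- paste(got$region_id, got$loop, got$gene_id)
    want_keys <- unique(unlist(want))
    if (is.null(want_keys)) want_keys <- character(0)
    if (nrow(got) == 0) got_keys <- character(0)
    expect_setequal(got_keys, want_keys)
  }
})

test_that("shifted controls preserve widths, stay on-chromosome and depend on seed", {
  fx <- fixture("comp")
  ocrs <- classify_ocrs(fx$truth$peaks$control$ATAC, fx$truth$genes)
  docrs <- ocrs[ocrs$locality == "distal"]
  sizes <- fx$map_control$chrom_sizes
  ctrl <- shifted_controls(docrs, sizes, seed = 5)
  expect_equal(nrow(ctrl), nrow(docrs))
  expect_equal(sort(ctrl$end - ctrl$start), sort(docrs$end - docrs$start))
  expect_true(all(ctrl$start >= 0 & ctrl$end <= sizes[ctrl$chrom]))
  ctrl2 <- shifted_controls(docrs, sizes, seed = 6)
  expect_false(identical(ctrl$start, ctrl2$start))
  expect_identical(ctrl, shifted_controls(docrs, sizes, seed = 5))
  # planted co-location: real dOCRs overlap loop anchors more than controls
  anchors <- with(fx$truth$loops$control, data.table::data.table(
    chrom = c(chrom, chrom),
    start = c(bin1, bin2) * fx$cfg$bin_size_bp,
    end = (c(bin1, bin2) + 1L) * fx$cfg$bin_size_bp))
  n_real <- sum(chromarch:::overlaps_any(docrs$chrom, docrs$start,
                                         docrs$end, anchors))
  n_ctrl <- sum(chromarch:::overlaps_any(ctrl$chrom, ctrl$start, ctrl$end,
                                         anchors))
  expect_gte(n_real, n_ctrl)
})

test_that("percent change reproduces the printed phenotype arithmetic", {
  expect_equal(percent_change(16.2, 30.7), 89.5)
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(10, 5), -50)
  expect_error(percent_change(0, 5), "positive")
})
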