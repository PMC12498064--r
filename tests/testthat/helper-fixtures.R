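# Shared synthetic fixtures, built lazily and cached across test files.
# Scales: compartment-level maps at 100-kb bins and 5e6 pairs; TAD-level at
# 40-kb bins and 2e7 pairs; loop-level at 10-kb bins and 2e7 pairs on a
# single 10-Mb chromosome.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, switch(
      name,
      comp = {
        cfg <- sim_config(bin_size_bp = 1e5, seed = 101)
        tr <- make_genome(cfg)
        list(cfg = cfg, truth = tr,
             map_control = balance(simulate_contacts(tr, cfg, "control")),
             map_treatment = balance(simulate_contacts(tr, cfg, "treatment")))
      },
      tad = {
        cfg <- sim_config(bin_size_bp = 4e4, sequencing_depth = 2e7,
                          compartment_delta = 0.2, seed = 202)
        tr <- make_genome(cfg)
        list(cfg = cfg, truth = tr,
             map_control = balance(simulate_contacts(tr, cfg, "control")),
             map_treatment = balance(simulate_contacts(tr, cfg, "treatment")))
      },
      loop = {
        cfg <- sim_config(n_chroms = 1, chrom_length_bp = 1e7,
                          bin_size_bp = 1e4, sequencing_depth = 2e7,
                          compartment_delta = 0.2, n_flipped_blocks = 1,
                          n_loops_per_chrom = 30, seed = 303)
        tr <- make_genome(cfg)
        list(cfg = cfg, truth = tr,
             map_control = balance(simulate_contacts(tr, cfg, "control")),
             map_treatment = balance(simulate_contacts(tr, cfg, "treatment")))
      },
      stop("unknown fixture ", name)
    ), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small hand-made contact map: one chromosome from a dense matrix
toy_map <- function(m, resolution = 1000L) {
  contact_map(list(chr1 = m), resolution)
}

# toy map with unit weights (no balancing): raw counts ARE the balanced
# values, so closed-form expectations hold exactly
unit_map <- function(m, resolution = 1000L) {
  cm <- toy_map(m, resolution)
  cm$weights <- list(chr1 = rep(1, nrow(m)))
  cm$mask <- list(chr1 = rep(FALSE, nrow(m)))
  cm$converged <- list(chr1 = TRUE)
  cm
}

# match loop calls against planted bin pairs at a bin tolerance
loop_recall_precision <- function(called, planted, tol = 1) {
  if (nrow(planted) == 0 || nrow(called) == 0) {
    return(c(recall = NA_real_, precision = NA_real_))
  }
  hit <- mapply(function(ch, b1, b2) {
    any(called$chrom1 == ch & abs(called$bin1 - b1) <= tol &
          abs(called$bin2 - b2) <= tol)
  }, planted$chrom, planted$bin1, planted$bin2)
  prec <- mapply(function(ch, b1, b2) {
    any(planted$chrom == ch & abs(planted$bin1 - b1) <= tol &
          abs(planted$bin2 - b2) <= tol)
  }, called$chrom1, called$bin1, called$bin2)
  c(recall = mean(hit), precision = mean(prec))
}

# truth TAD boundaries (interior domain edges) as a boundary-like table
truth_boundaries <- function(truth) {
  tt <- truth$tads$control
  b <- tt[, .(chrom, bin = end_bin)]
  b[bin < truth$n_bins]
}

gr_from_bed_test <- function(df) chromarch:::gr_from_bed(df)

mk_loopset <- function(dt) {
  dt <- data.table::as.data.table(dt)
  if (!"name" %in% names(dt)) dt[, name := sprintf("loop_%d", .I)]
  if (!"score" %in% names(dt)) dt[, score := 1]
  data.table::setattr(dt, "class", c("LoopSet", class(dt)))
  dt
}

random_link_fixture <- function(seed) {
  set.seed(seed)
  k <- 10
  s1 <- sample(seq(0, 4e5, by = 1e4), k)
  s2 <- s1 + sample(seq(1e5, 2e5, by = 1e4), k, replace = TRUE)
  loops <- mk_loopset(data.table::data.table(
    chrom1 = "chr1", start1 = s1, end1 = s1 + 1e4,
    chrom2 = "chr1", start2 = s2, end2 = s2 + 1e4))
  genes <- data.table::data.table(
    chrom = "chr1", start = sample(seq(0, 6e5, by = 500), 25))
  genes$end <- genes$start + sample(2000:6000, 25, replace = TRUE)
  genes$strand <- sample(c("+", "-"), 25, replace = TRUE)
  genes$gene_id <- sprintf("g%d", 1:25)
  ocrs <- data.table::data.table(
    chrom = "chr1", start = sample(seq(0, 6e5, by = 100), 40))
  ocrs$end <- ocrs$start + 400L
  ocrs <- classify_ocrs(ocrs, genes)
  list(loops = classify_loops(loops, genes), genes = genes, ocrs = ocrs)
}

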