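# Synthetic paired-condition multi-omic generator. Every downstream stage
# (compartments, TADs, loops, OCR/enhancer integration) is validated by
# recovering the planted truth emitted here, so the generator is first-class
# tested code, not a fixture.

SIM_CONDITIONS <- c("control", "treatment")

#' Simulation configuration
#'
#' Parameters of the paired-condition genome/contact/track/expression
#' generator. Contacts follow
#' `Lambda_ij = depth_norm * s^-alpha * (1 + delta * e_i * e_j) *
#'  tad_boost^[same TAD] * loop_boost^[anchor pixel]`
#' with Poisson counts; `e_i` is the per-bin compartment sign.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length_bp chromosome length in bp (all chromosomes equal).
#' @param bin_size_bp simulation resolution in bp; must divide the length.
#' @param decay_exponent power-law slope alpha of P(s).
#' @param compartment_delta plaid strength delta in (0,1).
#' @param tad_boost within-domain contact multiplier (>= 1).
#' @param loop_boost loop-anchor pixel multiplier (>= 1).
#' @param n_flipped_blocks compartment blocks whose sign flips between the
#'   two conditions (chosen non-adjacent so each flip is one maximal run).
#' @param tad_edits character vector of "merge"/"split" edits applied to the
#'   treatment TAD partition.
#' @param loop_edits character vector of "gain"/"loss" loop edits
#'   (gain = treatment-only loop, loss = control-only loop).
#' @param sequencing_depth expected total cis read pairs per condition.
#' @param trans_rate fraction of interaction pairs that are trans in
#'   [simulate_interaction_pairs()].
#' @param mean_block_bins mean compartment-block length in bins.
#' @param min_tad_bins,max_tad_bins TAD size range in bins.
#' @param n_loops_per_chrom planted shared loops per chromosome.
#' @param genes_per_chrom gene models per chromosome.
#' @param p_gene_in_A probability a gene is placed in a +1 (A-like) block.
#' @param local_fraction target fraction of ATAC peaks that are local
#'   (TSS-3kb to TTS); remaining peaks are distal.
#' @param deg_fraction fraction of genes (outside flipped blocks) planted as
#'   differentially expressed.
#' @param deg_fold planted expression fold change (1 = no DEGs).
#' @param expr_sdlog replicate log-normal noise (sdlog) of FPKM.
#' @param seed integer master seed; every stage derives its own stream.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(n_chroms = 2,
                       chrom_length_bp = 20e6,
                       bin_size_bp = 40000,
                       decay_exponent = 1.0,
                       compartment_delta = 0.4,
                       tad_boost = 2,
                       loop_boost = 4,
                       n_flipped_blocks = 3,
                       tad_edits = c("merge", "merge", "split"),
                       loop_edits = c("gain", "loss"),
                       sequencing_depth = 5e6,
                       trans_rate = 0.35,
                       mean_block_bins = 12,
                       min_tad_bins = 5,
                       max_tad_bins = 15,
                       n_loops_per_chrom = 15,
                       genes_per_chrom = 150,
                       p_gene_in_A = 0.8,
                       local_fraction = 0.174,
                       deg_fraction = 0.15,
                       deg_fold = 4,
                       expr_sdlog = 0.05,
                       seed = 1) {
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_length_bp = chrom_length_bp,
              bin_size_bp = as.integer(bin_size_bp),
              decay_exponent = decay_exponent,
              compartment_delta = compartment_delta,
              tad_boost = tad_boost, loop_boost = loop_boost,
              n_flipped_blocks = as.integer(n_flipped_blocks),
              tad_edits = tad_edits, loop_edits = loop_edits,
              sequencing_depth = sequencing_depth,
              trans_rate = trans_rate,
              mean_block_bins = mean_block_bins,
              min_tad_bins = as.integer(min_tad_bins),
              max_tad_bins = as.integer(max_tad_bins),
              n_loops_per_chrom = as.integer(n_loops_per_chrom),
              genes_per_chrom = as.integer(genes_per_chrom),
              p_gene_in_A = p_gene_in_A,
              local_fraction = local_fraction,
              deg_fraction = deg_fraction,
              deg_fold = deg_fold,
              expr_sdlog = expr_sdlog,
              seed = as.integer(seed))
  if (cfg$chrom_length_bp <= 0) stop("chrom_length_bp must be positive", call. = FALSE)
  if (cfg$chrom_length_bp %% cfg$bin_size_bp != 0) {
    stop("bin_size_bp must divide chrom_length_bp", call. = FALSE)
  }
  if (cfg$compartment_delta < 0 || cfg$compartment_delta >= 1) {
    stop("compartment_delta must be in [0, 1)", call. = FALSE)
  }
  if (cfg$tad_boost < 1 || cfg$loop_boost < 1) {
    stop("tad_boost and loop_boost must be >= 1", call. = FALSE)
  }
  if (!all(cfg$tad_edits %in% c("merge", "split"))) {
    stop("tad_edits entries must be 'merge' or 'split'", call. = FALSE)
  }
  if (!all(cfg$loop_edits %in% c("gain", "loss"))) {
    stop("loop_edits entries must be 'gain' or 'loss'", call. = FALSE)
  }
  structure(cfg, class = "SimConfig")
}

sim_chrom_names <- function(config) paste0("chr", seq_len(config$n_chroms))

# geometric-length alternating-sign compartment blocks covering n_bins
make_blocks <- function(n_bins, mean_block_bins) {
  lens <- integer(0)
  while (sum(lens) < n_bins) {
    lens <- c(lens, 3L + stats::rgeom(1, 1 / max(1, mean_block_bins - 3)))
  }
  excess <- sum(lens) - n_bins
  lens[length(lens)] <- lens[length(lens)] - excess
  if (lens[length(lens)] < 1) {
    lens <- lens[-length(lens)]
    lens[length(lens)] <- n_bins - sum(lens[-length(lens)])
  }
  start_sign <- sample(c(-1L, 1L), 1)
  signs <- start_sign * (-1L)^(seq_along(lens) - 1)
  ends <- cumsum(lens)
  data.table::data.table(start_bin = c(0L, head(ends, -1)),
                         end_bin = ends, sign = signs)
}

# TAD partition of n_bins into domains of min..max bins
make_tads <- function(n_bins, min_bins, max_bins) {
  lens <- integer(0)
  while (sum(lens) < n_bins) lens <- c(lens, sample(min_bins:max_bins, 1))
  lens[length(lens)] <- n_bins - sum(head(lens, -1))
  if (lens[length(lens)] < min_bins && length(lens) > 1) {
    lens[length(lens) - 1] <- lens[length(lens) - 1] + lens[length(lens)]
    lens <- head(lens, -1)
  }
  ends <- cumsum(lens)
  data.table::data.table(start_bin = c(0L, head(ends, -1)), end_bin = ends)
}

#' Generate a paired-condition genome architecture with planted truth
#'
#' Lays out compartment blocks (geometric lengths, alternating signs) with
#' `n_flipped_blocks` sign flips in the treatment condition, a TAD partition
#' with merge/split edits, shared and condition-specific loops, gene models
#' placed preferentially in +1 (A-like) blocks, planted expression means
#' coupled to compartment state and flips, and planted peak sets (ATAC,
#' H3K4me3, H3K9ac, H3K27me3) plus motif sites. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return An `ArchitectureTruth` list; see Details in the vignette.
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(stage_seed(config$seed, "genome"))
  chroms <- sim_chrom_names(config)
  n_bins <- as.integer(config$chrom_length_bp / config$bin_size_bp)
  bs <- config$bin_size_bp

  ## compartment blocks + flips
  blocks <- data.table::rbindlist(lapply(chroms, function(ch) {
    b <- make_blocks(n_bins, config$mean_block_bins)
    b[, `:=`(chrom = ch)]
    b
  }))
  blocks[, block_id := seq_len(.N)]
  # interior, pairwise non-adjacent flip candidates so each flip stays one
  # maximal differing run
  interior <- blocks[, .I[seq_len(.N) > 1 & seq_len(.N) < .N], by = chrom]$V1
  if (config$n_flipped_blocks > 0) {
    if (length(interior) < config$n_flipped_blocks) {
      stop("not enough interior blocks to flip", call. = FALSE)
    }
    picked <- integer(0)
    pool <- interior
    for (k in seq_len(config$n_flipped_blocks)) {
      if (!length(pool)) stop("cannot place non-adjacent flips", call. = FALSE)
      p <- sample(pool, 1)
      picked <- c(picked, p)
      pool <- setdiff(pool, c(p - 1L, p, p + 1L))
    }
    blocks[, flipped := block_id %in% picked]
  } else {
    blocks[, flipped := FALSE]
  }
  blocks[, sign_control := sign]
  blocks[, sign_treatment := data.table::fifelse(flipped, -sign, sign)]
  blocks[, sign := NULL]

  sign_vec <- function(col) {
    out <- lapply(chroms, function(ch) {
      b <- blocks[chrom == ch]
      v <- integer(n_bins)
      for (i in seq_len(nrow(b))) v[(b$start_bin[i] + 1):b$end_bin[i]] <- b[[col]][i]
      v
    })
    names(out) <- chroms
    out
  }
  comp_sign <- list(control = sign_vec("sign_control"),
                    treatment = sign_vec("sign_treatment"))

  ## TADs
  tads_control <- data.table::rbindlist(lapply(chroms, function(ch) {
    t <- make_tads(n_bins, config$min_tad_bins, config$max_tad_bins)
    t[, chrom := ch]
    t
  }))
  tads_treatment <- data.table::copy(tads_control)
  tad_edit_log <- list()
  for (edit in config$tad_edits) {
    if (edit == "merge") {
      # drop a shared interior boundary: fuse two adjacent treatment TADs
      cand <- tads_treatment[, .I[seq_len(.N) > 1], by = chrom]$V1
      cand <- cand[!(cand %in% unlist(lapply(tad_edit_log, `[[`, "rows")))]
      if (!length(cand)) next
      i <- sample(cand, 1)
      tad_edit_log[[length(tad_edit_log) + 1]] <-
        list(type = "merge", chrom = tads_treatment$chrom[i],
             boundary_bin = tads_treatment$start_bin[i], rows = c(i - 1L, i))
      tads_treatment$end_bin[i - 1L] <- tads_treatment$end_bin[i]
      tads_treatment <- tads_treatment[-i]
    } else {
      cand <- which(tads_treatment$end_bin - tads_treatment$start_bin >=
                      2 * config$min_tad_bins)
      cand <- cand[!(cand %in% unlist(lapply(tad_edit_log, `[[`, "rows")))]
      if (!length(cand)) next
      i <- sample(cand, 1)
      s <- tads_treatment$start_bin[i]; e <- tads_treatment$end_bin[i]
      cut <- sample((s + config$min_tad_bins):(e - config$min_tad_bins), 1)
      tad_edit_log[[length(tad_edit_log) + 1]] <-
        list(type = "split", chrom = tads_treatment$chrom[i],
             boundary_bin = cut, rows = i)
      new <- data.table::data.table(start_bin = c(s, cut), end_bin = c(cut, e),
                                    chrom = tads_treatment$chrom[i])
      tads_treatment <- data.table::rbindlist(
        list(tads_treatment[-i], new), use.names = TRUE)
    }
    data.table::setorder(tads_treatment, chrom, start_bin)
  }

  ## loops (bin pairs, min gap clears the donut ring of the caller)
  make_chrom_loops <- function(ch, n) {
    if (n == 0) return(NULL)
    b1 <- sort(sample(6:(n_bins - 62), n))
    gap <- sample(12:50, n, replace = TRUE)
    data.table::data.table(chrom = ch, bin1 = b1, bin2 = b1 + gap)
  }
  shared_loops <- data.table::rbindlist(
    lapply(chroms, make_chrom_loops, n = config$n_loops_per_chrom))
  shared_loops <- unique(shared_loops)
  loops_control <- data.table::copy(shared_loops)
  loops_treatment <- data.table::copy(shared_loops)
  loop_edit_log <- list()
  for (edit in config$loop_edits) {
    ch <- sample(chroms, 1)
    if (edit == "gain") {
      nl <- make_chrom_loops(ch, 1)
      loops_treatment <- data.table::rbindlist(list(loops_treatment, nl))
      loop_edit_log[[length(loop_edit_log) + 1]] <-
        c(list(type = "gain"), as.list(nl))
    } else {
      i <- sample(which(loops_treatment$chrom == ch), 1)
      loop_edit_log[[length(loop_edit_log) + 1]] <-
        c(list(type = "loss"), as.list(loops_treatment[i]))
      loops_treatment <- loops_treatment[-i]
    }
  }
  data.table::setorder(loops_control, chrom, bin1, bin2)
  data.table::setorder(loops_treatment, chrom, bin1, bin2)

  ## gene models, preferentially in +1 (A-like) control blocks
  genes <- data.table::rbindlist(lapply(chroms, function(ch) {
    sgn <- comp_sign$control[[ch]]
    a_bins <- which(sgn > 0) - 1L
    b_bins <- which(sgn < 0) - 1L
    n <- config$genes_per_chrom
    in_a <- stats::runif(n) < config$p_gene_in_A
    width <- as.integer(round(stats::runif(n, 2000, 8000)))
    pick_bin <- ifelse(in_a,
                       sample(a_bins, n, replace = TRUE),
                       sample(b_bins, n, replace = TRUE))
    offset <- as.integer(floor(stats::runif(n, 0, bs - 1)))
    start <- pmin(pick_bin * bs + offset, config$chrom_length_bp - width - 1)
    data.table::data.table(chrom = ch, start = as.integer(start),
                           end = as.integer(start + width),
                           strand = sample(c("+", "-"), n, replace = TRUE),
                           in_A = in_a)
  }))
  data.table::setorder(genes, chrom, start)
  genes[, gene_id := sprintf("g%04d", seq_len(.N))]

  ## planted expression means, coupled to compartment state and flips
  bin_of <- function(pos, ch) as.integer(pos %/% bs)
  genes[, tss := data.table::fifelse(strand == "+", start, end)]
  gene_sign <- mapply(function(ch, pos) comp_sign$control[[ch]][bin_of(pos, ch) + 1L],
                      genes$chrom, genes$tss)
  gene_sign_trt <- mapply(function(ch, pos) comp_sign$treatment[[ch]][bin_of(pos, ch) + 1L],
                          genes$chrom, genes$tss)
  base_mean <- ifelse(gene_sign > 0, 30, 0.5)
  hi <- which(gene_sign > 0)
  hi <- sample(hi, max(1, round(0.1 * length(hi))))
  base_mean[hi] <- 300
  mean_trt <- base_mean
  flip_dir <- gene_sign_trt - gene_sign   # +2 = B->A, -2 = A->B
  mean_trt[flip_dir > 0] <- base_mean[flip_dir > 0] * config$deg_fold
  mean_trt[flip_dir < 0] <- base_mean[flip_dir < 0] / config$deg_fold
  free <- which(flip_dir == 0)
  n_extra <- round(config$deg_fraction * length(free))
  extra <- if (n_extra > 0) sample(free, n_extra) else integer(0)
  up <- stats::runif(length(extra)) < 0.5
  mean_trt[extra[up]] <- base_mean[extra[up]] * config$deg_fold
  mean_trt[extra[!up]] <- base_mean[extra[!up]] / config$deg_fold
  expr_means <- data.table::data.table(gene_id = genes$gene_id,
                                       control = base_mean,
                                       treatment = mean_trt)
  planted_deg <- expr_means[
    pmax(control, treatment) / pmin(control, treatment) > 1.0001 &
      config$deg_fold > 1]
  genes[, in_A := NULL]

  ## planted peaks per mark per condition
  active_cut <- 5
  local_windows <- gene_local_windows(genes, config$chrom_length_bp)
  peaks <- list()
  for (cond in SIM_CONDITIONS) {
    mu <- expr_means[[cond]]
    act <- which(mu >= active_cut)
    g <- genes[act]
    atac_local <- data.table::data.table(chrom = g$chrom,
                                         start = pmax(0L, g$tss - 200L),
                                         end = g$tss + 200L,
                                         kind = "promoter")
    n_local <- nrow(atac_local)
    n_distal <- max(4L, round(n_local * (1 - config$local_fraction) /
                                config$local_fraction))
    # distal sites: a third at intergenic loop anchors (so dOCR-gene loops
    # exist), the rest uniform away from genic windows
    anchors <- loops_of(cond, loops_control, loops_treatment)
    anchor_pos <- data.table::data.table(
      chrom = rep(anchors$chrom, 2),
      pos = c(anchors$bin1, anchors$bin2) * bs + bs %/% 2)
    anchor_pos <- anchor_pos[!overlaps_any(anchor_pos$chrom, anchor_pos$pos - 200L,
                                           anchor_pos$pos + 200L, local_windows)]
    n_anch <- min(nrow(anchor_pos), round(n_distal / 3))
    distal_rows <- list()
    if (n_anch > 0) {
      sel <- anchor_pos[sample(.N, n_anch)]
      distal_rows[[1]] <- data.table::data.table(chrom = sel$chrom,
                                                 start = sel$pos - 200L,
                                                 end = sel$pos + 200L,
                                                 kind = "distal_anchor")
    }
    need <- n_distal - n_anch
    tries <- 0
    got <- list()
    while (need > 0 && tries < 50) {
      ch <- sample(chroms, 2 * need, replace = TRUE)
      pos <- as.integer(floor(stats::runif(2 * need, 1000, config$chrom_length_bp - 1000)))
      keep <- !overlaps_any(ch, pos - 200L, pos + 200L, local_windows)
      got[[length(got) + 1]] <- data.table::data.table(
        chrom = ch[keep], start = pos[keep] - 200L, end = pos[keep] + 200L,
        kind = "distal")[seq_len(min(sum(keep), need))]
      need <- need - min(sum(keep), need)
      tries <- tries + 1
    }
    distal <- data.table::rbindlist(c(distal_rows, got))
    atac <- data.table::rbindlist(list(atac_local, distal))
    data.table::setorder(atac, chrom, start)

    k4 <- data.table::data.table(chrom = g$chrom,
                                 start = pmax(0L, g$tss - 500L),
                                 end = g$tss + 1000L, kind = "promoter")
    k9 <- data.table::copy(k4)
    # planted enhancers: distal ATAC sites with K9ac (half also K4me3);
    # these are the Case 3 / Case 4 truth
    n_enh <- max(2L, round(0.2 * nrow(distal)))
    enh <- distal[sample(.N, min(n_enh, .N))]
    enh_k9 <- data.table::data.table(chrom = enh$chrom,
                                     start = enh$start - 100L,
                                     end = enh$end + 100L, kind = "enhancer")
    half <- seq_len(nrow(enh_k9)) <= nrow(enh_k9) / 2
    k9 <- data.table::rbindlist(list(k9, enh_k9))
    k4 <- data.table::rbindlist(list(k4, enh_k9[half]))
    rep_blocks <- blocks[get(paste0("sign_", cond)) < 0]
    k27 <- data.table::data.table(chrom = rep_blocks$chrom,
                                  start = rep_blocks$start_bin * bs,
                                  end = rep_blocks$end_bin * bs,
                                  kind = "block")
    peaks[[cond]] <- list(ATAC = atac, H3K4me3 = k4[order(chrom, start)],
                          H3K9ac = k9[order(chrom, start)],
                          H3K27me3 = k27[order(chrom, start)])
  }

  ## motif sites: one motif on loop-anchor bins, one at promoters
  anchors_all <- unique(data.table::rbindlist(list(
    loops_control[, .(chrom, bin = bin1)], loops_control[, .(chrom, bin = bin2)])))
  motifs <- data.table::rbindlist(list(
    data.table::data.table(chrom = anchors_all$chrom,
                           start = anchors_all$bin * bs + bs %/% 2 - 10L,
                           end = anchors_all$bin * bs + bs %/% 2 + 10L,
                           motif = "motif_anchor"),
    data.table::data.table(chrom = genes$chrom,
                           start = pmax(0L, genes$tss - 50L),
                           end = genes$tss - 30L,
                           motif = "motif_promoter")))

  structure(list(
    config = config,
    chroms = chroms, n_bins = n_bins,
    comp_sign = comp_sign, blocks = blocks[],
    flipped_blocks = blocks[flipped == TRUE][],
    tads = list(control = tads_control[], treatment = tads_treatment[]),
    tad_edits = tad_edit_log,
    loops = list(control = loops_control[], treatment = loops_treatment[]),
    loop_edits = loop_edit_log,
    genes = genes[, .(chrom, start, end, strand, gene_id, tss)],
    expr_means = expr_means,
    planted_deg = planted_deg,
    peaks = peaks,
    motifs = motifs[order(chrom, start)]
  ), class = "ArchitectureTruth")
}

loops_of <- function(cond, loops_control, loops_treatment) {
  if (cond == "control") loops_control else loops_treatment
}

# strand-aware local windows (TSS - 3 kb through TTS) as a data.table
gene_local_windows <- function(genes, chrom_length_bp = NULL, upstream = 3000L) {
  w <- data.table::data.table(
    chrom = genes$chrom,
    start = as.integer(ifelse(genes$strand == "-", genes$start,
                              pmax(0L, genes$start - upstream))),
    end = as.integer(ifelse(genes$strand == "-", genes$end + upstream,
                            genes$end)),
    gene_id = genes$gene_id)
  if (!is.null(chrom_length_bp)) w[, end := pmin(end, chrom_length_bp)]
  w
}

overlaps_any <- function(chrom, start, end, windows) {
  if (length(chrom) == 0) return(logical(0))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  s <- gr_from_bed(windows)
  GenomicRanges::countOverlaps(q, s) > 0
}

#' Simulate a Poisson contact map for one condition
#'
#' Expected counts follow a power-law distance decay modulated by the
#' planted compartment plaid, TAD blocks and loop pixels; the total over
#' cis pixels is normalized to `sequencing_depth`. Counts are independent
#' Poisson draws (upper triangle, mirrored), deterministic given the seed.
#'
#' @param truth an [make_genome()] truth.
#' @param config the same [sim_config()].
#' @param condition "control" or "treatment".
#' @return an unbalanced [contact_map()].
#' @export
simulate_contacts <- function(truth, config, condition = "control") {
  condition <- match.arg(condition, SIM_CONDITIONS)
  set.seed(stage_seed(config$seed, paste0("contacts_", condition)))
  n <- truth$n_bins
  alpha <- config$decay_exponent
  lam <- list()
  for (ch in truth$chroms) {
    e <- truth$comp_sign[[condition]][[ch]]
    D <- abs(outer(seq_len(n), seq_len(n), "-"))
    base <- pmax(D, 0.5)^(-alpha)
    plaid <- 1 + config$compartment_delta * outer(e, e)
    tt <- truth$tads[[condition]][chrom == ch]
    dom <- integer(n)
    for (i in seq_len(nrow(tt))) dom[(tt$start_bin[i] + 1):tt$end_bin[i]] <- i
    same_tad <- outer(dom, dom, "==") & dom > 0
    M <- base * plaid
    M[same_tad] <- M[same_tad] * config$tad_boost
    lp <- truth$loops[[condition]][chrom == ch]
    if (nrow(lp)) {
      idx <- cbind(lp$bin1 + 1L, lp$bin2 + 1L)
      M[idx] <- M[idx] * config$loop_boost
      M[idx[, 2:1, drop = FALSE]] <- M[cbind(idx[, 2], idx[, 1])] # keep symmetric
    }
    lam[[ch]] <- M
  }
  tot <- sum(vapply(lam, function(M) sum(M[upper.tri(M, diag = TRUE)]), 0))
  norm <- config$sequencing_depth / tot
  if (any(vapply(lam, max, 0) * norm > 2^31 - 1)) {
    stop("sequencing_depth overflows integer counts", call. = FALSE)
  }
  counts <- lapply(lam, function(M) {
    L <- M * norm
    ut <- upper.tri(L, diag = TRUE)
    v <- stats::rpois(sum(ut), L[ut])
    C <- matrix(0, n, n)
    C[ut] <- v
    C <- C + t(C) - diag(diag(C))
    C
  })
  contact_map(counts, config$bin_size_bp,
              stats::setNames(rep(config$chrom_length_bp, length(counts)),
                              names(counts)))
}

#' Simulate a labelled cis/trans interaction pair list
#'
#' Uniform background pair list with a configurable trans fraction; used to
#' exercise the cis/trans partition with known labels.
#'
#' @param truth,config as in [simulate_contacts()].
#' @param condition condition label (seeds the stream).
#' @param n_pairs number of pairs.
#' @return data.table chrom1, pos1, chrom2, pos2, is_cis_truth.
#' @export
simulate_interaction_pairs <- function(truth, config, condition = "control",
                                       n_pairs = 10000) {
  condition <- match.arg(condition, SIM_CONDITIONS)
  set.seed(stage_seed(config$seed, paste0("pairs_", condition)))
  is_trans <- stats::runif(n_pairs) < config$trans_rate &
    config$n_chroms > 1
  c1 <- sample(truth$chroms, n_pairs, replace = TRUE)
  c2 <- c1
  for (i in which(is_trans)) {
    c2[i] <- sample(setdiff(truth$chroms, c1[i]), 1)
  }
  data.table::data.table(
    chrom1 = c1,
    pos1 = as.integer(floor(stats::runif(n_pairs, 0, config$chrom_length_bp))),
    chrom2 = c2,
    pos2 = as.integer(floor(stats::runif(n_pairs, 0, config$chrom_length_bp))),
    is_cis_truth = !is_trans)
}

#' Simulate peak sets and bedGraph signal tracks for one condition
#'
#' Emits the planted peak sets (ATAC, H3K4me3, H3K9ac, H3K27me3) and
#' bedGraph tracks with plateau signal over every planted peak (amplitude
#' well above the noise floor), Gaussian shoulders, and a noisy baseline;
#' the methylation track is high outside peaks and low inside ATAC peaks.
#'
#' @param truth,config as in [simulate_contacts()].
#' @param condition condition label.
#' @param baseline_step bp resolution of the background grid (default 2000).
#' @return list with `peaks` (per-mark interval tables) and `tracks`
#'   (per-mark bedGraph data.tables, plus `methylation`).
#' @export
simulate_tracks <- function(truth, config, condition = "control",
                            baseline_step = 2000L) {
  condition <- match.arg(condition, SIM_CONDITIONS)
  set.seed(stage_seed(config$seed, paste0("tracks_", condition)))
  pk <- truth$peaks[[condition]]
  marks <- names(pk)
  L <- config$chrom_length_bp
  amp <- 5; floor_max <- 0.3
  tracks <- list()
  for (mark in marks) {
    rows <- list()
    for (ch in truth$chroms) {
      p <- pk[[mark]][chrom == ch]
      breaks <- sort(unique(c(seq(0L, L, by = baseline_step), L,
                              unlist(lapply(seq_len(nrow(p)), function(i) {
                                seq(max(0L, p$start[i] - 1000L),
                                    min(L, p$end[i] + 1000L), by = 50L)
                              })))))
      s <- head(breaks, -1); e <- tail(breaks, -1)
      mid <- (s + e) / 2
      val <- stats::runif(length(mid), 0.05, floor_max)
      if (nrow(p)) {
        gr_q <- GenomicRanges::GRanges(ch, IRanges::IRanges(s + 1L, e))
        gr_p <- GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start + 1L, p$end))
        inside <- GenomicRanges::countOverlaps(gr_q, gr_p) > 0
        val[inside] <- val[inside] + amp
        # Gaussian shoulders within 1 kb of a peak edge
        near <- which(!inside)
        if (length(near)) {
          hit <- GenomicRanges::distanceToNearest(gr_q[near], gr_p)
          dd <- rep(NA_real_, length(near))
          dd[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
          add <- amp * exp(-(dd / 300)^2 / 2)
          add[is.na(add)] <- 0
          val[near] <- val[near] + add
        }
      }
      rows[[ch]] <- data.table::data.table(chrom = ch, start = s, end = e,
                                           value = round(val, 4))
    }
    tracks[[mark]] <- data.table::rbindlist(rows)
  }
  # methylation: high background, hypomethylated inside ATAC peaks
  meth_rows <- list()
  for (ch in truth$chroms) {
    p <- pk$ATAC[chrom == ch]
    breaks <- sort(unique(c(seq(0L, L, by = baseline_step), L,
                            p$start, p$end)))
    s <- head(breaks, -1); e <- tail(breaks, -1)
    gr_q <- GenomicRanges::GRanges(ch, IRanges::IRanges(s + 1L, e))
    gr_p <- GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start + 1L, p$end))
    inside <- GenomicRanges::countOverlaps(gr_q, gr_p) > 0
    val <- stats::runif(length(s), 0.7, 0.9)
    val[inside] <- stats::runif(sum(inside), 0.01, 0.08)
    meth_rows[[ch]] <- data.table::data.table(chrom = ch, start = s, end = e,
                                              value = round(val, 4))
  }
  tracks$methylation <- data.table::rbindlist(meth_rows)
  list(peaks = pk, tracks = tracks)
}

#' Simulate a replicated expression table
#'
#' Per-gene, per-replicate FPKM drawn log-normally around the planted
#' condition mean (`sdlog = config$expr_sdlog`); deterministic given seed.
#'
#' @param truth,config as in [simulate_contacts()].
#' @param n_reps replicates per condition (>= 2).
#' @return data.table: gene_id, then `control_1..control_n`,
#'   `treatment_1..treatment_n` FPKM columns.
#' @export
simulate_expression <- function(truth, config, n_reps = 3) {
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  set.seed(stage_seed(config$seed, "expression"))
  em <- truth$expr_means
  out <- data.table::data.table(gene_id = em$gene_id)
  for (cond in SIM_CONDITIONS) {
    mu <- em[[cond]]
    for (r in seq_len(n_reps)) {
      out[[paste0(cond, "_", r)]] <-
        round(stats::rlnorm(length(mu), meanlog = log(mu),
                            sdlog = config$expr_sdlog), 4)
    }
  }
  out
}
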