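# A/B compartment calling, switch classification, saddle analysis and
# per-compartment summaries.

#' Per-bin gene density aligned to a contact map
#'
#' @param genes gene table (chrom, start, end).
#' @param map a ContactMap providing the bin grid.
#' @return named list per chromosome of per-bin overlapping-gene counts.
#' @export
gene_density_track <- function(genes, map) {
  bins <- cm_bins(map)
  gr_g <- gr_from_bed(genes)
  out <- lapply(names(map$counts), function(ch) {
    b <- bins[chrom == ch]
    gr_b <- gr_from_bed(b)
    GenomicRanges::countOverlaps(gr_b, gr_g)
  })
  names(out) <- names(map$counts)
  out
}

#' Call A/B compartments from a balanced contact map
#'
#' Per chromosome: observed/expected matrix, Pearson correlation matrix over
#' unmasked bins, leading eigenvector (PC1). The eigenvector sign is
#' per-matrix arbitrary, so it is anchored to gene density: PC1 is flipped
#' so that its correlation with per-bin gene count is positive, and bins
#' with PC1 > 0 are labelled A (gene-dense, active), PC1 < 0 labelled B.
#' PC1 exactly 0 gives label NA.
#'
#' @param map a balanced ContactMap (typically 100-kb resolution).
#' @param gene_density per-bin gene counts as from [gene_density_track()],
#'   or a gene table (chrom/start/end), converted internally.
#' @param min_bins chromosomes with fewer unmasked bins get an all-NA track
#'   with a warning (default 10).
#' @return A `CompartmentTrack` data.table: chrom, bin, start, end, pc1,
#'   label ("A"/"B"/NA); attribute `orientation_cor` records the per-chrom
#'   PC1-density correlation after orientation.
#' @export
call_compartments <- function(map, gene_density, min_bins = 10) {
  if (is.data.frame(gene_density)) {
    gene_density <- gene_density_track(gene_density, map)
  }
  oe <- observed_over_expected(map)
  bins <- cm_bins(map)
  orient <- numeric(0)
  out <- list()
  for (ch in names(map$counts)) {
    O <- oe[[ch]]
    n <- nrow(O)
    pc1 <- rep(NA_real_, n)
    keep <- which(apply(O, 1, function(r) any(is.finite(r))))
    if (length(keep) < min_bins) {
      warning(sprintf("chromosome %s has < %d usable bins; compartment track is NA",
                      ch, min_bins))
    } else {
      Osub <- O[keep, keep, drop = FALSE]
      Osub[!is.finite(Osub)] <- NA
      cc <- suppressWarnings(stats::cor(Osub, use = "pairwise.complete.obs"))
      cc[!is.finite(cc)] <- 0
      ev <- eigen(cc, symmetric = TRUE)
      v <- ev$vectors[, 1]
      dens <- gene_density[[ch]][keep]
      s <- suppressWarnings(stats::cor(v, dens))
      if (is.finite(s) && s < 0) v <- -v
      pc1[keep] <- v
      orient[ch] <- suppressWarnings(stats::cor(v, dens))
    }
    b <- bins[chrom == ch]
    b[, pc1 := pc1]
    b[, label := data.table::fifelse(is.na(pc1) | pc1 == 0, NA_character_,
                                     data.table::fifelse(pc1 > 0, "A", "B"))]
    out[[ch]] <- b
  }
  track <- data.table::rbindlist(out)
  data.table::setattr(track, "orientation_cor", orient)
  data.table::setattr(track, "class", c("CompartmentTrack", class(track)))
  track
}

#' Classify per-bin compartment switches between two conditions
#'
#' Pure function of the two labels: A2B means the bin is compartment A in
#' the first (control) track and B in the second (treatment) track; bins NA
#' in either track are NA.
#'
#' @param trackA,trackB CompartmentTracks on the same bins (control first).
#' @return A `SwitchTable`: list with `table` (per-bin pattern) and `counts`
#'   (named counts of A2A/A2B/B2A/B2B/NA, summing to the bin total).
#' @export
classify_switches <- function(trackA, trackB) {
  if (!identical(trackA$chrom, trackB$chrom) ||
      !identical(trackA$start, trackB$start)) {
    stop("compartment tracks do not share a bin table", call. = FALSE)
  }
  pattern <- ifelse(is.na(trackA$label) | is.na(trackB$label), NA_character_,
                    paste0(trackA$label, "2", trackB$label))
  tab <- data.table::data.table(chrom = trackA$chrom, bin = trackA$bin,
                                start = trackA$start, end = trackA$end,
                                label_control = trackA$label,
                                label_treatment = trackB$label,
                                pattern = pattern)
  counts <- sapply(c("A2A", "A2B", "B2A", "B2B"),
                   function(p) sum(pattern == p, na.rm = TRUE))
  counts <- c(counts, "NA" = sum(is.na(pattern)))
  structure(list(table = tab, counts = counts), class = "SwitchTable")
}

#' Saddle analysis and compartment strength
#'
#' Bins are ranked by PC1, trimmed to `qrange`, and cut into `n_quantiles`
#' groups (group 1 = most negative PC1, i.e. the B end). The saddle matrix
#' holds the mean cis O/E over all bin pairs per group pair. Compartment
#' strength uses the extreme `corner_frac` of retained bins:
#' `x = top(A-A) / bottom(A-B)` and `y = top(B-B) / bottom(A-B)`, where
#' top(A-A)/top(B-B) are mean O/E among pairs within the top/bottom corner
#' bins and bottom(A-B) the mean over cross pairs.
#'
#' @param map a balanced ContactMap.
#' @param track a CompartmentTrack for this map.
#' @param qrange PC1 quantile range retained (default c(0.02, 0.98)).
#' @param n_quantiles saddle dimension (default 10).
#' @param corner_frac corner fraction for the strength ratio (default 0.2).
#' @param oe optional precomputed per-chromosome O/E matrices (as from
#'   [observed_over_expected()]); computed from `map` when NULL.
#' @return A `SaddleResult`: list(saddle = Q x Q matrix, strength =
#'   c(x =, y =), corner means, n_bins used).
#' @export
saddle <- function(map, track, qrange = c(0.02, 0.98), n_quantiles = 10,
                   corner_frac = 0.2, oe = NULL) {
  if (is.null(oe)) oe <- observed_over_expected(map)
  ok <- which(is.finite(track$pc1))
  if (length(ok) < n_quantiles) stop("too few bins with PC1", call. = FALSE)
  pc1 <- track$pc1[ok]
  if (stats::sd(pc1) == 0) stop("degenerate PC1: all values equal", call. = FALSE)
  qs <- stats::quantile(pc1, qrange, names = FALSE)
  retained <- ok[pc1 >= qs[1] & pc1 <= qs[2]]
  pc1r <- track$pc1[retained]
  r <- rank(pc1r, ties.method = "first")
  grp <- ceiling(r / length(r) * n_quantiles)
  n_corner <- max(1L, floor(corner_frac * length(retained)))
  ordr <- order(pc1r)
  bot_idx <- retained[ordr[seq_len(n_corner)]]                    # B end
  top_idx <- retained[ordr[seq(length(ordr) - n_corner + 1, length(ordr))]]
  S_sum <- matrix(0, n_quantiles, n_quantiles)
  S_n <- matrix(0, n_quantiles, n_quantiles)
  acc <- c(AA_sum = 0, AA_n = 0, BB_sum = 0, BB_n = 0, AB_sum = 0, AB_n = 0)
  for (ch in names(oe)) {
    in_ch <- track$chrom[retained] == ch
    if (!any(in_ch)) next
    bins_ch <- track$bin[retained][in_ch] + 1L
    g_ch <- grp[in_ch]
    O <- oe[[ch]][bins_ch, bins_ch, drop = FALSE]
    for (q1 in seq_len(n_quantiles)) {
      ii <- which(g_ch == q1)
      if (!length(ii)) next
      for (q2 in seq_len(n_quantiles)) {
        jj <- which(g_ch == q2)
        if (!length(jj)) next
        Ox <- O[ii, jj, drop = FALSE]
        fin <- is.finite(Ox)
        S_sum[q1, q2] <- S_sum[q1, q2] + sum(Ox[fin])
        S_n[q1, q2] <- S_n[q1, q2] + sum(fin)
      }
    }
    corner_mean_acc <- function(idx_i, idx_j) {
      ii <- track$bin[idx_i][track$chrom[idx_i] == ch] + 1L
      jj <- track$bin[idx_j][track$chrom[idx_j] == ch] + 1L
      if (!length(ii) || !length(jj)) return(c(0, 0))
      Ox <- oe[[ch]][ii, jj, drop = FALSE]
      c(sum(Ox[is.finite(Ox)]), sum(is.finite(Ox)))
    }
    aa <- corner_mean_acc(top_idx, top_idx)
    bb <- corner_mean_acc(bot_idx, bot_idx)
    ab <- corner_mean_acc(top_idx, bot_idx)
    acc <- acc + c(aa[1], aa[2], bb[1], bb[2], ab[1], ab[2])
  }
  S <- S_sum / S_n
  top_aa <- acc["AA_sum"] / acc["AA_n"]
  top_bb <- acc["BB_sum"] / acc["BB_n"]
  bot_ab <- acc["AB_sum"] / acc["AB_n"]
  strength <- c(x = unname(top_aa / bot_ab), y = unname(top_bb / bot_ab))
  structure(list(saddle = S, strength = strength,
                 corners = c(top_AA = unname(top_aa), top_BB = unname(top_bb),
                             bottom_AB = unname(bot_ab)),
                 n_bins = length(retained)),
            class = "SaddleResult")
}

#' Per-compartment genomic summaries
#'
#' Distributions of gene count, GC fraction and mean expression per
#' compartment category, plus maximal same-label segment lengths.
#'
#' @param track a CompartmentTrack.
#' @param genes gene table.
#' @param gc_track optional per-bin GC fraction, aligned list per chromosome
#'   or data.table (chrom, bin, gc).
#' @param expression optional table gene_id + FPKM columns; per-bin mean
#'   FPKM of overlapping genes is summarized.
#' @param switches optional SwitchTable; adds A2B/B2A categories.
#' @return list with `per_bin` (bin-level annotations), `by_category`
#'   (summary stats) and `segments` (run-length segments of the labels).
#' @export
compartment_summary <- function(track, genes, gc_track = NULL,
                                expression = NULL, switches = NULL) {
  per_bin <- data.table::as.data.table(track)[, .(chrom, bin, start, end, pc1, label)]
  gr_b <- gr_from_bed(per_bin)
  gr_g <- gr_from_bed(genes)
  per_bin[, gene_count := GenomicRanges::countOverlaps(gr_b, gr_g)]
  if (!is.null(gc_track)) {
    if (is.list(gc_track) && !is.data.frame(gc_track)) {
      per_bin[, gc := unlist(gc_track[unique(per_bin$chrom)])]
    } else {
      per_bin <- merge(per_bin, gc_track, by = c("chrom", "bin"), all.x = TRUE)
    }
  }
  if (!is.null(expression)) {
    fpkm_cols <- setdiff(names(expression), "gene_id")
    gm <- data.table::data.table(gene_id = expression$gene_id,
                                 fpkm = rowMeans(expression[, fpkm_cols, with = FALSE]))
    gdt <- merge(data.table::as.data.table(genes), gm, by = "gene_id")
    hits <- GenomicRanges::findOverlaps(gr_b, gr_from_bed(gdt))
    fp <- rep(NA_real_, nrow(per_bin))
    agg <- tapply(gdt$fpkm[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), mean)
    fp[as.integer(names(agg))] <- agg
    per_bin[, mean_fpkm := fp]
  }
  cat_col <- per_bin$label
  if (!is.null(switches)) {
    sw <- switches$table$pattern
    cat_col <- ifelse(!is.na(sw) & sw %in% c("A2B", "B2A"), sw, cat_col)
  }
  per_bin[, category := cat_col]
  num_cols <- intersect(c("gene_count", "gc", "mean_fpkm"), names(per_bin))
  by_cat <- per_bin[!is.na(category),
                    c(list(n_bins = .N),
                      lapply(.SD, function(v) mean(v, na.rm = TRUE))),
                    by = category, .SDcols = num_cols]
  # maximal same-label runs per chromosome
  segs <- per_bin[, {
    r <- rle(ifelse(is.na(label), "NA", label))
    ends <- cumsum(r$lengths)
    data.table::data.table(label = r$values,
                           start_bin = c(0L, head(ends, -1)),
                           end_bin = ends, n_bins = r$lengths)
  }, by = chrom]
  list(per_bin = per_bin[], by_category = by_cat[], segments = segs[label != "NA"][])
}
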