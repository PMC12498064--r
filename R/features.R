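# Open-chromatin classification, differential gates, histone-mark case
# classification, enhancer calling and signal metaprofiles.

#' Strand-aware gene windows
#'
#' `gene_local_window()`: TSS - `upstream` through the TTS (the window a
#' peak must touch to be "local"). `gene_promoter_window()`: TSS +/-
#' `halfwidth` (the exclusion window for enhancer calling and the promoter
#' used for loop-anchor linking). Both clip at position 0.
#'
#' @param genes gene table (chrom, start, end, strand, gene_id).
#' @param upstream bp upstream of the TSS (default 3000).
#' @return interval data.table with gene_id.
#' @export
gene_local_window <- function(genes, upstream = 3000L) {
  gene_local_windows(genes, upstream = upstream)
}

#' @rdname gene_local_window
#' @param halfwidth bp either side of the TSS (default 3000).
#' @export
gene_promoter_window <- function(genes, halfwidth = 3000L) {
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  data.table::data.table(chrom = genes$chrom,
                         start = as.integer(pmax(0L, tss - halfwidth)),
                         end = as.integer(tss + halfwidth),
                         gene_id = genes$gene_id)
}

#' Classify OCRs as local or distal
#'
#' A peak is local iff it overlaps (>= 1 bp) the strand-aware
#' TSS-3kb-to-TTS window of at least one gene; otherwise distal. Unknown
#' strands are treated as "+" with a warning; with no genes every peak is
#' distal.
#'
#' @param peaks interval table of OCRs.
#' @param genes gene table.
#' @param upstream upstream window size in bp (default 3000).
#' @return the peaks with a `locality` column ("local"/"distal") and an
#'   `ocr_id`.
#' @export
classify_ocrs <- function(peaks, genes, upstream = 3000L) {
  peaks <- data.table::as.data.table(peaks)
  if (!"ocr_id" %in% names(peaks)) peaks[, ocr_id := sprintf("ocr_%d", .I)]
  if (nrow(genes) && any(!genes$strand %in% c("+", "-"))) {
    warning("unknown strand treated as '+'")
    genes <- data.table::as.data.table(genes)
    genes[!strand %in% c("+", "-"), strand := "+"]
  }
  if (nrow(genes) == 0) {
    peaks[, locality := "distal"]
    return(peaks[])
  }
  win <- gene_local_windows(genes, upstream = upstream)
  hit <- overlaps_any(peaks$chrom, peaks$start, peaks$end, win)
  peaks[, locality := ifelse(hit, "local", "distal")]
  peaks[]
}

# mean per-base track value over regions; bases not covered by any
# bedGraph row count as 0
track_region_means <- function(track, regions) {
  if (nrow(regions) == 0) return(numeric(0))
  t <- data.table::as.data.table(track)
  r <- data.table::as.data.table(regions)[, .(chrom, start, end)]
  r[, rid := .I]
  data.table::setkey(t, chrom, start, end)
  ov <- data.table::foverlaps(r, t, by.x = c("chrom", "start", "end"),
                              type = "any", nomatch = NULL)
  # foverlaps treats intervals as closed; half-open abutting rows share an
  # endpoint, so drop zero-length intersections explicitly
  ov[, olen := pmin(end, i.end) - pmax(start, i.start)]
  ov <- ov[olen > 0]
  sums <- ov[, .(s = sum(value * olen)), by = rid]
  out <- numeric(nrow(r))
  out[sums$rid] <- sums$s
  out / (r$end - r$start)
}

#' Signal enrichment of a region over background
#'
#' Mean per-base signal minus mean per-base background over the region
#' (both as normalized read count per base).
#'
#' @param signal_track,background_track bedGraph data.tables.
#' @param region one-row interval (chrom, start, end) or a multi-row table
#'   (vectorized).
#' @return numeric enrichment per region.
#' @export
peak_enrichment <- function(signal_track, background_track, region) {
  region <- data.table::as.data.table(region)
  covered <- function(trk) {
    rng <- trk[, .(mn = min(start), mx = max(end)), by = chrom]
    m <- merge(region, rng, by = "chrom", all.x = TRUE)
    !any(is.na(m$mn) | m$start < m$mn | m$end > m$mx)
  }
  if (!covered(signal_track) || !covered(background_track)) {
    stop("region extends outside track coverage", call. = FALSE)
  }
  track_region_means(signal_track, region) -
    track_region_means(background_track, region)
}

# vectorized Welch t-test on the rows of two matrices; returns p-values
welch_rows <- function(A, B) {
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- apply(A, 1, stats::var); vB <- apply(B, 1, stats::var)
  se2 <- vA / nA + vB / nB
  t <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[!is.finite(p)] <- 1     # zero-variance rows: no evidence either way
  p
}

#' Differential regions between two conditions
#'
#' Counts are scaled to CPM; the fold change is the ratio of condition mean
#' CPMs with pseudocount 1. With >= 2 replicates per condition the p-value
#' is a Welch t-test on log2(CPM + 1); with single replicates an
#' equal-rate binomial exact test on the summed counts (conditioning on
#' the total, rates proportional to library size). BH correction across
#' regions; significance gate `|log2FC| > lfc_cut` and `q < fdr_cut`.
#'
#' @param countsA,countsB region x replicate count matrices.
#' @param libsizesA,libsizesB per-replicate library sizes.
#' @param regions optional interval table carried through to the output.
#' @param lfc_cut log2 fold-change gate (default 0.5, strict >).
#' @param fdr_cut FDR gate (default 0.05, strict <).
#' @return data.table with meanA/meanB (CPM), log2fc (A over B), p, q,
#'   direction ("A-enriched"/"B-enriched"), significant.
#' @export
differential_regions <- function(countsA, countsB, libsizesA, libsizesB,
                                 regions = NULL, lfc_cut = 0.5,
                                 fdr_cut = 0.05) {
  countsA <- as.matrix(countsA); countsB <- as.matrix(countsB)
  if (any(libsizesA <= 0) || any(libsizesB <= 0)) {
    stop("library sizes must be positive", call. = FALSE)
  }
  cpmA <- sweep(countsA, 2, libsizesA, "/") * 1e6
  cpmB <- sweep(countsB, 2, libsizesB, "/") * 1e6
  mA <- rowMeans(cpmA); mB <- rowMeans(cpmB)
  log2fc <- log2((mA + 1) / (mB + 1))
  if (ncol(countsA) >= 2 && ncol(countsB) >= 2) {
    p <- welch_rows(log2(cpmA + 1), log2(cpmB + 1))
  } else {
    tA <- rowSums(countsA); tB <- rowSums(countsB)
    prob <- sum(libsizesA) / (sum(libsizesA) + sum(libsizesB))
    p <- vapply(seq_along(tA), function(i) {
      tot <- tA[i] + tB[i]
      if (tot == 0) return(1)
      stats::binom.test(tA[i], tot, prob)$p.value
    }, 0)
  }
  q <- stats::p.adjust(p, method = "BH")
  out <- data.table::data.table(meanA = mA, meanB = mB, log2fc = log2fc,
                                p = p, q = q,
                                direction = ifelse(log2fc >= 0, "A-enriched",
                                                   "B-enriched"),
                                significant = abs(log2fc) > lfc_cut &
                                  q < fdr_cut)
  if (!is.null(regions)) {
    out <- cbind(data.table::as.data.table(regions), out)
  }
  out[]
}

#' Call differentially expressed genes
#'
#' Fold change is the ratio of condition mean FPKMs (pseudocount 0.01),
#' reported in the larger-over-smaller direction; p from a Welch t-test on
#' log2(FPKM + 0.01) across replicates, BH-corrected. A gene is called iff
#' `q < q_cut` and FC > `fc_cut` (linear scale, either direction).
#' Expression class per condition: high (mean FPKM > 100), non-expressed
#' (mean FPKM < 1), else expressed.
#'
#' @param expression table: gene_id plus replicate FPKM columns.
#' @param cols_a,cols_b column names of the two conditions; by default
#'   columns matching `^control_` and `^treatment_`.
#' @param q_cut,fc_cut calling gates (defaults 0.01, 1.5).
#' @param pseudo pseudocount for the FPKM ratio (default 0.01).
#' @param high_cut,low_cut expression-class cutoffs (defaults 100, 1).
#' @return A `DegTable` data.table: gene_id, mean_a, mean_b, fc (>= 1),
#'   log2fc (signed, A over B), p, q, call ("A-enriched"/"B-enriched"/
#'   "ns"), class_a, class_b.
#' @export
deg_call <- function(expression, cols_a = NULL, cols_b = NULL,
                     q_cut = 0.01, fc_cut = 1.5, pseudo = 0.01,
                     high_cut = 100, low_cut = 1) {
  expression <- data.table::as.data.table(expression)
  if (is.null(cols_a)) cols_a <- grep("^control_", names(expression), value = TRUE)
  if (is.null(cols_b)) cols_b <- grep("^treatment_", names(expression), value = TRUE)
  if (length(cols_a) < 2 || length(cols_b) < 2) {
    stop("deg_call needs >= 2 replicates per condition", call. = FALSE)
  }
  A <- as.matrix(expression[, cols_a, with = FALSE])
  B <- as.matrix(expression[, cols_b, with = FALSE])
  mA <- rowMeans(A); mB <- rowMeans(B)
  ratio <- (mA + pseudo) / (mB + pseudo)
  fc <- pmax(ratio, 1 / ratio)
  p <- welch_rows(log2(A + pseudo), log2(B + pseudo))
  q <- stats::p.adjust(p, method = "BH")
  called <- q < q_cut & fc > fc_cut
  cls <- function(m) ifelse(m > high_cut, "high",
                            ifelse(m < low_cut, "non-expressed", "expressed"))
  out <- data.table::data.table(
    gene_id = expression$gene_id, mean_a = mA, mean_b = mB,
    fc = fc, log2fc = log2(ratio), p = p, q = q,
    call = ifelse(!called, "ns",
                  ifelse(mA > mB, "A-enriched", "B-enriched")),
    class_a = cls(mA), class_b = cls(mB))
  data.table::setattr(out, "class", c("DegTable", class(out)))
  out[]
}

#' Four-case histone-state classification of regions
#'
#' "Strong" means the region overlaps a called peak of that mark. Case 1:
#' strong H3K27me3; Case 2: all marks weak; Case 3: strong H3K4me3 (with
#' or without H3K9ac); Case 4: strong H3K9ac only. Mixed
#' repressive/active states resolve by overlap fraction: K27me3 wins when
#' its covered fraction of the region is >= the best active-mark fraction
#' (ties conservative to Case 1).
#'
#' @param regions interval table.
#' @param peaksets named list with H3K4me3, H3K9ac, H3K27me3 interval
#'   tables.
#' @return the regions with per-mark overlap fractions, `case` (1-4) and
#'   `region_id`.
#' @export
classify_histone_cases <- function(regions, peaksets) {
  regions <- data.table::as.data.table(regions)
  if (!"region_id" %in% names(regions)) {
    regions[, region_id := sprintf("region_%d", .I)]
  }
  frac_of <- function(mark) {
    p <- peaksets[[mark]]
    if (is.null(p) || nrow(p) == 0) return(rep(0, nrow(regions)))
    gr_r <- gr_from_bed(regions)
    gr_p <- GenomicRanges::reduce(gr_from_bed(p))
    hits <- GenomicRanges::findOverlaps(gr_r, gr_p)
    ov <- GenomicRanges::pintersect(gr_r[S4Vectors::queryHits(hits)],
                                    gr_p[S4Vectors::subjectHits(hits)])
    f <- numeric(nrow(regions))
    agg <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
    f[as.integer(names(agg))] <- agg
    f / (regions$end - regions$start)
  }
  f4 <- frac_of("H3K4me3"); f9 <- frac_of("H3K9ac"); f27 <- frac_of("H3K27me3")
  active <- pmax(f4, f9)
  case <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    has4 <- f4[i] > 0; has9 <- f9[i] > 0; has27 <- f27[i] > 0
    case[i] <- if (!has4 && !has9 && !has27) 2L
    else if (has27 && !(has4 || has9)) 1L
    else if (has27 && f27[i] >= active[i]) 1L
    else if (has4) 3L
    else 4L
  }
  regions[, `:=`(frac_H3K4me3 = f4, frac_H3K9ac = f9, frac_H3K27me3 = f27,
                 case = case)]
  regions[]
}

#' Call putative enhancers from histone cases
#'
#' Putative enhancers are Case 3 or Case 4 regions that do not overlap any
#' gene's TSS +/- `promoter_halfwidth` window.
#'
#' @param cases output of [classify_histone_cases()].
#' @param genes gene table.
#' @param promoter_halfwidth promoter exclusion half-width (default 3000).
#' @return the enhancer subset with `enhancer = TRUE`.
#' @export
call_enhancers <- function(cases, genes, promoter_halfwidth = 3000L) {
  prom <- gene_promoter_window(genes, promoter_halfwidth)
  in_prom <- if (nrow(genes)) {
    overlaps_any(cases$chrom, cases$start, cases$end, prom)
  } else rep(FALSE, nrow(cases))
  enh <- cases[cases$case %in% c(3L, 4L) & !in_prom]
  enh[, enhancer := TRUE]
  enh[]
}

#' Per-mark gain/loss status of enhancers between conditions
#'
#' Intersects enhancers with per-mark differential regions: an enhancer
#' overlapping an A-enriched significant region of a mark has that mark
#' "A-gain", a B-enriched one "B-gain", else "static".
#'
#' @param enhancers enhancer table from [call_enhancers()].
#' @param diffregions named list per mark of [differential_regions()]
#'   outputs carrying interval columns.
#' @return the enhancers with one status column per mark.
#' @export
differential_enhancers <- function(enhancers, diffregions) {
  enhancers <- data.table::copy(enhancers)
  for (mark in names(diffregions)) {
    dr <- data.table::as.data.table(diffregions[[mark]])
    dr <- dr[dr$significant == TRUE]
    status <- rep("static", nrow(enhancers))
    for (dir in c("A-enriched", "B-enriched")) {
      d <- dr[dr$direction == dir]
      if (nrow(d)) {
        hit <- overlaps_any(enhancers$chrom, enhancers$start, enhancers$end, d)
        status[hit] <- ifelse(dir == "A-enriched", "A-gain", "B-gain")
      }
    }
    enhancers[[paste0("status_", mark)]] <- status
  }
  enhancers[]
}

#' Signal metaprofile around anchor points
#'
#' Bins the track into `bin_bp` windows across +/- `flank_bp` of each
#' anchor, flipping rows for minus-strand anchors so upstream is always
#' left. Anchors too close to a chromosome edge produce NA bins, excluded
#' from the column means.
#'
#' @param track bedGraph data.table.
#' @param anchors table with chrom, pos and optionally strand.
#' @param flank_bp half-window (default 3000).
#' @param bin_bp profile bin width (default 50).
#' @param chrom_sizes optional named vector; positions beyond a chromosome
#'   end become NA.
#' @return list(matrix = anchors x bins, profile = column means, offsets =
#'   bin-center offsets in bp).
#' @export
metaprofile <- function(track, anchors, flank_bp = 3000L, bin_bp = 50L,
                        chrom_sizes = NULL) {
  anchors <- data.table::as.data.table(anchors)
  if (!"strand" %in% names(anchors)) anchors[, strand := "+"]
  nb <- as.integer(2 * flank_bp / bin_bp)
  offsets <- seq(-flank_bp, flank_bp - bin_bp, by = bin_bp) + bin_bp / 2
  # one query row per anchor x bin
  q <- data.table::CJ(aid = seq_len(nrow(anchors)), b = seq_len(nb))
  q[, chrom := anchors$chrom[aid]]
  q[, start := anchors$pos[aid] - flank_bp + (b - 1L) * bin_bp]
  q[, end := start + bin_bp]
  valid <- q$start >= 0
  if (!is.null(chrom_sizes)) valid <- valid & q$end <= chrom_sizes[q$chrom]
  vals <- rep(NA_real_, nrow(q))
  vals[valid] <- track_region_means(track, q[valid])
  M <- matrix(vals[order(q$aid, q$b)], nrow = nrow(anchors), ncol = nb,
              byrow = TRUE)
  flip <- anchors$strand == "-"
  M[flip, ] <- M[flip, nb:1, drop = FALSE]
  list(matrix = M, profile = colMeans(M, na.rm = TRUE), offsets = offsets)
}
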