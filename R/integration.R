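# Cross-layer linking: compartment switches x DEGs, dOCR-gene loops, dOCR
# activity, TFBS loop categories, enhancer-gene links, shifted controls.

#' Genes in compartment-switched bins, intersected with DEG calls
#'
#' @param switches a SwitchTable.
#' @param genes gene table.
#' @param deg_table a [deg_call()] DegTable (optional).
#' @return list(genes = per-gene table with switch pattern and DEG call,
#'   counts = per-pattern gene and DEG counts).
#' @export
genes_in_switched_bins <- function(switches, genes, deg_table = NULL) {
  sw <- switches$table[pattern %in% c("A2B", "B2A")]
  genes <- data.table::as.data.table(genes)
  if (nrow(sw) == 0 || nrow(genes) == 0) {
    out <- data.table::data.table(gene_id = character(), pattern = character())
  } else {
    hits <- GenomicRanges::findOverlaps(gr_from_bed(genes), gr_from_bed(sw))
    out <- data.table::data.table(
      gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
      pattern = sw$pattern[S4Vectors::subjectHits(hits)])
    out <- unique(out, by = c("gene_id", "pattern"))
  }
  if (!is.null(deg_table)) {
    out <- merge(out, deg_table[, .(gene_id, call, q, fc)], by = "gene_id",
                 all.x = TRUE, sort = FALSE)
    out[, is_deg := !is.na(call) & call != "ns"]
  }
  counts <- out[, .(n_genes = data.table::uniqueN(gene_id),
                    n_deg = if ("is_deg" %in% names(out))
                      data.table::uniqueN(gene_id[is_deg]) else NA_integer_),
                by = pattern]
  list(genes = out[], counts = counts[])
}

#' dOCR-gene loops
#'
#' Restricts to intergenic-gene loops and links those whose intergenic
#' anchor contains (>= 1 bp overlap) at least one distal OCR; linked genes
#' are those whose body or promoter (controlled by `gene_anchor`) overlaps
#' the gene-side anchor. The anchored fraction is
#' `100 * linked intergenic anchors / all intergenic anchors`.
#'
#' @param loops a classified LoopSet (see [classify_loops()]).
#' @param ocr_calls OCRs with a `locality` column ([classify_ocrs()]).
#' @param genes gene table.
#' @param gene_anchor "body_or_promoter" (default) or "body": what counts
#'   as gene overlap on the gene-side anchor.
#' @param promoter_halfwidth promoter half-width for linking (default 3000).
#' @return A `DocrGeneLinks` list: `links` (one row per loop x dOCR x gene),
#'   `per_loop` (loop-level link table), `anchored_fraction` (percent,
#'   1 decimal), `n_intergenic_anchors`, `n_linked_anchors`.
#' @export
docr_gene_loops <- function(loops, ocr_calls, genes,
                            gene_anchor = c("body_or_promoter", "body"),
                            promoter_halfwidth = 3000L) {
  gene_anchor <- match.arg(gene_anchor)
  loops <- data.table::as.data.table(loops)
  if (!"class" %in% names(loops)) {
    stop("loops must be classified first (classify_loops)", call. = FALSE)
  }
  ig <- loops[class == "intergenic-gene"]
  docrs <- data.table::as.data.table(ocr_calls)[locality == "distal"]
  n_anchors <- nrow(ig)
  if (n_anchors == 0) {
    return(structure(list(links = data.table::data.table(),
                          per_loop = data.table::data.table(),
                          anchored_fraction = NA_real_,
                          n_intergenic_anchors = 0L, n_linked_anchors = 0L),
                     class = "DocrGeneLinks"))
  }
  # the intergenic anchor is whichever side has no gene-body overlap
  ig[, ig_side := ifelse(anchor1_gene, 2L, 1L)]
  ig_anchor <- data.table::data.table(
    chrom = ifelse(ig$ig_side == 1L, ig$chrom1, ig$chrom2),
    start = ifelse(ig$ig_side == 1L, ig$start1, ig$start2),
    end = ifelse(ig$ig_side == 1L, ig$end1, ig$end2))
  gene_anchor_tbl <- data.table::data.table(
    chrom = ifelse(ig$ig_side == 1L, ig$chrom2, ig$chrom1),
    start = ifelse(ig$ig_side == 1L, ig$start2, ig$start1),
    end = ifelse(ig$ig_side == 1L, ig$end2, ig$end1))
  gr_ig <- gr_from_bed(ig_anchor)
  gr_docr <- gr_from_bed(docrs)
  h_docr <- GenomicRanges::findOverlaps(gr_ig, gr_docr)
  gtab <- data.table::as.data.table(genes)
  targets <- if (gene_anchor == "body_or_promoter") {
    rbind(gtab[, .(chrom, start, end, gene_id)],
          gene_promoter_window(gtab, promoter_halfwidth))
  } else gtab[, .(chrom, start, end, gene_id)]
  h_gene <- GenomicRanges::findOverlaps(gr_from_bed(gene_anchor_tbl),
                                        gr_from_bed(targets))
  docr_by_loop <- split(S4Vectors::subjectHits(h_docr),
                        S4Vectors::queryHits(h_docr))
  gene_by_loop <- split(targets$gene_id[S4Vectors::subjectHits(h_gene)],
                        S4Vectors::queryHits(h_gene))
  linked <- as.integer(names(docr_by_loop))
  rows <- list()
  for (li in linked) {
    g <- unique(gene_by_loop[[as.character(li)]]) %||% character(0)
    if (!length(g)) g <- NA_character_
    d <- docrs$ocr_id[docr_by_loop[[as.character(li)]]]
    rows[[length(rows) + 1]] <- data.table::CJ(loop = ig$name[li],
                                               docr = d, gene_id = g)
  }
  links <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(loop = character(), docr = character(),
                           gene_id = character())
  per_loop <- data.table::data.table(
    loop = ig$name, chrom = ig_anchor$chrom,
    ig_start = ig_anchor$start, ig_end = ig_anchor$end,
    gene_start = gene_anchor_tbl$start, gene_end = gene_anchor_tbl$end,
    n_docrs = 0L, linked = FALSE)
  per_loop$n_docrs[linked] <- lengths(docr_by_loop)
  per_loop$linked[linked] <- TRUE
  structure(list(links = links[], per_loop = per_loop[],
                 anchored_fraction = round1(100 * length(linked) / n_anchors),
                 n_intergenic_anchors = n_anchors,
                 n_linked_anchors = length(linked)),
            class = "DocrGeneLinks")
}

#' Classify dOCR activity between conditions
#'
#' A dOCR is A-active iff it is more open in condition A (overlaps an
#' A-enriched significant ATAC differential region) or carries weaker
#' H3K27me3 in A (overlaps, or lies within `flank_bp` of, a B-enriched
#' significant H3K27me3 region); symmetric for B. Evidence in both
#' directions gives "static" with a conflict flag.
#'
#' @param docrs distal OCR table.
#' @param atac_diffregions,k27_diffregions [differential_regions()] outputs
#'   with interval columns.
#' @param flank_bp H3K27me3 flank distance (default 2000).
#' @return the dOCRs with `activity` ("A-active"/"B-active"/"static") and
#'   `conflict`.
#' @export
classify_docr_activity <- function(docrs, atac_diffregions, k27_diffregions,
                                   flank_bp = 2000L) {
  docrs <- data.table::copy(data.table::as.data.table(docrs))
  hit_dir <- function(dr, dir, flank = 0L) {
    dr <- data.table::as.data.table(dr)
    d <- dr[dr$significant == TRUE & dr$direction == dir]
    if (nrow(d) == 0) return(rep(FALSE, nrow(docrs)))
    overlaps_any(docrs$chrom, docrs$start - flank, docrs$end + flank, d)
  }
  # "weaker K27 in A" = K27 enriched in B
  a_ev <- hit_dir(atac_diffregions, "A-enriched") |
    hit_dir(k27_diffregions, "B-enriched", flank_bp)
  b_ev <- hit_dir(atac_diffregions, "B-enriched") |
    hit_dir(k27_diffregions, "A-enriched", flank_bp)
  docrs[, conflict := a_ev & b_ev]
  docrs[, activity := data.table::fcase(a_ev & !b_ev, "A-active",
                                        b_ev & !a_ev, "B-active",
                                        default = "static")]
  docrs[]
}

#' Participation rate of active dOCRs in dOCR-gene loops
#'
#' @param activity dOCR table from [classify_docr_activity()] (needs
#'   ocr_id and activity).
#' @param links a [docr_gene_loops()] result (its `links$docr` ids).
#' @param label which activity class to rate ("A-active" or "B-active").
#' @return list(percent = 1-decimal percentage of active dOCRs appearing in
#'   >= 1 link, n_active, n_in_loops); percent is NA with a flag when no
#'   dOCR is active.
#' @export
active_docr_loop_rate <- function(activity, links, label = "A-active") {
  act <- activity$ocr_id[activity$activity == label]
  if (length(act) == 0) {
    return(list(percent = NA_real_, n_active = 0L, n_in_loops = 0L,
                undefined = TRUE))
  }
  in_loops <- sum(act %in% unique(links$links$docr))
  list(percent = round1(100 * in_loops / length(act)),
       n_active = length(act), n_in_loops = in_loops, undefined = FALSE)
}

#' TFBS categories on dOCR-gene loop anchors
#'
#' Per motif and link: a site only on the dOCR (intergenic) anchor is a
#' "dOCR TFBS", only on the gene anchor a "Local TFBS", on both a
#' "Joint TFBS".
#'
#' @param motif_sites interval table with a `motif` column.
#' @param links a [docr_gene_loops()] result (uses `per_loop`).
#' @return list(per_link = motif x link categories, counts = per-motif
#'   category counts and percentages).
#' @export
tfbs_loop_categories <- function(motif_sites, links) {
  pl <- links$per_loop[linked == TRUE]
  motif_sites <- data.table::as.data.table(motif_sites)
  if (nrow(pl) == 0 || nrow(motif_sites) == 0) {
    return(list(per_link = data.table::data.table(),
                counts = data.table::data.table()))
  }
  gr_ig <- GenomicRanges::GRanges(pl$chrom,
                                  IRanges::IRanges(pl$ig_start + 1L, pl$ig_end))
  gr_ga <- GenomicRanges::GRanges(pl$chrom,
                                  IRanges::IRanges(pl$gene_start + 1L, pl$gene_end))
  gr_m <- gr_from_bed(motif_sites)
  on_anchor <- function(gr_a) {
    h <- GenomicRanges::findOverlaps(gr_a, gr_m)
    unique(data.table::data.table(
      loop = pl$loop[S4Vectors::queryHits(h)],
      motif = motif_sites$motif[S4Vectors::subjectHits(h)]))
  }
  on_ig <- on_anchor(gr_ig); on_ig[, side_ig := TRUE]
  on_ga <- on_anchor(gr_ga); on_ga[, side_ga := TRUE]
  per <- merge(on_ig, on_ga, by = c("loop", "motif"), all = TRUE)
  per[, side_ig := !is.na(side_ig)]
  per[, side_ga := !is.na(side_ga)]
  per[, category := data.table::fcase(side_ig & side_ga, "Joint TFBS",
                                      side_ig, "dOCR TFBS",
                                      default = "Local TFBS")]
  counts <- per[, .N, by = .(motif, category)]
  counts[, pct := round1(100 * N / sum(N)), by = motif]
  list(per_link = per[], counts = counts[])
}

#' Link differential enhancers to genes through loop anchors
#'
#' An enhancer overlapping one loop anchor is linked to every gene whose
#' promoter (TSS +/- `promoter_halfwidth`) overlaps the partner anchor;
#' per-mark gain/loss status columns are carried through.
#'
#' @param diff_enhancers enhancer table (e.g. [differential_enhancers()]).
#' @param loops a LoopSet.
#' @param genes gene table.
#' @param promoter_halfwidth promoter half-width (default 3000).
#' @return data.table: enhancer region_id, loop name, gene_id, plus any
#'   status columns of the input.
#' @export
enhancer_gene_links <- function(diff_enhancers, loops, genes,
                                promoter_halfwidth = 3000L) {
  enh <- data.table::as.data.table(diff_enhancers)
  loops <- data.table::as.data.table(loops)
  prom <- gene_promoter_window(data.table::as.data.table(genes),
                               promoter_halfwidth)
  status_cols <- grep("^status_", names(enh), value = TRUE)
  empty <- data.table::data.table(region_id = character(), loop = character(),
                                  gene_id = character())
  if (nrow(enh) == 0 || nrow(loops) == 0 || nrow(prom) == 0) return(empty)
  gr_prom <- gr_from_bed(prom)
  gr_enh <- gr_from_bed(enh)
  rows <- list()
  for (side in 1:2) {
    other <- 3 - side
    h_e <- GenomicRanges::findOverlaps(gr_enh, loop_anchor_gr(loops, side))
    if (!length(h_e)) next
    h_p <- GenomicRanges::findOverlaps(loop_anchor_gr(loops, other), gr_prom)
    pmap <- split(prom$gene_id[S4Vectors::subjectHits(h_p)],
                  S4Vectors::queryHits(h_p))
    for (k in seq_along(h_e)) {
      li <- S4Vectors::subjectHits(h_e)[k]
      g <- unique(pmap[[as.character(li)]])
      if (is.null(g) || !length(g)) next
      ei <- S4Vectors::queryHits(h_e)[k]
      r <- data.table::data.table(region_id = enh$region_id[ei],
                                  loop = loops$name[li], gene_id = g)
      for (sc in status_cols) r[[sc]] <- enh[[sc]][ei]
      rows[[length(rows) + 1]] <- r
    }
  }
  if (!length(rows)) return(empty)
  unique(data.table::rbindlist(rows))
}

#' Randomly shifted control regions
#'
#' Same number and widths as the input regions; each region is shifted by
#' a uniform draw in [-max_shift, max_shift], redrawing until it lies
#' within its chromosome. Deterministic given `seed`.
#'
#' @param docrs interval table.
#' @param chrom_sizes named lengths in bp.
#' @param seed integer seed.
#' @param max_shift maximum absolute shift (default 5e5).
#' @return shifted interval table (same columns chrom/start/end plus
#'   source ocr_id if present).
#' @export
shifted_controls <- function(docrs, chrom_sizes, seed, max_shift = 5e5) {
  set.seed(stage_seed(seed, "shifted_controls"))
  docrs <- data.table::as.data.table(docrs)
  out <- data.table::copy(docrs[, intersect(c("chrom", "start", "end", "ocr_id"),
                                            names(docrs)), with = FALSE])
  for (i in seq_len(nrow(out))) {
    L <- chrom_sizes[[out$chrom[i]]]
    w <- out$end[i] - out$start[i]
    repeat {
      sh <- round(stats::runif(1, -max_shift, max_shift))
      s <- out$start[i] + sh
      if (s >= 0 && s + w <= L) { out$start[i] <- as.integer(s); break }
    }
    out$end[i] <- out$start[i] + w
  }
  out[]
}
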