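# Punctate-interaction (loop) calling against a donut local background,
# multi-resolution merging, cross-condition comparison and aggregate peak
# analysis.

# Donut offsets: ring with inner radius < chebyshev <= outer, excluding the
# row/column arms (di == 0 or dj == 0) so linear features do not inflate
# the background.
donut_offsets <- function(inner = 2, outer = 5) {
  off <- expand.grid(di = -outer:outer, dj = -outer:outer)
  cheb <- pmax(abs(off$di), abs(off$dj))
  off[cheb > inner & cheb <= outer & off$di != 0 & off$dj != 0, ]
}

# lower-left quadrant (between the anchors of an upper-triangle pixel):
# high there means the pixel sits on a domain interior/corner, not a spot
lower_left_offsets <- function(inner = 2, outer = 5) {
  off <- expand.grid(di = 1:outer, dj = -outer:-1)
  cheb <- pmax(abs(off$di), abs(off$dj))
  off[cheb > inner, ]
}

# mean of M over shifted copies at the given offsets (NA-aware)
shifted_mean <- function(M, offsets) {
  n <- nrow(M)
  S <- matrix(0, n, n)
  N <- matrix(0, n, n)
  fin <- is.finite(M)
  M0 <- ifelse(fin, M, 0)
  for (k in seq_len(nrow(offsets))) {
    di <- offsets$di[k]; dj <- offsets$dj[k]
    ri <- (1 + max(0, -di)):(n - max(0, di))
    rj <- (1 + max(0, -dj)):(n - max(0, dj))
    S[ri, rj] <- S[ri, rj] + M0[ri + di, rj + dj]
    N[ri, rj] <- N[ri, rj] + fin[ri + di, rj + dj]
  }
  list(mean = ifelse(N > 0, S / N, NA_real_), n = N)
}

#' Call chromatin loops with a donut-background Poisson test
#'
#' For every cis pixel within `max_dist_bp` (and far enough from the
#' diagonal for the donut to fit), the local expected O/E is the mean of a
#' donut ring (inner radius `inner`, outer radius `outer` bins, row/column
#' arms excluded), or of the lower-left quadrant between the anchors when
#' that is higher — the latter keeps domain corners, which sit on an
#' elevated interior, from masquerading as punctate calls. The raw-space
#' expectation is `local_OE * P(s) / (w_i w_j)` and the p-value the upper
#' Poisson tail of the raw count. BH-FDR is applied within log2-distance
#' strata; surviving pixels are clustered by 8-connectivity and each
#' cluster reduced to its maximal-enrichment pixel.
#'
#' In deep maps almost any structural deviation (TAD corners, plaid) is
#' Poisson-significant, so a punctate call additionally requires the
#' observed count to exceed `min_enrichment` times its local expectation —
#' the same role the fold-change gates play in donut-based callers
#' generally.
#'
#' @param map a balanced ContactMap.
#' @param max_dist_bp maximum anchor separation (default 2 Mb).
#' @param fdr BH threshold within distance strata (default 0.05).
#' @param inner,outer donut radii in bins (defaults 2 and 5).
#' @param min_enrichment minimum observed/expected ratio for a call
#'   (default 2.5).
#' @return A `LoopSet` data.table: chrom1/start1/end1, chrom2/start2/end2
#'   (anchor width = resolution, anchor1 upstream), bin1, bin2, resolution,
#'   score (observed/expected), q.
#' @export
call_loops <- function(map, max_dist_bp = 2e6, fdr = 0.05,
                       inner = 2, outer = 5, min_enrichment = 2.5) {
  res <- map$resolution
  profile <- expected_by_distance(map)
  oe <- observed_over_expected(map, profile)
  offs <- donut_offsets(inner, outer)
  min_d <- 2 * outer + 1    # donut fully off-diagonal
  max_d <- max(min_d, floor(max_dist_bp / res))
  px <- list()
  for (ch in names(map$counts)) {
    O <- oe[[ch]]
    n <- nrow(O)
    if (n < 2 * outer + min_d + 2) {
      warning(sprintf("chromosome %s too short for the donut; skipped", ch))
      next
    }
    sm <- shifted_mean(O, offs)
    sm_ll <- shifted_mean(O, lower_left_offsets(inner, outer))
    w <- map$weights[[ch]]
    C <- map$counts[[ch]]
    idx <- which(upper.tri(O), arr.ind = TRUE)
    d <- idx[, 2] - idx[, 1]
    keep <- d >= min_d & d <= max_d
    idx <- idx[keep, , drop = FALSE]; d <- d[keep]
    donut <- pmax(sm$mean[idx], sm_ll$mean[idx], na.rm = TRUE)
    n_donut <- sm$n[idx]
    exp_raw <- donut * profile$mean[d + 1] / (w[idx[, 1]] * w[idx[, 2]])
    ok <- is.finite(exp_raw) & exp_raw > 0 & n_donut >= nrow(offs) / 2 &
      is.finite(O[idx])
    if (!any(ok)) next
    idx <- idx[ok, , drop = FALSE]; d <- d[ok]; exp_raw <- exp_raw[ok]
    obs <- C[idx]
    p <- stats::ppois(obs - 1, exp_raw, lower.tail = FALSE)
    stratum <- floor(log2(d))
    q <- rep(NA_real_, length(p))
    for (s in unique(stratum)) {
      sel <- stratum == s
      q[sel] <- stats::p.adjust(p[sel], method = "BH")
    }
    sig <- which(q < fdr & obs / exp_raw >= min_enrichment)
    if (!length(sig)) next
    px[[ch]] <- data.table::data.table(
      chrom = ch, i = idx[sig, 1] - 1L, j = idx[sig, 2] - 1L,
      score = obs[sig] / exp_raw[sig], q = q[sig])
  }
  if (!length(px)) return(empty_loopset(res))
  px <- data.table::rbindlist(px)
  # 8-connectivity clustering of significant pixels, keep max-score pixel
  out <- list()
  for (ch in unique(px$chrom)) {
    p_ch <- px[chrom == ch]
    ord <- order(p_ch$i, p_ch$j)
    p_ch <- p_ch[ord]
    m <- nrow(p_ch)
    parent <- seq_len(m)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (a in seq_len(m)) {
      nb <- which(abs(p_ch$i - p_ch$i[a]) <= 1 & abs(p_ch$j - p_ch$j[a]) <= 1)
      for (b in nb) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
    comp <- vapply(seq_len(m), find, 0L)
    p_ch[, cluster := comp]
    best <- p_ch[, .SD[which.max(score)], by = cluster]
    out[[ch]] <- best
  }
  best <- data.table::rbindlist(out)
  loops <- data.table::data.table(
    chrom1 = best$chrom, start1 = best$i * res, end1 = (best$i + 1L) * res,
    chrom2 = best$chrom, start2 = best$j * res, end2 = (best$j + 1L) * res,
    bin1 = best$i, bin2 = best$j,
    resolution = res, score = best$score, q = best$q)
  data.table::setorder(loops, chrom1, start1, start2)
  loops[, name := sprintf("loop_%d", seq_len(.N))]
  data.table::setattr(loops, "class", c("LoopSet", class(loops)))
  loops[]
}

empty_loopset <- function(res) {
  l <- data.table::data.table(chrom1 = character(), start1 = integer(),
                              end1 = integer(), chrom2 = character(),
                              start2 = integer(), end2 = integer(),
                              bin1 = integer(), bin2 = integer(),
                              resolution = integer(), score = numeric(),
                              q = numeric(), name = character())
  data.table::setattr(l, "class", c("LoopSet", class(l)))
  l
}

loop_anchor_gr <- function(loops, which = 1) {
  GenomicRanges::GRanges(loops[[paste0("chrom", which)]],
                         IRanges::IRanges(loops[[paste0("start", which)]] + 1L,
                                          loops[[paste0("end", which)]]))
}

# loop-pair overlap: both anchors overlap by >= 1 bp
loop_overlap_pairs <- function(la, lb) {
  h1 <- GenomicRanges::findOverlaps(loop_anchor_gr(la, 1), loop_anchor_gr(lb, 1))
  h2 <- GenomicRanges::findOverlaps(loop_anchor_gr(la, 2), loop_anchor_gr(lb, 2))
  k1 <- paste(S4Vectors::queryHits(h1), S4Vectors::subjectHits(h1))
  k2 <- paste(S4Vectors::queryHits(h2), S4Vectors::subjectHits(h2))
  common <- intersect(k1, k2)
  if (!length(common)) {
    return(data.table::data.table(ia = integer(), ib = integer()))
  }
  parts <- do.call(rbind, strsplit(common, " "))
  data.table::data.table(ia = as.integer(parts[, 1]),
                         ib = as.integer(parts[, 2]))
}

#' Merge loop calls across resolutions
#'
#' Calls whose anchors mutually overlap are grouped (transitively); each
#' group keeps only its finest-resolution calls (ties by score), reported
#' with their anchors verbatim. Non-overlapping calls pass through.
#'
#' @param loopsets list of LoopSets, each tagged with its `resolution`.
#' @return a merged `LoopSet`.
#' @export
merge_resolutions <- function(loopsets) {
  all <- data.table::rbindlist(loopsets, use.names = TRUE, fill = TRUE)
  if (nrow(all) == 0) return(empty_loopset(NA_integer_))
  pairs <- loop_overlap_pairs(all, all)
  pairs <- pairs[ia != ib]
  n <- nrow(all)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs$ia[k]); rb <- find(pairs$ib[k])
    if (ra != rb) parent[rb] <- ra
  }
  comp <- vapply(seq_len(n), find, 0L)
  all[, .group := comp]
  merged <- all[, .SD[resolution == min(resolution)], by = .group]
  merged[, .group := NULL]
  data.table::setorder(merged, chrom1, start1, start2)
  merged[, name := sprintf("loop_%d", seq_len(.N))]
  data.table::setattr(merged, "class", c("LoopSet", class(merged)))
  merged[]
}

#' Compare two loop sets between conditions
#'
#' Common loops: pairs whose two anchors each overlap reciprocally by at
#' least `f` (fraction of both anchor widths), matched greedily by total
#' score so each loop is used at most once. Remaining loops are
#' condition-specific iff no loop of the other set lies within `slop_bp`
#' on both anchors; leftovers (a partner within slop but below `f`) are
#' labelled ambiguous. Statuses partition each input set; swapping the
#' arguments swaps the specific sets and keeps the common set.
#'
#' @param setA,setB LoopSets on the same assembly.
#' @param f reciprocal anchor-overlap fraction for common calls
#'   (default 0.5).
#' @param slop_bp slop distance for specific calls (default 40000).
#' @return A `LoopComparison`: list(common = matched pairs, a_specific,
#'   b_specific, a_status, b_status).
#' @export
compare_loops <- function(setA, setB, f = 0.5, slop_bp = 40000) {
  nA <- nrow(setA); nB <- nrow(setB)
  cand <- loop_overlap_pairs(setA, setB)
  if (nrow(cand)) {
    ovl <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))
    o1 <- ovl(setA$start1[cand$ia], setA$end1[cand$ia],
              setB$start1[cand$ib], setB$end1[cand$ib])
    o2 <- ovl(setA$start2[cand$ia], setA$end2[cand$ia],
              setB$start2[cand$ib], setB$end2[cand$ib])
    recip <- o1 / (setA$end1[cand$ia] - setA$start1[cand$ia]) >= f &
      o1 / (setB$end1[cand$ib] - setB$start1[cand$ib]) >= f &
      o2 / (setA$end2[cand$ia] - setA$start2[cand$ia]) >= f &
      o2 / (setB$end2[cand$ib] - setB$start2[cand$ib]) >= f
    cand <- cand[recip]
  }
  cand[, pair_score := setA$score[ia] + setB$score[ib]]
  data.table::setorder(cand, -pair_score, ia, ib)
  used_a <- logical(nA); used_b <- logical(nB)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_a[cand$ia[k]] && !used_b[cand$ib[k]]) {
      keep[k] <- TRUE
      used_a[cand$ia[k]] <- TRUE
      used_b[cand$ib[k]] <- TRUE
    }
  }
  common <- cand[keep, .(ia, ib)]
  # slop test for the unmatched
  near <- function(src, dst) {
    if (nrow(src) == 0 || nrow(dst) == 0) return(rep(FALSE, nrow(src)))
    h1 <- GenomicRanges::findOverlaps(loop_anchor_gr(src, 1),
                                      loop_anchor_gr(dst, 1),
                                      maxgap = slop_bp)
    h2 <- GenomicRanges::findOverlaps(loop_anchor_gr(src, 2),
                                      loop_anchor_gr(dst, 2),
                                      maxgap = slop_bp)
    k1 <- paste(S4Vectors::queryHits(h1), S4Vectors::subjectHits(h1))
    k2 <- paste(S4Vectors::queryHits(h2), S4Vectors::subjectHits(h2))
    both <- do.call(rbind, strsplit(intersect(k1, k2), " "))
    out <- rep(FALSE, nrow(src))
    if (!is.null(both)) out[unique(as.integer(both[, 1]))] <- TRUE
    out
  }
  a_near <- near(setA, setB)
  b_near <- near(setB, setA)
  a_status <- ifelse(used_a, "common", ifelse(a_near, "ambiguous", "specific"))
  b_status <- ifelse(used_b, "common", ifelse(b_near, "ambiguous", "specific"))
  structure(list(common = common,
                 a_specific = setA[a_status == "specific"],
                 b_specific = setB[b_status == "specific"],
                 a_status = a_status, b_status = b_status,
                 f = f, slop_bp = slop_bp),
            class = "LoopComparison")
}

#' Classify loops by genic context of their anchors
#'
#' An anchor is "gene" iff it overlaps at least one gene body by >= 1 bp;
#' the loop class follows from the two anchor states.
#'
#' @param loops a LoopSet.
#' @param genes gene table.
#' @return the LoopSet with logical `anchor1_gene`, `anchor2_gene` and
#'   `class` in gene-gene / intergenic-gene / intergenic-intergenic.
#' @export
classify_loops <- function(loops, genes) {
  loops <- data.table::copy(loops)
  gr_g <- gr_from_bed(genes)
  a1 <- GenomicRanges::countOverlaps(loop_anchor_gr(loops, 1), gr_g) > 0
  a2 <- GenomicRanges::countOverlaps(loop_anchor_gr(loops, 2), gr_g) > 0
  loops[, anchor1_gene := a1]
  loops[, anchor2_gene := a2]
  loops[, class := data.table::fcase(
    a1 & a2, "gene-gene",
    !a1 & !a2, "intergenic-intergenic",
    default = "intergenic-gene")]
  loops[]
}

#' Aggregate peak analysis (APA)
#'
#' Mean O/E submatrix over loop pixels, +/- `flank_bins` around each
#' anchor pair; the center score is the center pixel divided by the mean
#' of the four corner boxes (box width `max(1, floor(flank_bins / 2))`).
#' Loops whose window leaves the matrix or crosses the diagonal are
#' excluded and counted.
#'
#' @param map a balanced ContactMap.
#' @param loops a LoopSet with bin1/bin2 on this map's grid (or bp anchors;
#'   bins are derived from start coordinates if absent).
#' @param flank_bins window half-width (default 5).
#' @return list(pileup = (2f+1)^2 matrix, score, n_used, n_excluded).
#' @export
apa <- function(map, loops, flank_bins = 5) {
  oe <- observed_over_expected(map)
  res <- map$resolution
  f <- flank_bins
  if (!"bin1" %in% names(loops)) {
    loops <- data.table::copy(loops)
    loops[, bin1 := start1 %/% res]
    loops[, bin2 := start2 %/% res]
  }
  size <- 2 * f + 1
  acc <- matrix(0, size, size)
  nacc <- matrix(0, size, size)
  used <- 0L; excluded <- 0L
  for (k in seq_len(nrow(loops))) {
    ch <- loops$chrom1[k]
    O <- oe[[ch]]
    if (is.null(O)) { excluded <- excluded + 1L; next }
    i <- loops$bin1[k] + 1L; j <- loops$bin2[k] + 1L
    if (i - f < 1 || j + f > nrow(O) || (j - f) - (i + f) < 1) {
      excluded <- excluded + 1L; next
    }
    sub <- O[(i - f):(i + f), (j - f):(j + f)]
    fin <- is.finite(sub)
    acc[fin] <- acc[fin] + sub[fin]
    nacc <- nacc + fin
    used <- used + 1L
  }
  pileup <- ifelse(nacc > 0, acc / nacc, NA_real_)
  w <- max(1, floor(f / 2))
  corner <- function(ri, ci) mean(pileup[ri, ci], na.rm = TRUE)
  corners <- c(corner(1:w, 1:w), corner(1:w, (size - w + 1):size),
               corner((size - w + 1):size, 1:w),
               corner((size - w + 1):size, (size - w + 1):size))
  score <- pileup[f + 1, f + 1] / mean(corners)
  list(pileup = pileup, score = score, n_used = used, n_excluded = excluded)
}
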