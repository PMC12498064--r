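# Insulation-score TAD boundary detection and TAD-change classification.

#' Insulation score track
#'
#' For each bin i, the mean balanced contact over the diamond window
#' `{(u, v): i-w <= u < i < v <= i+w}` (pairs crossing the bin), excluding
#' the `ignore_diags` nearest diagonals, log2-normalized by the
#' chromosome-wide mean diamond value. NA within `w` bins of chromosome
#' ends and where more than half the diamond is masked.
#'
#' @param map a balanced ContactMap (typically 40-kb resolution).
#' @param window_bins diamond half-width w in bins (default 10, i.e.
#'   400 kb at 40-kb resolution).
#' @param ignore_diags diagonals |u - v| <= ignore_diags excluded
#'   (default 2).
#' @return An `InsulationTrack` data.table: chrom, bin, start, end, score,
#'   dist_bad (bins to nearest masked bin). Attributes record the window.
#' @export
insulation_track <- function(map, window_bins = 10, ignore_diags = 2) {
  if (window_bins < ignore_diags + 1) {
    stop("window_bins must be >= ignore_diags + 1", call. = FALSE)
  }
  bins <- cm_bins(map)
  out <- list()
  for (ch in names(map$counts)) {
    B <- balanced_matrix(map, ch)
    n <- nrow(B)
    raw <- rep(NA_real_, n)
    if (window_bins >= n) {
      warning(sprintf("window (%d bins) exceeds chromosome %s (%d bins); all-NA track",
                      window_bins, ch, n))
    } else {
      for (i in seq_len(n)) {
        if (i - window_bins < 1 || i + window_bins > n) next
        u <- (i - window_bins):(i - 1)
        v <- (i + 1):(i + window_bins)
        sub <- B[u, v, drop = FALSE]
        dmat <- outer(u, v, function(a, b) abs(a - b))
        sub[dmat <= ignore_diags] <- NA
        vals <- sub[!is.na(dmat) & dmat > ignore_diags]
        n_cells <- sum(dmat > ignore_diags)
        defined <- sum(is.finite(vals))
        if (n_cells > 0 && defined > n_cells / 2) {
          raw[i] <- mean(vals[is.finite(vals)])
        }
      }
      norm <- mean(raw, na.rm = TRUE)
      raw <- log2(raw / norm)
    }
    mask <- map$mask[[ch]]
    bad_bins <- which(mask)
    dist_bad <- if (length(bad_bins)) {
      vapply(seq_len(n), function(i) min(abs(i - bad_bins)), 0)
    } else rep(Inf, n)
    b <- bins[chrom == ch]
    b[, score := raw]
    b[, dist_bad := dist_bad]
    out[[ch]] <- b
  }
  track <- data.table::rbindlist(out)
  data.table::setattr(track, "window_bins", window_bins)
  data.table::setattr(track, "ignore_diags", ignore_diags)
  data.table::setattr(track, "class", c("InsulationTrack", class(track)))
  track
}

# local minima (leftmost of a plateau) of a vector with NAs; returns indices
local_minima <- function(x) {
  n <- length(x)
  out <- integer(0)
  for (i in seq_len(n)) {
    if (!is.finite(x[i])) next
    # previous and next defined values
    l <- i - 1; while (l >= 1 && !is.finite(x[l])) l <- l - 1
    r <- i + 1; while (r <= n && !is.finite(x[r])) r <- r + 1
    left_ok <- l < 1 || x[l] > x[i]
    right_ok <- r > n || x[r] >= x[i]
    if (left_ok && right_ok && !(l < 1 && r > n)) out <- c(out, i)
  }
  out
}

local_maxima <- function(x) local_minima(-x)

#' Call TAD boundaries from an insulation track
#'
#' Candidates are local minima of the insulation score; boundary strength
#' is the prominence `min(left flank maximum - I, right flank maximum - I)`
#' using the nearest flanking local maximum on each side (chromosome edge
#' runs fall back to the run maximum). A candidate is called iff strength
#' >= `threshold` and it lies at least `min_dist_bad_bin` bins from any
#' masked bin. Ties between equal adjacent minima resolve to the lower bin
#' index.
#'
#' @param track an [insulation_track()].
#' @param threshold minimum boundary strength (default 0.1).
#' @param min_dist_bad_bin minimum distance, in bins, to a masked bin
#'   (default 5).
#' @return data.table of boundaries: chrom, bin, start, end, score,
#'   strength.
#' @export
call_boundaries <- function(track, threshold = 0.1, min_dist_bad_bin = 5) {
  out <- list()
  for (ch in unique(track$chrom)) {
    t_ch <- track[chrom == ch]
    x <- t_ch$score
    mins <- local_minima(x)
    if (!length(mins)) next
    maxs <- local_maxima(x)
    strength <- vapply(mins, function(i) {
      lmax <- maxs[maxs < i]
      rmax <- maxs[maxs > i]
      run <- which(is.finite(x))
      lv <- if (length(lmax)) x[max(lmax)] else max(x[run[run < i]], x[i])
      rv <- if (length(rmax)) x[min(rmax)] else max(x[run[run > i]], x[i])
      min(lv - x[i], rv - x[i])
    }, 0)
    keep <- strength >= threshold & t_ch$dist_bad[mins] >= min_dist_bad_bin
    if (!any(keep)) next
    b <- t_ch[mins[keep]]
    b[, strength := strength[keep]]
    out[[ch]] <- b[, .(chrom, bin, start, end, score, strength)]
  }
  if (!length(out)) {
    return(data.table::data.table(chrom = character(), bin = integer(),
                                  start = integer(), end = integer(),
                                  score = numeric(), strength = numeric()))
  }
  data.table::rbindlist(out)
}

#' Derive TAD intervals from boundary calls
#'
#' TADs are the half-open bin intervals between consecutive boundary bins
#' (and the chromosome ends); boundary bins themselves belong to no TAD, so
#' TADs plus boundary bins tile each chromosome. Intervals shorter than
#' `min_bins` are dropped (set `min_bins = 1` to keep the exact tiling).
#'
#' @param boundaries output of [call_boundaries()].
#' @param map the ContactMap the track came from (for chromosome sizes), or
#'   a named vector of bin counts per chromosome.
#' @param min_bins minimum TAD span in bins (default 3).
#' @return A `TadSet` data.table: chrom, start_bin, end_bin, start, end,
#'   size_bp.
#' @export
derive_tads <- function(boundaries, map, min_bins = 3) {
  if (inherits(map, "ContactMap")) {
    nb <- vapply(map$counts, nrow, 0L)
    res <- map$resolution
  } else {
    nb <- map
    res <- attr(map, "resolution") %||% 1L
  }
  out <- list()
  for (ch in names(nb)) {
    n <- nb[[ch]]
    b <- sort(boundaries$bin[boundaries$chrom == ch])
    starts <- c(0L, b + 1L)
    ends <- c(b, n)
    keep <- (ends - starts) >= min_bins
    if (!any(keep)) next
    out[[ch]] <- data.table::data.table(chrom = ch,
                                        start_bin = starts[keep],
                                        end_bin = ends[keep])
  }
  tads <- if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(chrom = character(), start_bin = integer(),
                           end_bin = integer())
  tads[, start := start_bin * res]
  tads[, end := end_bin * res]
  tads[, size_bp := end - start]
  data.table::setattr(tads, "resolution", res)
  data.table::setattr(tads, "class", c("TadSet", class(tads)))
  tads[]
}

#' Compare boundary lists between two conditions
#'
#' Greedy nearest-first matching within `tol_bins`: candidate pairs are
#' sorted by distance (ties by position) and matched one-to-one, so
#' `|shared| + |A_specific| = |A|` and likewise for B.
#'
#' @param boundsA,boundsB boundary tables from [call_boundaries()].
#' @param tol_bins match tolerance in bins (default 1).
#' @return list(shared = matched pair table, a_specific, b_specific).
#' @export
compare_boundaries <- function(boundsA, boundsB, tol_bins = 1) {
  shared <- list(); a_spec <- list(); b_spec <- list()
  chroms <- union(unique(boundsA$chrom), unique(boundsB$chrom))
  for (ch in chroms) {
    a <- sort(boundsA$bin[boundsA$chrom == ch])
    b <- sort(boundsB$bin[boundsB$chrom == ch])
    cand <- data.table::CJ(ia = seq_along(a), ib = seq_along(b))
    if (nrow(cand)) {
      cand[, d := abs(a[ia] - b[ib])]
      cand <- cand[d <= tol_bins]
      data.table::setorder(cand, d, ia, ib)
    }
    used_a <- logical(length(a)); used_b <- logical(length(b))
    pairs <- list()
    for (k in seq_len(nrow(cand))) {
      ia <- cand$ia[k]; ib <- cand$ib[k]
      if (used_a[ia] || used_b[ib]) next
      used_a[ia] <- TRUE; used_b[ib] <- TRUE
      pairs[[length(pairs) + 1]] <- data.table::data.table(
        chrom = ch, bin_a = a[ia], bin_b = b[ib], dist = cand$d[k])
    }
    if (length(pairs)) shared[[ch]] <- data.table::rbindlist(pairs)
    if (any(!used_a)) a_spec[[ch]] <- data.table::data.table(chrom = ch,
                                                             bin = a[!used_a])
    if (any(!used_b)) b_spec[[ch]] <- data.table::data.table(chrom = ch,
                                                             bin = b[!used_b])
  }
  empty <- data.table::data.table(chrom = character(), bin = integer())
  list(shared = if (length(shared)) data.table::rbindlist(shared) else
         data.table::data.table(chrom = character(), bin_a = integer(),
                                bin_b = integer(), dist = integer()),
       a_specific = if (length(a_spec)) data.table::rbindlist(a_spec) else empty,
       b_specific = if (length(b_spec)) data.table::rbindlist(b_spec) else empty)
}

#' Classify TAD changes between two conditions
#'
#' Builds the bipartite bp-overlap graph between the two TAD sets and
#' labels each connected component: one control TAD overlapping one
#' treatment TAD reciprocally by more than 75% (strict) is stable; k >= 2
#' control TADs matching one treatment TAD is a merge; one control TAD
#' matching k >= 2 treatment TADs is a split; everything else (including
#' 1-to-1 below the 75% rule and unmatched TADs) is a rearrangement.
#'
#' @param tadsA,tadsB TadSets (control first; bp columns start/end used).
#' @param stable_frac reciprocal-overlap threshold (default 0.75, strict >).
#' @return A `TadComparison`: list with `tads` (every TAD with component id
#'   and label) and `counts` (label totals over components).
#' @export
classify_tad_changes <- function(tadsA, tadsB, stable_frac = 0.75) {
  a <- data.table::as.data.table(tadsA)[, .(chrom, start, end)]
  b <- data.table::as.data.table(tadsB)[, .(chrom, start, end)]
  a[, side := "control"]; b[, side := "treatment"]
  a[, idx := seq_len(.N)]; b[, idx := seq_len(.N)]
  hits <- if (nrow(a) && nrow(b)) {
    GenomicRanges::findOverlaps(gr_from_bed(a), gr_from_bed(b), minoverlap = 1L)
  } else S4Vectors::Hits(sort.by.query = TRUE)
  # union-find over nodes: control 1..nA, treatment nA+1..nA+nB
  nA <- nrow(a); nB <- nrow(b)
  parent <- seq_len(nA + nB)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_along(hits)) {
    i <- find(S4Vectors::queryHits(hits)[k])
    j <- find(nA + S4Vectors::subjectHits(hits)[k])
    if (i != j) parent[j] <- i
  }
  comp <- vapply(seq_len(nA + nB), find, 0L)
  comp <- match(comp, unique(comp))
  a[, component := comp[seq_len(nA)]]
  b[, component := comp[nA + seq_len(nB)]]
  all_tads <- data.table::rbindlist(list(a, b))
  lab <- character(max(comp, 0))
  for (cid in seq_len(max(comp, 0))) {
    ca <- a[component == cid]; cb <- b[component == cid]
    if (nrow(ca) == 1 && nrow(cb) == 1) {
      ov <- max(0, min(ca$end, cb$end) - max(ca$start, cb$start))
      fa <- ov / (ca$end - ca$start)
      fb <- ov / (cb$end - cb$start)
      lab[cid] <- if (fa > stable_frac && fb > stable_frac) "stable" else "rearrangement"
    } else if (nrow(ca) >= 2 && nrow(cb) == 1) {
      lab[cid] <- "merge"
    } else if (nrow(ca) == 1 && nrow(cb) >= 2) {
      lab[cid] <- "split"
    } else {
      lab[cid] <- "rearrangement"
    }
  }
  all_tads[, label := lab[component]]
  counts <- table(factor(lab, levels = c("stable", "merge", "split",
                                         "rearrangement")))
  structure(list(tads = all_tads[], counts = counts),
            class = "TadComparison")
}

#' Feature enrichment at TAD boundaries
#'
#' Mean per-bin feature density in boundary bins relative to the genome
#' background, with a flanking metaprofile.
#'
#' @param bounds boundary table from [call_boundaries()].
#' @param features interval table (chrom, start, end) of the feature
#'   (genes, OCRs, peaks), or a per-bin numeric list per chromosome.
#' @param map the ContactMap providing the bin grid.
#' @param flank_bins metaprofile half-width in bins (default 5).
#' @return list(ratio = boundary/background density ratio, boundary_mean,
#'   genome_mean, profile = mean density at offsets -flank..flank).
#' @export
boundary_feature_enrichment <- function(bounds, features, map, flank_bins = 5) {
  bins <- cm_bins(map)
  if (is.data.frame(features)) {
    gr_b <- gr_from_bed(bins)
    dens <- GenomicRanges::countOverlaps(gr_b, gr_from_bed(features))
  } else {
    dens <- unlist(features[unique(bins$chrom)])
  }
  bins[, dens := dens]
  genome_mean <- mean(bins$dens)
  bkey <- paste(bounds$chrom, bounds$bin)
  is_boundary <- paste(bins$chrom, bins$bin) %in% bkey
  boundary_mean <- mean(bins$dens[is_boundary])
  offs <- -flank_bins:flank_bins
  prof <- vapply(offs, function(o) {
    idx <- data.table::data.table(chrom = bounds$chrom, bin = bounds$bin + o)
    m <- merge(idx, bins, by = c("chrom", "bin"))
    mean(m$dens)
  }, 0)
  list(ratio = boundary_mean / genome_mean,
       boundary_mean = boundary_mean, genome_mean = genome_mean,
       profile = stats::setNames(prof, offs))
}
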