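# Contact-map data model and normalization. A ContactMap holds one dense
# symmetric raw-count matrix per chromosome plus balancing weights and a
# bad-bin mask; genomes handled here are small enough (<= a few thousand
# bins per chromosome) that dense storage is the simple, fast choice.

#' Construct a ContactMap
#'
#' @param counts named list of symmetric integer matrices, one per chromosome.
#' @param resolution bin size in bp.
#' @param chrom_sizes named numeric vector of chromosome lengths in bp;
#'   defaults to `nrow(matrix) * resolution`.
#' @return A `ContactMap` object: raw counts, resolution, chromosome sizes,
#'   and (after [balance()]) per-bin weights and a bad-bin mask.
#' @export
contact_map <- function(counts, resolution, chrom_sizes = NULL) {
  stopifnot(is.list(counts), length(counts) > 0, !is.null(names(counts)))
  for (nm in names(counts)) {
    m <- counts[[nm]]
    if (!is.matrix(m) || nrow(m) != ncol(m)) {
      stop(sprintf("counts[['%s']] must be a square matrix", nm), call. = FALSE)
    }
    if (!isTRUE(all.equal(m, t(m), tolerance = 0))) {
      stop(sprintf("counts[['%s']] is not symmetric", nm), call. = FALSE)
    }
  }
  if (is.null(chrom_sizes)) {
    chrom_sizes <- vapply(counts, nrow, 0L) * resolution
  }
  structure(list(counts = counts,
                 resolution = as.integer(resolution),
                 chrom_sizes = chrom_sizes,
                 weights = NULL, mask = NULL,
                 converged = NULL),
            class = "ContactMap")
}

#' @export
print.ContactMap <- function(x, ...) {
  nb <- vapply(x$counts, nrow, 0L)
  cat(sprintf("ContactMap: %d chromosome(s) at %d bp (%s bins), %s\n",
              length(x$counts), x$resolution, paste(nb, collapse = "+"),
              if (is.null(x$weights)) "unbalanced" else "balanced"))
  invisible(x)
}

#' Bin table of a ContactMap
#'
#' @param map a ContactMap.
#' @return data.table chrom, start, end, bin (0-based index within chromosome).
#' @export
cm_bins <- function(map) {
  res <- map$resolution
  data.table::rbindlist(lapply(names(map$counts), function(ch) {
    n <- nrow(map$counts[[ch]])
    data.table::data.table(chrom = ch, bin = 0:(n - 1L),
                           start = as.integer((0:(n - 1L)) * res),
                           end = as.integer((1:n) * res))
  }))
}

#' Write / read a contact map as sparse triples
#'
#' Upper-triangle (bin1 <= bin2) nonzero cis pixels, TSV with header
#' `chrom1 bin1 chrom2 bin2 count`. `read_contacts()` requires resolution and
#' chromosome sizes so empty chromosomes round-trip.
#'
#' @param map a ContactMap.
#' @param path output file.
#' @export
write_contacts <- function(map, path) {
  rows <- lapply(names(map$counts), function(ch) {
    m <- map$counts[[ch]]
    idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    data.table::data.table(chrom1 = ch, bin1 = idx[, 1] - 1L,
                           chrom2 = ch, bin2 = idx[, 2] - 1L,
                           count = m[idx])
  })
  dt <- data.table::rbindlist(rows)
  if (nrow(dt) == 0) {
    dt <- data.table::data.table(chrom1 = character(), bin1 = integer(),
                                 chrom2 = character(), bin2 = integer(),
                                 count = numeric())
  }
  data.table::setorder(dt, chrom1, bin1, bin2)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_contacts
#' @param resolution bin size in bp.
#' @param chrom_sizes named vector of chromosome lengths in bp.
#' @export
read_contacts <- function(path, resolution, chrom_sizes) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  if (nrow(dt) > 0) {
    stopifnot_cols(dt, c("chrom1", "bin1", "chrom2", "bin2", "count"),
                   "contact triples")
    bad <- which(!is.finite(dt$count) | dt$count < 0 |
                   dt$bin1 %% 1 != 0 | dt$bin2 %% 1 != 0)
    if (length(bad)) {
      stop(sprintf("malformed contact record at data line %d", bad[1]),
           call. = FALSE)
    }
    if (any(dt$chrom1 != dt$chrom2)) {
      stop("trans (inter-chromosomal) triples are not representable in a per-chromosome matrix",
           call. = FALSE)
    }
  }
  nbins <- ceiling(chrom_sizes / resolution)
  counts <- lapply(names(chrom_sizes), function(ch) {
    n <- as.integer(nbins[[ch]])
    m <- matrix(0, n, n)
    sub <- dt[dt$chrom1 == ch, ]
    if (nrow(sub)) {
      if (any(sub$bin1 >= n | sub$bin2 >= n | sub$bin1 < 0 | sub$bin2 < 0)) {
        stop(sprintf("bin index out of range on chromosome %s", ch),
             call. = FALSE)
      }
      m[cbind(sub$bin1 + 1L, sub$bin2 + 1L)] <- sub$count
      m[cbind(sub$bin2 + 1L, sub$bin1 + 1L)] <- sub$count
    }
    m
  })
  names(counts) <- names(chrom_sizes)
  contact_map(counts, resolution, chrom_sizes)
}

#' Balance a contact map by iterative correction
#'
#' Row-normalizing iterative correction: per-bin weights `w` are adjusted
#' until every unmasked row sum of `w_i * w_j * C_ij` is equal (within
#' `tol`, relative). Bins with no counts, or with marginal coverage below
#' the `mask_quantile` quantile of nonzero rows, are masked and excluded.
#' Weights are scaled so the mean balanced row sum is 1.
#'
#' @param map a ContactMap of raw counts.
#' @param tol relative row-sum convergence tolerance (default 1e-5).
#' @param max_iter maximum sweeps (default 200); non-convergence returns the
#'   partial weights with `converged = FALSE` and a warning.
#' @param mask_quantile coverage quantile below which nonzero bins are
#'   masked (default 0.02).
#' @return The map with `weights`, `mask` (TRUE = bad bin) and `converged`
#'   filled per chromosome.
#' @export
balance <- function(map, tol = 1e-5, max_iter = 200, mask_quantile = 0.02) {
  weights <- list(); mask <- list(); converged <- list()
  for (ch in names(map$counts)) {
    C <- map$counts[[ch]]
    n <- nrow(C)
    cov <- rowSums(C)
    bad <- cov == 0
    nz <- cov[!bad]
    if (length(nz) > 0 && mask_quantile > 0) {
      thr <- stats::quantile(nz, mask_quantile, names = FALSE)
      bad <- bad | (cov < thr)
    }
    if (all(bad)) {
      weights[[ch]] <- rep(NA_real_, n)
      mask[[ch]] <- rep(TRUE, n)
      converged[[ch]] <- TRUE
      next
    }
    keep <- which(!bad)
    Cs <- C[keep, keep, drop = FALSE]
    w <- rep(1, length(keep))
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      s <- as.vector(Cs %*% w) * w
      rel <- s / mean(s)
      if (max(abs(rel - 1)) <= tol) { ok <- TRUE; break }
      w <- w / sqrt(rel)
    }
    if (!ok) warning(sprintf("balance: chromosome %s did not converge in %d iterations",
                             ch, max_iter))
    s <- as.vector(Cs %*% w) * w
    w <- w / sqrt(mean(s))
    full <- rep(NA_real_, n)
    full[keep] <- w
    weights[[ch]] <- full
    mask[[ch]] <- bad
    converged[[ch]] <- ok
  }
  map$weights <- weights
  map$mask <- mask
  map$converged <- converged
  map
}

#' Balanced matrix for one chromosome
#'
#' @param map a balanced ContactMap.
#' @param chrom chromosome name.
#' @return dense matrix `w_i * w_j * C_ij`, NA on masked rows/columns.
#' @export
balanced_matrix <- function(map, chrom) {
  if (is.null(map$weights)) stop("map is not balanced; run balance() first",
                                 call. = FALSE)
  w <- map$weights[[chrom]]
  map$counts[[chrom]] * outer(w, w)
}

#' Distance-decay (P(s)) profile
#'
#' Mean balanced contact per bin-distance stratum, pooled over chromosomes
#' and unmasked pixels. This is the expected model used by O/E, z-scores and
#' the loop caller.
#'
#' @param map a balanced ContactMap.
#' @return A `DecayProfile` data.table: dist (bins), dist_bp, mean, sd, n
#'   (pixel count). Strata with no unmasked pixels have NA mean and are
#'   flagged by `n == 0`.
#' @export
expected_by_distance <- function(map) {
  maxn <- max(vapply(map$counts, nrow, 0L))
  sums <- numeric(maxn); sqs <- numeric(maxn); ns <- numeric(maxn)
  for (ch in names(map$counts)) {
    B <- balanced_matrix(map, ch)
    n <- nrow(B)
    for (d in 0:(n - 1)) {
      v <- B[cbind(1:(n - d), (1 + d):n)]
      v <- v[!is.na(v)]
      sums[d + 1] <- sums[d + 1] + sum(v)
      sqs[d + 1] <- sqs[d + 1] + sum(v^2)
      ns[d + 1] <- ns[d + 1] + length(v)
    }
  }
  mean_ <- ifelse(ns > 0, sums / ns, NA_real_)
  var_ <- ifelse(ns > 1, pmax(0, sqs / ns - mean_^2) * ns / (ns - 1), NA_real_)
  prof <- data.table::data.table(dist = 0:(maxn - 1),
                                 dist_bp = (0:(maxn - 1)) * map$resolution,
                                 mean = mean_, sd = sqrt(var_), n = ns)
  data.table::setattr(prof, "class", c("DecayProfile", class(prof)))
  prof
}

#' Observed/expected matrices
#'
#' Divides each balanced pixel by the distance-stratum mean from a
#' [expected_by_distance()] profile. Depth-invariant: scaling raw counts by
#' a constant leaves O/E unchanged.
#'
#' @param map a balanced ContactMap.
#' @param profile optional DecayProfile; computed from `map` if NULL.
#' @return named list of O/E matrices (NA on masked pixels and on strata
#'   with zero expected value).
#' @export
observed_over_expected <- function(map, profile = NULL) {
  if (is.null(profile)) profile <- expected_by_distance(map)
  exp_by_d <- profile$mean
  exp_by_d[!is.na(exp_by_d) & exp_by_d == 0] <- NA_real_
  out <- lapply(names(map$counts), function(ch) {
    B <- balanced_matrix(map, ch)
    n <- nrow(B)
    D <- abs(outer(1:n, 1:n, "-"))
    B / matrix(exp_by_d[D + 1], n, n)
  })
  names(out) <- names(map$counts)
  out
}

# Per-stratum mean/sd of balanced values smoothed over log-distance with
# LOWESS (span `span`); the diagonal stratum keeps its raw statistics since
# it is off the log-distance axis. sd floored to avoid division blow-ups.
lowess_mu_sigma <- function(profile, span = 0.3, sd_floor = 1e-6) {
  ok <- which(profile$dist >= 1 & profile$n >= 2 & is.finite(profile$mean) &
                profile$mean > 0 & is.finite(profile$sd) & profile$sd > 0)
  mu <- profile$mean
  sig <- profile$sd
  if (length(ok) >= 5) {
    # fit in log-log space: both moments decay as power laws of distance
    lx <- log10(profile$dist[ok])
    mu_fit <- stats::lowess(lx, log10(profile$mean[ok]), f = span)
    sd_fit <- stats::lowess(lx, log10(profile$sd[ok]), f = span)
    mu[ok] <- 10^stats::approx(mu_fit$x, mu_fit$y, xout = lx, rule = 2)$y
    sig[ok] <- 10^stats::approx(sd_fit$x, sd_fit$y, xout = lx, rule = 2)$y
  }
  sig <- pmax(sig, sd_floor)
  list(mu = mu, sigma = sig)
}

#' LOWESS z-score normalization of a contact map
#'
#' Standardizes every pixel against its distance stratum:
#' `Z_ij = (B_ij - mu(s)) / sigma(s)` with the stratum mean and SD smoothed
#' over log-distance by LOWESS, so maps of different depth become
#' comparable before subtraction.
#'
#' @param map a balanced ContactMap.
#' @param span LOWESS span over log10 bin-distance (default 0.3).
#' @param sd_floor lower bound for sigma (default 1e-6).
#' @return A `ZScoreMap`: list with per-chromosome `z` matrices, resolution
#'   and mask.
#' @export
zscore <- function(map, span = 0.3, sd_floor = 1e-6) {
  profile <- expected_by_distance(map)
  ms <- lowess_mu_sigma(profile, span = span, sd_floor = sd_floor)
  z <- lapply(names(map$counts), function(ch) {
    B <- balanced_matrix(map, ch)
    n <- nrow(B)
    D <- abs(outer(1:n, 1:n, "-"))
    (B - matrix(ms$mu[D + 1], n, n)) / matrix(ms$sigma[D + 1], n, n)
  })
  names(z) <- names(map$counts)
  structure(list(z = z, resolution = map$resolution,
                 chrom_sizes = map$chrom_sizes, mask = map$mask),
            class = "ZScoreMap")
}

#' Condition-difference matrix of two z-score maps
#'
#' Per-pixel `D = Z(first) - Z(second)`; the sign convention is fixed as
#' first argument minus second, so `difference(a, b)` is exactly the
#' negation of `difference(b, a)`.
#'
#' @param zA,zB ZScoreMaps on the same bin table and resolution.
#' @return A `DifferenceMap` with per-chromosome `d` matrices.
#' @export
difference <- function(zA, zB) {
  if (!identical(names(zA$z), names(zB$z)) ||
      zA$resolution != zB$resolution ||
      !identical(vapply(zA$z, nrow, 0L), vapply(zB$z, nrow, 0L))) {
    stop("z-score maps do not share a bin table", call. = FALSE)
  }
  d <- lapply(names(zA$z), function(ch) zA$z[[ch]] - zB$z[[ch]])
  names(d) <- names(zA$z)
  structure(list(d = d, resolution = zA$resolution,
                 chrom_sizes = zA$chrom_sizes),
            class = "DifferenceMap")
}

#' Partition an interaction pair list into cis and trans
#'
#' @param pairs table with columns chrom1 and chrom2 (one row per
#'   interaction).
#' @return list with `cis_count`, `trans_count` and a logical `is_cis`
#'   vector; counts always sum to `nrow(pairs)`.
#' @export
partition_cis_trans <- function(pairs) {
  stopifnot_cols(pairs, c("chrom1", "chrom2"), "interaction pairs")
  is_cis <- pairs$chrom1 == pairs$chrom2
  list(cis_count = sum(is_cis), trans_count = sum(!is_cis), is_cis = is_cis)
}
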