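#' @importFrom stats cor ecdf lowess p.adjust pbinom ppois pt quantile rgeom
#'   rlnorm rnorm rpois runif rbinom setNames t.test sd binom.test
#' @importFrom utils head tail
NULL

# Deterministic per-stage seed fan-out: one user-facing seed, independent
# streams per pipeline stage. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483029
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

round1 <- function(x) round(x, 1)

# All interval tables in this package are 0-based half-open (BED convention).
# GRanges is 1-based closed; these two helpers are the only crossing points.
gr_from_bed <- function(df, use_strand = FALSE) {
  strand <- if (use_strand && "strand" %in% names(df)) df$strand else "*"
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end),
                         strand = strand)
}

bed_from_gr <- function(gr) {
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

stopifnot_cols <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Signed percent change between two means
#'
#' Reporting arithmetic for phenotype comparisons: the relative change of a
#' treatment mean against a control mean, as a signed percentage rounded to
#' one decimal (e.g. nodule counts per transformed root).
#'
#' @param control_mean numeric > 0, the reference mean.
#' @param treatment_mean numeric, the comparison mean.
#' @return Signed percent change, `100 * (treatment - control) / control`,
#'   rounded to 1 decimal.
#' @examples
#' percent_change(16.2, 30.7)  # +89.5
#' percent_change(10, 5)       # -50
#' @export
percent_change <- function(control_mean, treatment_mean) {
  if (!is.numeric(control_mean) || control_mean <= 0) {
    stop("control_mean must be a positive number", call. = FALSE)
  }
  round1(100 * (treatment_mean - control_mean) / control_mean)
}

#' Pooled percentage from per-group counts
#'
#' Sums numerators and denominators across groups before forming the
#' percentage, so per-tissue counts pool the way totals do.
#'
#' @param n numerator count(s).
#' @param total denominator count(s), same length as `n` or length 1.
#' @param digits decimals to round to (default 1).
#' @return `100 * sum(n) / sum(total)`, rounded.
#' @examples
#' pooled_pct(c(223, 487), c(6455, 10878))  # 4.1
#' @export
pooled_pct <- function(n, total, digits = 1) {
  if (sum(total) <= 0) stop("total must be positive", call. = FALSE)
  round(100 * sum(n) / sum(total), digits)
}
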