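# Plain-text interchange formats. Everything is TSV-based with 0-based
# half-open coordinates; writers emit stable column orders so that repeated
# pipeline runs are byte-identical.

#' Read / write a BED interval file
#'
#' Minimal BED: `chrom start end [name score strand]`. Coordinates are
#' 0-based half-open. Extra columns beyond the first six are ignored on read.
#'
#' @param path file path.
#' @return `read_bed()`: a data.table with columns chrom, start, end and any
#'   of name, score, strand present in the file.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (nrow(dt) == 0) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer()))
  }
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(dt, seq_len(min(ncol(dt), 6L)),
                       cols[seq_len(min(ncol(dt), 6L))])
  dt[, seq_len(min(ncol(dt), 6L)), with = FALSE]
}

#' @rdname read_bed
#' @param x interval table with at least chrom, start, end.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  data.table::fwrite(x[, cols, with = FALSE], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read / write a bedGraph signal track
#'
#' Four columns: chrom, start, end, value; 0-based half-open, value is the
#' per-base signal over the interval. Intervals not covered by any row are
#' treated as signal 0 by all consumers in this package.
#'
#' @param path file path.
#' @return data.table with columns chrom, start, end, value.
#' @export
read_bedgraph <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  dt
}

#' @rdname read_bedgraph
#' @param x track table with chrom, start, end, value.
#' @export
write_bedgraph <- function(x, path) {
  data.table::fwrite(x[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read / write loops as BEDPE
#'
#' Columns: chrom1 start1 end1 chrom2 start2 end2 name score. Any further
#' columns written by this package (resolution, q) are restored on read.
#'
#' @param path file path.
#' @return data.table of loop anchors.
#' @export
read_bedpe <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  base <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "name", "score", "resolution", "q")
  data.table::setnames(dt, seq_len(min(ncol(dt), length(base))),
                       base[seq_len(min(ncol(dt), length(base)))])
  dt
}

#' @rdname read_bedpe
#' @param x loop table.
#' @export
write_bedpe <- function(x, path) {
  cols <- intersect(c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                      "name", "score", "resolution", "q"), names(x))
  data.table::fwrite(x[, cols, with = FALSE], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read / write gene models (GFF-lite TSV)
#'
#' Five tab-separated columns with header: chrom, start, end, strand,
#' gene_id; 0-based half-open, strand in {+,-}.
#'
#' @param path file path.
#' @return data.table of gene models.
#' @export
read_genes <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  stopifnot_cols(dt, c("chrom", "start", "end", "strand", "gene_id"), "gene table")
  dt
}

#' @rdname read_genes
#' @param x gene table.
#' @export
write_genes <- function(x, path) {
  data.table::fwrite(x[, c("chrom", "start", "end", "strand", "gene_id")],
                     path, sep = "\t")
  invisible(path)
}

#' Read / write an expression table
#'
#' TSV with header: gene_id then one column per sample (FPKM).
#'
#' @param path file path.
#' @return data.table, first column gene_id.
#' @export
read_expression <- function(path) {
  data.table::fread(path, header = TRUE, sep = "\t")
}

#' @rdname read_expression
#' @param x expression table.
#' @export
write_expression <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}
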