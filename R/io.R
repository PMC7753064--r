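#' Read a BED3/BED4/BED6 file
#'
#' Tab-separated, no header. Column 4 (name) is kept as \code{payload},
#' column 6 as \code{strand} when present.
#'
#' @param path file path.
#' @return interval data.frame in BED convention.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  s <- as.character(GenomicRanges::strand(gr))
  if (any(s != "*")) df$strand <- ifelse(s == "*", ".", s)
  if (!is.null(gr$name)) df$payload <- gr$name
  class(df) <- c("bed_intervals", "data.frame")
  df
}

#' Write intervals as BED
#'
#' Writes chrom/start/end and, when present, the payload as BED column 4.
#'
#' @param df interval data.frame.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  out <- df[, c("chrom", "start", "end"), drop = FALSE]
  if ("payload" %in% names(df)) out$name <- df$payload
  write.table(format(out, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSV gene-model table
#'
#' Expected columns: \code{gene_id}, \code{chrom}, \code{strand},
#' \code{tx_start}, \code{tx_end}, \code{exon_starts}, \code{exon_ends}
#' (comma-separated position lists), optionally \code{utr5_start},
#' \code{utr5_end}, \code{utr3_start}, \code{utr3_end}. Coordinates are
#' 0-based half-open.
#'
#' @param path file path.
#' @return normalized gene-model data.frame with list-columns
#'   \code{exon_starts}/\code{exon_ends} and derived \code{tss}/\code{tes}.
#' @export
read_gene_models <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  normalize_gene_models(df)
}

#' Write a gene-model table as TSV
#' @param genes normalized gene-model data.frame.
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  out <- genes
  out$exon_starts <- vapply(genes$exon_starts, paste, "", collapse = ",")
  out$exon_ends <- vapply(genes$exon_ends, paste, "", collapse = ",")
  out$tss <- NULL; out$tes <- NULL
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize and validate a gene-model table
#'
#' Parses comma lists into sorted integer vectors, derives \code{tss} and
#' \code{tes} from strand, and checks the gene-model invariants (exons
#' sorted, non-overlapping, inside the transcript span).
#'
#' @param df raw gene-model data.frame.
#' @return normalized data.frame.
#' @export
normalize_gene_models <- function(df) {
  req <- c("gene_id", "chrom", "strand", "tx_start", "tx_end",
           "exon_starts", "exon_ends")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("gene model table missing columns: ",
                         paste(miss, collapse = ", "))
  parse_list <- function(x) {
    if (is.list(x)) lapply(x, function(v) sort(as.numeric(v)))
    else lapply(strsplit(as.character(x), ","),
                function(v) sort(as.numeric(v)))
  }
  df$exon_starts <- parse_list(df$exon_starts)
  df$exon_ends <- parse_list(df$exon_ends)
  for (opt in c("utr5_start", "utr5_end", "utr3_start", "utr3_end"))
    if (is.null(df[[opt]])) df[[opt]] <- NA_real_
  for (i in seq_len(nrow(df))) {
    es <- df$exon_starts[[i]]; ee <- df$exon_ends[[i]]
    if (length(es) != length(ee) || any(ee <= es) ||
        (length(es) > 1L && any(es[-1L] < ee[-length(ee)])))
      stop("invalid exon structure for gene ", df$gene_id[i])
    if (es[1L] < df$tx_start[i] || ee[length(ee)] > df$tx_end[i])
      stop("exons outside transcript span for gene ", df$gene_id[i])
  }
  if (!all(df$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  df$tss <- ifelse(df$strand == "-", df$tx_end, df$tx_start)
  df$tes <- ifelse(df$strand == "-", df$tx_start, df$tx_end)
  df
}

#' Read a paired expression table
#'
#' @param fpkm_path TSV of FPKM values, genes in rows (first column
#'   \code{gene_id}), samples in columns.
#' @param pairing_path TSV with columns \code{patient}, \code{normal},
#'   \code{tumor} naming the sample columns of each matched pair.
#' @return an \code{expression_table}: list with \code{fpkm} matrix and
#'   \code{pairing} data.frame.
#' @export
read_expression <- function(fpkm_path, pairing_path) {
  df <- read.delim(fpkm_path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  pairing <- read.delim(pairing_path, stringsAsFactors = FALSE)
  expression_table(m, pairing)
}

#' Construct a paired expression table
#'
#' @param fpkm numeric matrix, genes x samples, FPKM units.
#' @param pairing data.frame with columns \code{patient}, \code{normal},
#'   \code{tumor}; the tumor/normal columns must name columns of \code{fpkm}
#'   and form a bijection on patients.
#' @return list with class \code{"expression_table"}.
#' @export
expression_table <- function(fpkm, pairing) {
  stopifnot(is.matrix(fpkm),
            all(c("patient", "normal", "tumor") %in% names(pairing)))
  if (any(fpkm < 0)) stop("FPKM values must be non-negative")
  cols <- c(pairing$normal, pairing$tumor)
  if (anyDuplicated(cols) || !all(cols %in% colnames(fpkm)))
    stop("pairing must be a bijection onto distinct fpkm columns")
  structure(list(fpkm = fpkm, pairing = pairing),
            class = "expression_table")
}
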