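#' @importFrom utils write.table read.table
NULL

# open a text connection; gzfile() transparently reads both gzip-compressed
# and plain files
.open_text <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gzfile(path, open = "rt")
}

.read_peak_file <- function(path, n_cols, format_name) {
  con <- .open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = integer(),
                      strand = character(), signal = numeric(),
                      summit = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != n_cols)
  if (length(bad)) {
    stop(sprintf("%s line %d: expected %d tab-separated columns, found %d",
                 format_name, bad[1], n_cols, nf[bad[1]]))
  }
  m <- matrix(unlist(fields), ncol = n_cols, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("%s line %d: non-numeric coordinates", format_name, bad[1]))
  }
  bad <- which(end <= start | start < 0)
  if (length(bad)) {
    stop(sprintf("%s line %d: invalid interval [%d, %d)", format_name,
                 bad[1], start[bad[1]], end[bad[1]]))
  }
  signal <- suppressWarnings(as.numeric(m[, 7]))
  bad <- which(is.na(signal))
  if (length(bad)) {
    stop(sprintf("%s line %d: non-numeric signal value", format_name, bad[1]))
  }
  summit <- if (n_cols == 10L) suppressWarnings(as.integer(m[, 10]))
            else rep(-1L, nrow(m))
  summit[is.na(summit) | summit < 0L] <- NA_integer_
  data.frame(chrom = m[, 1], start = start, end = end, name = m[, 4],
             score = suppressWarnings(as.integer(m[, 5])), strand = m[, 6],
             signal = signal, summit = summit)
}

#' Read an ENCODE narrowPeak file
#'
#' narrowPeak is BED6+4: chrom, start, end, name, score, strand,
#' signalValue, pValue, qValue, peak (summit offset, -1 if absent).
#' Peak enrichment is taken from signalValue (column 7); the summit is
#' parsed but the midpoint is used as the interaction site unless a
#' downstream call opts into `use_summit`.
#'
#' @param path Path to a narrowPeak file (optionally gzip-compressed).
#' @param factor_name Factor name; defaults to the file basename minus
#'   extensions.
#' @param cell_line Optional cell-line label carried on the track.
#' @return A [factor_track()] with `factor_class = "TF"`, peaks sorted by
#'   `(chrom, start)`.
#' @seealso [read_broadpeak()] for the BED6+3 histone-mark format.
#' @export
read_narrowpeak <- function(path, factor_name = NULL,
                            cell_line = NA_character_) {
  if (is.null(factor_name)) factor_name <- .strip_ext(basename(path))
  peaks <- .read_peak_file(path, 10L, "narrowPeak")
  factor_track(peaks, factor_name, "TF", cell_line)
}

#' Read an ENCODE broadPeak file
#'
#' broadPeak is BED6+3 (no summit column); a file with 10 columns is
#' rejected. Used for histone-modification tracks.
#'
#' @inheritParams read_narrowpeak
#' @return A [factor_track()] with `factor_class = "HM"`.
#' @export
read_broadpeak <- function(path, factor_name = NULL,
                           cell_line = NA_character_) {
  if (is.null(factor_name)) factor_name <- .strip_ext(basename(path))
  peaks <- .read_peak_file(path, 9L, "broadPeak")
  peaks$summit <- NA_integer_
  factor_track(peaks, factor_name, "HM", cell_line)
}

.strip_ext <- function(x) sub("\\.(narrowPeak|broadPeak|bed|tsv|txt)(\\.gz)?$",
                              "", x)

#' Write a track back to narrowPeak / broadPeak
#'
#' Inverse of [read_narrowpeak()] / [read_broadpeak()]: coordinates,
#' signal values and peak order round-trip exactly. pValue and qValue are
#' not retained by the reader and are written as -1.
#'
#' @param track A [factor_track()].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(track, path) {
  p <- track$peaks
  summit <- ifelse(is.na(p$summit), -1L, p$summit)
  df <- data.frame(p$chrom, p$start, p$end, p$name, p$score, p$strand,
                   .fmt_num(p$signal), -1L, -1L, summit)
  .write_tsv(df, path)
}

#' @rdname write_narrowpeak
#' @export
write_broadpeak <- function(track, path) {
  p <- track$peaks
  df <- data.frame(p$chrom, p$start, p$end, p$name, p$score, p$strand,
                   .fmt_num(p$signal), -1L, -1L)
  .write_tsv(df, path)
}

.fmt_num <- function(x) {
  out <- format(x, trim = TRUE, scientific = FALSE, digits = 15)
  sub("(\\.\\d*?)0+$", "\\1", sub("\\.$", "", out))
}

.write_tsv <- function(df, path, col.names = FALSE) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names)
  invisible(path)
}

#' Read a gene/transcript annotation
#'
#' Two dialects are supported. `"bed"`: BED6, one transcript per line; the
#' TSS is `start` for `+` records and `end - 1` for `-` records (0-based
#' half-open convention). `"tsv"`: four columns
#' `gene_id, chrom, tss, strand` with no header. `"auto"` sniffs the column
#' count of the first line (6 = BED, 4 = TSV).
#'
#' @param path Annotation file (optionally gzipped).
#' @param format `"auto"`, `"bed"` or `"tsv"`.
#' @return A data.frame of class `gene_annotation` with columns
#'   `gene_id`, `chrom`, `tss`, `strand`. Duplicate gene ids are an error.
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  con <- .open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_annotation(character(), character(),
                                             integer(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (format == "auto") format <- if (nf[1] >= 6L) "bed" else "tsv"
  want <- if (format == "bed") 6L else 4L
  bad <- which(nf != want)
  if (length(bad)) {
    stop(sprintf("annotation line %d: expected %d columns, found %d",
                 bad[1], want, nf[bad[1]]))
  }
  m <- matrix(unlist(fields), ncol = want, byrow = TRUE)
  if (format == "bed") {
    start <- suppressWarnings(as.integer(m[, 2]))
    end <- suppressWarnings(as.integer(m[, 3]))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad)) stop(sprintf("annotation line %d: non-numeric coordinates",
                                  bad[1]))
    strand <- m[, 6]
    bad <- which(!strand %in% c("+", "-"))
    if (length(bad)) stop(sprintf("annotation line %d: unknown strand '%s'",
                                  bad[1], strand[bad[1]]))
    tss <- ifelse(strand == "+", start, end - 1L)
    gene_annotation(m[, 4], m[, 1], tss, strand)
  } else {
    tss <- suppressWarnings(as.integer(m[, 3]))
    bad <- which(is.na(tss))
    if (length(bad)) stop(sprintf("annotation line %d: non-numeric TSS",
                                  bad[1]))
    strand <- m[, 4]
    bad <- which(!strand %in% c("+", "-"))
    if (length(bad)) stop(sprintf("annotation line %d: unknown strand '%s'",
                                  bad[1], strand[bad[1]]))
    gene_annotation(m[, 1], m[, 2], tss, strand)
  }
}

#' Construct a gene annotation table
#'
#' @param gene_id Unique transcript/gene identifiers.
#' @param chrom Chromosome names (exact string match downstream).
#' @param tss 0-based TSS positions.
#' @param strand `"+"` or `"-"`.
#' @return data.frame of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, tss, strand) {
  tss <- as.integer(tss)
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id: ", gene_id[duplicated(gene_id)][1])
  }
  if (length(tss) && any(tss < 0)) stop("negative TSS position")
  if (length(strand) && !all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  out <- data.frame(gene_id = as.character(gene_id),
                    chrom = as.character(chrom),
                    tss = tss, strand = as.character(strand))
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Drop genes with overlapping TSS windows
#'
#' Keeps exactly those genes whose `[tss - half_window, tss + half_window]`
#' interval intersects no other gene's interval on the same chromosome, so
#' that peak-to-gene assignment in the window is unambiguous. Output order
#' is preserved; the operation is idempotent.
#'
#' @param genes A [gene_annotation()].
#' @param half_window Half-width of the exclusion window in bp (default
#'   20 kb, i.e. a 40 kb window).
#' @return The filtered `gene_annotation`.
#' @export
filter_nonoverlapping_genes <- function(genes, half_window = 20000L) {
  stopifnot(half_window > 0)
  if (!nrow(genes)) return(genes)
  keep <- rep(TRUE, nrow(genes))
  for (chr in unique(genes$chrom)) {
    i <- which(genes$chrom == chr)
    if (length(i) < 2L) next
    ir <- IRanges::IRanges(start = genes$tss[i] - half_window,
                           end = genes$tss[i] + half_window)
    # a gene collides iff its window overlaps any other window
    keep[i] <- IRanges::countOverlaps(ir, ir) == 1L
  }
  out <- genes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a two-column expression table
#'
#' Tab-separated `gene_id`, `FPKM` with no header. FPKM values must be
#' nonnegative.
#'
#' @param path Expression TSV (optionally gzipped).
#' @return Named numeric vector of FPKM keyed by gene id.
#' @export
read_expression <- function(path) {
  con <- .open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(numeric(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 2L)
  if (length(bad)) stop(sprintf("expression line %d: expected 2 columns",
                                bad[1]))
  m <- matrix(unlist(fields), ncol = 2L, byrow = TRUE)
  fpkm <- suppressWarnings(as.numeric(m[, 2]))
  bad <- which(is.na(fpkm))
  if (length(bad)) stop(sprintf("expression line %d: non-numeric FPKM",
                                bad[1]))
  bad <- which(fpkm < 0)
  if (length(bad)) stop(sprintf("expression line %d: negative FPKM (%g)",
                                bad[1], fpkm[bad[1]]))
  if (anyDuplicated(m[, 1])) {
    stop("duplicate gene_id in expression table: ",
         m[duplicated(m[, 1]), 1][1])
  }
  stats::setNames(fpkm, m[, 1])
}

#' Write annotation / expression files in the formats the readers accept
#'
#' `write_gene_annotation()` emits the 4-column TSV dialect;
#' `write_expression()` the 2-column TSV.
#'
#' @param genes A [gene_annotation()].
#' @param expr Named numeric FPKM vector.
#' @param path Output path (`.gz` for compression).
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  .write_tsv(data.frame(genes$gene_id, genes$chrom, genes$tss, genes$strand),
             path)
}

#' @rdname write_gene_annotation
#' @export
write_expression <- function(expr, path) {
  .write_tsv(data.frame(names(expr), .fmt_num(unname(expr))), path)
}

#' Rename chromosomes in a track or annotation
#'
#' Chromosome matching is exact string comparison throughout the
#' pipeline (`"chr1" != "1"`); this helper applies a rename map (e.g.
#' `c("1" = "chr1")`) to reconcile naming schemes before analysis.
#'
#' @param x A [factor_track()] or [gene_annotation()].
#' @param map Named character vector, old name -> new name; chromosomes
#'   not in the map are left unchanged.
#' @return `x` with chromosomes renamed (tracks are re-sorted).
#' @export
rename_chromosomes <- function(x, map) {
  stopifnot(is.character(map), !is.null(names(map)))
  if (inherits(x, "FactorTrack")) {
    hit <- x$peaks$chrom %in% names(map)
    x$peaks$chrom[hit] <- unname(map[x$peaks$chrom[hit]])
    factor_track(x$peaks, x$factor_name, x$factor_class, x$cell_line)
  } else if (inherits(x, "gene_annotation")) {
    hit <- x$chrom %in% names(map)
    x$chrom[hit] <- unname(map[x$chrom[hit]])
    x
  } else {
    stop("unsupported input for chromosome renaming")
  }
}

#' Read a BED file of regions (e.g. enhancers)
#'
#' Only the first three columns are used; records are returned as a
#' data.frame `chrom`, `start`, `end` suitable for
#' [overlap_ratio_in_regions()].
#'
#' @param path BED file (>= 3 columns, optionally gzipped).
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_regions <- function(path) {
  con <- .open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(data.frame(chrom = character(),
                                        start = integer(), end = integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stop(sprintf("regions line %d: fewer than 3 columns",
                                bad[1]))
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad)) stop(sprintf("regions line %d: invalid interval", bad[1]))
  data.frame(chrom = chrom, start = start, end = end)
}
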