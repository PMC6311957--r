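#' Construct a ChIP-seq factor track
#'
#' A `FactorTrack` holds all peaks of one factor (transcription factor or
#' histone modification) in one cell line. Peaks are kept sorted by
#' `(chrom, start)`; every downstream statistic (TSS binning, overlap
#' ratios, TFAS) consumes this container.
#'
#' @param peaks data.frame with columns `chrom` (character), `start`,
#'   `end` (0-based half-open, integer), and optionally `name`, `score`,
#'   `strand`, `signal` (enrichment value, defaults to 1), `summit`
#'   (offset from `start`; `NA` = absent).
#' @param factor_name Name of the assayed factor, e.g. `"CTCF"`.
#' @param factor_class `"TF"` or `"HM"`.
#' @param cell_line Cell line label, e.g. `"GM12878"` (may be `NA`).
#' @return An object of class `FactorTrack`.
#' @examples
#' factor_track(data.frame(chrom = "chr1", start = 100L, end = 300L),
#'              factor_name = "CTCF")
#' @export
factor_track <- function(peaks, factor_name, factor_class = "TF",
                         cell_line = NA_character_) {
  if (!nzchar(factor_name)) stop("factor_name must be nonempty")
  factor_class <- match.arg(factor_class, c("TF", "HM"))
  stopifnot(is.data.frame(peaks))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(peaks))
  if (length(miss)) stop("peaks lacks columns: ", paste(miss, collapse = ", "))
  peaks$chrom <- as.character(peaks$chrom)
  peaks$start <- as.integer(peaks$start)
  peaks$end <- as.integer(peaks$end)
  if (nrow(peaks)) {
    if (any(is.na(peaks$start)) || any(is.na(peaks$end)))
      stop("non-numeric peak coordinates")
    if (any(peaks$start < 0)) stop("negative peak start")
    if (any(peaks$end <= peaks$start)) stop("peak end must exceed start")
  }
  if (is.null(peaks$name)) peaks$name <- rep(".", nrow(peaks))
  if (is.null(peaks$score)) peaks$score <- rep(0L, nrow(peaks))
  if (is.null(peaks$strand)) peaks$strand <- rep(".", nrow(peaks))
  if (is.null(peaks$signal)) peaks$signal <- rep(1, nrow(peaks))
  if (is.null(peaks$summit)) peaks$summit <- rep(NA_integer_, nrow(peaks))
  peaks$signal <- as.numeric(peaks$signal)
  if (nrow(peaks) && any(peaks$signal < 0)) stop("negative signal value")
  ord <- order(peaks$chrom, peaks$start, peaks$end)
  peaks <- peaks[ord, c("chrom", "start", "end", "name", "score", "strand",
                        "signal", "summit"), drop = FALSE]
  rownames(peaks) <- NULL
  structure(
    list(factor_name = factor_name, factor_class = factor_class,
         cell_line = cell_line, peaks = peaks),
    class = "FactorTrack")
}

#' @export
print.FactorTrack <- function(x, ...) {
  cat(sprintf("FactorTrack: %s [%s]%s, %d peaks on %d chromosome(s)\n",
              x$factor_name, x$factor_class,
              if (is.na(x$cell_line)) "" else paste0(" in ", x$cell_line),
              nrow(x$peaks), length(unique(x$peaks$chrom))))
  invisible(x)
}

#' Number of peaks in a track
#' @param track A [factor_track()].
#' @return Integer peak count.
#' @export
n_peaks <- function(track) nrow(track$peaks)

#' Peak centers and widths
#'
#' The interaction site of a peak is taken to be its midpoint
#' `floor((start + end) / 2)`; `peak_widths()` returns `end - start`.
#' When `use_summit = TRUE` and a summit offset is recorded (narrowPeak
#' column 10), `start + summit` is used instead for peaks that have one.
#'
#' @param track A [factor_track()].
#' @param use_summit Use the called summit where available.
#' @return Integer vector, one entry per peak.
#' @export
peak_centers <- function(track, use_summit = FALSE) {
  p <- track$peaks
  ctr <- (p$start + p$end) %/% 2L
  if (use_summit) {
    has <- !is.na(p$summit) & p$summit >= 0L
    ctr[has] <- p$start[has] + p$summit[has]
  }
  ctr
}

#' @rdname peak_centers
#' @export
peak_widths <- function(track) track$peaks$end - track$peaks$start

# IRanges view of the peaks of one chromosome, in "doubled" coordinates:
# a peak with center c and width L maps to [2c - L + 1, 2c + L].  Two such
# integer ranges intersect exactly when 2|c1 - c2| < L1 + L2, i.e. the
# strict midpoint-distance overlap predicate.  Exact in integer arithmetic.
.doubled_ranges <- function(peaks, use_summit = FALSE) {
  ctr <- (peaks$start + peaks$end) %/% 2L
  if (use_summit) {
    has <- !is.na(peaks$summit) & peaks$summit >= 0L
    ctr[has] <- peaks$start[has] + peaks$summit[has]
  }
  w <- peaks$end - peaks$start
  IRanges::IRanges(start = 2L * ctr - w + 1L, width = 2L * w)
}

# split a peak data.frame by chromosome, preserving original row indices
.split_by_chrom <- function(peaks) {
  idx <- split(seq_len(nrow(peaks)), peaks$chrom)
  lapply(idx, function(i) list(rows = i, peaks = peaks[i, , drop = FALSE]))
}
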