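# Assign peak centers to gene windows.
#
# A peak belongs to a gene when its strand-oriented offset from the TSS
# lies in the half-open window [-half_window, half_window).  For minus
# strand genes the offset is negated (upstream stays negative), so the
# admissible center positions are [tss - hw + 1, tss + hw] instead of
# [tss - hw, tss + hw - 1].  Returns one row per (gene, peak) assignment.
.assign_peaks_to_genes <- function(track, genes, half_window = 20000L,
                                   strand_flip = TRUE, use_summit = FALSE) {
  hw <- as.integer(half_window)
  centers <- peak_centers(track, use_summit = use_summit)
  out <- list()
  for (chr in intersect(unique(genes$chrom), unique(track$peaks$chrom))) {
    gi <- which(genes$chrom == chr)
    pi <- which(track$peaks$chrom == chr)
    minus <- strand_flip & genes$strand[gi] == "-"
    win <- IRanges::IRanges(
      start = genes$tss[gi] - hw + ifelse(minus, 1L, 0L),
      width = 2L * hw)
    pts <- IRanges::IRanges(start = centers[pi], width = 1L)
    hits <- IRanges::findOverlaps(pts, win)
    if (!length(hits)) next
    g <- gi[S4Vectors::subjectHits(hits)]
    p <- pi[S4Vectors::queryHits(hits)]
    off <- centers[p] - genes$tss[g]
    if (strand_flip) off <- ifelse(genes$strand[g] == "-", -off, off)
    out[[chr]] <- data.frame(gene_idx = g, peak_idx = p, offset = off)
  }
  if (!length(out)) {
    return(data.frame(gene_idx = integer(), peak_idx = integer(),
                      offset = integer()))
  }
  do.call(rbind, unname(out))
}

#' Count peak centers in 200-bp bins around each TSS
#'
#' The 40 kb window flanking each TSS (20 kb upstream, 20 kb downstream by
#' default) is cut into `2 * half_window / bin_size` bins (200 with the
#' defaults). A peak's interaction site is its midpoint; it falls in bin
#' `floor((offset + half_window) / bin_size) + 1` where `offset` is the
#' strand-oriented distance from the TSS, so bin 1 is the most upstream
#' bin and offset 0 lands in the first downstream bin. A peak within the
#' windows of several genes counts toward each.
#'
#' @param track A [factor_track()].
#' @param genes A filtered [gene_annotation()].
#' @param half_window Half window in bp; must be divisible by `bin_size`.
#' @param bin_size Bin width in bp.
#' @param strand_flip Orient bins by gene strand (bin 1 = upstream). Set
#'   `FALSE` for a strand-naive profile.
#' @param use_summit Use narrowPeak summits instead of midpoints.
#' @return A `BinMatrix`: list with `factor_name`, `cell_line`, `counts`
#'   (genes x bins integer matrix, rownames = gene ids), `bin_size`,
#'   `half_window`.
#' @export
bin_peaks <- function(track, genes, half_window = 20000L, bin_size = 200L,
                      strand_flip = TRUE, use_summit = FALSE) {
  if (half_window %% bin_size != 0L) {
    stop("half_window (", half_window, ") is not divisible by bin_size (",
         bin_size, ")")
  }
  n_bins <- as.integer(2L * half_window / bin_size)
  asg <- .assign_peaks_to_genes(track, genes, half_window, strand_flip,
                                use_summit)
  counts <- matrix(0L, nrow = nrow(genes), ncol = n_bins,
                   dimnames = list(genes$gene_id, NULL))
  if (nrow(asg)) {
    bin <- (asg$offset + as.integer(half_window)) %/% as.integer(bin_size) + 1L
    tab <- table(factor(asg$gene_idx, levels = seq_len(nrow(genes))),
                 factor(bin, levels = seq_len(n_bins)))
    counts <- matrix(as.integer(tab), nrow = nrow(genes),
                     dimnames = list(genes$gene_id, NULL))
  }
  structure(list(factor_name = track$factor_name, cell_line = track$cell_line,
                 counts = counts, bin_size = as.integer(bin_size),
                 half_window = as.integer(half_window)),
            class = "BinMatrix")
}

#' Per-bin signal intensity
#'
#' Aggregates a [bin_peaks()] matrix over genes: the intensity of bin j is
#' `S_j = (10^3 / n) * sum_i N_ij` with `n` the number of genes.
#'
#' @param bins A `BinMatrix` from [bin_peaks()].
#' @return A `SignalProfile`: list with `factor_name`, `cell_line`, `s`
#'   (numeric vector, one value per bin) and `n_genes`.
#' @export
signal_intensity <- function(bins) {
  n <- nrow(bins$counts)
  if (n < 1L) stop("signal intensity needs at least one gene")
  structure(list(factor_name = bins$factor_name, cell_line = bins$cell_line,
                 s = 1000 * colSums(bins$counts) / n, n_genes = n),
            class = "SignalProfile")
}

# Three-way classification by TSS-proximal enrichment between the two
# cell lines.  The boxes follow the (f, d) thresholds; since
# d = (f - 1)/(f + 1), f > 1.5 <=> d > 0.2 and f < 0.6 <=> d < -0.25, the
# pairs of bounds are mutually consistent, but points on a boundary fall
# in no box and are labelled "unclassified".
.classify_dynamics <- function(f, d) {
  if (is.infinite(f) || (f > 1.5 && d > 0.2)) "GM12878_rich_factor"
  else if (f < 0.6 && d < -0.25) "K562_rich_factor"
  else if (f > 0.6 && f < 1.5 && d > -0.25 && d < 0.2) "unbiased_factor"
  else "unclassified"
}

#' Cross-cell-line dynamics of one factor
#'
#' From the two 200-bin signal profiles of the same factor in two cell
#' lines (reference first, e.g. GM12878, then e.g. K562) computes the
#' signal ratio `f = sum(S^G) / sum(S^K)`, the total difference index
#' `D_signal = (sum(S^G) - sum(S^K)) / (sum(S^G) + sum(S^K))`, and the
#' three-way enrichment label: `f > 1.5` and `D_signal > 0.2` gives
#' `GM12878_rich_factor`, `f < 0.6` and `D_signal < -0.25` gives
#' `K562_rich_factor`, the open box between them `unbiased_factor`, and
#' anything on a boundary `unclassified`. `D_signal = (f - 1)/(f + 1)`
#' holds identically whenever both totals are positive.
#'
#' @param profile_g,profile_k `SignalProfile`s of the same factor in the
#'   two cell lines.
#' @return A one-row data.frame with `factor_name`, `f`, `d_signal`,
#'   `label`.
#' @export
dynamics_indices <- function(profile_g, profile_k) {
  if (profile_g$factor_name != profile_k$factor_name) {
    stop("profiles are for different factors: ", profile_g$factor_name,
         " vs ", profile_k$factor_name)
  }
  if (length(profile_g$s) != length(profile_k$s)) {
    stop("profiles have different bin counts")
  }
  tg <- sum(profile_g$s)
  tk <- sum(profile_k$s)
  if (tg == 0 && tk == 0) {
    stop("factor ", profile_g$factor_name,
         ": zero signal in both cell lines, dynamics undefined")
  }
  f <- if (tk == 0) Inf else tg / tk
  d <- (tg - tk) / (tg + tk)
  data.frame(factor_name = profile_g$factor_name, f = f, d_signal = d,
             label = .classify_dynamics(f, d))
}

#' Normalized peak-count difference between two cell lines
#'
#' `|a - b| / (a + b)` for the total peak counts `a`, `b` of one factor in
#' two cell lines: 0 for identical counts, 1 when one cell line has no
#' peaks at all.
#'
#' @param a,b Nonnegative peak counts with `a + b > 0`.
#' @return Value in `[0, 1]`.
#' @export
peak_count_difference <- function(a, b) {
  stopifnot(a >= 0, b >= 0)
  if (a + b == 0) stop("both peak counts are zero")
  abs(a - b) / (a + b)
}

#' Factor dynamics table for matched track sets
#'
#' Convenience wrapper running [bin_peaks()], [signal_intensity()] and
#' [dynamics_indices()] for every factor present in both cell lines,
#' mirroring the columns of a factor-classification table.
#'
#' @param tracks_g,tracks_k Named lists of [factor_track()]s (names =
#'   factor names), one per cell line.
#' @param genes Filtered [gene_annotation()].
#' @inheritParams bin_peaks
#' @return data.frame with `factor_name`, `f`, `d_signal`, `label`,
#'   `peak_count_diff`, `n_peaks_g`, `n_peaks_k`.
#' @export
factor_dynamics_table <- function(tracks_g, tracks_k, genes,
                                  half_window = 20000L, bin_size = 200L,
                                  strand_flip = TRUE) {
  common <- intersect(names(tracks_g), names(tracks_k))
  rows <- lapply(common, function(fn) {
    pg <- signal_intensity(bin_peaks(tracks_g[[fn]], genes, half_window,
                                     bin_size, strand_flip))
    pk <- signal_intensity(bin_peaks(tracks_k[[fn]], genes, half_window,
                                     bin_size, strand_flip))
    dyn <- dynamics_indices(pg, pk)
    a <- n_peaks(tracks_g[[fn]])
    b <- n_peaks(tracks_k[[fn]])
    cbind(dyn, peak_count_diff = peak_count_difference(a, b),
          n_peaks_g = a, n_peaks_k = b)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
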