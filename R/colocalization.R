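#' Midpoint-distance overlap predicate for two peaks
#'
#' Two peaks co-localize when the distance between their centers is
#' strictly less than the mean of their widths:
#' `|S1 - S2| < (L1 + L2) / 2`. Evaluated in exact integer arithmetic
#' (`2 |S1 - S2| < L1 + L2`), so touching half-widths do NOT overlap.
#' Peaks on different chromosomes never overlap.
#'
#' @param p,q Single peaks: lists or one-row data.frames with `chrom`,
#'   `start`, `end`.
#' @return Logical scalar.
#' @export
peaks_overlap <- function(p, q) {
  if (as.character(p$chrom) != as.character(q$chrom)) return(FALSE)
  c1 <- (as.integer(p$start) + as.integer(p$end)) %/% 2L
  c2 <- (as.integer(q$start) + as.integer(q$end)) %/% 2L
  w1 <- as.integer(p$end) - as.integer(p$start)
  w2 <- as.integer(q$end) - as.integer(q$start)
  2L * abs(c1 - c2) < w1 + w2
}

# For each peak of a, whether it overlaps (midpoint predicate) >= 1 peak
# of b; vectorized per chromosome through IRanges in doubled coordinates.
.hit_flags <- function(peaks_a, peaks_b, use_summit = FALSE) {
  hit <- logical(nrow(peaks_a))
  if (!nrow(peaks_a) || !nrow(peaks_b)) return(hit)
  for (chr in intersect(unique(peaks_a$chrom), unique(peaks_b$chrom))) {
    ia <- which(peaks_a$chrom == chr)
    ib <- which(peaks_b$chrom == chr)
    ra <- .doubled_ranges(peaks_a[ia, , drop = FALSE], use_summit)
    rb <- .doubled_ranges(peaks_b[ib, , drop = FALSE], use_summit)
    hit[ia] <- IRanges::overlapsAny(ra, rb)
  }
  hit
}

# number of overlapping (a, b) peak pairs
.hit_pairs <- function(peaks_a, peaks_b) {
  n <- 0L
  for (chr in intersect(unique(peaks_a$chrom), unique(peaks_b$chrom))) {
    ra <- .doubled_ranges(peaks_a[peaks_a$chrom == chr, , drop = FALSE])
    rb <- .doubled_ranges(peaks_b[peaks_b$chrom == chr, , drop = FALSE])
    n <- n + length(IRanges::findOverlaps(ra, rb))
  }
  n
}

#' Genome-wide overlap ratio of two tracks
#'
#' `R_o = 2n / (N1 + N2)` where `N1`, `N2` are the peak totals and `n`
#' counts overlapping peaks under the midpoint predicate
#' ([peaks_overlap()]). With the default `count_mode = "matched"`,
#' `n = (|A-peaks hit| + |B-peaks hit|) / 2`, which keeps `R_o` in
#' `[0, 1]`, symmetric, and equal to 1 for a track against itself.
#' `count_mode = "pairs"` instead counts overlapping (a, b) pairs — the
#' literal pair-event reading, which can exceed 1 — and is provided for
#' sensitivity analysis only.
#'
#' @param track_a,track_b [factor_track()]s.
#' @param count_mode `"matched"` (default) or `"pairs"`.
#' @return A one-row data.frame of class `PairOverlap` with `factor_a`,
#'   `factor_b`, `n_overlap`, `n_a`, `n_b`, `r_o`.
#' @export
overlap_ratio <- function(track_a, track_b,
                          count_mode = c("matched", "pairs")) {
  count_mode <- match.arg(count_mode)
  na <- n_peaks(track_a)
  nb <- n_peaks(track_b)
  if (na + nb == 0L) stop("both tracks are empty")
  n <- if (count_mode == "matched") {
    (sum(.hit_flags(track_a$peaks, track_b$peaks)) +
       sum(.hit_flags(track_b$peaks, track_a$peaks))) / 2
  } else {
    .hit_pairs(track_a$peaks, track_b$peaks)
  }
  out <- data.frame(factor_a = track_a$factor_name,
                    factor_b = track_b$factor_name,
                    n_overlap = n, n_a = na, n_b = nb,
                    r_o = 2 * n / (na + nb))
  class(out) <- c("PairOverlap", "data.frame")
  out
}

# merged copy of regions (data.frame chrom/start/end), as per-chrom IRanges
.region_ranges <- function(regions) {
  idx <- split(seq_len(nrow(regions)), regions$chrom)
  lapply(idx, function(i) {
    IRanges::reduce(IRanges::IRanges(start = regions$start[i],
                                     end = regions$end[i] - 1L))
  })
}

# restrict a track to peaks whose center falls inside any region
.restrict_track <- function(track, region_ranges) {
  ctr <- peak_centers(track)
  keep <- logical(length(ctr))
  for (chr in intersect(unique(track$peaks$chrom), names(region_ranges))) {
    i <- which(track$peaks$chrom == chr)
    pts <- IRanges::IRanges(start = ctr[i], width = 1L)
    keep[i] <- IRanges::overlapsAny(pts, region_ranges[[chr]])
  }
  track$peaks <- track$peaks[keep, , drop = FALSE]
  rownames(track$peaks) <- NULL
  track
}

#' Overlap ratio restricted to a region set
#'
#' Restricts both tracks to peaks whose center falls inside any of the
#' given regions (merged first), e.g. enhancers, then applies
#' [overlap_ratio()].
#'
#' @inheritParams overlap_ratio
#' @param regions data.frame `chrom`, `start`, `end` (0-based half-open),
#'   e.g. from [read_regions()].
#' @return As [overlap_ratio()]. If no peaks of either track survive the
#'   restriction, an error of class `cochip_empty_restriction` is raised.
#' @export
overlap_ratio_in_regions <- function(track_a, track_b, regions,
                                     count_mode = c("matched", "pairs")) {
  rr <- .region_ranges(regions)
  a <- .restrict_track(track_a, rr)
  b <- .restrict_track(track_b, rr)
  if (n_peaks(a) + n_peaks(b) == 0L) {
    stop(structure(class = c("cochip_empty_restriction", "error",
                             "condition"),
                   list(message = "no peaks remain inside the regions",
                        call = sys.call())))
  }
  overlap_ratio(a, b, count_mode)
}

#' Relative variation index of a pair's overlap ratio
#'
#' `I_RV = (R_G - R_K) / (R_G + R_K + alpha)`; the small `alpha`
#' (default 0.001) guards the case `R_G + R_K = 0`. Antisymmetric under
#' swapping the two cell lines.
#'
#' @param r_g,r_k Overlap ratios of the pair in the two cell lines, in
#'   `[0, 1]`.
#' @param alpha Denominator guard.
#' @return Index in `[-1, 1]`.
#' @export
relative_variation <- function(r_g, r_k, alpha = 0.001) {
  stopifnot(all(r_g >= 0 & r_g <= 1), all(r_k >= 0 & r_k <= 1))
  (r_g - r_k) / (r_g + r_k + alpha)
}

#' Flag pairs with outlying relative variation
#'
#' Computes the mean and the population standard deviation of `i_rv` over
#' all pairs and flags pairs falling strictly outside the mean +/- 2 sd
#' band. With zero dispersion nothing is flagged.
#'
#' @param pairs data.frame with at least an `i_rv` column (>= 2 rows),
#'   e.g. from [pair_dynamics_table()].
#' @return `pairs` with logical column `is_outlier` plus attributes `mu`
#'   and `sigma`.
#' @export
outlier_pairs <- function(pairs) {
  stopifnot(nrow(pairs) >= 2L)
  v <- pairs$i_rv
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  pairs$is_outlier <- if (sigma == 0) rep(FALSE, length(v))
                      else v < mu - 2 * sigma | v > mu + 2 * sigma
  attr(pairs, "mu") <- mu
  attr(pairs, "sigma") <- sigma
  pairs
}

#' Average overlap ratio of one factor against a panel
#'
#' For each of the `m` peaks of `track`, `x_i` counts the distinct other
#' factors having at least one peak overlapping peak i; with `N` the
#' panel size, `R_av = (1/m) * sum_i x_i / N`, the factor's overall
#' co-binding propensity in `[0, 1]`.
#'
#' @param track A [factor_track()] with at least one peak.
#' @param others Nonempty list of the other factors' tracks.
#' @return List of class `AverageOverlap`: `factor_name`, `x` (per-peak
#'   factor counts), `m`, `n_others`, `r_av`.
#' @export
average_overlap_ratio <- function(track, others) {
  if (!length(others)) stop("panel of other factors is empty")
  m <- n_peaks(track)
  if (m == 0L) stop("track ", track$factor_name, " has no peaks")
  x <- integer(m)
  for (other in others) {
    x <- x + .hit_flags(track$peaks, other$peaks)
  }
  structure(list(factor_name = track$factor_name, x = x, m = m,
                 n_others = length(others),
                 r_av = mean(x / length(others))),
            class = "AverageOverlap")
}

#' All pairwise overlap ratios of a track set
#'
#' @param tracks Named list of [factor_track()]s.
#' @param count_mode Passed to [overlap_ratio()].
#' @return data.frame with one row per unordered factor pair
#'   (`F (F - 1) / 2` rows): `factor_a`, `factor_b`, `r_o`, `n_overlap`,
#'   `n_a`, `n_b`.
#' @export
overlap_ratio_table <- function(tracks, count_mode = c("matched", "pairs")) {
  count_mode <- match.arg(count_mode)
  fac <- names(tracks)
  if (length(fac) < 2L) stop("need at least two tracks")
  cmb <- utils::combn(length(fac), 2L)
  rows <- lapply(seq_len(ncol(cmb)), function(k) {
    overlap_ratio(tracks[[cmb[1, k]]], tracks[[cmb[2, k]]], count_mode)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-cell-line pair dynamics table
#'
#' Joins the per-cell-line overlap ratios of every factor pair, computes
#' [relative_variation()] and flags mean +/- 2 sd outliers via
#' [outlier_pairs()].
#'
#' @param tracks_g,tracks_k Named lists of tracks; factors present in
#'   both cell lines are used.
#' @param alpha Guard constant of [relative_variation()].
#' @param count_mode Passed to [overlap_ratio()].
#' @return data.frame: `factor_a`, `factor_b`, `r_g`, `r_k`, `i_rv`,
#'   `is_outlier`, with attributes `mu`, `sigma`.
#' @export
pair_dynamics_table <- function(tracks_g, tracks_k, alpha = 0.001,
                                count_mode = c("matched", "pairs")) {
  count_mode <- match.arg(count_mode)
  common <- intersect(names(tracks_g), names(tracks_k))
  tg <- overlap_ratio_table(tracks_g[common], count_mode)
  tk <- overlap_ratio_table(tracks_k[common], count_mode)
  out <- data.frame(factor_a = tg$factor_a, factor_b = tg$factor_b,
                    r_g = tg$r_o, r_k = tk$r_o)
  out$i_rv <- relative_variation(out$r_g, out$r_k, alpha)
  outlier_pairs(out)
}

#' Mine k-factor combinations with high mutual overlap
#'
#' Builds the graph whose edges are factor pairs with `r_o > threshold`
#' and enumerates its k-cliques: factor groups in which every pair
#' co-localizes above the threshold. Cliques are returned sorted by their
#' weakest internal edge, descending.
#'
#' @param pair_table data.frame with `factor_a`, `factor_b`, `r_o`
#'   covering all pairs of the factor set (e.g. [overlap_ratio_table()]).
#' @param k Clique size (default 3: triple combinations).
#' @param threshold Strict lower bound on `r_o` for an edge (default 0.6).
#' @return data.frame with `members` (factors joined by `"+"`) and
#'   `min_r_o` (weakest edge in the clique); zero rows when none qualify.
#' @export
mine_combinations <- function(pair_table, k = 3L, threshold = 0.6) {
  keep <- pair_table$r_o > threshold
  if (!any(keep)) {
    return(data.frame(members = character(), min_r_o = numeric()))
  }
  edges <- pair_table[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("factor_a", "factor_b")], directed = FALSE)
  igraph::E(g)$weight <- edges$r_o
  cl <- igraph::cliques(g, min = k, max = k)
  if (!length(cl)) {
    return(data.frame(members = character(), min_r_o = numeric()))
  }
  rows <- lapply(cl, function(v) {
    nm <- sort(igraph::V(g)$name[as.integer(v)])
    sub <- igraph::induced_subgraph(g, v)
    data.frame(members = paste(nm, collapse = "+"),
               min_r_o = min(igraph::E(sub)$weight))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$min_r_o, out$members), , drop = FALSE]
  rownames(out) <- NULL
  out
}
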