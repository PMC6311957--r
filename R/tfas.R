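#' Association strength of one factor on one gene
#'
#' TFAS sums the distance-decayed intensities of all peaks of the factor
#' near the gene's TSS: `A = sum_k g_k * exp(-d_k / d0)` with `g_k` the
#' peak enrichment (signalValue), `d_k = |center_k - tss|` in bp, over
#' peaks whose strand-oriented offset lies in the half-open window
#' `[-half_window, half_window)` — the same window rule the TSS binning
#' uses. No peaks in range gives 0.
#'
#' @param track A [factor_track()].
#' @param gene One-row [gene_annotation()] (or a list with `gene_id`,
#'   `chrom`, `tss`, `strand`).
#' @param d0 Decay length in bp (default 2 kb).
#' @param half_window Window half-width in bp (default 20 kb).
#' @param use_summit Use narrowPeak summits as peak positions.
#' @return Nonnegative scalar association strength.
#' @export
tfas <- function(track, gene, d0 = 2000, half_window = 20000L,
                 use_summit = FALSE) {
  stopifnot(d0 > 0, half_window > 0)
  g <- gene_annotation(gene$gene_id, gene$chrom, gene$tss, gene$strand)
  drop(tfas_matrix(stats::setNames(list(track), track$factor_name), g,
                   d0, half_window, use_summit)[1, 1])
}

#' TFAS matrix over genes and factors
#'
#' Applies the exponential distance-decay association strength to every
#' (gene, factor) combination.
#'
#' @param tracks Named list of [factor_track()]s.
#' @param genes Filtered [gene_annotation()].
#' @inheritParams tfas
#' @return Numeric matrix, genes in rows (rownames = gene ids), factors
#'   in columns; entries are >= 0 and 0 exactly when no peak of the
#'   factor lies in the gene's window.
#' @export
tfas_matrix <- function(tracks, genes, d0 = 2000, half_window = 20000L,
                        use_summit = FALSE) {
  stopifnot(d0 > 0, half_window > 0)
  a <- matrix(0, nrow = nrow(genes), ncol = length(tracks),
              dimnames = list(genes$gene_id, names(tracks)))
  for (j in seq_along(tracks)) {
    track <- tracks[[j]]
    asg <- .assign_peaks_to_genes(track, genes, half_window,
                                  strand_flip = TRUE, use_summit = use_summit)
    if (!nrow(asg)) next
    w <- track$peaks$signal[asg$peak_idx] * exp(-abs(asg$offset) / d0)
    s <- rowsum(w, group = asg$gene_idx)
    a[as.integer(rownames(s)), j] <- s[, 1]
  }
  a
}

#' Pearson correlation of two factors' TFAS profiles
#'
#' The co-binding tendency of two factors is the Pearson correlation of
#' their per-gene association strengths. A constant column has no defined
#' correlation and yields `NA` (flagged, no error).
#'
#' @param x_col,y_col Numeric vectors of equal length (>= 2): TFAS values
#'   of the two factors over the same genes.
#' @return Correlation in `[-1, 1]`, or `NA` if either input is constant.
#' @export
pair_pcc <- function(x_col, y_col) {
  if (length(x_col) != length(y_col)) {
    stop("TFAS columns have different lengths")
  }
  stopifnot(length(x_col) >= 2L)
  if (stats::sd(x_col) == 0 || stats::sd(y_col) == 0) return(NA_real_)
  stats::cor(x_col, y_col)
}

#' All pairwise TFAS correlations
#'
#' @param a TFAS matrix from [tfas_matrix()].
#' @return data.frame with `factor_a`, `factor_b`, `pcc` for every
#'   unordered column pair.
#' @export
tfas_pcc_table <- function(a) {
  fac <- colnames(a)
  if (length(fac) < 2L) stop("need at least two factors")
  cmb <- utils::combn(length(fac), 2L)
  data.frame(factor_a = fac[cmb[1, ]], factor_b = fac[cmb[2, ]],
             pcc = vapply(seq_len(ncol(cmb)), function(k) {
               pair_pcc(a[, cmb[1, k]], a[, cmb[2, k]])
             }, numeric(1)))
}

#' Thresholded factor interaction network
#'
#' Nodes are factors labelled by their cross-cell-line enrichment class
#' ([dynamics_indices()]); edges are pairs whose weight — the overlap
#' ratio `r_o` by default, or the TFAS correlation `pcc` — reaches the
#' threshold. Each edge carries a specificity class from the pair's
#' relative-variation outlier status: an outlier with `i_rv > 0` is
#' `GM12878_specific`, with `i_rv < 0` `K562_specific`, all other edges
#' `unbiased`.
#'
#' @param pair_weights data.frame `factor_a`, `factor_b` plus the weight
#'   column (`r_o` or `pcc`).
#' @param pair_dynamics data.frame from [pair_dynamics_table()] (needs
#'   `i_rv`, `is_outlier`).
#' @param factor_dynamics data.frame from [factor_dynamics_table()]
#'   (needs `factor_name`, `label`).
#' @param weight `"r_o"` or `"pcc"`.
#' @param threshold Minimum edge weight (weights >= threshold are kept).
#' @return List of class `InteractionNetwork`: `nodes` (data.frame
#'   `factor_name`, `label`) and `edges` (data.frame `factor_a`,
#'   `factor_b`, `weight`, `specificity`).
#' @export
build_network <- function(pair_weights, pair_dynamics, factor_dynamics,
                          weight = c("r_o", "pcc"), threshold = 0.6) {
  weight <- match.arg(weight)
  if (!weight %in% names(pair_weights)) {
    stop("pair_weights lacks a '", weight, "' column")
  }
  known <- factor_dynamics$factor_name
  pf <- unique(c(pair_weights$factor_a, pair_weights$factor_b,
                 pair_dynamics$factor_a, pair_dynamics$factor_b))
  unknown <- setdiff(pf, known)
  if (length(unknown)) {
    stop("factor(s) missing from factor_dynamics: ",
         paste(unknown, collapse = ", "))
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  dyn_key <- key(pair_dynamics$factor_a, pair_dynamics$factor_b)
  w <- pair_weights[[weight]]
  sel <- which(!is.na(w) & w >= threshold)
  edges <- data.frame(factor_a = pair_weights$factor_a[sel],
                      factor_b = pair_weights$factor_b[sel],
                      weight = w[sel])
  idx <- match(key(edges$factor_a, edges$factor_b), dyn_key)
  spec <- rep("unbiased", nrow(edges))
  hit <- !is.na(idx)
  out_flag <- hit & pair_dynamics$is_outlier[idx]
  spec[out_flag & pair_dynamics$i_rv[idx] > 0] <- "GM12878_specific"
  spec[out_flag & pair_dynamics$i_rv[idx] < 0] <- "K562_specific"
  edges$specificity <- spec
  structure(list(nodes = data.frame(factor_name = known,
                                    label = factor_dynamics$label),
                 edges = edges),
            class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat(sprintf("InteractionNetwork: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write an interaction network as plain-text tables
#'
#' Emits `<stem>_nodes.tsv` (factor, label) and `<stem>_edges.tsv`
#' (factor_a, factor_b, weight, specificity).
#'
#' @param network An `InteractionNetwork` from [build_network()].
#' @param stem Output path stem.
#' @return The two paths, invisibly.
#' @export
write_network <- function(network, stem) {
  np <- paste0(stem, "_nodes.tsv")
  ep <- paste0(stem, "_edges.tsv")
  .write_tsv(network$nodes, np, col.names = TRUE)
  .write_tsv(network$edges, ep, col.names = TRUE)
  invisible(c(np, ep))
}
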