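# Fixture builders and independent brute-force oracles. The oracles
# reimplement each statistic with naive double loops and plain
# arithmetic, sharing no code with the package internals.

make_track <- function(start, end, chrom = "chr1", signal = 1,
                       name = "T", class = "TF", cell = NA_character_,
                       summit = NA_integer_) {
  n <- length(start)
  factor_track(data.frame(chrom = rep_len(chrom, n), start = start,
                          end = end, signal = rep_len(signal, n),
                          summit = rep_len(summit, n)),
               factor_name = name, factor_class = class, cell_line = cell)
}

random_track <- function(n, chrom_length = 1e6, name = "T",
                         chroms = "chr1", width_max = 400) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(chrom_length, n, replace = TRUE)
  width <- sample.int(width_max, n, replace = TRUE)
  make_track(start, start + width, chrom = chrom,
             signal = round(runif(n, 0.5, 10), 3), name = name)
}

# strict midpoint predicate, scalar arithmetic only
oracle_overlaps <- function(c1, w1, c2, w2) 2 * abs(c1 - c2) < w1 + w2

# O(N^2) overlap ratio with matched-peak counting
oracle_overlap_ratio <- function(track_a, track_b) {
  pa <- track_a$peaks
  pb <- track_b$peaks
  ca <- (pa$start + pa$end) %/% 2
  cb <- (pb$start + pb$end) %/% 2
  wa <- pa$end - pa$start
  wb <- pb$end - pb$start
  hit_a <- logical(nrow(pa))
  hit_b <- logical(nrow(pb))
  for (i in seq_len(nrow(pa))) {
    for (j in seq_len(nrow(pb))) {
      if (pa$chrom[i] == pb$chrom[j] &&
          oracle_overlaps(ca[i], wa[i], cb[j], wb[j])) {
        hit_a[i] <- TRUE
        hit_b[j] <- TRUE
      }
    }
  }
  n <- (sum(hit_a) + sum(hit_b)) / 2
  2 * n / (nrow(pa) + nrow(pb))
}

# O(peaks x genes) TSS bin assignment
oracle_bin_matrix <- function(track, genes, half_window = 20000,
                              bin_size = 200) {
  n_bins <- 2 * half_window / bin_size
  counts <- matrix(0L, nrow(genes), n_bins)
  p <- track$peaks
  ctr <- (p$start + p$end) %/% 2
  for (i in seq_len(nrow(genes))) {
    for (k in seq_len(nrow(p))) {
      if (p$chrom[k] != genes$chrom[i]) next
      off <- ctr[k] - genes$tss[i]
      if (genes$strand[i] == "-") off <- -off
      if (off >= -half_window && off < half_window) {
        j <- (off + half_window) %/% bin_size + 1
        counts[i, j] <- counts[i, j] + 1L
      }
    }
  }
  counts
}

# per-cell TFAS loop
oracle_tfas_matrix <- function(tracks, genes, d0 = 2000,
                               half_window = 20000) {
  a <- matrix(0, nrow(genes), length(tracks),
              dimnames = list(genes$gene_id, names(tracks)))
  for (j in seq_along(tracks)) {
    p <- tracks[[j]]$peaks
    ctr <- (p$start + p$end) %/% 2
    for (i in seq_len(nrow(genes))) {
      s <- 0
      for (k in seq_len(nrow(p))) {
        if (p$chrom[k] != genes$chrom[i]) next
        off <- ctr[k] - genes$tss[i]
        if (genes$strand[i] == "-") off <- -off
        if (off >= -half_window && off < half_window) {
          s <- s + p$signal[k] * exp(-abs(off) / d0)
        }
      }
      a[i, j] <- s
    }
  }
  a
}

# all-pairs gene window collision check
oracle_filter_genes <- function(genes, half_window = 20000) {
  keep <- rep(TRUE, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(genes))) {
      if (i == j || genes$chrom[i] != genes$chrom[j]) next
      if (abs(genes$tss[i] - genes$tss[j]) <= 2 * half_window) {
        keep[i] <- FALSE
      }
    }
  }
  genes[keep, , drop = FALSE]
}

random_genes <- function(n, chrom_length = 2e6, chroms = "chr1") {
  gene_annotation(sprintf("g%03d", seq_len(n)),
                  sample(chroms, n, replace = TRUE),
                  sample.int(chrom_length, n),
                  sample(c("+", "-"), n, replace = TRUE))
}
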