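#' Configuration for the synthetic ChIP-seq / RNA-seq generator
#'
#' Defines a synthetic genome with evenly spaced genes and per-factor,
#' per-cell-line peak tracks carrying planted structure that the
#' pipeline's statistics should recover:
#'
#' * `planted_pairs`: for a pair (A, B, `co_rate`), a `co_rate` fraction
#'   of A's peaks receives a matched B peak whose center lies strictly
#'   within the midpoint-overlap bound; unmatched B peaks are placed at
#'   least half a grid step from every A peak, so the recovered overlap
#'   ratio estimates `co_rate`.
#' * `planted_enrichment`: factor -> `f_true`; the factor's TSS-proximal
#'   peaks are split between the two cell lines in ratio `f_true : 1`, so
#'   the recovered signal ratio `f` estimates `f_true` (diluted slightly
#'   toward 1 by background peaks that fall inside gene windows).
#' * `driver_factors`: factors whose TFAS later determines expression in
#'   [simulate_expression()].
#'
#' @param n_genes Number of genes (default 300).
#' @param gene_spacing Distance between consecutive TSSs in bp; the
#'   default 120 kb keeps all 40 kb windows disjoint (so
#'   [filter_nonoverlapping_genes()] keeps every gene) and leaves two
#'   thirds of the chromosome as intergenic background.
#' @param n_chrom Number of chromosomes (genes dealt round-robin).
#' @param n_factors,factor_names Number of factors, or explicit names
#'   (default `TF01`, `TF02`, ...).
#' @param hm_factors Subset of factor names to treat as histone marks
#'   (broad peaks, wider width distribution).
#' @param peaks_per_factor Peaks per factor per cell line (default 2000).
#' @param peak_width_mean,peak_width_sd Lognormal width distribution for
#'   TF peaks, bp (defaults 300 / 100 — narrowPeak-like).
#' @param hm_width_mean,hm_width_sd Width distribution for HM peaks
#'   (defaults 1500 / 500).
#' @param tss_enrichment Fraction of a factor's peaks placed within
#'   2 kb of a TSS (default 0.7); the rest is uniform background.
#' @param planted_pairs List of `list(factor_a=, factor_b=, co_rate=)`.
#' @param planted_enrichment Named numeric vector, factor -> `f_true > 0`.
#' @param driver_factors Factors coupled to expression.
#' @param beta Expression link slope (> 0).
#' @param noise_sd Standard deviation of the log-expression noise.
#' @param cell_lines Two cell-line labels (reference first).
#' @param seed Integer RNG seed.
#' @return Validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_genes = 300L, gene_spacing = 120000L,
                              n_chrom = 1L, n_factors = 4L,
                              factor_names = NULL, hm_factors = character(),
                              peaks_per_factor = 2000L,
                              peak_width_mean = 300, peak_width_sd = 100,
                              hm_width_mean = 1500, hm_width_sd = 500,
                              tss_enrichment = 0.7,
                              planted_pairs = list(),
                              planted_enrichment = numeric(),
                              driver_factors = character(),
                              beta = 1, noise_sd = 0.5,
                              cell_lines = c("GM12878", "K562"),
                              seed = 1L) {
  if (is.null(factor_names)) {
    factor_names <- sprintf("TF%02d", seq_len(n_factors))
  }
  n_factors <- length(factor_names)
  stopifnot(n_genes >= 1, gene_spacing > 0, n_chrom >= 1,
            peaks_per_factor >= 1, peak_width_mean > 0,
            tss_enrichment >= 0, tss_enrichment <= 1,
            beta > 0, noise_sd >= 0, length(cell_lines) == 2L)
  if (anyDuplicated(factor_names)) stop("duplicate factor names")
  bad <- setdiff(hm_factors, factor_names)
  if (length(bad)) stop("unknown hm_factors: ", paste(bad, collapse = ", "))
  paired <- character()
  for (p in planted_pairs) {
    stopifnot(is.list(p), !is.null(p$factor_a), !is.null(p$factor_b),
              !is.null(p$co_rate))
    if (p$co_rate < 0 || p$co_rate > 1) stop("co_rate must be in [0, 1]")
    bad <- setdiff(c(p$factor_a, p$factor_b), factor_names)
    if (length(bad)) stop("unknown factor in planted pair: ",
                          paste(bad, collapse = ", "))
    paired <- c(paired, p$factor_a, p$factor_b)
  }
  if (anyDuplicated(paired)) {
    stop("a factor may appear in at most one planted pair")
  }
  if (length(planted_enrichment)) {
    if (is.null(names(planted_enrichment)) ||
        !all(names(planted_enrichment) %in% factor_names)) {
      stop("planted_enrichment must be named by known factors")
    }
    if (any(planted_enrichment <= 0)) stop("f_true must be > 0")
    clash <- intersect(names(planted_enrichment), paired)
    if (length(clash)) {
      stop("factor(s) both pair-planted and enrichment-planted: ",
           paste(clash, collapse = ", "))
    }
  }
  bad <- setdiff(driver_factors, factor_names)
  if (length(bad)) stop("unknown driver factor(s): ",
                        paste(bad, collapse = ", "))
  genes_per_chrom <- ceiling(n_genes / n_chrom)
  chrom_length <- as.integer(100000 + genes_per_chrom * gene_spacing)
  # grid footprint of pair-planted factors must fit on the chromosome
  if (length(planted_pairs)) {
    gap <- 8L * as.integer(peak_width_mean)
    need <- 1000 + length(planted_pairs) * 1000 +
      (peaks_per_factor + 1) * gap
    if (need > chrom_length) {
      stop("infeasible config: ", peaks_per_factor,
           " grid-placed peaks do not fit a chromosome of ",
           chrom_length, " bp")
    }
  }
  structure(list(n_genes = as.integer(n_genes),
                 gene_spacing = as.integer(gene_spacing),
                 n_chrom = as.integer(n_chrom),
                 chrom_length = chrom_length,
                 factor_names = factor_names, hm_factors = hm_factors,
                 peaks_per_factor = as.integer(peaks_per_factor),
                 peak_width_mean = peak_width_mean,
                 peak_width_sd = peak_width_sd,
                 hm_width_mean = hm_width_mean, hm_width_sd = hm_width_sd,
                 tss_enrichment = tss_enrichment,
                 planted_pairs = planted_pairs,
                 planted_enrichment = planted_enrichment,
                 driver_factors = driver_factors,
                 beta = beta, noise_sd = noise_sd,
                 cell_lines = cell_lines, seed = as.integer(seed)),
            class = "SimulationConfig")
}

# lognormal widths with the requested arithmetic mean/sd, floored at 50 bp
.draw_widths <- function(n, mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  w <- stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
  pmax(50L, as.integer(round(w)))
}

.peaks_df <- function(chrom, center, width, signal) {
  start <- pmax(0L, as.integer(center) - as.integer(width) %/% 2L)
  data.frame(chrom = chrom, start = start,
             end = start + as.integer(width),
             name = sprintf("p%d", seq_along(start)),
             score = 0L, strand = ".", signal = signal,
             summit = NA_integer_)
}

#' Simulate a genome with planted peak-track structure
#'
#' Generates the gene annotation and, for each of the two cell lines, one
#' peak track per configured factor, honouring the planted
#' co-localization, cell-line enrichment, and TSS-enrichment structure of
#' the [simulation_config()]. Each TSS-proximal peak picks its host gene
#' uniformly at random — independently per factor, so factors are
#' uncoupled unless planted — and sits at a uniform offset within 2 kb of
#' the TSS; background peaks are uniform over the chromosome.
#' Deterministic given the config (which includes the seed).
#'
#' @param config A [simulation_config()].
#' @return List: `genes` (a [gene_annotation()]) and `tracks`, a list
#'   keyed by cell line, each a named list of [factor_track()]s.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  .with_seed(config$seed, {
    chroms <- sprintf("chrS%d", seq_len(config$n_chrom))
    gi <- seq_len(config$n_genes)
    chrom_of_gene <- chroms[(gi - 1L) %% config$n_chrom + 1L]
    slot <- (gi - 1L) %/% config$n_chrom
    genes <- gene_annotation(
      gene_id = sprintf("g%05d", gi),
      chrom = chrom_of_gene,
      tss = 50000L + slot * config$gene_spacing,
      strand = sample(c("+", "-"), config$n_genes, replace = TRUE))

    pair_of <- list()
    for (k in seq_along(config$planted_pairs)) {
      p <- config$planted_pairs[[k]]
      pair_of[[p$factor_a]] <- list(role = "a", k = k, mate = p$factor_b,
                                    co_rate = p$co_rate)
      pair_of[[p$factor_b]] <- list(role = "b", k = k, mate = p$factor_a,
                                    co_rate = p$co_rate)
    }

    tracks <- stats::setNames(vector("list", 2L), config$cell_lines)
    for (cl in config$cell_lines) tracks[[cl]] <- list()

    P <- config$peaks_per_factor
    for (fn in config$factor_names) {
      is_hm <- fn %in% config$hm_factors
      wmean <- if (is_hm) config$hm_width_mean else config$peak_width_mean
      wsd <- if (is_hm) config$hm_width_sd else config$peak_width_sd
      if (!is.null(pair_of[[fn]])) {
        # grid scheme: fixed-width peaks on a regular lattice; the mate
        # factor's matched peaks are jittered inside the overlap bound,
        # its unmatched peaks sit on lattice midpoints, out of reach
        info <- pair_of[[fn]]
        w <- as.integer(config$peak_width_mean)
        gap <- 8L * w
        base <- 1000L + info$k * 1000L
        pos_a <- base + (seq_len(P) - 1L) * gap
        for (cl in config$cell_lines) {
          if (info$role == "a") {
            centers <- pos_a
          } else {
            # per-(cell line, pair) Bernoulli draw shared via a derived
            # seed so A and B agree on which peaks are matched
            sub <- (config$seed + 104729L * info$k +
                      7919L * match(cl, config$cell_lines)) %% 2147483647L
            matched <- .with_seed(sub, stats::runif(P) < info$co_rate)
            delta <- .with_seed(sub + 1L,
                                sample(seq(-(w - 1L), w - 1L), P,
                                       replace = TRUE))
            centers <- ifelse(matched, pos_a + delta, pos_a + gap %/% 2L)
          }
          tracks[[cl]][[fn]] <- factor_track(
            .peaks_df(chroms[1], centers, w,
                      stats::rlnorm(P, 1, 0.5)),
            fn, if (is_hm) "HM" else "TF", cl)
        }
      } else {
        n_prox_base <- round(P * config$tss_enrichment)
        f_true <- if (fn %in% names(config$planted_enrichment))
          config$planted_enrichment[[fn]] else NA_real_
        for (cl in config$cell_lines) {
          n_prox <- if (is.na(f_true)) n_prox_base
          else if (cl == config$cell_lines[1])
            round(2 * n_prox_base * f_true / (1 + f_true))
          else 2 * n_prox_base - round(2 * n_prox_base * f_true /
                                         (1 + f_true))
          n_bg <- P - n_prox_base
          host <- sample.int(config$n_genes, n_prox, replace = TRUE)
          prox_ctr <- genes$tss[host] +
            sample(seq(-2000L, 2000L), n_prox, replace = TRUE)
          prox_chr <- genes$chrom[host]
          bg_chr <- sample(chroms, n_bg, replace = TRUE)
          bg_ctr <- sample.int(config$chrom_length - 4000L, n_bg,
                               replace = TRUE) + 2000L
          n_tot <- n_prox + n_bg
          tracks[[cl]][[fn]] <- factor_track(
            .peaks_df(c(prox_chr, bg_chr), c(prox_ctr, bg_ctr),
                      .draw_widths(n_tot, wmean, wsd),
                      stats::rlnorm(n_tot, 1, 0.5)),
            fn, if (is_hm) "HM" else "TF", cl)
        }
      }
    }
    list(genes = genes, tracks = tracks)
  })
}

#' Simulate expression coupled to driver-factor TFAS
#'
#' FPKM of gene i is `exp(beta * mean(driver TFAS_i) + eps_i)` with
#' `eps ~ Normal(0, noise_sd)`: a noisy monotone (exponential-link)
#' function of the designated factors' association strengths, strictly
#' positive as FPKM must be. With `noise_sd = 0` the expression rank
#' order equals the driver-TFAS rank order exactly.
#'
#' @param genes A [gene_annotation()].
#' @param tfas_mat TFAS matrix covering all genes ([tfas_matrix()]).
#' @param driver_factors Columns of `tfas_mat` that drive expression.
#' @param noise_sd Noise standard deviation (log scale).
#' @param beta Link slope (> 0).
#' @param seed RNG seed.
#' @return Named numeric FPKM vector over `genes$gene_id`.
#' @export
simulate_expression <- function(genes, tfas_mat, driver_factors,
                                noise_sd = 0.5, beta = 1, seed = 1L) {
  bad <- setdiff(driver_factors, colnames(tfas_mat))
  if (length(bad)) stop("unknown driver factor(s): ",
                        paste(bad, collapse = ", "))
  if (!length(driver_factors)) stop("need at least one driver factor")
  miss <- setdiff(genes$gene_id, rownames(tfas_mat))
  if (length(miss)) stop("TFAS matrix does not cover all genes")
  drv <- rowMeans(tfas_mat[genes$gene_id, driver_factors, drop = FALSE])
  eps <- if (noise_sd > 0) {
    .with_seed(seed, stats::rnorm(length(drv), 0, noise_sd))
  } else rep(0, length(drv))
  stats::setNames(exp(beta * drv + eps), genes$gene_id)
}

#' Write a simulated dataset in the formats the readers accept
#'
#' One narrowPeak (TF) or broadPeak (HM) file per factor under
#' `<dir>/<cell_line>/`, the gene annotation as 4-column TSV, and
#' optionally per-cell-line expression tables.
#'
#' @param sim Result of [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @param expression Optional named list, cell line -> FPKM vector.
#' @return Character vector of files written, invisibly.
#' @export
write_simulation <- function(sim, dir, expression = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  anno <- file.path(dir, "genes.tsv")
  write_gene_annotation(sim$genes, anno)
  files <- c(files, anno)
  for (cl in names(sim$tracks)) {
    cdir <- file.path(dir, cl)
    dir.create(cdir, showWarnings = FALSE)
    for (fn in names(sim$tracks[[cl]])) {
      track <- sim$tracks[[cl]][[fn]]
      if (track$factor_class == "HM") {
        path <- file.path(cdir, paste0(fn, ".broadPeak"))
        write_broadpeak(track, path)
      } else {
        path <- file.path(cdir, paste0(fn, ".narrowPeak"))
        write_narrowpeak(track, path)
      }
      files <- c(files, path)
    }
    if (!is.null(expression) && cl %in% names(expression)) {
      ep <- file.path(dir, paste0("expression_", cl, ".tsv"))
      write_expression(expression[[cl]], ep)
      files <- c(files, ep)
    }
  }
  invisible(files)
}
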