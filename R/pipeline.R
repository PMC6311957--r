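#' Assemble a pipeline configuration
#'
#' Collects the inputs and parameters of the full two-step analysis:
#' ingest peak tracks and annotation, filter genes, profile TSS signal
#' and classify factor dynamics, compute pairwise co-localization and
#' its cross-cell-line variation, TFAS and the interaction network, and
#' the SVM expression classification. Parameter defaults are the
#' pipeline's standard constants: 20 kb half window, 200 bp bins, 2 kb
#' TFAS decay length, 0.6 network threshold.
#'
#' @param peak_dirs Named list/vector, cell line -> directory holding one
#'   `.narrowPeak` / `.broadPeak` file per factor (two cell lines).
#' @param annotation Path to the gene annotation ([read_gene_annotation()]).
#' @param expression Named list/vector, cell line -> expression TSV; may
#'   be empty, which skips the prediction stage.
#' @param out_dir Output directory for the stage TSVs.
#' @param half_window,bin_size,d0 Core distance parameters, bp.
#' @param count_mode Overlap counting mode ([overlap_ratio()]).
#' @param network_threshold,network_weight Edge rule for
#'   [build_network()].
#' @param svm_folds,svm_cost SVM cross-validation settings.
#' @param seed Integer seed for all pipeline randomness.
#' @param regions Optional BED of regions for region-restricted overlap.
#' @return List of class `PipelineConfig`.
#' @export
pipeline_config <- function(peak_dirs, annotation, expression = list(),
                            out_dir = "cochip_out", half_window = 20000L,
                            bin_size = 200L, d0 = 2000,
                            count_mode = "matched",
                            network_threshold = 0.6, network_weight = "r_o",
                            svm_folds = 5L, svm_cost = 1, seed = 1L,
                            regions = NULL) {
  structure(list(peak_dirs = as.list(peak_dirs), annotation = annotation,
                 expression = as.list(expression), out_dir = out_dir,
                 half_window = as.integer(half_window),
                 bin_size = as.integer(bin_size), d0 = d0,
                 count_mode = count_mode,
                 network_threshold = network_threshold,
                 network_weight = network_weight,
                 svm_folds = as.integer(svm_folds), svm_cost = svm_cost,
                 seed = as.integer(seed), regions = regions),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Validate a pipeline configuration
#'
#' Checks paths and parameter ranges without running anything; returns
#' diagnostics rather than raising errors.
#'
#' @param config A `PipelineConfig`.
#' @return Character vector of problems; empty when the config is clean.
#' @export
validate_config <- function(config) {
  diag <- character()
  if (length(config$peak_dirs) != 2L) {
    diag <- c(diag, "peak_dirs must name exactly two cell lines")
  }
  for (cl in names(config$peak_dirs)) {
    d <- config$peak_dirs[[cl]]
    if (!dir.exists(d)) {
      diag <- c(diag, sprintf("peak directory missing for %s: %s", cl, d))
    } else if (!length(list.files(d, "\\.(narrowPeak|broadPeak)(\\.gz)?$"))) {
      diag <- c(diag, sprintf("no peak files in %s", d))
    }
  }
  if (!file.exists(config$annotation)) {
    diag <- c(diag, paste("annotation missing:", config$annotation))
  }
  for (cl in names(config$expression)) {
    if (!file.exists(config$expression[[cl]])) {
      diag <- c(diag, sprintf("expression table missing for %s: %s", cl,
                              config$expression[[cl]]))
    }
  }
  if (config$half_window <= 0) diag <- c(diag, "half_window must be > 0")
  if (config$bin_size <= 0) diag <- c(diag, "bin_size must be > 0")
  if (config$half_window > 0 && config$bin_size > 0 &&
      config$half_window %% config$bin_size != 0) {
    diag <- c(diag, "half_window is not divisible by bin_size")
  }
  if (config$d0 <= 0) diag <- c(diag, "d0 must be > 0")
  if (!is.null(config$regions) && !file.exists(config$regions)) {
    diag <- c(diag, paste("regions file missing:", config$regions))
  }
  if (length(config$peak_dirs) == 2L &&
      all(vapply(config$peak_dirs, dir.exists, logical(1)))) {
    fls <- lapply(config$peak_dirs, function(d) {
      .strip_ext(list.files(d, "\\.(narrowPeak|broadPeak)(\\.gz)?$"))
    })
    if (!length(intersect(fls[[1]], fls[[2]]))) {
      diag <- c(diag, "no factor names in common between the two cell lines")
    }
  }
  diag
}

.read_peak_dir <- function(dir, cell_line) {
  files <- list.files(dir, "\\.(narrowPeak|broadPeak)(\\.gz)?$",
                      full.names = TRUE)
  tracks <- lapply(files, function(f) {
    if (grepl("\\.broadPeak(\\.gz)?$", f)) {
      read_broadpeak(f, cell_line = cell_line)
    } else read_narrowpeak(f, cell_line = cell_line)
  })
  stats::setNames(tracks, vapply(tracks, `[[`, "", "factor_name"))
}

#' Run the full integrative pipeline
#'
#' Executes the stages in dependency order, writing one TSV per result
#' table under `config$out_dir` plus a `MANIFEST.tsv` naming every output
#' with a content hash. With fewer than two shared factors the
#' co-localization, network and dynamics stages are skipped with a
#' warning; without expression tables the prediction stage is skipped.
#' All randomness flows from `config$seed`, so a re-run with the same
#' config is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return List of class `RunReport`: `counts` (per-stage row counts),
#'   `outputs` (file manifest with md5 hashes), `timings` (per-stage
#'   elapsed seconds), `config`, `version`.
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems)) {
    stop("invalid pipeline config:\n  ", paste(problems, collapse = "\n  "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  counts <- list()
  outputs <- character()
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(code), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  emit <- function(df, file) {
    path <- file.path(config$out_dir, file)
    .write_tsv(df, path, col.names = TRUE)
    outputs <<- c(outputs, path)
    path
  }

  cls <- names(config$peak_dirs)
  ingest <- stage("ingest", {
    tracks <- lapply(cls, function(cl) {
      .read_peak_dir(config$peak_dirs[[cl]], cl)
    })
    names(tracks) <- cls
    genes <- read_gene_annotation(config$annotation)
    list(tracks = tracks, genes = genes)
  })
  counts$genes_read <- nrow(ingest$genes)
  counts$factors <- vapply(ingest$tracks, length, integer(1))

  genes <- stage("filter_genes", {
    filter_nonoverlapping_genes(ingest$genes, config$half_window)
  })
  counts$genes_kept <- nrow(genes)
  if (!nrow(genes)) stop("pipeline stage 'filter_genes' failed: no genes left")

  common <- intersect(names(ingest$tracks[[1]]), names(ingest$tracks[[2]]))
  tg <- ingest$tracks[[1]][common]
  tk <- ingest$tracks[[2]][common]

  dyn <- stage("profile", {
    factor_dynamics_table(tg, tk, genes, config$half_window,
                          config$bin_size)
  })
  emit(dyn, "factor_dynamics.tsv")
  counts$factors_profiled <- nrow(dyn)

  pair_dyn <- NULL
  if (length(common) >= 2L) {
    pair_dyn <- stage("colocalization", {
      pair_dynamics_table(tg, tk, count_mode = config$count_mode)
    })
    emit(pair_dyn, "pair_dynamics.tsv")
    counts$pairs <- nrow(pair_dyn)

    rav <- stage("average_overlap", {
      do.call(rbind, lapply(seq_along(common), function(i) {
        data.frame(
          factor_name = common[i],
          r_av_g = average_overlap_ratio(tg[[i]], tg[-i])$r_av,
          r_av_k = average_overlap_ratio(tk[[i]], tk[-i])$r_av)
      }))
    })
    emit(rav, "average_overlap.tsv")

    combos <- stage("combinations", {
      ro_g <- overlap_ratio_table(tg, config$count_mode)
      mine_combinations(ro_g, k = 3L,
                        threshold = config$network_threshold)
    })
    emit(combos, "triples.tsv")
    counts$triples <- nrow(combos)
  } else {
    warning("fewer than two shared factors: co-localization stage skipped")
  }

  tfas_mats <- stage("tfas", {
    list(G = tfas_matrix(tg, genes, config$d0, config$half_window),
         K = tfas_matrix(tk, genes, config$d0, config$half_window))
  })
  emit(data.frame(gene_id = rownames(tfas_mats$G), tfas_mats$G,
                  check.names = FALSE), "tfas_G.tsv")
  emit(data.frame(gene_id = rownames(tfas_mats$K), tfas_mats$K,
                  check.names = FALSE), "tfas_K.tsv")

  if (!is.null(pair_dyn)) {
    net <- stage("network", {
      ro_g <- overlap_ratio_table(tg, config$count_mode)
      pcc <- tfas_pcc_table(tfas_mats$G)
      w <- if (config$network_weight == "pcc") pcc else ro_g
      build_network(w, pair_dyn, dyn, weight = config$network_weight,
                    threshold = config$network_threshold)
    })
    emit(net$edges, "network_edges.tsv")
    emit(net$nodes, "network_nodes.tsv")
    counts$network_edges <- nrow(net$edges)
  }

  if (length(config$expression)) {
    pred <- stage("predict", {
      rows <- lapply(names(config$expression), function(cl) {
        expr <- read_expression(config$expression[[cl]])
        labels <- quartile_labels(expr)
        a <- if (cl == cls[1]) tfas_mats$G else tfas_mats$K
        cbind(cell_line = cl,
              svm_scan(a, labels, folds = config$svm_folds,
                       seed = config$seed, cost = config$svm_cost))
      })
      do.call(rbind, rows)
    })
    emit(pred, "prediction_metrics.tsv")
    counts$models <- nrow(pred)
    if (length(config$expression) == 2L && nrow(dyn)) {
      dacc <- stage("prediction_difference", {
        ag <- pred[pred$cell_line == cls[1], ]
        ak <- pred[pred$cell_line == cls[2], ]
        common_f <- intersect(ag$feature_set, ak$feature_set)
        d <- data.frame(
          factor_name = common_f,
          acc_g = ag$acc[match(common_f, ag$feature_set)],
          acc_k = ak$acc[match(common_f, ak$feature_set)])
        d$d_acc <- prediction_difference(d$acc_g, d$acc_k)
        d$d_signal <- dyn$d_signal[match(common_f, dyn$factor_name)]
        d
      })
      emit(dacc, "prediction_difference.tsv")
      ok <- stats::complete.cases(dacc[, c("d_acc", "d_signal")])
      counts$d_acc_d_signal_pcc <- if (sum(ok) >= 3) {
        correlate_dynamics(dacc$d_acc[ok], dacc$d_signal[ok])
      } else NA_real_
    }
  }

  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         bytes = file.size(outputs))
  .write_tsv(manifest, file.path(config$out_dir, "MANIFEST.tsv"),
             col.names = TRUE)
  structure(list(counts = counts, outputs = manifest,
                 timings = unlist(timings), config = config,
                 version = as.character(utils::packageVersion("cochip"))),
            class = "RunReport")
}

#' @export
print.RunReport <- function(x, ...) {
  cat("cochip run report (version ", x$version, ")\n", sep = "")
  cat("  outputs: ", nrow(x$outputs), " files in ", x$config$out_dir, "\n",
      sep = "")
  for (nm in names(x$counts)) {
    v <- x$counts[[nm]]
    cat("  ", nm, ": ", paste(format(v, digits = 4), collapse = " / "),
        "\n", sep = "")
  }
  invisible(x)
}
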