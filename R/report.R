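# Reporting: rank-order summary plots, the replicate-level heat map, and
# the end-to-end pipeline driver. Every plotted number is also written as a
# plain TSV so reports are re-derivable without image comparison.

heat_bin_colours <- c(
  bright_green = "#00B200", dark_green = "#1B5E20", grey = "grey65",
  dark_red = "#8B1A1A", bright_red = "#FF2400", white = "white"
)

#' Rank-order plot data
#'
#' Replicate-level merged ratios sorted ascending within each series: one
#' series per non-reference condition, plus the reference self-ratio series
#' (which hovers around 1 by construction). Capped values sit at the cap.
#'
#' @param merged Output of [merge_peptide_forms()].
#' @param reference Reference condition name.
#' @return Tibble with `series`, `rank` (1..n ascending within series),
#'   `ratio`, `capped`.
#' @export
rank_plot_data <- function(merged, reference) {
  merged |>
    dplyr::mutate(
      series = ifelse(.data$condition == reference,
                      paste0(reference, " (self)"), .data$condition)
    ) |>
    dplyr::group_by(.data$series) |>
    dplyr::arrange(.data$ratio, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number(), capped = .data$any_capped) |>
    dplyr::ungroup() |>
    dplyr::select("series", "rank", "ratio", "capped")
}

#' Rank-order summary plot
#'
#' @param data Output of [rank_plot_data()].
#' @return A ggplot: ratio (log scale) against rank, one panel per series.
#' @export
plot_rank_order <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$rank, y = .data$ratio)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6, colour = "#B2182B") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~series, scales = "free_x") +
    ggplot2::labs(x = "rank order of peptide replicates",
                  y = "relative peptide level") +
    ggplot2::theme_bw()
}

#' Replicate-level heat-map matrix
#'
#' One cell per peptide x experiment x replicate, coloured by the
#' fold-change bin of the merged replicate value; peptides not quantified
#' in a replicate get white cells.
#'
#' @param merged Output of [merge_peptide_forms()].
#' @param reference Reference condition; its self-ratio columns are
#'   excluded by default.
#' @param include_reference Keep the reference replicate columns?
#' @return Tibble with `sequence`, `run_id`, `condition`, `replicate`,
#'   `column` (condition.replicate label), `ratio`, `heat_bin`, `colour`;
#'   complete over peptides x observed columns.
#' @export
heatmap_matrix <- function(merged, reference, include_reference = FALSE) {
  m <- merged
  if (!include_reference) {
    m <- dplyr::filter(m, .data$condition != reference)
  }
  cols <- dplyr::distinct(m, .data$run_id, .data$condition,
                          .data$replicate) |>
    dplyr::arrange(.data$condition, .data$replicate)
  grid <- tidyr::crossing(
    sequence = unique(m$sequence), cols
  )
  grid |>
    dplyr::left_join(
      m[c("sequence", "run_id", "condition", "replicate", "ratio")],
      by = c("sequence", "run_id", "condition", "replicate")
    ) |>
    dplyr::mutate(
      column = paste(.data$condition, .data$replicate, sep = "."),
      heat_bin = heat_bin(.data$ratio),
      colour = unname(heat_bin_colours[.data$heat_bin])
    )
}

#' Heat map of replicate-level fold changes
#'
#' @param matrix_data Output of [heatmap_matrix()].
#' @return A ggplot tile map: peptides as rows, replicates as columns.
#' @export
plot_heatmap <- function(matrix_data) {
  ord <- matrix_data |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(m = mean(.data$ratio, na.rm = TRUE)) |>
    dplyr::arrange(.data$m)
  d <- dplyr::mutate(
    matrix_data,
    sequence = factor(.data$sequence, levels = ord$sequence)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$column, y = .data$sequence,
                                  fill = .data$heat_bin)) +
    ggplot2::geom_tile(colour = "grey85", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = heat_bin_colours,
                               name = "relative level") +
    ggplot2::labs(x = "experiment / replicate", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. With `simulate = TRUE`
#' the input files are generated by the synthetic study generator;
#' otherwise `paths` must name existing peak, FASTA, identification and
#' scheme files.
#'
#' @param out_dir Output directory (created if needed).
#' @param simulate Generate synthetic inputs?
#' @param paths Named list of input paths (`peaks`, `fasta`,
#'   `identifications`, `scheme`) when `simulate = FALSE`.
#' @param n_proteins,model,design,params Synthetic-study settings (see
#'   [simulate_study()]).
#' @param reference Reference condition.
#' @param ppm_tol,rt_tol Detection tolerances.
#' @param low_cap,high_cap Ratio caps; `high_cap = NULL` disables the upper
#'   cap.
#' @param counting Cleavage counting mode.
#' @param pool_conditions Pool non-reference conditions in the P1 table?
#' @param seed Master seed.
#' @return Validated config list.
#' @export
pipeline_config <- function(out_dir, simulate = TRUE, paths = list(),
                            n_proteins = 30, model = degradome_model(),
                            design = effect_design(),
                            params = spectrum_params(),
                            reference = design$reference,
                            ppm_tol = 10, rt_tol = 0.2, low_cap = 0.20,
                            high_cap = 5.0,
                            counting = "per_replicate",
                            pool_conditions = TRUE, seed = 1) {
  cfg <- list(out_dir = out_dir, simulate = simulate, paths = paths,
              n_proteins = n_proteins, model = model, design = design,
              params = params, reference = reference, ppm_tol = ppm_tol,
              rt_tol = rt_tol, low_cap = low_cap, high_cap = high_cap,
              counting = counting, pool_conditions = pool_conditions,
              seed = seed)
  if (!simulate) {
    needed <- c("peaks", "fasta", "identifications", "scheme")
    missing <- setdiff(needed, names(paths))
    if (length(missing) > 0) {
      stop("config error: missing input paths: ",
           paste(missing, collapse = ", "))
    }
    absent <- unlist(paths[needed])[!file.exists(unlist(paths[needed]))]
    if (length(absent) > 0) {
      stop("config error: input files do not exist: ",
           paste(absent, collapse = ", "))
    }
  }
  cfg
}

#' Run the full pipeline
#'
#' simulate (optional) -> detect -> quantify -> cleavage -> report. All
#' intermediate tables are written as TSV under `out_dir`, plots as PDF
#' beside their point data, plus a `manifest.json` recording the seed, a
#' config hash and the row counts of every output. Re-running with the same
#' config and seed reproduces the outputs byte for byte.
#'
#' @param config Output of [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`study`, `groups`,
#'   `quant`, `cleavage`, `manifest`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)

  if (config$simulate) {
    study <- simulate_study(
      n_proteins = config$n_proteins, model = config$model,
      design = config$design, params = config$params, seed = config$seed
    )
    write_proteome_fasta(study$proteome, path("proteome.fasta"))
    write_identifications(study$identifications, path("identifications.tsv"))
    write_scheme(study$scheme, path("scheme.tsv"))
    write_peaks(study$peaks, path("peaks.tsv"))
    readr::write_tsv(study$truth, path("ground_truth.tsv"))
  } else {
    study <- list(
      proteome = read_proteome_fasta(config$paths$fasta),
      identifications = read_identifications(config$paths$identifications),
      scheme = read_scheme(config$paths$scheme),
      peaks = read_peaks(config$paths$peaks)
    )
  }

  clusters <- detect_isotope_clusters(study$peaks, ppm_tol = config$ppm_tol,
                                      rt_tol = config$rt_tol)
  groups <- find_peak_groups(clusters, study$scheme,
                             ppm_tol = config$ppm_tol,
                             rt_tol = config$rt_tol,
                             identifications = study$identifications)
  groups <- flag_overlap(groups, clusters, rt_tol = config$rt_tol)
  readr::write_tsv(groups, path("peak_groups.tsv"))

  quant <- quantify_study(groups, study$scheme, study$identifications,
                          config$reference, low = config$low_cap,
                          high = config$high_cap, ppm_tol = config$ppm_tol)
  readr::write_tsv(quant$ratios, path("ratios.tsv"))
  readr::write_tsv(quant$merged, path("merged_ratios.tsv"))
  readr::write_tsv(quant$summary, path("peptide_summary.tsv"))

  cleavage <- analyze_cleavage(quant, study$proteome,
                               pool_conditions = config$pool_conditions,
                               count = config$counting)
  readr::write_tsv(cleavage$sites, path("cleavage_sites.tsv"))
  freq_out <- dplyr::mutate(cleavage$freq, counting = config$counting)
  readr::write_tsv(freq_out, path("p1_frequencies.tsv"))

  rank_data <- rank_plot_data(quant$merged, config$reference)
  readr::write_tsv(rank_data, path("rank_plot_data.tsv"))
  grDevices::pdf(NULL)  # keep ggsave from leaving an empty default device
  on.exit(grDevices::dev.off(), add = TRUE)
  ggplot2::ggsave(path("rank_plot.pdf"), plot_rank_order(rank_data),
                  width = 8, height = 4)
  hm <- heatmap_matrix(quant$merged, config$reference)
  readr::write_tsv(hm, path("heatmap_data.tsv"))
  ggplot2::ggsave(path("heatmap.pdf"), plot_heatmap(hm),
                  width = 7, height = 8)

  outputs <- c("peaks.tsv", "peak_groups.tsv", "ratios.tsv",
               "merged_ratios.tsv", "peptide_summary.tsv",
               "cleavage_sites.tsv", "p1_frequencies.tsv",
               "rank_plot_data.tsv", "heatmap_data.tsv")
  outputs <- outputs[file.exists(file.path(config$out_dir, outputs))]
  manifest <- list(
    package_version = as.character(utils::packageVersion("tmabquant")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    reference = config$reference,
    row_counts = lapply(
      stats::setNames(outputs, outputs),
      function(f) nrow(readr::read_tsv(file.path(config$out_dir, f),
                                       show_col_types = FALSE))
    )
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(study = study, groups = groups, quant = quant,
                 cleavage = cleavage, manifest = manifest))
}

#' Rank-order plot of a quantification result
#'
#' @param object A `tmab_quant` object.
#' @param ... Unused.
#' @return A ggplot (see [plot_rank_order()]).
#' @method autoplot tmab_quant
#' @export
autoplot.tmab_quant <- function(object, ...) {
  plot_rank_order(rank_plot_data(object$merged, object$reference))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
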