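# Stage 2: peak groups to per-replicate ratios relative to the reference
# condition, with dynamic-range capping, form merging, per-condition
# summaries (Student's t-test against reference self-ratios) and
# fold-change classification.

#' Cap a ratio to the quantifiable dynamic range
#'
#' Ratios below `low` or above `high` are clamped and flagged; the bounds
#' reflect a typical 5:1 signal-to-noise floor, under which a channel absent
#' from the spectrum can only be said to be below one fifth of the reference
#' level. The high cap can be disabled (`high = NULL` or `Inf`) for designs
#' where only the lower bound applies.
#'
#' @param x Numeric vector of raw ratios (>= 0; `NA` allowed and passed
#'   through).
#' @param low,high Cap values; `high = NULL` disables the upper cap.
#' @return Tibble with columns `raw`, `ratio` (capped) and `cap_flag`
#'   (`"none"`, `"low"`, `"high"`).
#' @export
#' @examples
#' cap_ratio(c(0.05, 0.43, 7.3))
cap_ratio <- function(x, low = 0.20, high = 5.0) {
  if (any(x < 0, na.rm = TRUE)) stop("ratios must be >= 0")
  if (is.null(high)) high <- Inf
  tibble::tibble(
    raw = x,
    ratio = pmin(pmax(x, low), high),
    cap_flag = dplyr::case_when(
      is.na(x) ~ NA_character_,
      x < low ~ "low",
      x > high ~ "high",
      TRUE ~ "none"
    )
  )
}

#' Per-replicate ratios of a set of peak groups
#'
#' For every group the denominator is the mean representative intensity of
#' the run's reference channels (so reference self-ratios average exactly 1
#' within each run). Every present, non-overlapped channel - including the
#' reference replicates themselves - yields `intensity / denominator`,
#' capped to the dynamic range. A channel missing from the spectrum while
#' reference signal is present can only be below the noise floor and is
#' recorded at the low cap. Overlap-flagged channels are skipped; groups
#' with no usable reference channel are dropped and reported in the
#' `unquantifiable` attribute.
#'
#' @param groups Output of [flag_overlap()] (or [find_peak_groups()], in
#'   which case no channel is overlap-flagged).
#' @param scheme Labeling scheme tibble.
#' @param reference Reference condition name.
#' @param low,high Cap bounds, see [cap_ratio()].
#' @return Tibble of ratio records: `run_id`, `group_id`, `z`, `n_labels`,
#'   `neutral_mass`, `tag`, `condition`, `replicate`, `raw_ratio`, `ratio`,
#'   `cap_flag`. Attribute `unquantifiable` holds dropped group keys.
#' @export
replicate_ratios <- function(groups, scheme, reference, low = 0.20,
                             high = 5.0) {
  validate_scheme(scheme, reference)
  if (!"overlap" %in% names(groups)) groups$overlap <- FALSE
  if ("coincident" %in% names(groups)) {
    groups$overlap <- groups$overlap | groups$coincident
  }
  g <- dplyr::inner_join(groups, scheme, by = c("run_id", "tag"))
  g <- g |>
    dplyr::group_by(.data$run_id, .data$group_id) |>
    dplyr::mutate(
      denom = mean(.data$intensity[.data$condition == reference &
                                     !.data$missing & !.data$overlap])
    ) |>
    dplyr::ungroup()
  bad <- g |>
    dplyr::filter(is.na(.data$denom) | .data$denom <= 0) |>
    dplyr::distinct(.data$run_id, .data$group_id)
  g <- dplyr::anti_join(g, bad, by = c("run_id", "group_id"))
  g <- g |>
    dplyr::filter(!.data$overlap) |>
    dplyr::mutate(
      raw_ratio = ifelse(.data$missing, NA_real_,
                         .data$intensity / .data$denom)
    )
  capped <- cap_ratio(g$raw_ratio, low, high)
  g$ratio <- ifelse(g$missing, low, capped$ratio)
  g$cap_flag <- ifelse(g$missing, "low", capped$cap_flag)
  out <- g |>
    dplyr::select("run_id", "group_id", "z", "n_labels", "neutral_mass",
                  "tag", "condition", "replicate", "raw_ratio", "ratio",
                  "cap_flag")
  attr(out, "unquantifiable") <- bad
  out
}

#' Attach peptide identifications to peak groups
#'
#' Matches each group's inferred neutral peptide mass against the
#' identification table (labeled mass arithmetic must agree on the label
#' count); the nearest identification within tolerance wins.
#'
#' @param ratios Tibble from [replicate_ratios()] (or the groups tibble).
#' @param identifications Tibble with `sequence`, `n_term_acetylated` and
#'   optionally `protein_id`, `peptide_id`.
#' @param ppm_tol Mass matching tolerance, ppm.
#' @param constants Output of [mass_constants()].
#' @return Input with `sequence`, `n_term_acetylated` and (if present)
#'   `protein_id`, `peptide_id` columns added; unmatched rows carry `NA`.
#' @export
assign_identifications <- function(ratios, identifications, ppm_tol = 10,
                                   constants = mass_constants()) {
  ids <- identifications |>
    dplyr::mutate(
      id_mass = peptide_mass(.data$sequence, .data$n_term_acetylated,
                             constants = constants),
      id_labels = count_tmab_labels(.data$sequence, .data$n_term_acetylated)
    )
  keys <- dplyr::distinct(ratios, .data$neutral_mass, .data$n_labels)
  pick <- function(neutral_mass, n_labels) {
    cand <- which(ids$id_labels == n_labels &
                    abs(ids$id_mass - neutral_mass) <=
                      ppm_tol_da(neutral_mass, ppm_tol) * 2)
    if (length(cand) == 0) return(NA_integer_)
    cand[which.min(abs(ids$id_mass[cand] - neutral_mass))]
  }
  keys$id_row <- purrr::pmap_int(keys, pick)
  keep <- intersect(c("peptide_id", "sequence", "n_term_acetylated",
                      "protein_id"), names(ids))
  keys <- dplyr::bind_cols(
    keys[c("neutral_mass", "n_labels")],
    ids[keys$id_row, keep]
  )
  dplyr::left_join(ratios, keys, by = c("neutral_mass", "n_labels"))
}

#' Merge multiple observed forms of one peptide
#'
#' A peptide observed in one replicate at several charge states and/or as
#' several peak groups is averaged (arithmetic mean of capped ratios) into a
#' single value per replicate. Overlap-excluded forms never reach this
#' point; a replicate whose every form was excluded is simply absent
#' (missing, white in the heat map).
#'
#' @param ratios Identified ratio records (see [assign_identifications()]);
#'   rows with `NA` sequence are dropped.
#' @return Tibble with one row per peptide x run x channel: `sequence`,
#'   `n_term_acetylated`, `protein_id`/`peptide_id` if present, `run_id`,
#'   `condition`, `replicate`, `n_forms`, `ratio` (mean over forms),
#'   `any_capped`.
#' @export
merge_peptide_forms <- function(ratios) {
  keep <- intersect(c("peptide_id", "protein_id", "n_term_acetylated"),
                    names(ratios))
  ratios |>
    dplyr::filter(!is.na(.data$sequence)) |>
    dplyr::group_by(
      .data$sequence, .data$run_id, .data$condition, .data$replicate,
      dplyr::across(dplyr::all_of(keep))
    ) |>
    dplyr::summarise(
      n_forms = dplyr::n(),
      ratio = mean(.data$ratio),
      any_capped = any(.data$cap_flag != "none"),
      .groups = "drop"
    )
}

# Two-sample two-tailed Student's t-test (equal variance), tolerant of
# degenerate inputs: identical constant groups give p = 1, constant but
# different groups give p ~ 0.
student_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) return(NA_real_)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  if (sp2 == 0) return(if (mean(x) == mean(y)) 1 else 0)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * stats::pt(-abs(t), nx + ny - 2)
}

#' Classify a mean fold-change
#'
#' `decrease` for mean ratios at or below 0.80, `increase` at or above
#' 1.25, `no_change` between. The printed 0.81-1.24 band is treated as the
#' contiguous open interval (0.80, 1.25): the two-decimal bounds imply
#' rounding, not a gap.
#'
#' @param mean_ratio Numeric vector (>= 0; `NA` gives `NA`).
#' @param thresholds Numeric `c(decrease, increase)` bounds.
#' @return Character vector in \{`decrease`, `no_change`, `increase`\}.
#' @export
#' @examples
#' classify_change(c(0.43, 0.87, 1.59))
classify_change <- function(mean_ratio, thresholds = c(0.80, 1.25)) {
  if (any(mean_ratio < 0, na.rm = TRUE)) stop("mean ratios must be >= 0")
  dplyr::case_when(
    is.na(mean_ratio) ~ NA_character_,
    mean_ratio <= thresholds[1] ~ "decrease",
    mean_ratio >= thresholds[2] ~ "increase",
    TRUE ~ "no_change"
  )
}

#' Heat-map bin of a mean fold-change
#'
#' Five colour bins plus white for missing values: bright green below 0.60
#' (large decrease), dark green 0.60-0.80 (small decrease), grey strictly
#' between 0.80 and 1.20 (within 20% of reference), dark red 1.20-1.40
#' (small increase, left boundary included), bright red above 1.40.
#'
#' @param mean_ratio Numeric vector; `NA` maps to `"white"`.
#' @return Character vector of bin names.
#' @export
#' @examples
#' heat_bin(c(0.43, 1.00, 1.20, NA))
heat_bin <- function(mean_ratio) {
  dplyr::case_when(
    is.na(mean_ratio) ~ "white",
    mean_ratio < 0.60 ~ "bright_green",
    mean_ratio <= 0.80 ~ "dark_green",
    mean_ratio < 1.20 ~ "grey",
    mean_ratio <= 1.40 ~ "dark_red",
    TRUE ~ "bright_red"
  )
}

p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Per-condition peptide summary
#'
#' For each peptide and condition: mean, sample SD (n - 1) and n of the
#' merged replicate values, a two-tailed unpaired equal-variance Student's
#' t-test against the peptide's reference self-ratios (omitted when either
#' side has fewer than two values), significance stars at 0.05 / 0.01 /
#' 0.001, the fold-change category and the heat-map bin.
#'
#' @param merged Output of [merge_peptide_forms()].
#' @param reference Reference condition name.
#' @return Tibble: `sequence` (plus provenance columns when present),
#'   `condition`, `n`, `mean_ratio`, `sd_ratio`, `p_value`, `stars`,
#'   `category`, `heat_bin`.
#' @export
condition_summary <- function(merged, reference) {
  keep <- intersect(c("peptide_id", "protein_id", "n_term_acetylated"),
                    names(merged))
  ref_vals <- merged |>
    dplyr::filter(.data$condition == reference) |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(ref = list(.data$ratio), .groups = "drop")
  merged |>
    dplyr::group_by(.data$sequence, .data$condition,
                    dplyr::across(dplyr::all_of(keep))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_ratio = mean(.data$ratio),
      sd_ratio = stats::sd(.data$ratio),
      values = list(.data$ratio),
      .groups = "drop"
    ) |>
    dplyr::left_join(ref_vals, by = "sequence") |>
    dplyr::mutate(
      p_value = purrr::map2_dbl(
        .data$values, .data$ref,
        function(v, r) if (is.null(r)) NA_real_ else student_t_p(v, r)
      ),
      p_value = ifelse(.data$condition == reference, NA_real_,
                       .data$p_value),
      stars = p_stars(.data$p_value),
      category = classify_change(.data$mean_ratio),
      heat_bin = heat_bin(.data$mean_ratio)
    ) |>
    dplyr::select(-"values", -"ref")
}

#' Quantify a labeling study end to end
#'
#' Chains [replicate_ratios()], [assign_identifications()],
#' [merge_peptide_forms()] and [condition_summary()] over detected peak
#' groups, returning a `tmab_quant` object.
#'
#' @param groups Output of [flag_overlap()].
#' @param scheme Labeling scheme tibble.
#' @param identifications Identification table (see
#'   [assign_identifications()]).
#' @param reference Reference condition name.
#' @param low,high Cap bounds; `high = NULL` disables the upper cap.
#' @param ppm_tol Identification mass tolerance, ppm.
#' @param constants Output of [mass_constants()].
#' @return A `tmab_quant` object: list with `ratios`, `merged`, `summary`,
#'   `reference`, `unquantifiable`.
#' @export
quantify_study <- function(groups, scheme, identifications, reference,
                           low = 0.20, high = 5.0, ppm_tol = 10,
                           constants = mass_constants()) {
  ratios <- replicate_ratios(groups, scheme, reference, low, high)
  ratios <- assign_identifications(ratios, identifications, ppm_tol,
                                   constants)
  merged <- merge_peptide_forms(ratios)
  summary <- condition_summary(merged, reference)
  structure(
    list(ratios = ratios, merged = merged, summary = summary,
         reference = reference,
         unquantifiable = attr(ratios, "unquantifiable")),
    class = "tmab_quant"
  )
}

#' @export
print.tmab_quant <- function(x, ...) {
  cat("TMAB quantification:",
      dplyr::n_distinct(x$merged$sequence), "peptides,",
      dplyr::n_distinct(x$ratios$group_id, x$ratios$run_id),
      "peak groups, reference =", x$reference, "\n")
  invisible(x)
}

#' Tidy a TMAB quantification
#'
#' @param x A `tmab_quant` object.
#' @param ... Unused.
#' @return The per-peptide, per-condition summary tibble.
#' @method tidy tmab_quant
#' @export
tidy.tmab_quant <- function(x, ...) x$summary

#' One-row overview of a TMAB quantification
#'
#' @param x A `tmab_quant` object.
#' @param ... Unused.
#' @return Tibble with peptide/group/record counts and the fraction of
#'   non-reference condition summaries in each fold-change category.
#' @method glance tmab_quant
#' @export
glance.tmab_quant <- function(x, ...) {
  s <- dplyr::filter(x$summary, .data$condition != x$reference)
  tibble::tibble(
    n_peptides = dplyr::n_distinct(x$merged$sequence),
    n_ratio_records = nrow(x$ratios),
    n_conditions = dplyr::n_distinct(x$merged$condition),
    prop_decrease = mean(s$category == "decrease"),
    prop_no_change = mean(s$category == "no_change"),
    prop_increase = mean(s$category == "increase")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
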