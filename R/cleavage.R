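# Stage 3: map peptides back to protein coordinates, enumerate the
# cleavage events that generated them, and tabulate P1 residue frequencies
# by fold-change category.

#' Locate peptides within their source proteins
#'
#' Exact substring search in the named protein. Multiple matches take the
#' first occurrence and set `ambiguous`; no match is an error unless
#' `on_missing = "drop"` (dropped rows are reported in a warning). Terminal
#' status follows the counting rules used for cleavage enumeration: a start
#' at residue 1 or 2 counts as the protein N-terminus (initiator-Met removal
#' is ubiquitous co-translational processing, and N-terminally acetylated
#' peptides at those positions carry the protein's own terminus, not a
#' proteasome cleavage).
#'
#' @param peptides Tibble with `sequence`, `protein_id` and optionally
#'   `n_term_acetylated` (default `FALSE`).
#' @param proteome Tibble with `protein_id`, `sequence`.
#' @param on_missing `"error"` or `"drop"` for peptides absent from their
#'   protein.
#' @return Input plus `start`, `end` (1-based inclusive), `protein_length`,
#'   `terminal` (`n_terminal`/`c_terminal`/`internal`/`full_length`) and
#'   `ambiguous`.
#' @export
locate_peptide <- function(peptides, proteome, on_missing = c("error",
                                                              "drop")) {
  on_missing <- match.arg(on_missing)
  if (!"n_term_acetylated" %in% names(peptides)) {
    peptides$n_term_acetylated <- FALSE
  }
  prot <- stats::setNames(proteome$sequence, proteome$protein_id)
  unknown <- setdiff(unique(peptides$protein_id), names(prot))
  if (length(unknown) > 0) {
    stop("protein_id absent from proteome: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }
  pseq <- unname(prot[peptides$protein_id])
  hit <- stringr::str_locate(pseq, stringr::fixed(peptides$sequence))
  n_hits <- stringr::str_count(pseq, stringr::fixed(peptides$sequence))
  missing <- is.na(hit[, 1])
  if (any(missing)) {
    msg <- paste0(sum(missing), " peptide(s) not found in their protein")
    if (on_missing == "error") stop(msg) else warning(msg, "; dropped")
  }
  out <- peptides |>
    dplyr::mutate(
      start = as.integer(hit[, 1]),
      end = as.integer(hit[, 2]),
      protein_length = nchar(pseq),
      ambiguous = n_hits > 1,
      terminal = dplyr::case_when(
        is.na(.data$start) ~ NA_character_,
        .data$start <= 2L & .data$end == .data$protein_length ~
          "full_length",
        .data$start <= 2L ~ "n_terminal",
        .data$end == .data$protein_length ~ "c_terminal",
        TRUE ~ "internal"
      )
    )
  dplyr::filter(out, !is.na(.data$start))
}

#' Enumerate cleavage sites generating located peptides
#'
#' Internal peptides require two cleavages (the bonds preceding `start` and
#' following `end`); N- or C-terminal fragments one; full-length spans none.
#' A site at position `i` names the bond between residues `i` and `i + 1`;
#' its P1 residue sits at `i` (so a peptide's C-side site has the peptide's
#' last residue in P1). The protein N-terminus, including the Met-removed
#' and acetylated forms, is never counted as a cleavage.
#'
#' @param spans Output of [locate_peptide()].
#' @param proteome Tibble with `protein_id`, `sequence`.
#' @return Tibble, 0-2 rows per peptide: `sequence`, `protein_id`,
#'   `position` (the bond's P1 residue index), `p1`, `p1prime`, `side`
#'   (`generates_peptide_nterm` / `generates_peptide_cterm`).
#' @export
cleavage_sites <- function(spans, proteome) {
  prot <- stats::setNames(proteome$sequence, proteome$protein_id)
  one <- function(sequence, protein_id, start, end, protein_length,
                  n_term_acetylated = FALSE, ...) {
    pos <- integer(0); side <- character(0)
    if (start >= 3L && !n_term_acetylated) {
      pos <- c(pos, start - 1L)
      side <- c(side, "generates_peptide_nterm")
    }
    if (end < protein_length) {
      pos <- c(pos, end)
      side <- c(side, "generates_peptide_cterm")
    }
    if (length(pos) == 0) return(NULL)
    ps <- prot[[protein_id]]
    tibble::tibble(
      sequence = sequence, protein_id = protein_id, position = pos,
      p1 = substring(ps, pos, pos), p1prime = substring(ps, pos + 1L,
                                                        pos + 1L),
      side = side
    )
  }
  out <- purrr::pmap(spans, one)
  dplyr::bind_rows(purrr::compact(out))
}

#' P1 residue of a cleavage site
#'
#' @param position Bond index (residue on the bond's N-terminal side);
#'   must be >= 1 - the protein N-terminus is not a cleavage.
#' @param protein_sequence Protein sequence string (recycled).
#' @return Character vector of P1 residues.
#' @export
p1_residue <- function(position, protein_sequence) {
  if (any(position < 1)) {
    stop("position must be >= 1: the protein N-terminus is not a cleavage")
  }
  substring(protein_sequence, position, position)
}

#' Category-wise P1 residue frequency table
#'
#' Each observation of a peptide (by default one per replicate in which it
#' was quantified, so frequent peptides weigh more, matching how abundance
#' was reflected in the original counting) contributes all of its cleavage
#' sites to its category's counts. Peptides flagged as ambiguously located
#' should be excluded before calling. All 20 residues appear in every
#' category; proportions sum to 1 within categories with any observations.
#'
#' @param observations Tibble with `sequence` and `category`; for
#'   `count = "per_replicate"` one row per (peptide, replicate observation),
#'   for `"per_experiment"` duplicates within `sequence` x `run_id` x
#'   `category` are collapsed first (requires a `run_id` column).
#' @param sites Output of [cleavage_sites()].
#' @param count Counting mode; recorded in the `counting` attribute of the
#'   result.
#' @return Tibble: `category`, `residue`, `n`, `prop`, `residue_class`
#'   (`hydrophobic`/`basic`/`acidic`/`other`).
#' @export
p1_frequency_table <- function(observations, sites,
                               count = c("per_replicate",
                                         "per_experiment")) {
  count <- match.arg(count)
  obs <- observations
  if (count == "per_experiment") {
    if (!"run_id" %in% names(obs)) {
      stop("per_experiment counting needs a run_id column")
    }
    obs <- dplyr::distinct(obs, .data$sequence, .data$run_id,
                           .data$category)
  }
  cls <- residue_classes()
  aa <- names(mass_constants()$residues)
  cats <- unique(stats::na.omit(obs$category))
  counts <- obs |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::inner_join(
      sites |> dplyr::select("sequence", "p1"),
      by = "sequence", relationship = "many-to-many"
    ) |>
    dplyr::count(.data$category, .data$p1, name = "n")
  full <- tidyr::crossing(
    category = if (length(cats)) cats else character(0),
    residue = aa
  )
  out <- full |>
    dplyr::left_join(counts, by = c("category", "residue" = "p1")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::group_by(.data$category) |>
    dplyr::mutate(prop = .data$n / max(sum(.data$n), 1L)) |>
    dplyr::ungroup() |>
    dplyr::mutate(residue_class = dplyr::case_when(
      .data$residue %in% cls$hydrophobic ~ "hydrophobic",
      .data$residue %in% cls$basic ~ "basic",
      .data$residue %in% cls$acidic ~ "acidic",
      TRUE ~ "other"
    ))
  attr(out, "counting") <- count
  out
}

#' Cleavage-site analysis of a quantified study
#'
#' Builds per-replicate observations from a `tmab_quant` object (each merged
#' replicate value of each identified peptide is one observation, carrying
#' the peptide's per-condition fold-change category), locates peptides,
#' enumerates cleavage sites and tabulates P1 frequencies. Ambiguously
#' located peptides are excluded from the tables. Data from all
#' non-reference conditions can be pooled (as when heterozygous and
#' homozygous polyQ lines are analysed together) or kept per condition.
#'
#' @param quant A `tmab_quant` object.
#' @param proteome Tibble with `protein_id`, `sequence`.
#' @param pool_conditions Pool non-reference conditions into one table?
#' @param count Counting mode, see [p1_frequency_table()].
#' @return List with `spans`, `sites`, `observations` and `freq` (the
#'   frequency table, or a tibble with a `condition` column when not
#'   pooled).
#' @export
analyze_cleavage <- function(quant, proteome, pool_conditions = TRUE,
                             count = c("per_replicate", "per_experiment")) {
  count <- match.arg(count)
  stopifnot(inherits(quant, "tmab_quant"))
  ids <- quant$merged |>
    dplyr::distinct(.data$sequence, .data$n_term_acetylated,
                    .data$protein_id)
  spans <- locate_peptide(ids, proteome, on_missing = "drop")
  spans_ok <- dplyr::filter(spans, !.data$ambiguous)
  sites <- cleavage_sites(spans_ok, proteome)
  cats <- quant$summary |>
    dplyr::filter(.data$condition != quant$reference) |>
    dplyr::select("sequence", "condition", "category")
  observations <- quant$merged |>
    dplyr::filter(.data$condition != quant$reference,
                  .data$sequence %in% spans_ok$sequence) |>
    dplyr::inner_join(cats, by = c("sequence", "condition"))
  if (pool_conditions) {
    freq <- p1_frequency_table(observations, sites, count)
  } else {
    freq <- observations |>
      dplyr::group_by(.data$condition) |>
      dplyr::group_modify(~p1_frequency_table(.x, sites, count)) |>
      dplyr::ungroup()
  }
  list(spans = spans, sites = sites, observations = observations,
       freq = freq)
}
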