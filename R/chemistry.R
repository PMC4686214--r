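# Shared mass arithmetic for TMAB multiplex labeling: tag isotopologue
# definitions, label counting on peptides, and theoretical m/z of labeled,
# protonated species. Both the spectrum simulator and the peak-group
# detector go through these functions, so their conventions agree by
# construction.

#' Monoisotopic mass constants
#'
#' Returns the constants used throughout the package: standard residue
#' monoisotopic masses, water, acetyl, proton, the heavy-isotope mass
#' differences, and the mass added per TMAB tag.
#'
#' The TMAB tag acylates a free amine: the net addition per label is the
#' trimethylammonium-butyryl cation C7H14NO+ (the amine hydrogen is retained
#' on the amide nitrogen), 128.1070 Da after subtracting the electron carried
#' away by the fixed positive charge. `tag_base_mass` is configurable because
#' run-relative ratio quantification never depends on its exact value; it only
#' places peak groups on the m/z axis.
#'
#' @param tag_base_mass Mass in Da added per D0 tag (default 128.1070).
#' @return A named list of constants. `residues` is a named numeric vector
#'   over the 20 standard amino acids.
#' @export
#' @examples
#' mass_constants()$residues[["K"]]
mass_constants <- function(tag_base_mass = 128.1070) {
  list(
    proton = 1.007276467,
    electron = 0.000548580,
    d_minus_h = 1.006276746,   # m(2H) - m(1H)
    c13_minus_c12 = 1.003354835,
    water = 18.010564684,
    acetyl = 42.010564684,
    tag_base_mass = tag_base_mass,
    residues = c(
      G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
      V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
      I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
      K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
      F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
    )
  )
}

#' TMAB isotopologue tag table
#'
#' The five isotopic forms of the TMAB label: D0, D3, D6 and D9 carry 0, 3, 6
#' and 9 deuterium atoms; D12 carries 9 deuteriums plus three 13C atoms. The
#' D9 to D12 step is therefore three 13C-12C differences (3.0101 Da), about
#' 9 mDa less than the 3 x (2H-1H) steps between the lighter tags - resolvable
#' at high resolution and honoured by all spacing arithmetic here.
#'
#' @param constants Output of [mass_constants()].
#' @return A tibble with columns `tag`, `deuterium`, `c13`, `mass_shift`
#'   (Da relative to D0), ordered D0 < D3 < D6 < D9 < D12.
#' @export
tmab_tags <- function(constants = mass_constants()) {
  tibble::tibble(
    tag = c("D0", "D3", "D6", "D9", "D12"),
    deuterium = c(0L, 3L, 6L, 9L, 9L),
    c13 = c(0L, 0L, 0L, 0L, 3L)
  ) |>
    dplyr::mutate(
      mass_shift = .data$deuterium * constants$d_minus_h +
        .data$c13 * constants$c13_minus_c12
    )
}

#' Mass shift of a TMAB tag relative to D0
#'
#' @param tag Character vector of tag names (`"D0"`, `"D3"`, `"D6"`, `"D9"`,
#'   `"D12"`).
#' @param constants Output of [mass_constants()].
#' @return Numeric vector of shifts in Da.
#' @export
#' @examples
#' tag_mass_shift(c("D0", "D3", "D12"))
tag_mass_shift <- function(tag, constants = mass_constants()) {
  tags <- tmab_tags(constants)
  idx <- match(tag, tags$tag)
  if (anyNA(idx)) {
    stop("unknown TMAB tag: ", paste(unique(tag[is.na(idx)]), collapse = ", "))
  }
  tags$mass_shift[idx]
}

assert_sequence <- function(sequence) {
  ok <- nzchar(sequence) &
    grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", sequence)
  if (!all(ok)) {
    stop(
      "peptide sequences must be non-empty strings over the 20 standard ",
      "residues; offending: ",
      paste(utils::head(sequence[!ok], 3), collapse = ", ")
    )
  }
  invisible(sequence)
}

#' Number of TMAB labels on a peptide
#'
#' TMAB-NHS acylates primary amines. After hydroxylamine treatment removes
#' tyrosine O-acylation, only the peptide N-terminal amine (absent when the
#' N-terminus is acetylated) and lysine side-chain amines carry labels.
#'
#' @param sequence Character vector of peptide sequences (uppercase,
#'   20 standard residues).
#' @param n_term_acetylated Logical vector (recycled): is the N-terminus
#'   acetylated?
#' @return Integer vector of label counts.
#' @export
#' @examples
#' count_tmab_labels("DLTIKLPDGHEF")                       # 2
#' count_tmab_labels("MDTSRVQPIKL", n_term_acetylated = TRUE)  # 1
count_tmab_labels <- function(sequence, n_term_acetylated = FALSE) {
  assert_sequence(sequence)
  n_term_acetylated <- rep_len(as.logical(n_term_acetylated), length(sequence))
  as.integer(!n_term_acetylated) +
    stringr::str_count(sequence, stringr::fixed("K"))
}

#' Neutral monoisotopic peptide mass
#'
#' Residue masses plus water, plus the acetyl group when the N-terminus is
#' acetylated, plus any additional modification mass (e.g. +15.9949 per Met
#' oxidation, or a cyanylation delta on Cys). Modifications are passed as a
#' total delta because label counting and peak-group arithmetic are invariant
#' to where on the peptide they sit.
#'
#' @inheritParams count_tmab_labels
#' @param mod_mass Numeric vector (recycled) of summed modification deltas
#'   in Da.
#' @param constants Output of [mass_constants()].
#' @return Numeric vector of neutral monoisotopic masses in Da.
#' @export
peptide_mass <- function(sequence, n_term_acetylated = FALSE, mod_mass = 0,
                         constants = mass_constants()) {
  assert_sequence(sequence)
  n <- length(sequence)
  n_term_acetylated <- rep_len(as.logical(n_term_acetylated), n)
  mod_mass <- rep_len(as.numeric(mod_mass), n)
  res_sum <- vapply(
    strsplit(sequence, "", fixed = TRUE),
    function(a) sum(constants$residues[a]),
    numeric(1)
  )
  res_sum + constants$water + ifelse(n_term_acetylated, constants$acetyl, 0) +
    mod_mass
}

#' m/z spacing between two tag channels of one peak group
#'
#' A peptide carrying `n_labels` tags observed at charge `z` appears in
#' channel `tag_b` at `n_labels * (shift_b - shift_a) / z` Th above its
#' position in channel `tag_a`. The function is antisymmetric in the two
#' tags and uses each tag pair's exact isotopic shift (so D9 to D12 is
#' 3.0101 Da per label, not 3.0188).
#'
#' @param n_labels Integer, number of TMAB labels (>= 1).
#' @param tag_a,tag_b Tag names.
#' @param z Charge state (>= 1).
#' @param constants Output of [mass_constants()].
#' @return Numeric spacing in Th (m/z units); positive when `tag_b` is
#'   heavier than `tag_a`.
#' @export
#' @examples
#' peakgroup_spacing(2, "D0", "D3", z = 2)
#' peakgroup_spacing(1, "D9", "D12", z = 1)
peakgroup_spacing <- function(n_labels, tag_a, tag_b, z = 1,
                              constants = mass_constants()) {
  stopifnot(all(n_labels >= 1), all(z >= 1))
  n_labels * (tag_mass_shift(tag_b, constants) -
                tag_mass_shift(tag_a, constants)) / z
}

#' Theoretical m/z of a TMAB-labeled peptide
#'
#' Fixed-charge convention: every TMAB tag carries one permanent positive
#' charge, and remaining charges are protons, so the observed charge must be
#' at least the label count. An acetylated, lysine-free peptide carries no
#' tag and is not observable as a labeled species (label count 0 is an
#' error).
#'
#' @inheritParams peptide_mass
#' @param tag Tag name (recycled).
#' @param z Charge state, `z >= count_tmab_labels(sequence)` and `z >= 1`.
#' @return Numeric vector of m/z values.
#' @export
#' @examples
#' theoretical_mz("GG", "D0", z = 1)   # 260.1605
theoretical_mz <- function(sequence, tag, z, n_term_acetylated = FALSE,
                           mod_mass = 0, constants = mass_constants()) {
  n_labels <- count_tmab_labels(sequence, n_term_acetylated)
  if (any(n_labels < 1)) {
    stop("peptide carries no TMAB label (acetylated N-terminus, no Lys): ",
         "not observable as a labeled species")
  }
  if (any(z < n_labels)) {
    stop("charge deficit: z must be >= the number of TMAB labels ",
         "(each tag carries one fixed charge)")
  }
  m <- peptide_mass(sequence, n_term_acetylated, mod_mass, constants)
  (m + n_labels * (constants$tag_base_mass + tag_mass_shift(tag, constants)) +
      (z - n_labels) * constants$proton) / z
}
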