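# Synthetic proteome and proteasome degradome generator. The degradome
# model makes the proteasome's cleavage-site preference an explicit
# parameter: flanking P1 residues of simulated peptides are drawn from a
# user-controlled weight vector, so downstream frequency analysis can be
# validated against a known generating distribution.

#' Default P1 cleavage-preference weights
#'
#' Hydrophobic-biased preference emulating chymotrypsin-like proteasome
#' output: Leu alone carries 0.30, the hydrophobic class \{L, I, M, V, F, Y,
#' W\} carries 0.65 in total, basic (K, R) 0.04, acidic (D, E) 0.02, and the
#' remaining mass is spread over the other residues.
#'
#' @return Named numeric vector over the 20 residues, summing to 1.
#' @export
default_p1_weights <- function() {
  w <- c(
    L = 0.30, I = 0.08, M = 0.05, V = 0.08, F = 0.06, Y = 0.04, W = 0.04,
    K = 0.02, R = 0.02, D = 0.01, E = 0.01
  )
  rest <- setdiff(names(mass_constants()$residues), names(w))
  w <- c(w, stats::setNames(rep((1 - sum(w)) / length(rest), length(rest)),
                            rest))
  w[names(mass_constants()$residues)]
}

#' Residue classes used in cleavage-site reporting
#'
#' @return Named list with `hydrophobic` (L, I, M, V, F, Y, W), `basic`
#'   (K, R) and `acidic` (D, E) character vectors.
#' @export
residue_classes <- function() {
  list(
    hydrophobic = c("L", "I", "M", "V", "F", "Y", "W"),
    basic = c("K", "R"),
    acidic = c("D", "E")
  )
}

#' Simulate a random proteome
#'
#' Sequences are drawn i.i.d. from `aa_freqs`; the default is uniform over
#' the 20 residues, which keeps the marginal P1 distribution of the
#' degradome generator equal to its weight vector (see
#' [simulate_degradome()]).
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param length_range Integer vector `c(min, max)` protein length, sampled
#'   uniformly.
#' @param aa_freqs Named numeric vector of residue frequencies (normalised
#'   internally); default uniform.
#' @param seed Integer seed; identical seeds give identical proteomes.
#' @return Tibble with columns `protein_id`, `sequence`, `length`.
#' @export
simulate_proteome <- function(n_proteins = 30, length_range = c(200, 400),
                              aa_freqs = NULL, seed = 1) {
  if (n_proteins < 1) stop("n_proteins must be >= 1")
  aa <- names(mass_constants()$residues)
  if (is.null(aa_freqs)) {
    aa_freqs <- stats::setNames(rep(1 / 20, 20), aa)
  }
  if (is.null(names(aa_freqs)) || !all(names(aa_freqs) %in% aa) ||
      any(aa_freqs < 0) || sum(aa_freqs) <= 0) {
    stop("aa_freqs must be a non-negative named vector over standard residues")
  }
  freqs <- rep(0, 20); names(freqs) <- aa
  freqs[names(aa_freqs)] <- aa_freqs
  freqs <- freqs / sum(freqs)
  set.seed(seed)
  lens <- length_range[1] +
    sample.int(length_range[2] - length_range[1] + 1L, n_proteins,
               replace = TRUE) - 1L
  seqs <- vapply(
    lens,
    function(L) paste(sample(aa, L, replace = TRUE, prob = freqs),
                      collapse = ""),
    character(1)
  )
  tibble::tibble(
    protein_id = sprintf("SYNP%04d", seq_len(n_proteins)),
    sequence = seqs,
    length = lens
  )
}

#' Degradome model parameters
#'
#' @param p1_weights Named residue weights for the P1 position of simulated
#'   cleavages (normalised internally).
#' @param length_range Peptide length range in residues, `min >= 2`.
#' @param peptides_per_protein Mean number of peptide draws per protein
#'   (Poisson over the whole proteome; distinct spans after deduplication
#'   are somewhat fewer, with draw multiplicity kept in `copies`).
#' @param terminal_fraction Probability that a draw attempts a protein N-
#'   or C-terminal fragment (one cleavage) rather than an internal peptide
#'   (two); the realised share is close to this value.
#' @param acetylated_nterm_prob Probability that a protein-N-terminal
#'   fragment retains co-translational N-terminal acetylation.
#' @return A list of validated model parameters.
#' @export
degradome_model <- function(p1_weights = default_p1_weights(),
                            length_range = c(6, 30),
                            peptides_per_protein = 9,
                            terminal_fraction = 0.25,
                            acetylated_nterm_prob = 0.5) {
  aa <- names(mass_constants()$residues)
  if (is.null(names(p1_weights)) || !all(names(p1_weights) %in% aa) ||
      any(p1_weights < 0) || sum(p1_weights) <= 0) {
    stop("p1_weights must be a non-negative named vector over standard residues")
  }
  w <- rep(0, 20); names(w) <- aa
  w[names(p1_weights)] <- p1_weights
  w <- w / sum(w)
  if (length_range[1] < 2) stop("minimum peptide length must be >= 2")
  list(
    p1_weights = w,
    length_range = as.integer(length_range),
    peptides_per_protein = peptides_per_protein,
    terminal_fraction = terminal_fraction,
    acetylated_nterm_prob = acetylated_nterm_prob
  )
}

# Draw one peptide span from the proteome; returns c(protein index,
# start, end) or NULL when the draw is thinned away. All flank residues
# are sampled so that their marginal distribution over the whole proteome
# equals p1_weights exactly: internal left bonds target the global bond
# pool (protein chosen proportional to its total bond weight, then bond
# proportional to the weight of its P1 residue), and every other flank
# uses a single absolute-probability acceptance w[P1]/max(w). Retrying
# inside one protein's fixed terminal window would renormalise the
# weights over whatever residues that window contains and bias the
# marginal toward common residues, so failed draws redraw everything,
# protein included.
draw_span <- function(chars, Lps, bond_w, protein_w, model,
                      max_tries = 60) {
  w <- model$p1_weights
  wmax <- max(w)
  lmin <- model$length_range[1]; lmax <- model$length_range[2]
  n_prot <- length(Lps)
  for (try in seq_len(max_tries)) {
    u <- stats::runif(1)
    if (u < model$terminal_fraction / 2) {
      # protein N-terminal fragment
      p <- sample.int(n_prot, 1)
      sc <- chars[[p]]
      start <- if (sc[1] == "M" && stats::runif(1) < 0.5) 2L else 1L
      len <- lmin + sample.int(lmax - lmin + 1L, 1) - 1L
      end <- start + len - 1L
      if (end <= Lps[p] - 1L &&
          stats::runif(1) < w[sc[end]] / wmax) {
        return(c(p, start, end))
      }
    } else if (u < model$terminal_fraction) {
      # protein C-terminal fragment
      p <- sample.int(n_prot, 1)
      sc <- chars[[p]]
      lo <- max(3L, Lps[p] - lmax + 1L); hi <- Lps[p] - lmin + 1L
      if (lo > hi) next
      start <- lo + sample.int(hi - lo + 1L, 1) - 1L
      if (stats::runif(1) < w[sc[start - 1L]] / wmax) {
        return(c(p, start, Lps[p]))
      }
    } else {
      p <- sample.int(n_prot, 1, prob = protein_w)
      sc <- chars[[p]]
      i <- sample.int(Lps[p] - 1L, 1, prob = bond_w[[p]])
      start <- i + 1L
      len <- lmin + sample.int(lmax - lmin + 1L, 1) - 1L
      end <- start + len - 1L
      if (start >= 3L && end <= Lps[p] - 1L &&
          stats::runif(1) < w[sc[end]] / wmax) {
        return(c(p, start, end))
      }
    }
  }
  NULL
}

#' Simulate a proteasome degradome
#'
#' Samples peptides from each protein under the cleavage-preference model.
#' Every peptide is an exact substring of its source protein; internal
#' peptides have both flanking P1 residues drawn from `p1_weights`, terminal
#' fragments have one. Protein-N-terminal fragments may retain N-terminal
#' acetylation (such termini are not proteasome cleavage products).
#' Duplicate spans are dropped.
#'
#' @param proteome Tibble from [simulate_proteome()] (columns `protein_id`,
#'   `sequence`).
#' @param model Output of [degradome_model()].
#' @param seed Integer seed.
#' @return Tibble of peptides: `peptide_id`, `protein_id`, `sequence`,
#'   `start`, `end` (1-based inclusive), `copies` (how many times the
#'   span was drawn), `n_term_acetylated`, `terminal`
#'   (`n_terminal`/`c_terminal`/`internal`/`full_length`), `n_labels`.
#' @export
simulate_degradome <- function(proteome, model = degradome_model(), seed = 1) {
  if (nrow(proteome) == 0) stop("proteome must be non-empty")
  set.seed(seed)
  lmin <- model$length_range[1]
  usable <- nchar(proteome$sequence) >= lmin + 4L
  if (any(!usable)) {
    warning(sum(!usable), " protein(s) too short for the peptide length ",
            "range; skipped")
  }
  pp <- proteome[usable, ]
  if (nrow(pp) == 0) stop("no protein long enough for the length range")
  chars <- strsplit(pp$sequence, "", fixed = TRUE)
  Lps <- nchar(pp$sequence)
  w <- model$p1_weights
  bond_w <- lapply(chars, function(sc) w[sc[-length(sc)]])
  protein_w <- vapply(bond_w, sum, numeric(1))
  n_attempts <- stats::rpois(1, nrow(pp) * model$peptides_per_protein)
  spans <- purrr::compact(purrr::map(
    seq_len(max(1L, n_attempts)),
    ~draw_span(chars, Lps, bond_w, protein_w, model)
  ))
  if (length(spans) == 0) stop("no peptide could be sampled")
  d <- tibble::tibble(
    p = vapply(spans, `[`, numeric(1), 1),
    start = as.integer(vapply(spans, `[`, numeric(1), 2)),
    end = as.integer(vapply(spans, `[`, numeric(1), 3))
  ) |>
    dplyr::count(.data$p, .data$start, .data$end, name = "copies")
  pep <- tibble::tibble(
    protein_id = pp$protein_id[d$p],
    start = d$start,
    end = d$end,
    copies = d$copies,
    sequence = substr(pp$sequence[d$p], d$start, d$end),
    n_term_acetylated = d$start <= 2L &
      stats::runif(nrow(d)) < model$acetylated_nterm_prob,
    terminal = dplyr::case_when(
      start <= 2L & end == Lps[d$p] ~ "full_length",
      start <= 2L ~ "n_terminal",
      end == Lps[d$p] ~ "c_terminal",
      TRUE ~ "internal"
    )
  )
  # one rendered species per distinct peptide form; a span drawn several
  # times keeps its draw multiplicity in `copies` so that site-frequency
  # analyses can weight by it (the generator samples with replacement)
  pep <- pep |>
    dplyr::group_by(.data$sequence, .data$n_term_acetylated) |>
    dplyr::mutate(copies = sum(.data$copies)) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$protein_id, .data$start, .data$end)
  pep$peptide_id <- sprintf("PEP%05d", seq_len(nrow(pep)))
  pep$n_labels <- count_tmab_labels(pep$sequence, pep$n_term_acetylated)
  dplyr::relocate(pep, "peptide_id")
}
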