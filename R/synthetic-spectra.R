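# Condition effects, labeling schemes, and rendering of multiplex MS1
# centroid peak lists with ground truth.

#' Condition effect design
#'
#' Describes the study arms applied to the synthetic degradome. Effects are
#' multiplicative on peptide abundance and apply to proteasome-product
#' peptides only; a configurable fraction of peptides is exempt (emulating
#' peptides, like thymosin beta-10, whose production does not require the
#' proteasome).
#'
#' @param effects Named numeric vector: condition -> abundance ratio relative
#'   to the reference. Default models two polyQ-expanded lines at 0.35 of
#'   reference levels.
#' @param reference Name of the reference condition; its effect must be 1.
#' @param non_product_fraction Fraction of peptides exempt from effects.
#' @param cv Lognormal sigma of between-replicate biological/technical noise.
#' @return Validated design list.
#' @export
effect_design <- function(effects = c(Q7Q7 = 1.0, Q7Q111 = 0.35,
                                      Q111Q111 = 0.35),
                          reference = "Q7Q7",
                          non_product_fraction = 0.10,
                          cv = 0.15) {
  if (!reference %in% names(effects)) stop("reference must be a condition")
  if (effects[[reference]] != 1.0) {
    stop("the reference condition must have effect ratio 1.0")
  }
  if (cv < 0) stop("cv must be >= 0")
  if (non_product_fraction < 0 || non_product_fraction > 1) {
    stop("non_product_fraction must be in [0, 1]")
  }
  list(effects = effects, reference = reference,
       non_product_fraction = non_product_fraction, cv = cv)
}

#' Default 4-run labeling scheme
#'
#' Four LC-MS runs with 4-5 tag channels each, rotating the tag/condition
#' assignment between runs so that no condition is tied to one isotopologue.
#' The totals are 6 reference (Q7Q7) replicates, 5 Q7Q111 and 6 Q111Q111;
#' runs 1-2 carry two reference channels, runs 3-4 a single one.
#'
#' @param conditions Character vector of three condition names in the order
#'   (reference, heterozygous-like, homozygous-like).
#' @return Tibble with columns `run_id`, `tag`, `condition`, `replicate`
#'   (condition-scoped replicate label).
#' @export
default_labeling_scheme <- function(conditions = c("Q7Q7", "Q7Q111",
                                                   "Q111Q111")) {
  stopifnot(length(conditions) == 3)
  ref <- conditions[1]; het <- conditions[2]; hom <- conditions[3]
  scheme <- tibble::tribble(
    ~run_id, ~tag,  ~condition, ~replicate,
    "run1",  "D0",  ref, "r1",
    "run1",  "D3",  ref, "r2",
    "run1",  "D9",  het, "r1",
    "run1",  "D6",  hom, "r1",
    "run1",  "D12", hom, "r2",
    "run2",  "D3",  ref, "r3",
    "run2",  "D6",  ref, "r4",
    "run2",  "D0",  het, "r2",
    "run2",  "D9",  hom, "r3",
    "run3",  "D6",  ref, "r5",
    "run3",  "D9",  het, "r3",
    "run3",  "D0",  hom, "r4",
    "run3",  "D3",  hom, "r5",
    "run4",  "D6",  ref, "r6",
    "run4",  "D12", het, "r4",
    "run4",  "D3",  het, "r5",
    "run4",  "D9",  hom, "r6"
  )
  validate_scheme(scheme)
  scheme
}

validate_scheme <- function(scheme, reference = NULL) {
  needed <- c("run_id", "tag", "condition", "replicate")
  if (!all(needed %in% names(scheme))) {
    stop("scheme needs columns ", paste(needed, collapse = ", "))
  }
  dup <- scheme |>
    dplyr::count(.data$run_id, .data$tag) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate tag assignment within a run: ",
         paste(dup$run_id, dup$tag, collapse = "; "))
  }
  if (!is.null(reference)) {
    missing_ref <- setdiff(unique(scheme$run_id),
                           unique(scheme$run_id[scheme$condition == reference]))
    if (length(missing_ref) > 0) {
      stop("runs without a reference channel: ",
           paste(missing_ref, collapse = ", "))
    }
  }
  invisible(scheme)
}

#' Spectrum rendering parameters
#'
#' @param mz_jitter_ppm Gaussian m/z error, ppm.
#' @param rt_jitter_min Gaussian per-channel retention-time error, minutes
#'   (models small deuterium RT shifts and alignment error).
#' @param envelope_rate_per_kda Mean heavy-isotope count per 1000 Da of
#'   peptide mass; isotopomer intensities follow a Poisson envelope (an
#'   averagine-like scalar, enough to exercise deisotoping and the
#'   most-intense-peak rule).
#' @param lod Intensity limit of detection; channels whose strongest
#'   isotopomer falls below it are omitted and flagged missing.
#' @param n_noise_peaks Uniform random noise peaks added per run, with
#'   intensities up to `lod` (encoding the ~5:1 signal-to-noise floor that
#'   motivates the 0.20 ratio cap).
#' @param overlap_rate Per channel-observation probability of injecting a
#'   co-eluting interfering cluster 0.01 Th away.
#' @param extra_charge_prob Probability a peptide is also rendered at one
#'   charge above its base charge state.
#' @param mz_range,rt_range Acquisition windows (Th, minutes).
#' @return Validated parameter list.
#' @export
spectrum_params <- function(mz_jitter_ppm = 2, rt_jitter_min = 0.02,
                            envelope_rate_per_kda = 0.6, lod = 50,
                            n_noise_peaks = 300, overlap_rate = 0.02,
                            extra_charge_prob = 0.3,
                            mz_range = c(300, 1600), rt_range = c(5, 40)) {
  p <- list(mz_jitter_ppm = mz_jitter_ppm, rt_jitter_min = rt_jitter_min,
            envelope_rate_per_kda = envelope_rate_per_kda, lod = lod,
            n_noise_peaks = n_noise_peaks, overlap_rate = overlap_rate,
            extra_charge_prob = extra_charge_prob, mz_range = mz_range,
            rt_range = rt_range)
  if (any(unlist(p[1:7]) < 0)) stop("spectrum parameters must be >= 0")
  p
}

#' Simulate per-channel peptide abundances
#'
#' One abundance per (peptide, scheme channel): a lognormal per-peptide base
#' level times the condition effect (for non-exempt peptides) times
#' lognormal replicate noise `exp(N(0, cv))`. Peptides without any TMAB
#' label (acetylated, no Lys) are retained here but are unobservable
#' downstream.
#'
#' @param peptides Tibble from [simulate_degradome()].
#' @param scheme Labeling scheme tibble (see [default_labeling_scheme()]).
#' @param design Output of [effect_design()].
#' @param base_meanlog,base_sdlog Lognormal parameters of per-peptide base
#'   intensity (defaults give a median of 1e4 with a wide dynamic range, so
#'   low-abundance peptides fall below the detection limit in suppressed
#'   conditions).
#' @param seed Integer seed.
#' @return Tibble: one row per peptide x channel with `abundance`, the
#'   peptide's `base` level, `exempt` flag and `true_ratio` (the condition
#'   effect applied, 1 for exempt peptides).
#' @export
simulate_abundances <- function(peptides, scheme, design = effect_design(),
                                base_meanlog = log(1e4), base_sdlog = 0.8,
                                seed = 1) {
  validate_scheme(scheme, design$reference)
  missing_cond <- setdiff(unique(scheme$condition), names(design$effects))
  if (length(missing_cond) > 0) {
    stop("scheme conditions without an effect: ",
         paste(missing_cond, collapse = ", "))
  }
  set.seed(seed)
  n <- nrow(peptides)
  base <- stats::rlnorm(n, base_meanlog, base_sdlog)
  exempt <- stats::runif(n) < design$non_product_fraction
  per_pep <- tibble::tibble(
    peptide_id = peptides$peptide_id,
    base = base,
    exempt = exempt
  )
  out <- tidyr::crossing(per_pep, scheme) |>
    dplyr::mutate(
      effect = unname(design$effects[.data$condition]),
      true_ratio = ifelse(.data$exempt, 1, .data$effect),
      abundance = .data$base * .data$true_ratio *
        stats::rlnorm(dplyr::n(), 0, design$cv)
    )
  dplyr::select(out, "peptide_id", "run_id", "tag", "condition", "replicate",
                "base", "exempt", "true_ratio", "abundance")
}

# Poisson isotope envelope, relative to the strongest isotopomer;
# isotopomers are rendered until they drop below `cutoff` of the apex.
envelope_weights <- function(neutral_mass, rate_per_kda, cutoff = 0.01) {
  lambda <- rate_per_kda * neutral_mass / 1000
  k_max <- max(1L, ceiling(lambda + 6 * sqrt(lambda) + 3))
  w <- stats::dpois(0:k_max, lambda)
  w <- w / max(w)
  w[seq_len(max(which(w >= cutoff)))]
}

#' Render multiplex MS1 centroid peak lists
#'
#' For every peptide, charge state, and tag channel with abundance at or
#' above the detection limit, an isotope cluster is placed at the
#' theoretical m/z (plus ppm jitter), with the strongest isotopomer's
#' intensity equal to the channel abundance. Charge states are the smallest
#' `z >= n_labels` that puts the species inside the m/z window, plus
#' optionally `z + 1`. Uniform noise peaks and co-eluting interferents are
#' added per `params`.
#'
#' @param abundances Tibble from [simulate_abundances()].
#' @param peptides Tibble from [simulate_degradome()].
#' @param params Output of [spectrum_params()].
#' @param constants Output of [mass_constants()].
#' @param seed Integer seed.
#' @return List with `peaks` (tibble `run_id`, `rt_min`, `mz`, `intensity`,
#'   sorted by run, rt, mz) and `truth`, one row per rendered or
#'   below-limit channel observation: `peptide_id`, `run_id`, `tag`, `z`,
#'   `n_labels`, `mono_mz`, `rt_min`, `intensity`, `missing`,
#'   `overlap_injected`.
#' @export
render_runs <- function(abundances, peptides, params = spectrum_params(),
                        constants = mass_constants(), seed = 1) {
  set.seed(seed)
  pep <- peptides |>
    dplyr::filter(.data$n_labels >= 1) |>
    dplyr::mutate(
      neutral_mass = peptide_mass(.data$sequence, .data$n_term_acetylated,
                                  constants = constants)
    )
  # one retention time and charge-state set per peptide, shared across runs
  pep$rt_base <- stats::runif(nrow(pep), params$rt_range[1],
                              params$rt_range[2])
  base_z <- function(mass, n_labels) {
    z <- max(1L, n_labels)
    mz <- (mass + n_labels * constants$tag_base_mass +
             (z - n_labels) * constants$proton) / z
    while (mz > params$mz_range[2] && z < n_labels + 6L) {
      z <- z + 1L
      mz <- (mass + n_labels * constants$tag_base_mass +
               (z - n_labels) * constants$proton) / z
    }
    z
  }
  pep$z1 <- mapply(base_z, pep$neutral_mass, pep$n_labels)
  pep$two_z <- stats::runif(nrow(pep)) < params$extra_charge_prob

  obs <- abundances |>
    dplyr::inner_join(
      pep[c("peptide_id", "sequence", "n_term_acetylated", "n_labels",
            "neutral_mass", "rt_base", "z1", "two_z")],
      by = "peptide_id"
    )
  obs <- dplyr::bind_rows(
    dplyr::mutate(obs, z = .data$z1),
    dplyr::mutate(dplyr::filter(obs, .data$two_z), z = .data$z1 + 1L)
  )
  obs$mono_mz <- theoretical_mz(obs$sequence, obs$tag, obs$z,
                                obs$n_term_acetylated, constants = constants)
  obs$missing <- obs$abundance < params$lod
  # Channels whose isotopomer ladders coincide cannot be independently
  # quantified by any detector. The D12 tag differs from D9 by three 13C
  # atoms, so for n labels the two channels sit exactly 3n isotopomer
  # steps apart: whenever the lighter channel's rendered envelope reaches
  # that far, the two envelopes collapse onto shared positions and both
  # channels are marked coincident in the ground truth.
  iso <- constants$c13_minus_c12
  obs$n_iso <- vapply(
    obs$neutral_mass,
    function(m) length(envelope_weights(m, params$envelope_rate_per_kda)),
    integer(1)
  )
  obs <- obs |>
    dplyr::group_by(.data$peptide_id, .data$run_id, .data$z) |>
    dplyr::mutate(
      coincident = vapply(seq_along(.data$mono_mz), function(i) {
        if (.data$missing[i]) return(FALSE)
        d <- abs(.data$mono_mz[-i] - .data$mono_mz[i])
        steps <- round(d / (iso / .data$z[i]))
        resid <- abs(d - steps * iso / .data$z[i])
        any(!.data$missing[-i] & resid < 1e-3 &
              steps < .data$n_iso[i])
      }, logical(1))
    ) |>
    dplyr::ungroup()
  obs$rt_min <- obs$rt_base +
    stats::rnorm(nrow(obs), 0, params$rt_jitter_min)
  # Co-eluting signal close in m/z is recorded as interference - such
  # channels may not be accurately quantifiable, mirroring the
  # peak-overlap exclusions of real analyses. Two regimes: a different
  # species (another peptide, or the same peptide at another charge)
  # within the overlap window of a channel's envelope; or a sibling
  # channel of the same peak group whose interleaved ladder comes within
  # instrument-resolution distance (one-label peptides at high charge
  # interleave at n x 8.77/z mDa).
  obs$interfered <- FALSE
  for (r in unique(obs$run_id)) {
    sel <- which(obs$run_id == r & !obs$missing)
    if (length(sel) < 2) next
    lo <- obs$mono_mz[sel]
    hi <- lo + (obs$n_iso[sel] - 1) * iso / obs$z[sel]
    rt0 <- obs$rt_min[sel]
    key <- paste(obs$peptide_id[sel], obs$z[sel])
    for (a in seq_along(sel)) {
      thr <- ifelse(key == key[a], 0.005, 0.025)
      close <- abs(rt0 - rt0[a]) <= 0.25 & seq_along(sel) != a &
        lo <= hi[a] + thr & hi >= lo[a] - thr
      if (!any(close)) next
      pk_a <- lo[a] + (seq_len(obs$n_iso[sel[a]]) - 1) * iso / obs$z[sel[a]]
      hit <- FALSE
      for (b in which(close)) {
        pk_b <- lo[b] + (seq_len(obs$n_iso[sel[b]]) - 1) * iso / obs$z[sel[b]]
        if (min(abs(outer(pk_a, pk_b, "-"))) <= thr[b]) { hit <- TRUE; break }
      }
      obs$interfered[sel[a]] <- hit
    }
  }
  obs$overlap_injected <- !obs$missing &
    stats::runif(nrow(obs)) < params$overlap_rate

  spacing <- constants$c13_minus_c12
  render_one <- function(mono_mz, z, neutral_mass, abundance, rt_min) {
    w <- envelope_weights(neutral_mass, params$envelope_rate_per_kda)
    k <- seq_along(w) - 1L
    mz <- mono_mz + k * spacing / z
    tibble::tibble(mz = mz, intensity = abundance * w, rt_min = rt_min)
  }
  present <- obs[!obs$missing, ]
  signal <- purrr::pmap(
    present[c("mono_mz", "z", "neutral_mass", "abundance", "rt_min")],
    render_one
  )
  signal <- dplyr::bind_rows(signal, .id = "i")
  signal$run_id <- present$run_id[as.integer(signal$i)]
  signal$i <- NULL

  # co-eluting interferents: a two-peak cluster 0.01 Th off the channel mono
  ovl <- present[present$overlap_injected, ]
  if (nrow(ovl) > 0) {
    amp <- ovl$abundance * stats::runif(nrow(ovl), 0.5, 2)
    interf <- tibble::tibble(
      run_id = rep(ovl$run_id, each = 2),
      rt_min = rep(ovl$rt_min, each = 2),
      mz = as.vector(rbind(ovl$mono_mz + 0.01,
                           ovl$mono_mz + 0.01 + spacing / ovl$z)),
      intensity = as.vector(rbind(amp, amp * 0.6))
    )
    signal <- dplyr::bind_rows(signal, interf)
  }

  runs <- unique(abundances$run_id)
  noise <- tibble::tibble(
    run_id = rep(runs, each = params$n_noise_peaks),
    rt_min = stats::runif(length(runs) * params$n_noise_peaks,
                          params$rt_range[1], params$rt_range[2]),
    mz = stats::runif(length(runs) * params$n_noise_peaks,
                      params$mz_range[1], params$mz_range[2]),
    intensity = stats::runif(length(runs) * params$n_noise_peaks,
                             0, params$lod)
  )
  peaks <- dplyr::bind_rows(signal, noise)
  if (params$mz_jitter_ppm > 0) {
    peaks$mz <- peaks$mz *
      (1 + stats::rnorm(nrow(peaks), 0, params$mz_jitter_ppm * 1e-6))
  }
  peaks <- peaks |>
    dplyr::select("run_id", "rt_min", "mz", "intensity") |>
    dplyr::arrange(.data$run_id, .data$rt_min, .data$mz)
  truth <- obs |>
    dplyr::select("peptide_id", "run_id", "tag", "condition", "replicate",
                  "z", "n_labels", "mono_mz", "rt_min", "abundance",
                  "true_ratio", "exempt", "missing", "coincident",
                  "interfered", "overlap_injected")
  list(peaks = peaks, truth = truth)
}

#' Simulate a complete labeling study
#'
#' Convenience wrapper chaining [simulate_proteome()],
#' [simulate_degradome()], [simulate_abundances()] and [render_runs()] with
#' one master seed.
#'
#' @param n_proteins Number of synthetic proteins.
#' @param model Degradome model ([degradome_model()]).
#' @param design Effect design ([effect_design()]).
#' @param scheme Labeling scheme; defaults to [default_labeling_scheme()]
#'   over the design's conditions.
#' @param params Spectrum parameters ([spectrum_params()]).
#' @param constants Mass constants.
#' @param seed Master seed; stage seeds are derived from it.
#' @return List with `proteome`, `peptides`, `identifications` (the
#'   sequence/protein/acetylation table a search engine would supply),
#'   `scheme`, `abundances`, `peaks`, `truth`.
#' @export
simulate_study <- function(n_proteins = 30, model = degradome_model(),
                           design = effect_design(),
                           scheme = NULL,
                           params = spectrum_params(),
                           constants = mass_constants(), seed = 1) {
  if (is.null(scheme)) {
    scheme <- default_labeling_scheme(names(design$effects))
  }
  validate_scheme(scheme, design$reference)
  proteome <- simulate_proteome(n_proteins, seed = seed)
  peptides <- simulate_degradome(proteome, model, seed = seed + 1L)
  abundances <- simulate_abundances(peptides, scheme, design,
                                    seed = seed + 2L)
  rendered <- render_runs(abundances, peptides, params, constants,
                          seed = seed + 3L)
  identifications <- peptides |>
    dplyr::select("peptide_id", "sequence", "n_term_acetylated",
                  "protein_id", "n_labels")
  list(proteome = proteome, peptides = peptides,
       identifications = identifications, scheme = scheme,
       abundances = abundances, peaks = rendered$peaks,
       truth = rendered$truth)
}
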