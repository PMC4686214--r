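# Stage 1 of the analysis: from centroided MS1 peak lists to deisotoped
# clusters and TMAB multiplex peak groups. The logic automates what the
# original manual spectrum reading did: find isotope series spaced
# 1.0034/z, take the most intense peak of each series as its
# representative intensity, then look for co-eluting companion series at
# the exact per-tag-pair label spacings.

ppm_tol_da <- function(mz, ppm) mz * ppm * 1e-6

#' Representative intensity of an isotope cluster
#'
#' The most intense member peak; in practice either the monoisotopic peak or
#' the one-13C peak, depending on peptide mass. Ties are broken toward the
#' monoisotopic (lowest-m/z) peak.
#'
#' @param mz Numeric vector of member peak m/z values.
#' @param intensity Numeric vector of member peak intensities.
#' @return The representative intensity (scalar).
#' @export
#' @examples
#' representative_intensity(c(500.0, 500.5), c(80, 100))  # 100
representative_intensity <- function(mz, intensity) {
  stopifnot(length(mz) == length(intensity), length(mz) > 0)
  ord <- order(-intensity, mz)
  intensity[ord[1]]
}

# nearest unassigned peak to `target` m/z within tol_da and rt window,
# subject to an intensity ceiling; returns its index into the run's peak
# table or NA.
nearest_peak <- function(target, rt0, mz_sorted, ord, rt, int, assigned,
                         tol_da, rt_tol, max_int = Inf, min_int = 0,
                         exclude = integer(0)) {
  lo <- findInterval(target - tol_da, mz_sorted) + 1L
  hi <- findInterval(target + tol_da, mz_sorted)
  if (lo > hi) return(NA_integer_)
  pos <- lo:hi
  cand <- ord[pos]
  keep <- !assigned[cand] & abs(rt[cand] - rt0) <= rt_tol &
    int[cand] <= max_int & int[cand] >= min_int & !(cand %in% exclude)
  if (!any(keep)) return(NA_integer_)
  pos <- pos[keep]
  cand[keep][which.min(abs(mz_sorted[pos] - target))]
}

detect_clusters_one_run <- function(pk, z_range, ppm_tol, rt_tol,
                                    max_isotopomers, envelope_rate_per_kda,
                                    envelope_slack, constants) {
  n <- nrow(pk)
  if (n == 0) {
    return(tibble::tibble(
      cluster_id = integer(0), z = integer(0), mono_mz = numeric(0),
      rt = numeric(0), rep_intensity = numeric(0), n_peaks = integer(0),
      members = list()
    ))
  }
  mz <- pk$mz; rt <- pk$rt_min; int <- pk$intensity
  ord <- order(mz)
  mz_sorted <- mz[ord]
  assigned <- logical(n)
  spacing <- constants$c13_minus_c12
  seeds <- order(-int)
  res <- vector("list", n)
  n_clusters <- 0L

  # Envelope plausibility ceiling for a peak `p` ladder steps from the seed
  # (negative = below). The seed, being the tallest unassigned peak, is
  # taken as the apex of a Poisson envelope whose rate is implied by the
  # neutral peptide mass. That mass is only known up to the (label-count
  # dependent) share of tag mass in the observed m/z, so the ceiling is the
  # maximum over a small grid of plausible rates. Without this ceiling,
  # channels of low-label-count peptides bridge at high m/z: three
  # isotopomer steps (3.0101 Da) fall within ppm tolerance of the
  # 3-deuterium tag spacing (3.0188 Da).
  env_bound <- function(lambda_max, seed_int, p) {
    lams <- lambda_max * c(0.7, 0.85, 1.0)
    r <- vapply(lams, function(l) {
      a <- max(0, floor(l))
      k <- a + p
      if (k < 0) return(0)
      stats::dpois(k, l) / stats::dpois(a, l)
    }, numeric(1))
    envelope_slack * seed_int * max(r)
  }

  extend <- function(seed, z, direction) {
    members <- integer(0)
    cur <- mz[seed]
    lambda_max <- max(1e-6, envelope_rate_per_kda *
                        z * (mz[seed] - constants$proton) / 1000)
    for (step in seq_len(max_isotopomers)) {
      bound <- env_bound(lambda_max, int[seed], direction * step)
      if (bound <= 0) break
      # below the apex a true pre-apex member cannot be arbitrarily weak;
      # the floor keeps faint tails of neighbouring species from being
      # mistaken for the monoisotopic region
      min_int <- if (direction < 0) 0.25 * int[seed] else 0
      target <- cur + direction * spacing / z
      j <- nearest_peak(target, rt[seed], mz_sorted, ord, rt, int, assigned,
                        ppm_tol_da(target, ppm_tol), rt_tol,
                        max_int = bound, min_int = min_int,
                        exclude = c(seed, members))
      if (is.na(j)) break
      members <- c(members, j)
      cur <- mz[j]
    }
    members
  }

  for (seed in seeds) {
    if (assigned[seed]) next
    best_members <- seed
    best_z <- NA_integer_
    for (z in sort(z_range, decreasing = TRUE)) {
      up <- extend(seed, z, +1)
      down <- extend(seed, z, -1)
      members <- c(rev(down), seed, up)
      # keep the charge explaining the most peaks; ties resolved toward
      # higher z by the descending loop order
      if (length(members) > length(best_members)) {
        best_members <- members
        best_z <- z
      }
    }
    assigned[best_members] <- TRUE
    n_clusters <- n_clusters + 1L
    m <- best_members[order(mz[best_members])]
    res[[n_clusters]] <- tibble::tibble(
      cluster_id = n_clusters,
      z = best_z,
      mono_mz = mz[m[1]],
      rt = rt[seed],
      rep_intensity = representative_intensity(mz[m], int[m]),
      n_peaks = length(m),
      members = list(tibble::tibble(mz = mz[m], intensity = int[m]))
    )
  }
  dplyr::bind_rows(res[seq_len(n_clusters)])
}

#' Detect isotope clusters in centroid peak lists
#'
#' Greedy intensity-descending deisotoping: the tallest unassigned peak
#' seeds a cluster; for each candidate charge the isotopomer ladder
#' (spacing 1.0033548/z) is walked in both m/z directions within the ppm
#' and co-elution tolerances, and the charge explaining the most peaks
#' wins (ties to the higher charge). Peaks with no ladder partner become
#' single-peak clusters with undetermined charge (`z = NA`).
#'
#' @param peaks Tibble with columns `run_id`, `rt_min`, `mz`, `intensity`.
#' @param z_range Integer charge states to consider.
#' @param ppm_tol m/z matching tolerance, ppm.
#' @param rt_tol Co-elution tolerance, minutes.
#' @param max_isotopomers Maximum ladder steps walked in each direction.
#' @param envelope_rate_per_kda Averagine-like isotope envelope rate (mean
#'   heavy-isotope count per 1000 Da) used for the plausibility ceiling.
#' @param envelope_slack Multiplicative slack on the envelope ceiling.
#' @param constants Output of [mass_constants()].
#' @return Tibble of clusters: `run_id`, `cluster_id` (unique within run),
#'   `z`, `mono_mz`, `rt`, `rep_intensity`, `n_peaks`, and `members`
#'   (list-column of member peak tibbles).
#' @export
detect_isotope_clusters <- function(peaks, z_range = 1:6, ppm_tol = 10,
                                    rt_tol = 0.2, max_isotopomers = 8,
                                    envelope_rate_per_kda = 0.6,
                                    envelope_slack = 2,
                                    constants = mass_constants()) {
  stopifnot(all(c("run_id", "rt_min", "mz", "intensity") %in% names(peaks)))
  if (any(peaks$intensity < 0)) stop("peak intensities must be >= 0")
  peaks |>
    dplyr::group_by(.data$run_id) |>
    dplyr::group_modify(~detect_clusters_one_run(
      .x, z_range, ppm_tol, rt_tol, max_isotopomers,
      envelope_rate_per_kda, envelope_slack, constants
    )) |>
    dplyr::ungroup()
}

# Match clusters of one run against a target m/z; same z (clusters with
# undetermined z never match), co-eluting, nearest within tolerance.
match_cluster <- function(target, z0, rt0, cl_mz, cl_z, cl_rt, tol_da,
                          rt_tol) {
  cand <- which(!is.na(cl_z) & cl_z == z0 &
                  abs(cl_mz - target) <= tol_da &
                  abs(cl_rt - rt0) <= rt_tol)
  if (length(cand) == 0) return(NA_integer_)
  cand[which.min(abs(cl_mz[cand] - target))]
}

find_groups_one_run <- function(cl, tags, max_labels, ppm_tol, rt_tol,
                                identifications, constants) {
  empty <- tibble::tibble(
    group_id = integer(0), z = integer(0), n_labels = integer(0),
    neutral_mass = numeric(0), rt = numeric(0), tag = character(0),
    cluster_id = integer(0), mono_mz = numeric(0), intensity = numeric(0),
    missing = logical(0), coincident = logical(0),
    ambiguity_flag = logical(0)
  )
  if (nrow(cl) == 0) return(empty)
  shifts <- tag_mass_shift(tags, constants)
  cl_mz <- cl$mono_mz; cl_z <- cl$z; cl_rt <- cl$rt
  # every member peak of the run, for deciding whether an unmatched
  # channel's predicted position is truly empty or merely obscured
  n_members <- vapply(cl$members, nrow, integer(1))
  all_mz <- unlist(lapply(cl$members, `[[`, "mz"), use.names = FALSE)
  all_rt <- rep(cl$rt, n_members)
  o <- order(all_mz)
  all_mz <- all_mz[o]; all_rt <- all_rt[o]
  claimed <- logical(nrow(cl))
  claimed_by <- integer(nrow(cl))
  id_mass <- NULL
  if (!is.null(identifications) && nrow(identifications) > 0) {
    id_mass <- peptide_mass(identifications$sequence,
                            identifications$n_term_acetylated,
                            constants = constants)
    id_labels <- count_tmab_labels(identifications$sequence,
                                   identifications$n_term_acetylated)
  }
  seeds <- order(-cl$rep_intensity)
  out <- list()
  gid <- 0L
  for (s in seeds) {
    if (claimed[s] || is.na(cl_z[s])) next
    z0 <- cl_z[s]
    hyps <- list()
    for (n in seq_len(max_labels)) {
      if (z0 < n) break  # fixed-charge convention: z >= n_labels
      for (t0 in seq_along(tags)) {
        targets <- cl_mz[s] + n * (shifts - shifts[t0]) / z0
        matched <- vapply(seq_along(tags), function(t) {
          if (t == t0) return(s)
          match_cluster(targets[t], z0, cl_rt[s], cl_mz, cl_z, cl_rt,
                        ppm_tol_da(targets[t], ppm_tol), rt_tol)
        }, integer(1))
        n_ch <- sum(!is.na(matched))
        if (n_ch < 2) next
        # a seed whose every companion already belongs to an earlier group
        # is an interloper (typically a co-eluting interferent riding on a
        # real group), not a new peak group
        comp <- matched[!is.na(matched)]
        comp <- comp[comp != s]
        if (all(claimed[comp])) next
        neutral <- z0 * cl_mz[s] -
          n * (constants$tag_base_mass + shifts[t0]) -
          (z0 - n) * constants$proton
        id_ok <- FALSE
        if (!is.null(id_mass)) {
          tol <- ppm_tol_da(neutral, ppm_tol) * 2
          id_ok <- any(id_labels == n & abs(id_mass - neutral) <= tol)
        }
        hyps[[length(hyps) + 1L]] <- list(
          n = n, t0 = t0, matched = matched, n_ch = n_ch,
          neutral = neutral, id_ok = id_ok
        )
      }
    }
    if (length(hyps) == 0) next
    # tie-break order: identification-consistent first, then most matched
    # channels, then smaller label count
    score <- vapply(hyps, function(h) {
      h$id_ok * 1e6 + h$n_ch * 1e3 - h$n
    }, numeric(1))
    best <- hyps[[which.max(score)]]
    gid <- gid + 1L
    matched <- best$matched
    amb <- any(claimed[matched[!is.na(matched)]])
    if (amb) {
      prev <- unique(claimed_by[matched[!is.na(matched)]])
      prev <- prev[prev > 0]
      for (p in prev) out[[p]]$ambiguity_flag <- TRUE
    }
    idx <- matched[!is.na(matched)]
    claimed[idx] <- TRUE
    claimed_by[idx][claimed_by[idx] == 0L] <- gid
    # coincident channels cannot be independently quantified: two channels
    # resolving to one cluster (for one-label peptides the D9 and D12
    # channels sit exactly three isotopomer steps apart), or a channel
    # whose predicted position is obscured by the member peaks of another
    # channel's cluster - such a channel must not be mistaken for one that
    # is genuinely below the detection limit.
    coincident <- !is.na(matched) & matched %in% matched[duplicated(matched)]
    if (any(is.na(matched))) {
      t0 <- best$t0
      targets <- cl_mz[s] + best$n * (shifts - shifts[t0]) / z0
      for (t in which(is.na(matched))) {
        tol <- ppm_tol_da(targets[t], ppm_tol)
        lo <- findInterval(targets[t] - tol, all_mz) + 1L
        hi <- findInterval(targets[t] + tol, all_mz)
        if (lo <= hi &&
            any(abs(all_rt[lo:hi] - cl_rt[s]) <= rt_tol)) {
          coincident[t] <- TRUE
        }
      }
    }
    out[[gid]] <- tibble::tibble(
      group_id = gid,
      z = z0,
      n_labels = best$n,
      neutral_mass = best$neutral,
      rt = cl_rt[s],
      tag = tags,
      cluster_id = ifelse(is.na(matched), NA_integer_, matched),
      mono_mz = ifelse(is.na(matched), NA_real_, cl_mz[matched]),
      intensity = ifelse(is.na(matched), NA_real_,
                         cl$rep_intensity[matched]),
      missing = is.na(matched),
      coincident = coincident,
      ambiguity_flag = amb
    )
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out)
}

#' Find TMAB multiplex peak groups
#'
#' For each seed cluster (descending representative intensity) every
#' hypothesis over label count (1..`max_labels`, limited by the seed's
#' charge under the fixed-charge convention) and seed-channel assignment is
#' scored by how many tag channels it matches with a co-eluting cluster of
#' the same charge at the exact per-tag-pair spacing. The winning hypothesis
#' needs at least two present channels; unmatched tags are recorded as
#' missing channels. When a supplied identification table contains a peptide
#' whose labeled neutral mass is consistent with a hypothesis, that
#' hypothesis is preferred; otherwise more matched channels, then the
#' smaller label count win. Groups that share a cluster with an earlier
#' group carry `ambiguity_flag`.
#'
#' @param clusters Output of [detect_isotope_clusters()].
#' @param scheme Labeling scheme tibble; per run, the tags searched are the
#'   ones the scheme assigns in that run.
#' @param max_labels Maximum label count hypothesis.
#' @param ppm_tol,rt_tol Matching tolerances (ppm, minutes).
#' @param identifications Optional tibble with `sequence` and
#'   `n_term_acetylated`, used only for hypothesis tie-breaking.
#' @param constants Output of [mass_constants()].
#' @return Tidy tibble, one row per group x tag channel: `run_id`,
#'   `group_id`, `z`, `n_labels`, `neutral_mass` (inferred, Da), `rt`,
#'   `tag`, `cluster_id`, `mono_mz`, `intensity`, `missing`, `coincident`
#'   (the channel cannot be quantified because its signal coincides with
#'   another channel's peaks), `ambiguity_flag`.
#' @export
find_peak_groups <- function(clusters, scheme, max_labels = 6, ppm_tol = 10,
                             rt_tol = 0.2, identifications = NULL,
                             constants = mass_constants()) {
  validate_scheme(scheme)
  run_tags <- split(scheme$tag, scheme$run_id)
  clusters |>
    dplyr::group_by(.data$run_id) |>
    dplyr::group_modify(function(cl, key) {
      tags <- run_tags[[key$run_id]]
      if (is.null(tags)) {
        stop("run ", key$run_id, " is absent from the labeling scheme")
      }
      find_groups_one_run(cl, tags, max_labels, ppm_tol, rt_tol,
                          identifications, constants)
    }) |>
    dplyr::ungroup()
}

#' Flag channels corrupted by co-eluting overlap
#'
#' A channel is overlap-flagged when a cluster outside its own peak group
#' co-elutes with a member peak within `overlap_mz_tol` of any of the
#' channel's member peaks; its intensity cannot be trusted and it is
#' excluded from quantification downstream. A group all of whose present
#' channels are overlapped cannot be quantified at all (rendered white in
#' the heat map).
#'
#' @param groups Output of [find_peak_groups()].
#' @param clusters The clusters the groups were built from.
#' @param overlap_mz_tol m/z proximity defining interference, Th.
#' @param rt_tol Co-elution tolerance, minutes.
#' @param coincide_mz_tol Proximity at which even a cluster of the same
#'   peak group corrupts a channel. Interleaved channels of low-label-count
#'   peptides sit n x 8.77/z mDa apart; below about 5 mDa such sticks are
#'   not separable at typical time-of-flight resolving power, so those
#'   channels are treated as mutually unquantifiable.
#' @return `groups` with a logical `overlap` column added (OR-ed with the
#'   detector's `coincident` flag when present).
#' @export
flag_overlap <- function(groups, clusters, overlap_mz_tol = 0.02,
                         rt_tol = 0.2, coincide_mz_tol = 0.005) {
  member_tbl <- clusters |>
    dplyr::select("run_id", "cluster_id", "rt", "members") |>
    tidyr::unnest("members")
  by_run <- split(member_tbl, member_tbl$run_id)
  by_run <- lapply(by_run, function(d) d[order(d$mz), ])
  grp_clusters <- groups |>
    dplyr::filter(!.data$missing) |>
    dplyr::distinct(.data$run_id, .data$group_id, .data$cluster_id)
  check_channel <- function(run_id, group_id, cluster_id) {
    d <- by_run[[run_id]]
    own <- d[d$cluster_id == cluster_id, ]
    group_ids <- grp_clusters$cluster_id[
      grp_clusters$run_id == run_id & grp_clusters$group_id == group_id
    ]
    for (i in seq_len(nrow(own))) {
      lo <- findInterval(own$mz[i] - overlap_mz_tol, d$mz) + 1L
      hi <- findInterval(own$mz[i] + overlap_mz_tol, d$mz)
      if (lo > hi) next
      cand <- d[lo:hi, ]
      coelute <- abs(cand$rt - own$rt[i]) <= rt_tol
      hit <- coelute &
        (!(cand$cluster_id %in% group_ids) |
           (cand$cluster_id != cluster_id &
              abs(cand$mz - own$mz[i]) <= coincide_mz_tol))
      if (any(hit)) return(TRUE)
    }
    FALSE
  }
  present <- !groups$missing
  ovl <- rep(FALSE, nrow(groups))
  ovl[present] <- purrr::pmap_lgl(
    groups[present, c("run_id", "group_id", "cluster_id")],
    check_channel
  )
  if ("coincident" %in% names(groups)) ovl <- ovl | groups$coincident
  groups$overlap <- ovl
  groups
}
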