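test_that("deisotoping infers charge from isotopomer spacing", {
  pk <- tibble::tibble(
    run_id = "r", rt_min = 10,
    mz = 500 + 0:2 * 1.0033548 / 2,
    intensity = c(100, 80, 30)
  )
  cl <- detect_isotope_clusters(pk)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$z, 2L)
  expect_equal(cl$mono_mz, 500)
  expect_identical(cl$n_peaks, 3L)

  # z = 1 envelope is not mistaken for higher charge
  pk1 <- tibble::tibble(run_id = "r", rt_min = 5,
                        mz = 700 + 0:3 * 1.0033548,
                        intensity = c(100, 42, 9, 1.3))
  cl1 <- detect_isotope_clusters(pk1)
  expect_identical(cl1$z, 1L)
})

test_that("empty and sparse inputs give empty or singleton clusters", {
  empty <- tibble::tibble(run_id = character(0), rt_min = numeric(0),
                          mz = numeric(0), intensity = numeric(0))
  expect_identical(nrow(detect_isotope_clusters(empty)), 0L)
  iso <- tibble::tibble(run_id = "r", rt_min = 5, mz = c(500, 510),
                        intensity = c(50, 60))
  cl <- detect_isotope_clusters(iso)
  expect_identical(nrow(cl), 2L)
  expect_true(all(is.na(cl$z)))
  expect_error(detect_isotope_clusters(dplyr::mutate(iso, intensity = -1)),
               ">= 0")
})

test_that("representative intensity takes the tallest peak, ties to mono", {
  expect_identical(representative_intensity(c(500, 500.5, 501),
                                            c(100, 80, 30)), 100)
  expect_identical(representative_intensity(c(500, 500.5, 501),
                                            c(80, 100, 30)), 100)
  # exact tie resolved toward the monoisotopic (lowest m/z) peak
  expect_identical(representative_intensity(c(500, 500.5), c(100, 100)),
                   100)
})

test_that("co-elution separates clusters at the same m/z", {
  pk <- dplyr::bind_rows(
    tibble::tibble(run_id = "r", rt_min = 10,
                   mz = 600 + 0:2 * 1.0033548, intensity = c(90, 32, 6)),
    tibble::tibble(run_id = "r", rt_min = 20,
                   mz = 600 + 0:2 * 1.0033548, intensity = c(90, 32, 6))
  )
  cl <- detect_isotope_clusters(pk)
  expect_identical(nrow(cl), 2L)
  expect_setequal(round(cl$rt), c(10, 20))
})

test_that("noise-free multiplex groups are recovered completely", {
  fx <- noise_free_study()
  truth <- fx$study$truth
  clean <- truth[!truth$missing & !truth$coincident & !truth$interfered, ]
  expected <- clean |>
    dplyr::count(.data$peptide_id, .data$run_id, .data$z) |>
    dplyr::filter(.data$n >= 2)
  # match detected channels to truth by exact channel position
  det <- fx$groups[!fx$groups$missing, ]
  m <- det |>
    dplyr::inner_join(truth, by = c("run_id", "tag", "z"),
                      suffix = c("", ".t"), relationship = "many-to-many") |>
    dplyr::filter(abs(.data$mono_mz - .data$mono_mz.t) < 1e-4)
  found <- dplyr::semi_join(
    expected, dplyr::distinct(m, .data$peptide_id, .data$run_id, .data$z),
    by = c("peptide_id", "run_id", "z")
  )
  expect_identical(nrow(found), nrow(expected))  # 100% recall
  # every emitted group has >= 2 present channels and a correct label count
  per_group <- fx$groups |>
    dplyr::group_by(.data$run_id, .data$group_id) |>
    dplyr::summarise(present = sum(!.data$missing), .groups = "drop")
  expect_true(all(per_group$present >= 2))
  mlab <- m |> dplyr::distinct(.data$run_id, .data$group_id, .data$n_labels,
                               .data$n_labels.t)
  expect_true(all(mlab$n_labels == mlab$n_labels.t))
})

test_that("detected inter-channel spacings agree with the chemistry module", {
  fx <- noise_free_study()
  g <- fx$groups[!fx$groups$missing, ]
  per_group <- split(g, paste(g$run_id, g$group_id))
  checked <- 0L
  for (grp in per_group) {
    if (nrow(grp) < 2) next
    for (i in 2:nrow(grp)) {
      exp_sp <- peakgroup_spacing(grp$n_labels[1], grp$tag[1], grp$tag[i],
                                  z = grp$z[1])
      expect_equal(grp$mono_mz[i] - grp$mono_mz[1], exp_sp,
                   tolerance = 1.1e-5 * abs(grp$mono_mz[1]) + 1e-9)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 100)
})

test_that("no cluster belongs to two unflagged groups", {
  fx <- noise_free_study()
  shared <- fx$groups |>
    dplyr::filter(!.data$missing, !.data$ambiguity_flag) |>
    dplyr::count(.data$run_id, .data$cluster_id) |>
    dplyr::filter(.data$n > 1)
  expect_identical(nrow(shared), 0L)
})

test_that("channels below the limit of detection are reported missing", {
  pep <- tibble::tibble(peptide_id = "P1", protein_id = "X",
                        sequence = "SAMTEEAAVAIKAMAK",
                        n_term_acetylated = FALSE, start = 2L, end = 17L,
                        terminal = "internal", n_labels = 3L)
  scheme <- default_labeling_scheme()
  ab <- simulate_abundances(
    pep, scheme,
    effect_design(effects = c(Q7Q7 = 1, Q7Q111 = 0.05, Q111Q111 = 0.05),
                  non_product_fraction = 0, cv = 0),
    base_meanlog = log(5000), base_sdlog = 0, seed = 1
  )
  params <- spectrum_params(mz_jitter_ppm = 0, rt_jitter_min = 0, lod = 400,
                            n_noise_peaks = 0, overlap_rate = 0)
  rr <- render_runs(ab, pep, params, seed = 1)
  cl <- detect_isotope_clusters(rr$peaks)
  g <- find_peak_groups(cl, scheme, identifications = pep)
  miss <- dplyr::inner_join(
    g, scheme, by = c("run_id", "tag")
  )
  expect_true(all(miss$missing[miss$condition != "Q7Q7"]))
  expect_true(all(!miss$missing[miss$condition == "Q7Q7"]))
})

test_that("injected co-eluting interferents are overlap-flagged", {
  pep <- tibble::tibble(peptide_id = "P1", protein_id = "X",
                        sequence = "AQATGKPAQYIAVHVVPDQL",
                        n_term_acetylated = FALSE, start = 5L, end = 24L,
                        terminal = "internal", n_labels = 2L)
  scheme <- default_labeling_scheme()
  ab <- simulate_abundances(pep, scheme, noise_free_design(), seed = 3)
  params <- spectrum_params(mz_jitter_ppm = 0, rt_jitter_min = 0, lod = 0,
                            n_noise_peaks = 0, overlap_rate = 1)
  rr <- render_runs(ab, pep, params, seed = 3)
  expect_true(all(rr$truth$overlap_injected[!rr$truth$missing]))
  cl <- detect_isotope_clusters(rr$peaks)
  g <- find_peak_groups(cl, scheme, identifications = pep)
  g <- flag_overlap(g, cl)
  expect_true(all(g$overlap[!g$missing]))

  # an isolated clean study has overlap only where physics forces it
  fx <- noise_free_study()
  tclean <- fx$study$truth |>
    dplyr::filter(!.data$missing, !.data$coincident, !.data$interfered)
  det <- fx$groups[!fx$groups$missing, ] |>
    dplyr::inner_join(tclean, by = c("run_id", "tag", "z"),
                      suffix = c("", ".t"), relationship = "many-to-many") |>
    dplyr::filter(abs(.data$mono_mz - .data$mono_mz.t) < 1e-4)
  expect_false(any(det$overlap))
})
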