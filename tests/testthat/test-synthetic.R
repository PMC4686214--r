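test_that("proteome simulation is seeded and honours residue frequencies", {
  p1 <- simulate_proteome(3, c(50, 50), seed = 5)
  p2 <- simulate_proteome(3, c(50, 50), seed = 5)
  expect_identical(p1, p2)
  expect_true(all(nchar(p1$sequence) == 50))
  expect_error(simulate_proteome(0), ">= 1")
  expect_error(simulate_proteome(2, aa_freqs = c(Z = 1)), "named vector")

  # uniform frequencies: empirical per-residue frequency 0.05 within 4 sigma
  big <- simulate_proteome(40, c(300, 300), seed = 11)
  chars <- strsplit(paste(big$sequence, collapse = ""), "")[[1]]
  n <- length(chars)
  freq <- table(factor(chars, levels = names(mass_constants()$residues))) / n
  se <- sqrt(0.05 * 0.95 / n)
  expect_true(all(abs(freq - 0.05) < 4 * se))
})

test_that("degradome peptides are substrings with P1-weighted flanks", {
  prot <- simulate_proteome(4, c(250, 300), seed = 3)
  # degenerate weights: every sampled cleavage has Leu in P1
  degL <- simulate_degradome(prot, degradome_model(
    p1_weights = c(L = 1), terminal_fraction = 0
  ), seed = 3)
  expect_gt(nrow(degL), 0)
  for (i in seq_len(nrow(degL))) {
    ps <- prot$sequence[prot$protein_id == degL$protein_id[i]]
    expect_identical(substr(ps, degL$start[i], degL$end[i]),
                     degL$sequence[i])
    expect_identical(substr(ps, degL$start[i] - 1, degL$start[i] - 1), "L")
    expect_identical(substr(degL$sequence[i], nchar(degL$sequence[i]),
                            nchar(degL$sequence[i])), "L")
  }
  expect_true(all(degL$terminal == "internal"))
})

test_that("empirical P1 distribution converges to the generating weights", {
  prot <- simulate_proteome(250, c(500, 700), seed = 9)
  deg <- simulate_degradome(prot, degradome_model(peptides_per_protein = 30),
                            seed = 9)
  sites <- cleavage_sites(locate_peptide(deg, prot), prot) |>
    dplyr::inner_join(deg[c("sequence", "copies")], by = "sequence")
  expect_gt(sum(sites$copies), 8000)
  w <- default_p1_weights()
  # each draw of a span counts once (spans can be drawn repeatedly)
  counts <- tapply(sites$copies, factor(sites$p1, levels = names(w)), sum)
  counts[is.na(counts)] <- 0
  # chi-square goodness of fit against the generating weights
  gof <- suppressWarnings(stats::chisq.test(counts, p = w))
  expect_gt(gof$p.value, 0.01)
})

test_that("abundance simulation applies effects and replicate noise", {
  pep <- tibble::tibble(peptide_id = paste0("P", 1:40),
                        sequence = strrep("ACK", 4),
                        n_term_acetylated = FALSE)
  scheme <- default_labeling_scheme()
  des0 <- effect_design(non_product_fraction = 0, cv = 0)
  ab <- simulate_abundances(pep, scheme, des0, seed = 2)
  # noise-free: treated / reference equals the design effect exactly
  wide <- ab |>
    dplyr::group_by(.data$peptide_id, .data$condition) |>
    dplyr::summarise(a = mean(.data$abundance), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "a")
  expect_equal(wide$Q111Q111 / wide$Q7Q7, rep(0.35, nrow(wide)))
  expect_equal(wide$Q7Q111 / wide$Q7Q7, rep(0.35, nrow(wide)))

  # lognormal replicate noise: geometric-mean ratio within the lognormal CI
  des <- effect_design(non_product_fraction = 0, cv = 0.2)
  ab2 <- simulate_abundances(pep, scheme, des, seed = 4)
  r <- ab2 |>
    dplyr::group_by(.data$peptide_id) |>
    dplyr::summarise(
      gm = exp(mean(log(.data$abundance[.data$condition == "Q111Q111"])) -
                 mean(log(.data$abundance[.data$condition == "Q7Q7"])))
    )
  n_eff <- 1 / 6 + 1 / 6
  ci <- exp(log(0.35) + c(-4, 4) * 0.2 * sqrt(n_eff / 40))
  expect_gt(mean(r$gm), ci[1])
  expect_lt(mean(r$gm), ci[2])

  # exempt peptides keep effect 1 in every condition
  des_ex <- effect_design(non_product_fraction = 1, cv = 0)
  ab3 <- simulate_abundances(pep, scheme, des_ex, seed = 5)
  expect_true(all(ab3$true_ratio == 1))
})

test_that("rendered runs place clusters at theoretical positions", {
  pep <- tibble::tibble(peptide_id = "P1", protein_id = "X",
                        sequence = "DLTIKLPDGHEF",
                        n_term_acetylated = FALSE, start = 3L, end = 14L,
                        terminal = "internal", n_labels = 2L)
  scheme <- default_labeling_scheme()
  ab <- simulate_abundances(pep, scheme, noise_free_design(), seed = 1)
  rr <- render_runs(ab, pep, noise_free_params(), seed = 1)
  # every expected channel present at the exact theoretical m/z
  for (i in seq_len(nrow(rr$truth))) {
    t <- rr$truth[i, ]
    expect_equal(t$mono_mz,
                 theoretical_mz("DLTIKLPDGHEF", t$tag, t$z),
                 tolerance = 1e-9)
    hit <- rr$peaks$run_id == t$run_id &
      abs(rr$peaks$mz - t$mono_mz) < 1e-6
    expect_true(any(hit))
  }
  # rendered D0-D3 spacing equals the chemistry oracle
  tr <- rr$truth[rr$truth$run_id == "run1", ]
  d0 <- tr$mono_mz[tr$tag == "D0"]; d3 <- tr$mono_mz[tr$tag == "D3"]
  expect_equal(d3 - d0, peakgroup_spacing(2, "D0", "D3", z = tr$z[1]),
               tolerance = 1e-6)
})

test_that("channels below the detection limit are omitted and flagged", {
  pep <- tibble::tibble(peptide_id = "P1", protein_id = "X",
                        sequence = "SAMTEEAAVAIKAMAK",
                        n_term_acetylated = FALSE, start = 2L, end = 17L,
                        terminal = "internal", n_labels = 3L)
  scheme <- default_labeling_scheme()
  ab <- simulate_abundances(pep, scheme,
                            effect_design(effects = c(Q7Q7 = 1,
                                                      Q7Q111 = 0.1,
                                                      Q111Q111 = 0.1),
                                          non_product_fraction = 0, cv = 0),
                            base_meanlog = log(300), base_sdlog = 0,
                            seed = 1)
  params <- spectrum_params(mz_jitter_ppm = 0, rt_jitter_min = 0,
                            lod = 100, n_noise_peaks = 0, overlap_rate = 0)
  rr <- render_runs(ab, pep, params, seed = 1)
  tr <- rr$truth
  expect_true(all(tr$missing[tr$condition != "Q7Q7"]))
  expect_false(any(tr$missing[tr$condition == "Q7Q7"]))
  # missing channels leave no peaks behind
  gone <- tr[tr$missing, ]
  for (i in seq_len(nrow(gone))) {
    expect_false(any(rr$peaks$run_id == gone$run_id[i] &
                       abs(rr$peaks$mz - gone$mono_mz[i]) < 1e-4))
  }
})

test_that("simulated studies are byte-identical for a fixed seed", {
  s1 <- simulate_study(n_proteins = 3, seed = 17,
                       params = spectrum_params(n_noise_peaks = 30))
  s2 <- simulate_study(n_proteins = 3, seed = 17,
                       params = spectrum_params(n_noise_peaks = 30))
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(s1$truth, s2$truth)
})

test_that("scheme validation rejects duplicate tags and missing references", {
  s <- default_labeling_scheme()
  bad <- s; bad$tag[2] <- "D0"
  expect_error(tmabquant:::validate_scheme(bad), "duplicate tag")
  noref <- s[s$condition != "Q7Q7" | s$run_id != "run3", ]
  expect_error(tmabquant:::validate_scheme(noref, "Q7Q7"), "without a reference")
})
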