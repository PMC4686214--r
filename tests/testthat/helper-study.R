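# Shared fixtures. Heavier simulations are cached per test run so several
# test files can reuse them without re-simulating.

noise_free_params <- function() {
  spectrum_params(mz_jitter_ppm = 0, rt_jitter_min = 0, lod = 0,
                  n_noise_peaks = 0, overlap_rate = 0)
}

noise_free_design <- function() {
  effect_design(effects = c(Q7Q7 = 1, Q7Q111 = 0.5, Q111Q111 = 0.35),
                non_product_fraction = 0, cv = 0)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small noise-free study plus full detection/quantification
noise_free_study <- function() {
  cached("noise_free", {
    s <- simulate_study(n_proteins = 6, design = noise_free_design(),
                        params = noise_free_params(), seed = 23)
    cl <- detect_isotope_clusters(s$peaks)
    g <- flag_overlap(find_peak_groups(cl, s$scheme,
                                       identifications = s$identifications),
                      cl)
    q <- quantify_study(g, s$scheme, s$identifications, "Q7Q7")
    list(study = s, clusters = cl, groups = g, quant = q)
  })
}

# toy proteome with hand-enumerated cleavage geometry
toy_proteome <- function() {
  tibble::tibble(
    protein_id = paste0("TP", 1:5),
    sequence = c(
      "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
      "MDTSRVQPIKLARVTKVLGRTGSQGQCTQVRVE",
      "GGSSGGSSGAL",
      "MLLSAKQRRELLL",
      "AAAAKAAAAL"
    )
  )
}
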