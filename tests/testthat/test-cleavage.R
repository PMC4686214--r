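test_that("peptides are located with correct coordinates and status", {
  prot <- toy_proteome()
  peps <- tibble::tibble(
    sequence = c("TAYIAKQR",                       # internal in TP1
                 "MKTAYIAK",                       # N-terminal, Met retained
                 "DTSRVQPIKL",                     # start 2 (Met removed)
                 "GGSSGGSSGAL",                    # full protein TP3
                 "RELLL"),                         # C-terminal in TP4
    protein_id = c("TP1", "TP1", "TP2", "TP3", "TP4")
  )
  sp <- locate_peptide(peps, prot)
  expect_identical(sp$terminal,
                   c("internal", "n_terminal", "n_terminal", "full_length",
                     "c_terminal"))
  expect_identical(sp$start, c(3L, 1L, 2L, 1L, 9L))
  expect_identical(sp$end, c(10L, 8L, 11L, 11L, 13L))
  expect_error(
    locate_peptide(tibble::tibble(sequence = "WWWWW", protein_id = "TP1"),
                   prot),
    "not found"
  )
  expect_error(
    locate_peptide(tibble::tibble(sequence = "AAA", protein_id = "NOPE"),
                   prot),
    "absent from proteome"
  )
  # repeated motif: first occurrence, flagged ambiguous
  amb <- locate_peptide(tibble::tibble(sequence = "GGSS",
                                       protein_id = "TP3"), prot)
  expect_identical(amb$start, 1L)
  expect_true(amb$ambiguous)
})

test_that("cleavage enumeration: internal 2 sites, terminal 1, full-length 0", {
  prot <- toy_proteome()
  peps <- tibble::tibble(
    sequence = c("TAYIAKQR", "MKTAYIAK", "GGSSGGSSGAL", "RELLL"),
    protein_id = c("TP1", "TP1", "TP3", "TP4")
  )
  sites <- cleavage_sites(locate_peptide(peps, prot), prot)
  per_pep <- table(factor(sites$sequence, levels = peps$sequence))
  expect_identical(as.integer(per_pep),
                   c(2L, 1L, 0L, 1L))
  # internal peptide: bonds before start and after end, P1 on the N side
  int <- sites[sites$sequence == "TAYIAKQR", ]
  expect_identical(int$position, c(2L, 10L))
  expect_identical(int$p1, c("K", "R"))
  expect_identical(int$p1prime, c("T", "Q"))
  expect_setequal(int$side,
                  c("generates_peptide_nterm", "generates_peptide_cterm"))
})

test_that("acetylated protein N-termini are never counted as cleavages", {
  prot <- toy_proteome()
  ac <- tibble::tibble(sequence = "MDTSRVQPIKL", protein_id = "TP2",
                       n_term_acetylated = TRUE)
  sites <- cleavage_sites(locate_peptide(ac, prot), prot)
  expect_identical(nrow(sites), 1L)
  expect_identical(sites$side, "generates_peptide_cterm")
  expect_identical(sites$p1, "L")  # peptide's last residue by definition
})

test_that("p1_residue reads the residue N-terminal to the cleaved bond", {
  expect_identical(p1_residue(10, "RGEVASDAKSFVLNL"), "S")
  expect_identical(p1_residue(c(1, 15), "RGEVASDAKSFVLNL"), c("R", "L"))
  expect_error(p1_residue(0, "GAGA"), "not a cleavage")
})

test_that("frequency tables equal a brute-force enumeration", {
  prot <- toy_proteome()
  obs <- tibble::tibble(
    sequence = c("TAYIAKQR", "TAYIAKQR", "MKTAYIAK", "RELLL", "DTSRVQPIKL"),
    protein_id = c("TP1", "TP1", "TP1", "TP4", "TP2"),
    category = c("decrease", "decrease", "no_change", "decrease",
                 "decrease")
  )
  sp <- locate_peptide(dplyr::distinct(obs, .data$sequence,
                                       .data$protein_id), prot)
  sites <- cleavage_sites(sp, prot)
  ft <- p1_frequency_table(obs, sites)

  # independent brute force: scan each observation's span by hand
  brute <- list()
  for (i in seq_len(nrow(obs))) {
    ps <- prot$sequence[prot$protein_id == obs$protein_id[i]]
    st <- regexpr(obs$sequence[i], ps, fixed = TRUE)[1]
    en <- st + nchar(obs$sequence[i]) - 1L
    p1s <- character(0)
    if (st >= 3) p1s <- c(p1s, substr(ps, st - 1, st - 1))
    if (en < nchar(ps)) p1s <- c(p1s, substr(ps, en, en))
    for (r in p1s) {
      key <- paste(obs$category[i], r)
      if (is.null(brute[[key]])) brute[[key]] <- 0L
      brute[[key]] <- brute[[key]] + 1L
    }
  }
  for (key in names(brute)) {
    parts <- strsplit(key, " ")[[1]]
    got <- ft$n[ft$category == parts[1] & ft$residue == parts[2]]
    expect_identical(got, as.integer(brute[[key]]))
  }
  expect_identical(sum(ft$n), sum(unlist(brute)))
  # proportions sum to one within categories
  sums <- tapply(ft$prop, ft$category, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # residue classes are attached
  expect_identical(unique(ft$residue_class[ft$residue == "L"]),
                   "hydrophobic")
  expect_identical(unique(ft$residue_class[ft$residue == "K"]), "basic")
  expect_identical(unique(ft$residue_class[ft$residue == "D"]), "acidic")
})

test_that("empty observations give an all-zero table", {
  ft <- p1_frequency_table(
    tibble::tibble(sequence = character(0), category = character(0)),
    tibble::tibble(sequence = character(0), p1 = character(0))
  )
  expect_identical(nrow(ft), 0L)
})

test_that("per-experiment counting collapses replicate duplicates", {
  prot <- toy_proteome()
  obs <- tibble::tibble(
    sequence = rep("TAYIAKQR", 3),
    run_id = c("run1", "run1", "run2"),
    category = "decrease"
  )
  sites <- cleavage_sites(
    locate_peptide(tibble::tibble(sequence = "TAYIAKQR",
                                  protein_id = "TP1"), prot), prot
  )
  per_rep <- p1_frequency_table(obs, sites, count = "per_replicate")
  per_exp <- p1_frequency_table(obs, sites, count = "per_experiment")
  expect_identical(sum(per_rep$n), 6L)   # 3 observations x 2 sites
  expect_identical(sum(per_exp$n), 4L)   # 2 experiments x 2 sites
  expect_identical(attr(per_exp, "counting"), "per_experiment")
})

test_that("site totals exceed observation counts unless all terminal", {
  prot <- toy_proteome()
  mixed <- tibble::tibble(
    sequence = c("TAYIAKQR", "RELLL"), protein_id = c("TP1", "TP4"),
    category = "decrease"
  )
  sites <- cleavage_sites(locate_peptide(mixed, prot), prot)
  expect_gt(nrow(sites), nrow(mixed))
  terminal_only <- mixed[2, ]
  sites_t <- cleavage_sites(locate_peptide(terminal_only, prot), prot)
  expect_identical(nrow(sites_t), nrow(terminal_only))
})

test_that("end-to-end cleavage analysis recovers hydrophobic preference", {
  fx <- noise_free_study()
  clv <- analyze_cleavage(fx$quant, fx$study$proteome)
  expect_true(all(c("decrease") %in% clv$freq$category))
  dec <- clv$freq[clv$freq$category == "decrease", ]
  hyd <- sum(dec$prop[dec$residue_class == "hydrophobic"])
  # generating weights put 0.65 on hydrophobic residues
  expect_gt(hyd, 0.5)
  expect_lt(hyd, 0.8)
  # category totals partition the observations
  expect_identical(
    nrow(clv$observations),
    sum(!is.na(clv$observations$category))
  )
})
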