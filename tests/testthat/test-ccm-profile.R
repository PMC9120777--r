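# Presence matrices, Ci-uptake genotypes, CA complement, gamma-CA check.

test_that("packaged matrices have the published shape and spot values", {
  ci <- load_fixture("ci_uptake")
  cb <- load_fixture("carboxysome")
  expect_equal(dim(ci$present), c(17L, 14L))
  expect_equal(dim(cb$present), c(17L, 14L))
  expect_equal(ci$identity["Leptodesmis A121", "cmpC"], 73.6)
  expect_equal(ci$identity["Thermosynechococcus TA-1", "sbtB"], 80.2)
  expect_equal(ci$identity["Leptolyngbya JSC-1", "sbtA"], 75.9)
  expect_equal(cb$identity["Thermoleptolyngbya O-77", "ccmP"], 76.1)
  expect_equal(cb$identity["Thermosynechococcus BP-1", "ccmK1"], 86.1)
  expect_false(cb$present["Thermostichus 60AY4M2", "ccaA"])
  meta <- load_fixture("strains")
  expect_equal(nrow(meta), 17L)
  expect_equal(meta$accession[meta$strain == "Thermostichus JA-2-3Ba"],
               "GCA_000013225")
})

test_that("build_presence_matrix assembles rows and rejects ragged input", {
  row1 <- data.frame(gene_symbol = c("a", "b"), strain = "s1",
                     subject_id = c("x", NA),
                     identity_pct = c(80, NA), present = c(TRUE, FALSE))
  row2 <- data.frame(gene_symbol = c("b", "a"), strain = "s2",
                     subject_id = NA, identity_pct = c(60, 70),
                     present = c(TRUE, TRUE))
  m <- build_presence_matrix(list(row1, row2))
  expect_equal(dim(m$present), c(2L, 2L))
  expect_equal(m$identity["s2", "a"], 70)      # symbol order normalized
  expect_true(is.na(m$identity["s1", "b"]))    # identity only when present
  row3 <- data.frame(gene_symbol = "a", strain = "s3", subject_id = NA,
                     identity_pct = 1, present = TRUE)
  expect_error(build_presence_matrix(list(row1, row3)), "ragged")
  one <- build_presence_matrix(list(row3))
  expect_equal(dim(one$present), c(1L, 1L))
})

test_that("system completeness rules match the transporter biology", {
  ci <- load_fixture("ci_uptake")
  # sbtB alone still counts as Sbt (regulator-only strain)
  ta1 <- matrix_row(ci, "Thermosynechococcus TA-1")
  expect_true(system_present(ta1, "Sbt"))
  expect_false(system_present(ta1, "Sbt", sbt_mode = "both"))
  # BCT1 needs all four cmp subunits
  a183 <- matrix_row(ci, "Thermoleptolyngbya A183")
  expect_false(system_present(a183, "BCT1"))
  expect_equal(bct1_status(a183), "absent")
  a121 <- matrix_row(ci, "Leptodesmis A121")
  expect_true(system_present(a121, "BCT1"))
  expect_equal(bct1_status(a121), "complete")
  # partial complement is not complete
  part <- setNames(c(TRUE, TRUE, FALSE, TRUE), c("cmpA", "cmpB", "cmpC",
                                                 "cmpD"))
  expect_false(system_present(part, "BCT1"))
  expect_equal(bct1_status(part), "partial")
  # all-absent row: every system absent
  empty <- setNames(rep(FALSE, length(unlist(ccm_systems()))),
                    unlist(ccm_systems()))
  for (s in names(ccm_systems()))
    expect_false(system_present(empty, s))
  expect_error(system_present(a121, "nonsense"), "unknown system")
})

test_that("genotype classification reproduces the published assignment", {
  ci <- load_fixture("ci_uptake")
  geno <- function(s) classify_genotype(matrix_row(ci, s))$genotype
  expect_equal(geno("Leptolyngbya JSC-1"), "I")
  expect_equal(geno("Thermoleptolyngbya O-77"), "I")
  expect_equal(geno("Thermosynechococcus CL-1"), "I")
  expect_equal(geno("Thermosynechococcus E542"), "II")
  expect_equal(geno("Thermosynechococcus TA-1"), "II")
  expect_equal(geno("Leptodesmis A121"), "III")
  expect_equal(geno("Thermostichus JA-2-3Ba"), "III")
  all_geno <- vapply(ci$strains, geno, character(1))
  expect_equal(sum(all_geno == "I"), 3L)
  expect_equal(sum(all_geno == "II"), 4L)
  expect_equal(sum(all_geno == "III"), 10L)
})

test_that("genotype is a function of system presence only", {
  # feed classify_genotype a bare named logical vector (no identities,
  # no matrix): only system_present outputs can be consulted
  syms <- unlist(ccm_systems()[c("NDH-1_3", "NDH-1_4", "BicA", "Sbt",
                                 "BCT1")])
  row <- setNames(rep(FALSE, length(syms)), syms)
  row[c("ndhD3", "ndhF3", "cupA", "ndhD4", "ndhF4", "cupB")] <- TRUE
  row[c("bicA1", "sbtA", "sbtB")] <- TRUE
  row[c("cmpA", "cmpB", "cmpC", "cmpD")] <- TRUE
  expect_equal(classify_genotype(row)$genotype, "I")
  row[c("cmpA")] <- FALSE   # partial BCT1 -> treated absent -> II
  expect_equal(classify_genotype(row)$genotype, "II")
  row[c("sbtA", "sbtB")] <- FALSE
  row["cmpA"] <- TRUE       # BCT1 back, no sbt -> III
  expect_equal(classify_genotype(row)$genotype, "III")
  row[syms] <- FALSE
  expect_equal(classify_genotype(row)$genotype, "unclassified")
})

test_that("summaries reproduce the published in-text counts and ranges", {
  m <- load_fixture_combined()
  s <- summarize_ccm(m)
  expect_equal(s$n_strains, 17L)
  expect_equal(unname(s$genotype_counts[c("I", "II", "III")]),
               c(3L, 4L, 10L), ignore_attr = TRUE)
  expect_equal(s$n_bct1_absent, 4L)
  expect_equal(s$n_beta_ca, 6L)
  # NDH-complex genes other than cupA: identity 50.4-64.7
  ndh <- identity_range(m, c("ndhD4", "ndhF4", "cupB", "ndhD3", "ndhF3"))
  expect_equal(unname(ndh["min"]), 50.4)
  expect_equal(unname(ndh["max"]), 64.7)
  # cupA homology is uniformly high
  expect_gte(unname(identity_range(m, "cupA")["min"]), 70)
  # rbcL highly conserved, ccmN weakly
  expect_gt(unname(identity_range(m, "rbcL")["min"]), 83)
  expect_lt(unname(identity_range(m, "ccmN")["max"]), 40)
})

test_that("the gamma-CA domain check separates active from inactive", {
  cfg <- gamma_ca_config()
  refs <- make_gamma_refs(seed = 9, config = cfg)
  act_v <- gamma_ca_check(refs$active, refs$active, refs$inactive, cfg)
  expect_equal(act_v$verdict, "active-like")
  expect_true(act_v$cysteines_present)
  expect_equal(act_v$matched_positions, act_v$n_positions)
  inact_v <- gamma_ca_check(refs$inactive, refs$active, refs$inactive, cfg)
  expect_equal(inact_v$verdict, "inactive-like")
  expect_error(gamma_ca_check("MKVLAAAGHP", refs$active,
                              refs$inactive, cfg),
               "shorter than the domain window")
})

test_that("the CA complement flags ccmM compensation candidates", {
  cb <- load_fixture("carboxysome")
  cfg <- gamma_ca_config()
  refs <- make_gamma_refs(seed = 9, config = cfg)
  active <- gamma_ca_check(refs$active, refs$active, refs$inactive, cfg)
  inactive <- gamma_ca_check(refs$inactive, refs$active, refs$inactive, cfg)
  # BP-1-like: no ccaA, active-like ccmM -> compensation candidate
  bp1 <- matrix_row(cb, "Thermosynechococcus BP-1")
  r <- ca_complement(bp1, active)
  expect_true(r$ccm_m_compensation_candidate)
  # ccaA present -> not flagged even with active ccmM
  a121 <- matrix_row(cb, "Leptodesmis A121")
  r2 <- ca_complement(a121, active)
  expect_false(r2$ccm_m_compensation_candidate)
  expect_true("ccaA" %in% r2$cas_present)
  # nothing present, inactive ccmM -> no CA detected
  none <- setNames(rep(FALSE, 4), c("ccaA", "ecaB", "ecaA", "ccmM"))
  r3 <- ca_complement(none, inactive)
  expect_equal(r3$note, "no CA detected")
})
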