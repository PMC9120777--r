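# Local alignment engine against independent oracles.

test_that("self-alignment is perfect", {
  r <- align_local("ACDEFGH", "ACDEFGH")
  expect_equal(r$identity_pct, 100)
  expect_equal(r$cov_a, 100)
  expect_equal(r$cov_b, 100)
  expect_equal(r$n_columns, 7L)
})

test_that("classic pair matches the brute-force dynamic program", {
  s <- oracle_local_score("HEAGAWGHEE", "PAWHEAE")
  r <- align_local("HEAGAWGHEE", "PAWHEAE")
  expect_equal(r$score, s)
  expect_equal(r$score, 17)  # frozen from the oracle
})

test_that("all-mismatch DNA pair yields an empty alignment", {
  r <- align_local("AAAA", "TTTT", scoring_scheme("DNA"))
  expect_equal(r$score, 0)
  expect_equal(r$n_columns, 0L)
  expect_true(is.na(r$identity_pct))
})

test_that("engine equals the brute-force oracle on random small pairs", {
  scheme <- scoring_scheme()
  alpha <- c("A", "C", "D", "E")
  set.seed(11)
  for (k in 1:300) {
    a <- random_seq(sample(1:8, 1), alpha)
    b <- random_seq(sample(1:8, 1), alpha)
    expect_equal(align_local(a, b, scheme)$score,
                 oracle_local_score(a, b, scheme),
                 info = paste(a, b))
  }
})

test_that("engine equals Biostrings on longer random pairs", {
  scheme <- scoring_scheme()
  alpha <- setdiff(scheme$alphabet, "X")
  set.seed(12)
  for (k in 1:100) {
    a <- random_seq(sample(10:60, 1), alpha)
    b <- random_seq(sample(10:60, 1), alpha)
    expect_equal(align_local(a, b, scheme)$score,
                 biostrings_local_score(a, b, scheme),
                 info = paste(a, b))
  }
})

test_that("score is symmetric for symmetric matrices", {
  set.seed(13)
  alpha <- setdiff(scoring_scheme()$alphabet, "X")
  for (k in 1:50) {
    a <- random_seq(sample(5:30, 1), alpha)
    b <- random_seq(sample(5:30, 1), alpha)
    expect_equal(align_local(a, b)$score, align_local(b, a)$score)
  }
})

test_that("appending identical residues never decreases the score", {
  set.seed(14)
  alpha <- setdiff(scoring_scheme()$alphabet, "X")
  for (k in 1:30) {
    a <- random_seq(sample(5:20, 1), alpha)
    b <- random_seq(sample(5:20, 1), alpha)
    ext <- random_seq(5, alpha)
    expect_gte(align_local(paste0(a, ext), paste0(b, ext))$score,
               align_local(a, b)$score)
  }
})

test_that("the ambiguity residue X scores zero against everything", {
  r <- align_local("MKVLX", "MKVLW")
  # X-W column contributes 0, so score is the MKVL prefix score
  expect_equal(r$score, align_local("MKVL", "MKVL")$score)
})

test_that("input validation rejects unusable sequences", {
  expect_error(align_local("", "MKV"), "nonempty")
  expect_error(align_local("MKV", "MK1"), "alphabet")
})

test_that("E-value follows the Karlin-Altschul closed form", {
  sch <- scoring_scheme()
  expect_equal(alignment_evalue(0, 100, 200, sch),
               sch$k_ka * 100 * 200)
  # linear in each length
  expect_equal(alignment_evalue(50, 200, 300, sch),
               2 * alignment_evalue(50, 100, 300, sch))
  # strictly decreasing in score
  e <- vapply(0:100, alignment_evalue, numeric(1), len_a = 400,
              len_b = 400, scheme = sch)
  expect_true(all(diff(e) < 0))
  # the 1e-6 threshold on a 400x400 search space falls between the
  # hand-computed bracketing scores: ln(K*m*n/1e-6)/lambda = 84.67
  expect_gt(alignment_evalue(84, 400, 400, sch), 1e-6)
  expect_lt(alignment_evalue(85, 400, 400, sch), 1e-6)
  expect_error(alignment_evalue(10, 0, 5, sch), "positive")
  expect_error(alignment_evalue(-1, 5, 5, sch), "non-negative")
})

test_that("identity and coverage arithmetic is exact", {
  # construct a 50-residue query aligned over its first 35 residues
  set.seed(15)
  core <- random_seq(35, setdiff(scoring_scheme()$alphabet, "X"))
  query <- paste0(core, strrep("P", 15))
  subject <- core
  r <- align_local(query, subject)
  st <- identity_and_coverage(r)
  expect_equal(unname(st["cov_a"]), 70)
  expect_equal(unname(st["identity_pct"]), 100)
  empty <- align_local("AAAA", "TTTT", scoring_scheme("DNA"))
  expect_error(identity_and_coverage(empty), "zero aligned columns")
})

test_that("scoring scheme invariants are enforced", {
  expect_error(scoring_scheme(gap_open = -1, gap_extend = -5))
  expect_error(scoring_scheme(lambda_ka = -1))
  sch <- scoring_scheme()
  expect_equal(sch$matrix["X", "W"], 0L)
  expect_equal(sch$matrix["A", "A"], 4L)
})
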