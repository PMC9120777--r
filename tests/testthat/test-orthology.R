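# Bidirectional best-hit ortholog detection.

test_that("an exact copy in the target is the best hit at 100% identity", {
  rs <- test_refset()
  target <- proteome(c(copy = rs$proteome$seqs[["rbcL"]],
                       junk = random_protein(200, seed = 2)),
                     strain = "t")
  h <- best_hit(rs$proteome$seqs[["rbcL"]], target)
  expect_equal(h$subject_id, "copy")
  expect_equal(h$identity_pct, 100)
})

test_that("hits below the identity or coverage thresholds are discarded", {
  rs <- test_refset()
  q <- rs$proteome$seqs[["rbcL"]]
  # a ~20% identity mutant passes nothing at the 30% threshold
  far <- mutate_protein(q, 20, seed = 3)
  expect_null(best_hit(q, proteome(c(m = far), strain = "t")))
  # a 80% mutant passes, but not if we demand 90% identity
  near <- mutate_protein(q, 80, seed = 4)
  tgt <- proteome(c(m = near), strain = "t")
  expect_false(is.null(best_hit(q, tgt)))
  expect_null(best_hit(q, tgt, thresholds = bbh_thresholds(identity = 90)))
  # a short fragment fails the 70% query-coverage rule
  frag <- substr(q, 1, ceiling(nchar(q) * 0.4))
  expect_null(best_hit(q, proteome(c(f = frag), strain = "t")))
})

test_that("score ties break to the lexicographically smaller subject id", {
  rs <- test_refset()
  q <- rs$proteome$seqs[["rbcL"]]
  tgt1 <- proteome(c(zeta = q, alpha = q), strain = "t")
  tgt2 <- proteome(c(alpha = q, zeta = q), strain = "t")
  expect_equal(best_hit(q, tgt1)$subject_id, "alpha")
  expect_equal(best_hit(q, tgt2)$subject_id, "alpha")
})

test_that("a proteome of exact reference copies is fully recovered", {
  rs <- test_refset()
  p <- proteome(setNames(unname(rs$proteome$seqs),
                         paste0("c_", rs$symbols)), strain = "t")
  calls <- bidirectional_best_hits(rs, p)
  expect_true(all(calls$present))
  expect_true(all(calls$identity_pct == 100))
})

test_that("decoy-only proteomes produce no calls", {
  rs <- test_refset()
  p <- generate_proteome(rs, plants = NULL, n_decoys = 30, seed = 5)
  calls <- profile_strain(p, rs)
  expect_false(any(calls$present))
})

test_that("asymmetric best hits are rejected by the reciprocity check", {
  # the strain protein is closer to refA than to refB, but refB's best
  # strain hit is that same protein: (refB, p) must not be called
  base <- random_protein(200, seed = 6)
  refA <- base
  refB <- mutate_protein(base, 70, seed = 7)
  manifest <- data.frame(symbol = c("rbcL", "rbcS"),
                         locus_tag = c("t1", "t2"), organism = "syn")
  rs <- reference_set(proteome(c(rbcL = refA, rbcS = refB),
                               strain = "ref"), manifest)
  p <- proteome(c(p1 = mutate_protein(base, 90, seed = 8)), strain = "s")
  calls <- bidirectional_best_hits(rs, p)
  expect_true(calls$present[calls$gene_symbol == "rbcL"])
  expect_false(calls$present[calls$gene_symbol == "rbcS"])
})

test_that("missing plants are reported absent, others present", {
  rs <- test_refset(symbols = c("cmpA", "cmpB", "cmpC", "cmpD",
                                "rbcL", "sbtA"))
  plants <- do.call(rbind, lapply(c("rbcL", "sbtA"), plant_spec,
                                  target_identity_pct = 80))
  p <- generate_proteome(rs, plants, n_decoys = 10, seed = 9)
  calls <- profile_strain(p, rs)
  pres <- setNames(calls$present, calls$gene_symbol)
  expect_true(all(pres[c("rbcL", "sbtA")]))
  expect_false(any(pres[c("cmpA", "cmpB", "cmpC", "cmpD")]))
})

test_that("BBH pairing is symmetric in the two proteomes", {
  # collect RBH pairs in both orders via the AAI machinery and compare
  rs <- test_refset()
  for (seed in 1:3) {
    plants <- do.call(rbind, lapply(rs$symbols, plant_spec,
                                    target_identity_pct = 70))
    p <- generate_proteome(rs, plants, n_decoys = 5, seed = seed)
    ab <- aai(rs$proteome, p)$pairs
    ba <- aai(p, rs$proteome)$pairs
    expect_setequal(paste(ab$id_a, ab$id_b),
                    paste(ba$id_b, ba$id_a))
  }
})

test_that("raising thresholds never increases the number of calls", {
  rs <- test_refset()
  plants <- rbind(plant_spec("rbcL", 85), plant_spec("rbcS", 60),
                  plant_spec("ccmM", 45), plant_spec("sbtA", 35))
  p <- generate_proteome(rs, plants, n_decoys = 10, seed = 10)
  n_calls <- function(th) sum(bidirectional_best_hits(rs, p,
                                                      thresholds = th)$present)
  ids <- vapply(c(30, 40, 50, 60, 70, 90),
                function(x) n_calls(bbh_thresholds(identity = x)),
                numeric(1))
  expect_true(all(diff(ids) <= 0))
  covs <- vapply(c(50, 70, 90, 99),
                 function(x) n_calls(bbh_thresholds(coverage = x)),
                 numeric(1))
  expect_true(all(diff(covs) <= 0))
})

test_that("the reference manifest covers the 29 symbols", {
  m <- ccm_reference_manifest()
  expect_equal(nrow(m), 29L)
  expect_false(anyDuplicated(m$symbol) > 0)
  expect_false(anyDuplicated(m$locus_tag) > 0)
  expect_equal(m$locus_tag[m$symbol == "ccmM"], "sll1031")
  expect_equal(m$organism[m$symbol == "ecaA"], "Anabaena sp. PCC 7120")
  # reference sets can be keyed by locus tag as well as symbol
  seqs <- setNames(c(random_protein(100, 1), random_protein(100, 2)),
                   c("sll1031", "rbcL"))
  rs <- reference_set(proteome(seqs))
  expect_setequal(rs$symbols, c("ccmM", "rbcL"))
})
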