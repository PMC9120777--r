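# Locus clustering and classification of the carboxysome gene neighborhood.

mcl_syms <- c("ccmK2", "ccmK1", "ccmL", "ccmM", "ccmN")

test_that("an adjacent MCL layout clusters into a single labeled locus", {
  g <- generate_annotated_genome(
    list(locus_layout("MCL", c(mcl_syms, "ccmO")),
         locus_layout("sat", "ccmP")),
    contig_length = 60000, seed = 1)
  cl <- cluster_loci(g$annotation)
  labels <- vapply(cl, `[[`, character(1), "label")
  expect_equal(labels, c("MCL", "satellite:ccmP"))
  expect_equal(nrow(cl[[1]]$genes), 6L)
  expect_equal(cl[[1]]$span_bp,
               max(cl[[1]]$genes$end) - min(cl[[1]]$genes$start))
})

test_that("a gap of max_gap_bp + 1 splits a locus", {
  mk <- function(gap) {
    feats <- data.frame(
      gene_id = c("g1", "g2"), symbol = c("ccmK3", "ccmK4"),
      contig = "chr1", start = c(0L, 600L + gap),
      end = c(600L, 1200L + gap), strand = 1L)
    genome_annotation(feats, c(chr1 = 50000L), strain = "s")
  }
  joined <- cluster_loci(mk(5000L), max_gap_bp = 5000L)
  expect_length(joined, 1L)
  expect_equal(joined[[1]]$label, "satellite:ccmK3K4")
  split <- cluster_loci(mk(5001L), max_gap_bp = 5000L)
  expect_length(split, 2L)
})

test_that("intervening non-CCM genes beyond the limit split a locus", {
  feats <- data.frame(
    gene_id = paste0("g", 1:5),
    symbol = c("rbcL", NA, NA, NA, "rbcS"),
    contig = "chr1",
    start = c(0L, 700L, 1400L, 2100L, 2800L),
    end = c(600L, 1300L, 2000L, 2700L, 3400L),
    strand = 1L)
  ann <- genome_annotation(feats, c(chr1 = 10000L), strain = "s")
  expect_length(cluster_loci(ann, max_intervening = 3L), 1L)
  expect_length(cluster_loci(ann, max_intervening = 2L), 2L)
})

test_that("classification covers every locus type", {
  cl <- function(syms) {
    feats <- data.frame(
      gene_id = paste0("g", seq_along(syms)), symbol = syms,
      contig = "c", start = seq(0L, by = 800L, length.out = length(syms)),
      end = seq(600L, by = 800L, length.out = length(syms)), strand = 1L)
    structure(list(strain = "s", contig = "c", genes = feats,
                   span_bp = max(feats$end), label = NA),
              class = "locus_cluster")
  }
  expect_equal(classify_locus(cl(c("rbcL", "rbcX", "rbcS"))), "rubisco")
  expect_equal(classify_locus(cl(c("ccmK3", "ccmK4"))), "satellite:ccmK3K4")
  expect_equal(classify_locus(cl("ccmO")), "satellite:ccmO")
  expect_equal(classify_locus(cl("ccmP")), "satellite:ccmP")
  expect_equal(classify_locus(cl(c(mcl_syms, "ccmO"))), "MCL")
  expect_equal(classify_locus(cl(c("ccmK1", "ccmL", "ccmM", "ccmN"))),
               "MCL")  # one ccmK1/2 suffices
  expect_equal(classify_locus(cl(c("ndhD3", "ndhF3", "cupA"))),
               "ci-uptake:NDH-1_3")
  expect_equal(classify_locus(cl(c("cmpA", "cmpB", "cmpC", "cmpD"))),
               "ci-uptake:BCT1")
  expect_equal(classify_locus(cl(c("ccmL", "rbcL"))), "other")
})

test_that("MCL reports capture ccmO placement and satellites", {
  with_o <- generate_annotated_genome(
    list(locus_layout("MCL", c(mcl_syms, "ccmO")),
         locus_layout("sat", "ccmP")), contig_length = 60000, seed = 2)
  r <- mcl_report(cluster_loci(with_o$annotation))
  expect_true(r$has_mcl && r$ccmo_in_mcl && r$ccmo_terminal)
  expect_equal(r$satellites, "satellite:ccmP")
  # Thermosynechococcus-like pattern: satellite ccmO away from the MCL
  without_o <- generate_annotated_genome(
    list(locus_layout("MCL", mcl_syms),
         locus_layout("satO", "ccmO"),
         locus_layout("satP", "ccmP")), contig_length = 80000, seed = 3)
  r2 <- mcl_report(cluster_loci(without_o$annotation))
  expect_true(r2$has_mcl && !r2$ccmo_in_mcl && !r2$ccmo_terminal)
  expect_setequal(r2$satellites, c("satellite:ccmO", "satellite:ccmP"))
  # no ccm genes at all
  empty <- generate_annotated_genome(list(), contig_length = 10000, seed = 4)
  expect_length(cluster_loci(empty$annotation), 0L)
  expect_false(mcl_report(list())$has_mcl)
})

test_that("clustering is invariant to feature input order", {
  g <- generate_annotated_genome(
    list(locus_layout("MCL", c(mcl_syms, "ccmO")),
         locus_layout("rub", c("rbcL", "rbcX", "rbcS"))),
    contig_length = 60000, seed = 5)
  ann <- g$annotation
  shuffled <- ann
  set.seed(6)
  shuffled$features <- shuffled$features[sample(nrow(shuffled$features)), ]
  shuffled <- genome_annotation(shuffled$features, ann$contig_lengths,
                                strain = ann$strain)
  expect_equal(vapply(cluster_loci(shuffled), `[[`, character(1), "label"),
               vapply(cluster_loci(ann), `[[`, character(1), "label"))
})

test_that("tightening max_gap_bp never merges clusters", {
  g <- generate_annotated_genome(
    list(locus_layout("MCL", c(mcl_syms, "ccmO"), gap_bp = c(100, 2000,
                                                             150, 3000, 120)),
         locus_layout("sat", c("ccmK3", "ccmK4"), gap_bp = 900)),
    contig_length = 80000, seed = 7)
  n_at <- function(gap) length(cluster_loci(g$annotation, max_gap_bp = gap))
  counts <- vapply(c(5000L, 2500L, 1000L, 500L, 50L), n_at, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("planted layouts are recovered across random battery seeds", {
  templates <- list(
    list(lab = "MCL", layout = locus_layout("m", c(mcl_syms, "ccmO"))),
    list(lab = "MCL", layout = locus_layout("m", mcl_syms)),
    list(lab = "rubisco", layout = locus_layout("r", c("rbcL", "rbcX",
                                                       "rbcS"))),
    list(lab = "satellite:ccmP", layout = locus_layout("p", "ccmP")),
    list(lab = "satellite:ccmK3K4",
         layout = locus_layout("k", c("ccmK3", "ccmK4"))),
    list(lab = "satellite:ccmO", layout = locus_layout("o", "ccmO")),
    list(lab = "ci-uptake:NDH-1_3",
         layout = locus_layout("n", c("ndhD3", "ndhF3", "cupA"))),
    list(lab = "ci-uptake:Sbt", layout = locus_layout("s", c("sbtA",
                                                             "sbtB"))))
  for (seed in 1:20) {
    set.seed(seed)
    picked <- templates[sample(length(templates), 4)]
    gaps <- sample(50:2000, 1)
    loci <- lapply(picked, function(t) {
      l <- t$layout; l$gap_bp <- rep_len(gaps, length(l$gap_bp)); l
    })
    g <- generate_annotated_genome(loci, contig_length = 200000,
                                   locus_spacing_bp = 15000, seed = seed)
    got <- vapply(cluster_loci(g$annotation), `[[`, character(1), "label")
    expect_equal(got, vapply(picked, `[[`, character(1), "lab"),
                 info = paste("seed", seed))
  }
})
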