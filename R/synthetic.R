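#' Seeded synthetic data generators
#'
#' Everything the pipeline consumes can be generated in-process: proteomes
#' with planted orthologs at controlled identity plus unrelated decoys,
#' genome pairs at controlled nucleotide divergence, and annotated toy
#' genomes with planted CCM locus layouts.  All generators are
#' deterministic given their seed and leave the caller's RNG state
#' untouched.  The protein substitution model is uniform over the 19
#' non-identical residues (not score-matrix biased); achieved identity is
#' therefore verified by alignment where it matters.
#'
#' @name synthetic_data
NULL

#' Random protein sequence
#'
#' @param n Length in residues.
#' @param seed Integer seed (optional).
#' @return Amino-acid string of length \code{n}, uniform over the 20
#'   standard residues.
#' @export
random_protein <- function(n, seed = NULL) {
  .with_seed(seed, paste(sample(.AA20, n, replace = TRUE), collapse = ""))
}

#' Mutate a protein toward a target percent identity
#'
#' Substitutes exactly \code{ceiling((1 - target/100) * nchar(seq))}
#' positions, chosen uniformly; each replacement residue is drawn uniformly
#' from the 19 residues different from the original.  Because local
#' alignment measures identity over aligned columns, the achieved
#' alignment identity sits within a few points of the target.
#'
#' @param seq Amino-acid string of length >= 20.
#' @param target_identity_pct Target identity in (0, 100].
#' @param seed Integer seed.
#' @return Mutated sequence of the same length.
#' @export
mutate_protein <- function(seq, target_identity_pct, seed = NULL) {
  n <- nchar(seq)
  if (n < 20) stop("sequence too short to mutate meaningfully (< 20 aa)")
  if (target_identity_pct <= 0 || target_identity_pct > 100)
    stop("target identity must be in (0, 100]")
  n_sub <- ceiling((1 - target_identity_pct / 100) * n)
  if (n_sub == 0) return(seq)
  .with_seed(seed, {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    pos <- sample.int(n, n_sub)
    for (p in pos)
      chars[p] <- sample(setdiff(.AA20, chars[p]), 1)
    paste(chars, collapse = "")
  })
}

#' Specification of one planted ortholog
#'
#' @param gene_symbol Reference symbol to plant.
#' @param target_identity_pct Target identity in (0, 100].
#' @param coverage_fraction Fraction of the reference length retained
#'   (a central slice), in (0, 1].
#' @return A one-row data frame.
#' @export
plant_spec <- function(gene_symbol, target_identity_pct = 80,
                       coverage_fraction = 1) {
  stopifnot(target_identity_pct > 0, target_identity_pct <= 100,
            coverage_fraction > 0, coverage_fraction <= 1)
  data.frame(gene_symbol = gene_symbol,
             target_identity_pct = target_identity_pct,
             coverage_fraction = coverage_fraction,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic strain proteome with planted orthologs
#'
#' One mutated copy of the reference sequence per plant spec (optionally a
#' central slice, to exercise coverage filtering) plus \code{n_decoys}
#' random sequences with lengths uniform over [0.5, 1.5] times the mean
#' reference length.  Record order is shuffled deterministically; the
#' mapping from planted symbol to record id is attached as
#' \code{attr(, "truth")}.
#'
#' @param refset A \code{\link{reference_set}}.
#' @param plants Data frame of \code{\link{plant_spec}} rows (may be
#'   empty).
#' @param n_decoys Number of decoy proteins (>= 0).
#' @param seed Integer seed.
#' @param strain Strain tag.
#' @return A \code{\link{proteome}} with a \code{truth} attribute.
#' @export
generate_proteome <- function(refset, plants = NULL, n_decoys = 10,
                              seed = 1, strain = "synthetic") {
  if (n_decoys < 0) stop("n_decoys must be >= 0")
  if (is.null(plants))
    plants <- data.frame(gene_symbol = character(0),
                         target_identity_pct = numeric(0),
                         coverage_fraction = numeric(0),
                         stringsAsFactors = FALSE)
  .with_seed(seed, {
    seqs <- character(0)
    truth <- data.frame(gene_symbol = character(0), id = character(0),
                        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(plants))) {
      sym <- plants$gene_symbol[i]
      if (!sym %in% refset$symbols)
        stop("plant symbol not in reference set: ", sym)
      ref <- refset$proteome$seqs[[sym]]
      keep <- round(plants$coverage_fraction[i] * nchar(ref))
      lo <- max(1, floor((nchar(ref) - keep) / 2) + 1)
      sliced <- substr(ref, lo, lo + keep - 1)
      mut <- mutate_protein(sliced, plants$target_identity_pct[i],
                            seed = NULL)
      id <- sprintf("p%04d", length(seqs) + 1L)
      seqs[id] <- mut
      truth <- rbind(truth, data.frame(gene_symbol = sym, id = id,
                                       stringsAsFactors = FALSE))
    }
    mean_len <- if (length(refset$symbols))
      mean(nchar(refset$proteome$seqs)) else 300
    for (j in seq_len(n_decoys)) {
      len <- max(20L, as.integer(round(runif(1, 0.5, 1.5) * mean_len)))
      id <- sprintf("p%04d", length(seqs) + 1L)
      seqs[id] <- paste(sample(.AA20, len, replace = TRUE), collapse = "")
    }
    ord <- sample.int(length(seqs))
    p <- proteome(seqs[ord], strain = strain)
    truth$id_new <- truth$id  # ids are stable; only record order shuffles
    attr(p, "truth") <- truth[, c("gene_symbol", "id")]
    p
  })
}

#' Generate a synthetic reference set
#'
#' Random reference sequences for a chosen subset of the CCM manifest
#' symbols; used by tests and examples in place of user-downloaded
#' reference FASTA.
#'
#' @param symbols Symbols to include (default: all 29).
#' @param length_range Residue-length range to draw from.
#' @param seed Integer seed.
#' @return A \code{\link{reference_set}}.
#' @export
generate_reference_set <- function(symbols = ccm_reference_manifest()$symbol,
                                   length_range = c(150L, 450L), seed = 1) {
  .with_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]),
                   length(symbols), replace = TRUE)
    seqs <- setNames(vapply(lens, function(n)
      paste(sample(.AA20, n, replace = TRUE), collapse = ""),
      character(1)), symbols)
    reference_set(proteome(seqs, strain = "reference"))
  })
}

#' Generate a diverged genome pair
#'
#' Genome B is genome A with i.i.d. substitutions at the given rate
#' (replacement base always differs from the original), mimicking two
#' related genomes at a controlled average nucleotide divergence.
#'
#' @param length_bp Genome length (>= 10x the ANI fragment size is
#'   sensible).
#' @param substitution_rate Per-site substitution probability in [0, 0.5].
#' @param seed Integer seed.
#' @return List with \code{a} and \code{b} (named character vectors of one
#'   contig each) and \code{n_substitutions}.
#' @export
generate_genome_pair <- function(length_bp, substitution_rate, seed = 1) {
  if (substitution_rate < 0 || substitution_rate > 0.5)
    stop("substitution_rate must be in [0, 0.5]")
  bases <- c("A", "C", "G", "T")
  .with_seed(seed, {
    a <- sample(bases, length_bp, replace = TRUE)
    hit <- runif(length_bp) < substitution_rate
    b <- a
    if (any(hit)) {
      idx <- which(hit)
      for (i in idx) b[i] <- sample(setdiff(bases, a[i]), 1)
    }
    list(a = c(chrA = paste(a, collapse = "")),
         b = c(chrB = paste(b, collapse = "")),
         n_substitutions = sum(hit))
  })
}

#' Describe one planted locus for a toy genome
#'
#' @param label Free-text label recorded with the locus (e.g. "MCL").
#' @param symbols Ordered CCM gene symbols.
#' @param gap_bp Intergenic gap(s) within the locus, bp (recycled).
#' @param strand +1 or -1 (recycled).
#' @param gene_len Gene length(s) in bp (recycled).
#' @return A list of class \code{locus_layout}.
#' @export
locus_layout <- function(label, symbols, gap_bp = 150L, strand = 1L,
                         gene_len = 600L) {
  stopifnot(length(symbols) >= 1, all(gap_bp >= 0))
  structure(list(label = label, symbols = symbols,
                 gap_bp = rep_len(gap_bp, max(1, length(symbols) - 1)),
                 strand = rep_len(strand, length(symbols)),
                 gene_len = rep_len(gene_len, length(symbols))),
            class = "locus_layout")
}

#' Generate an annotated toy genome with planted CCM loci
#'
#' Loci are placed left to right with large inter-locus spacers
#' (\code{locus_spacing_bp}), separated within a locus by the configured
#' intergenic gaps; the rest of the contig is random filler sequence.
#' Re-reading the written GFF3/FASTA pair through
#' \code{\link{read_genome_annotation}} reproduces the layout exactly.
#'
#' @param loci List of \code{\link{locus_layout}} objects.
#' @param contig_length Contig length in bp.
#' @param locus_spacing_bp Distance between consecutive loci (bp).
#' @param seed Integer seed.
#' @param strain Strain tag.
#' @return List with \code{annotation} (a \code{genome_annotation}),
#'   \code{genome} (named character vector) and \code{planted} (data frame
#'   of locus labels and symbols).
#' @export
generate_annotated_genome <- function(loci, contig_length = 100000L,
                                      locus_spacing_bp = 20000L,
                                      seed = 1, strain = "synthetic") {
  .with_seed(seed, {
    pos <- 1000L
    feats <- list()
    planted <- list()
    gid <- 0L
    for (locus in loci) {
      start_pos <- pos
      for (k in seq_along(locus$symbols)) {
        gid <- gid + 1L
        len <- locus$gene_len[k]
        feats[[gid]] <- data.frame(
          gene_id = sprintf("gene%04d", gid),
          symbol = locus$symbols[k],
          contig = "chr1",
          start = pos, end = pos + len,
          strand = locus$strand[k],
          stringsAsFactors = FALSE)
        pos <- pos + len +
          if (k < length(locus$symbols)) locus$gap_bp[k] else 0L
      }
      planted[[length(planted) + 1L]] <-
        data.frame(label = locus$label,
                   symbols = paste(locus$symbols, collapse = ","),
                   start = start_pos, stringsAsFactors = FALSE)
      pos <- pos + locus_spacing_bp
    }
    if (pos > contig_length)
      stop("loci overflow the contig (need > ", pos, " bp)")
    features <- if (length(feats)) do.call(rbind, feats) else
      data.frame(gene_id = character(0), symbol = character(0),
                 contig = character(0), start = integer(0),
                 end = integer(0), strand = integer(0),
                 stringsAsFactors = FALSE)
    genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), contig_length,
                                    replace = TRUE), collapse = ""))
    ann <- if (nrow(features))
      genome_annotation(features, c(chr1 = contig_length), strain = strain)
    else structure(list(strain = strain, features = features,
                        contig_lengths = c(chr1 = contig_length)),
                   class = "genome_annotation")
    list(annotation = ann, genome = genome,
         planted = if (length(planted)) do.call(rbind, planted) else NULL)
  })
}
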