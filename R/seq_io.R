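#' Protein sets and genome annotations
#'
#' The internal data model is deliberately small: a \code{proteome} is a
#' named character vector of uppercase amino-acid strings plus a strain
#' tag; a \code{genome_annotation} is a sorted feature table with 0-based
#' half-open coordinates plus contig lengths.  FASTA parsing goes through
#' Biostrings and GFF3 parsing through rtracklayer; the GFF3 1-based
#' inclusive convention is converted at the I/O boundary only.
#'
#' @name seq_io
NULL

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a proteome
#'
#' @param seqs Named character vector of amino-acid sequences (20 standard
#'   residues plus X; lowercase is accepted and uppercased).
#' @param strain Strain tag.
#' @param desc Optional named character vector of record descriptions.
#' @return An object of class \code{proteome}.
#' @export
proteome <- function(seqs, strain = "unknown", desc = NULL) {
  if (length(seqs) == 0) stop("a proteome needs at least one record")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every record needs a nonempty id")
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate record id: ", dup)
  }
  seqs <- toupper(seqs)
  bad <- grepl(paste0("[^", paste(c(.AA20, "X"), collapse = ""), "]"), seqs)
  if (any(bad))
    stop("non-amino-acid characters in record(s): ",
         paste(head(ids[bad], 3), collapse = ", "))
  if (any(grepl("\\s", seqs))) stop("whitespace in residues")
  structure(list(strain = strain, ids = ids,
                 seqs = setNames(as.character(seqs), ids),
                 desc = desc),
            class = "proteome")
}

#' @export
length.proteome <- function(x) length(x$seqs)

#' @export
print.proteome <- function(x, ...) {
  cat(sprintf("proteome '%s': %d proteins (median length %d aa)\n",
              x$strain, length(x$seqs), as.integer(stats::median(nchar(x$seqs)))))
  invisible(x)
}

#' Read a protein FASTA file into a proteome
#'
#' @param path FASTA file.
#' @param strain Strain tag (defaults to the file name without extension).
#' @return A \code{\link{proteome}}.
#' @export
read_protein_fasta <- function(path, strain = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("no FASTA records in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  if (anyDuplicated(ids))
    stop("duplicate record id: ", ids[duplicated(ids)][1])
  if (is.null(strain)) strain <- sub("\\.[^.]*$", "", basename(path))
  proteome(setNames(toupper(as.character(set)), ids), strain = strain,
           desc = setNames(desc, ids))
}

#' Read a nucleotide FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences (one per contig).
#' @export
read_nucleotide_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate record id: ", ids[duplicated(ids)][1])
  setNames(toupper(as.character(set)), ids)
}

#' Write sequences as wrapped FASTA
#'
#' Writes 60-column FASTA re-readable by the readers above.  Ids containing
#' whitespace are truncated at the first whitespace with a warning (FASTA
#' convention).
#'
#' @param x A \code{proteome} or a named character vector of sequences.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "proteome")) x$seqs else x
  if (length(seqs) == 0) stop("nothing to write")
  ids <- names(seqs)
  if (is.null(ids)) stop("sequences must be named")
  if (any(grepl("\\s", ids))) {
    warning("ids containing whitespace truncated at first whitespace")
    ids <- sub("\\s.*$", "", ids)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
  invisible(path)
}

# symbol synonyms applied when reading annotations (historical gene names)
.default_symbol_synonyms <- c(chpY = "cupA", chpX = "cupB")

#' Known CCM gene symbols, in reporting order
#'
#' The Ci-uptake block (NDH-1_4, NDH-1_3, BicA, Sbt, BCT1 subunits)
#' followed by the carboxysome block (shell proteins, Rubisco, carbonic
#' anhydrases) and the alpha-CA \code{ecaA}.
#'
#' @return Character vector of gene symbols.
#' @export
ccm_symbols <- function() {
  c(
    # Ci uptake
    "ndhD4", "ndhF4", "cupB", "ndhD3", "ndhF3", "cupA",
    "bicA1", "bicA2", "sbtA", "sbtB", "cmpA", "cmpB", "cmpC", "cmpD",
    # carboxysome
    "ccmK1", "ccmK2", "ccmK3", "ccmK4", "ccmL", "ccmM", "ccmN", "ccmO",
    "ccmP", "rbcL", "rbcS", "rbcX", "ccaA", "ecaB",
    # alpha-CA searched separately
    "ecaA"
  )
}

#' Construct a genome annotation
#'
#' @param features Data frame with columns \code{gene_id}, \code{symbol}
#'   (NA when not a recognized CCM gene), \code{contig}, \code{start},
#'   \code{end} (0-based half-open, bp) and \code{strand} (+1/-1).
#' @param contig_lengths Named numeric vector, contig -> length in bp.
#' @param strain Strain tag.
#' @return An object of class \code{genome_annotation} with features sorted
#'   by (contig, start).
#' @export
genome_annotation <- function(features, contig_lengths, strain = "unknown") {
  need <- c("gene_id", "symbol", "contig", "start", "end", "strand")
  if (!all(need %in% names(features)))
    stop("features must have columns: ", paste(need, collapse = ", "))
  if (any(features$start < 0) || any(features$end <= features$start))
    stop("invalid feature coordinates (need 0 <= start < end)")
  if (!all(features$strand %in% c(1L, -1L)))
    stop("strand must be +1 or -1")
  unknown <- setdiff(unique(features$contig), names(contig_lengths))
  if (length(unknown))
    stop("feature on unknown contig: ", unknown[1])
  too_long <- features$end > contig_lengths[features$contig]
  if (any(too_long))
    stop("feature extends beyond its contig: ",
         features$gene_id[too_long][1])
  ord <- order(features$contig, features$start)
  features <- features[ord, , drop = FALSE]
  rownames(features) <- NULL
  structure(list(strain = strain, features = features,
                 contig_lengths = contig_lengths),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome annotation '%s': %d features on %d contig(s), %d CCM-labeled\n",
              x$strain, nrow(x$features), length(x$contig_lengths),
              sum(!is.na(x$features$symbol))))
  invisible(x)
}

#' Read a GFF3 + FASTA pair into a genome annotation
#'
#' Gene/CDS features are retained; GFF3 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention.  A CCM gene
#' symbol is attached when the \code{gene} (or \code{product}) attribute
#' matches a known symbol exactly, after applying the synonym table
#' (e.g. chpY -> cupA).
#'
#' @param gff_path GFF3 file.
#' @param fasta_path Nucleotide FASTA giving the contig sequences/lengths.
#' @param strain Strain tag.
#' @param synonyms Named character vector mapping annotation gene names to
#'   canonical CCM symbols.
#' @return A \code{\link{genome_annotation}}.
#' @export
read_genome_annotation <- function(gff_path, fasta_path, strain = NULL,
                                   synonyms = .default_symbol_synonyms) {
  contigs <- read_nucleotide_fasta(fasta_path)
  gr <- tryCatch(rtracklayer::import(gff_path, format = "gff3"),
                 error = function(e)
                   stop("malformed GFF3 (", conditionMessage(e), ")"))
  gr <- gr[as.character(gr$type) %in% c("gene", "CDS")]
  if (length(gr) == 0) stop("no gene/CDS features in ", gff_path)
  md <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(md)) as.character(md$ID) else NA_character_
  gene <- if ("gene" %in% names(md)) as.character(md$gene) else
    rep(NA_character_, length(gr))
  prod <- if ("product" %in% names(md)) as.character(md$product) else
    rep(NA_character_, length(gr))
  name <- ifelse(is.na(gene) | !nzchar(gene), prod, gene)
  canon <- ifelse(name %in% names(synonyms),
                  unname(synonyms[name]), name)
  symbol <- ifelse(canon %in% ccm_symbols(), canon, NA_character_)
  if (any(is.na(id) | !nzchar(id)))
    stop("every GFF3 feature needs an ID attribute")
  features <- data.frame(
    gene_id = id,
    symbol = symbol,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # 1-based incl -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", -1L, 1L),
    stringsAsFactors = FALSE
  )
  if (is.null(strain)) strain <- sub("\\.[^.]*$", "", basename(gff_path))
  genome_annotation(features, nchar(contigs), strain = strain)
}

#' Write a genome annotation and its sequence back to GFF3 + FASTA
#'
#' The exact inverse of \code{\link{read_genome_annotation}}: internal
#' 0-based half-open coordinates become 1-based inclusive GFF3 lines.
#'
#' @param annotation A \code{genome_annotation}.
#' @param genome Named character vector of contig sequences.
#' @param gff_path,fasta_path Output files.
#' @return Invisibly, the two paths.
#' @export
write_genome_annotation <- function(annotation, genome, gff_path,
                                    fasta_path) {
  f <- annotation$features
  attrs <- paste0("ID=", f$gene_id,
                  ifelse(is.na(f$symbol), "", paste0(";gene=", f$symbol)))
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d",
                     names(annotation$contig_lengths),
                     as.integer(annotation$contig_lengths)),
             paste(f$contig, "cyanoccm", "gene",
                   f$start + 1L, f$end, ".",
                   ifelse(f$strand < 0, "-", "+"), ".", attrs,
                   sep = "\t"))
  writeLines(lines, gff_path)
  write_fasta(genome, fasta_path)
  invisible(c(gff = gff_path, fasta = fasta_path))
}
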