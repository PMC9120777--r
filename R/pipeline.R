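#' End-to-end profiling pipeline
#'
#' Ties the stages together: ortholog detection per strain, presence
#' matrix assembly, genotype classification, locus mapping and summary
#' statistics, with deterministic outputs (TSV matrices + JSON summary).
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' All thresholds default to the conventions used throughout the package
#' (BBH at E <= 1e-6 / 30 percent identity / 70 percent query coverage;
#' POCP at 1e-5 / 40 / 50; fragment ANI at 1020 bp and 70/70 retention;
#' locus clustering at 5 kb / 2 intervening genes).  The configuration
#' round-trips losslessly through YAML.
#'
#' @param bbh A \code{\link{bbh_thresholds}} list.
#' @param scheme_name Scoring scheme name.
#' @param ani_fragment_len Fragment length for ANI, bp.
#' @param max_gap_bp,max_intervening Locus clustering thresholds.
#' @param sbt_mode Sbt completeness rule ("any" or "both").
#' @param seed Seed recorded in outputs.
#' @param out_dir Output directory or NULL for in-memory only.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(bbh = bbh_thresholds(),
                            scheme_name = "BLOSUM62",
                            ani_fragment_len = 1020L,
                            max_gap_bp = 5000L, max_intervening = 2L,
                            sbt_mode = "any",
                            seed = 1L, out_dir = NULL) {
  structure(list(bbh = unclass(bbh), scheme_name = scheme_name,
                 ani_fragment_len = as.integer(ani_fragment_len),
                 max_gap_bp = as.integer(max_gap_bp),
                 max_intervening = as.integer(max_intervening),
                 sbt_mode = sbt_mode, seed = as.integer(seed),
                 out_dir = out_dir, version = 1L),
            class = "pipeline_config")
}

#' Read/write a pipeline configuration as YAML
#'
#' @param config A \code{pipeline_config}.
#' @param path YAML file path.
#' @return \code{write_config}: the path; \code{read_config}: the
#'   configuration.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$bbh <- do.call(bbh_thresholds, x$bbh)
  x$out_dir <- x$out_dir %||% NULL
  cfg <- do.call(pipeline_config, x[setdiff(names(x), "version")])
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full CCM profile over a set of strains
#'
#' For every input strain, detects orthologs of the reference set by BBH,
#' assembles the presence/identity matrix, classifies the Ci-uptake
#' genotype, and (when an annotation is supplied) maps CCM loci.  With
#' \code{fixtures = TRUE} the packaged matrices replace the sequence
#' stage, reproducing the published characterization without any
#' sequence input.
#'
#' @param inputs List of per-strain entries, each a list with
#'   \code{proteome} (a \code{\link{proteome}} or FASTA path) and
#'   optionally \code{annotation} (a \code{\link{genome_annotation}}).
#' @param refset A \code{\link{reference_set}} (ignored in fixture mode).
#' @param config A \code{\link{pipeline_config}}.
#' @param fixtures Use the packaged matrices instead of sequence inputs.
#' @return A list of class \code{ccm_report}: \code{matrix},
#'   \code{genotypes}, \code{loci} (per strain), \code{summary},
#'   \code{config}.  When \code{config$out_dir} is set, writes
#'   \code{presence_matrix.tsv}, \code{genotypes.tsv}, \code{loci.tsv} and
#'   \code{summary.json} there.
#' @export
run_full_profile <- function(inputs = NULL, refset = NULL,
                             config = pipeline_config(),
                             fixtures = is.null(inputs)) {
  if (fixtures) {
    mat <- load_fixture_combined()
  } else {
    if (length(inputs) == 0) stop("no inputs supplied (usage error)")
    scheme <- scoring_scheme(config$scheme_name)
    thresholds <- do.call(bbh_thresholds, config$bbh)
    rows <- lapply(inputs, function(entry) {
      p <- entry$proteome
      if (is.character(p)) p <- read_protein_fasta(p, strain = entry$strain)
      profile_strain(p, refset, scheme, thresholds)
    })
    mat <- build_presence_matrix(rows)
  }

  summary <- summarize_ccm(mat, sbt_mode = config$sbt_mode)
  genotypes <- data.frame(
    strain = mat$strains,
    genotype = if (!is.null(summary$genotypes))
      unname(summary$genotypes) else NA_character_,
    stringsAsFactors = FALSE)

  loci <- list()
  if (!fixtures) {
    for (entry in inputs) {
      if (is.null(entry$annotation)) next
      cl <- cluster_loci(entry$annotation,
                         max_gap_bp = config$max_gap_bp,
                         max_intervening = config$max_intervening)
      loci[[entry$annotation$strain]] <-
        list(clusters = cl, mcl = mcl_report(cl))
    }
  }

  bundle <- structure(list(matrix = mat, genotypes = genotypes,
                           loci = loci, summary = summary,
                           config = config),
                      class = "ccm_report")
  if (!is.null(config$out_dir)) write_report(bundle, config$out_dir)
  bundle
}

#' Write a report bundle to disk
#'
#' Deterministic TSV/JSON outputs: identical inputs and configuration give
#' byte-identical files.
#'
#' @param bundle A \code{ccm_report}.
#' @param out_dir Output directory (created if missing).
#' @return \code{out_dir}, invisibly.
#' @export
write_report <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_presence_matrix(bundle$matrix,
                        file.path(out_dir, "presence_matrix.tsv"))
  write.table(bundle$genotypes, file.path(out_dir, "genotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  loci_rows <- list()
  for (strain in names(bundle$loci)) {
    for (cl in bundle$loci[[strain]]$clusters)
      loci_rows[[length(loci_rows) + 1L]] <- data.frame(
        strain = strain, contig = cl$contig, label = cl$label,
        genes = paste(cl$genes$symbol, collapse = ","),
        span_bp = cl$span_bp, stringsAsFactors = FALSE)
  }
  if (length(loci_rows))
    write.table(do.call(rbind, loci_rows), file.path(out_dir, "loci.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  s <- bundle$summary
  json <- list(n_strains = s$n_strains,
               genotype_counts = as.list(s$genotype_counts),
               n_bct1_absent = s$n_bct1_absent,
               n_beta_ca = s$n_beta_ca,
               seed = bundle$config$seed,
               config_version = bundle$config$version)
  jsonlite::write_json(json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' One-line-per-strain report summary
#'
#' @param bundle A \code{ccm_report}.
#' @return Character vector, one line per strain (stable order), plus a
#'   header; \code{"no strains"} for an empty bundle.
#' @export
summarize_report <- function(bundle) {
  mat <- bundle$matrix
  if (length(mat$strains) == 0) return("no strains")
  lines <- vapply(mat$strains, function(s) {
    row <- matrix_row(mat, s)
    geno <- bundle$genotypes$genotype[bundle$genotypes$strain == s]
    ca <- ca_complement(row)
    arch <- if (s %in% names(bundle$loci)) {
      m <- bundle$loci[[s]]$mcl
      if (m$has_mcl) paste0("MCL[", paste(m$mcl_gene_order, collapse = "-"),
                            "]")
      else "no MCL"
    } else "loci n/a"
    sprintf("%s | genotype %s | CA: %s | %s", s, geno, ca$note, arch)
  }, character(1))
  unname(lines)
}

#' @export
print.ccm_report <- function(x, ...) {
  cat(sprintf("CCM report: %d strains\n", length(x$matrix$strains)))
  print(x$summary)
  invisible(x)
}
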