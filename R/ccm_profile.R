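#' CCM characterization from ortholog calls
#'
#' Presence/identity matrices, Ci-uptake genotype classification, the
#' carbonic-anhydrase complement, and the gamma-CA-like domain assessment
#' of ccmM.
#'
#' @name ccm_profile
NULL

#' The CCM gene catalog, grouped by functional system
#'
#' @return Named list of gene-symbol vectors: the two CO2-uptake NDH-1
#'   complexes, the three bicarbonate transport systems, the carboxysome
#'   shell, Rubisco, and the carbonic anhydrases.
#' @export
ccm_systems <- function() {
  list(
    `NDH-1_3` = c("ndhD3", "ndhF3", "cupA"),
    `NDH-1_4` = c("ndhD4", "ndhF4", "cupB"),
    BicA = c("bicA1", "bicA2"),
    Sbt = c("sbtA", "sbtB"),
    BCT1 = c("cmpA", "cmpB", "cmpC", "cmpD"),
    shell = c("ccmK1", "ccmK2", "ccmK3", "ccmK4", "ccmL", "ccmM",
              "ccmN", "ccmO", "ccmP"),
    Rubisco = c("rbcL", "rbcS", "rbcX"),
    CA = c("ccaA", "ecaB", "ecaA", "ccmM")
  )
}

#' Assemble per-strain ortholog calls into a presence/identity matrix
#'
#' @param rows List of per-strain call data frames (as returned by
#'   \code{\link{profile_strain}}); all must cover the same symbol set.
#' @return An object of class \code{presence_matrix}: \code{strains},
#'   \code{symbols}, logical matrix \code{present} and numeric matrix
#'   \code{identity} (NA where absent), strains in input order.
#' @export
build_presence_matrix <- function(rows) {
  if (length(rows) == 0) stop("no rows supplied")
  symbols <- rows[[1]]$gene_symbol
  for (r in rows)
    if (!identical(sort(r$gene_symbol), sort(symbols)))
      stop("ragged rows: all strains must cover the same symbol set")
  strains <- vapply(rows, function(r) r$strain[1], character(1))
  if (anyDuplicated(strains)) stop("duplicate strain names")
  present <- matrix(FALSE, length(rows), length(symbols),
                    dimnames = list(strains, symbols))
  identity <- matrix(NA_real_, length(rows), length(symbols),
                     dimnames = list(strains, symbols))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    j <- match(symbols, r$gene_symbol)
    present[i, ] <- r$present[j]
    identity[i, ] <- ifelse(r$present[j], r$identity_pct[j], NA_real_)
  }
  structure(list(strains = strains, symbols = symbols,
                 present = present, identity = identity),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence matrix: %d strains x %d symbols (%d present cells)\n",
              length(x$strains), length(x$symbols), sum(x$present)))
  invisible(x)
}

#' Extract one strain's row from a presence matrix
#'
#' @param matrix A \code{presence_matrix}.
#' @param strain Strain name.
#' @return Call data frame for that strain (same shape as
#'   \code{\link{profile_strain}} output).
#' @export
matrix_row <- function(matrix, strain) {
  i <- match(strain, matrix$strains)
  if (is.na(i)) stop("unknown strain: ", strain)
  data.frame(gene_symbol = matrix$symbols, strain = strain,
             subject_id = NA_character_,
             identity_pct = matrix$identity[i, ],
             present = matrix$present[i, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

.row_presence <- function(row) {
  if (is.data.frame(row)) setNames(row$present, row$gene_symbol)
  else row   # already a named logical vector
}

#' Is a Ci-uptake or carboxysome system present in a strain?
#'
#' Completeness rules: the NDH-1 complexes require all three member genes;
#' BicA requires at least one of bicA1/bicA2; Sbt requires at least one of
#' sbtA/sbtB (strains carrying only the regulator sbtB group with
#' sbt-bearing strains; set \code{sbt_mode = "both"} for the strict rule);
#' BCT1, a four-subunit ABC transporter, requires all of cmpA-cmpD (a
#' partial complement is treated as absent, see \code{\link{bct1_status}}).
#'
#' @param row Per-strain call data frame or named logical vector.
#' @param system System name from \code{names(ccm_systems())}.
#' @param sbt_mode "any" (default) or "both".
#' @return Logical scalar.
#' @export
system_present <- function(row, system, sbt_mode = c("any", "both")) {
  sbt_mode <- match.arg(sbt_mode)
  systems <- ccm_systems()
  if (!system %in% names(systems)) stop("unknown system: ", system)
  pres <- .row_presence(row)
  members <- systems[[system]]
  if (!all(members %in% names(pres)))
    stop("row does not cover all genes of system ", system)
  p <- pres[members]
  switch(system,
         `NDH-1_3` = , `NDH-1_4` = , BCT1 = , Rubisco = all(p),
         BicA = any(p),
         Sbt = if (sbt_mode == "both") all(p) else any(p),
         shell = , CA = any(p))
}

#' Status of the four-subunit BCT1 transporter
#'
#' @param row Per-strain call data frame or named logical vector.
#' @return "complete", "partial" or "absent".
#' @export
bct1_status <- function(row) {
  pres <- .row_presence(row)
  p <- pres[ccm_systems()$BCT1]
  if (all(p)) "complete" else if (any(p)) "partial" else "absent"
}

#' Ci-uptake genotype of a strain
#'
#' Genotype I: both NDH-1 complexes plus BicA, Sbt and BCT1 (all five
#' Ci-uptake systems).  Genotype II: Sbt without BCT1.  Genotype III: BCT1
#' without Sbt.  Anything else is "unclassified" (the three patterns cover
#' all strains of the study dataset, but arbitrary inputs may fall
#' outside them).  The decision is a function of
#' \code{\link{system_present}} outputs only.
#'
#' @param row Per-strain call data frame or named logical vector.
#' @param sbt_mode Passed to \code{\link{system_present}}.
#' @return A list of class \code{genotype_call}: \code{strain},
#'   \code{genotype} ("I", "II", "III" or "unclassified"),
#'   \code{systems_present}.
#' @export
classify_genotype <- function(row, sbt_mode = "any") {
  strain <- if (is.data.frame(row)) row$strain[1] else NA_character_
  ci <- c("NDH-1_3", "NDH-1_4", "BicA", "Sbt", "BCT1")
  pres <- vapply(ci, function(s) system_present(row, s, sbt_mode),
                 logical(1))
  genotype <-
    if (pres[["BicA"]] && pres[["Sbt"]] && pres[["BCT1"]] &&
        pres[["NDH-1_3"]] && pres[["NDH-1_4"]]) "I"
    else if (pres[["Sbt"]] && !pres[["BCT1"]]) "II"
    else if (pres[["BCT1"]] && !pres[["Sbt"]]) "III"
    else "unclassified"
  structure(list(strain = strain, genotype = genotype,
                 systems_present = names(pres)[pres]),
            class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("%s: genotype %s [%s]\n", x$strain, x$genotype,
              paste(x$systems_present, collapse = ", ")))
  invisible(x)
}

#' Identity range over a symbol subset of a presence matrix
#'
#' @param matrix A \code{presence_matrix}.
#' @param symbols Symbols to pool (default: all).
#' @return Named numeric vector \code{min}, \code{max}, \code{mean},
#'   \code{n} over cells where the gene is present.
#' @export
identity_range <- function(matrix, symbols = matrix$symbols) {
  symbols <- intersect(symbols, matrix$symbols)
  v <- matrix$identity[, symbols, drop = FALSE]
  v <- v[!is.na(v)]
  if (!length(v)) return(c(min = NA, max = NA, mean = NA, n = 0))
  c(min = min(v), max = max(v), mean = mean(v), n = length(v))
}

#' Summary statistics of a presence matrix
#'
#' Per-symbol presence counts and identity ranges, genotype counts (when
#' the Ci-uptake symbols are covered), the number of strains lacking the
#' complete BCT1 transporter, and the number of strains carrying a beta-CA
#' (ccaA or ecaB; when those symbols are covered).
#'
#' @param matrix A \code{presence_matrix}.
#' @param sbt_mode Passed to genotype classification.
#' @return A list of class \code{ccm_summary}.
#' @export
summarize_ccm <- function(matrix, sbt_mode = "any") {
  symbol_stats <- data.frame(
    symbol = matrix$symbols,
    n_present = colSums(matrix$present),
    identity_min = suppressWarnings(apply(matrix$identity, 2, min, na.rm = TRUE)),
    identity_max = suppressWarnings(apply(matrix$identity, 2, max, na.rm = TRUE)),
    identity_mean = colMeans(matrix$identity, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  symbol_stats$identity_min[!is.finite(symbol_stats$identity_min)] <- NA
  symbol_stats$identity_max[!is.finite(symbol_stats$identity_max)] <- NA
  symbol_stats$identity_mean[!is.finite(symbol_stats$identity_mean)] <- NA

  out <- list(n_strains = length(matrix$strains),
              symbol_stats = symbol_stats)

  ci <- unlist(ccm_systems()[c("NDH-1_3", "NDH-1_4", "BicA", "Sbt", "BCT1")])
  if (all(ci %in% matrix$symbols)) {
    genos <- vapply(matrix$strains, function(s)
      classify_genotype(matrix_row(matrix, s), sbt_mode)$genotype,
      character(1))
    out$genotypes <- genos
    out$genotype_counts <- table(factor(genos, levels = c("I", "II", "III",
                                                          "unclassified")))
    bct1 <- ccm_systems()$BCT1
    out$n_bct1_absent <- sum(rowSums(matrix$present[, bct1, drop = FALSE]) == 0)
  }
  beta_ca <- c("ccaA", "ecaB")
  if (all(beta_ca %in% matrix$symbols))
    out$n_beta_ca <- sum(rowSums(
      matrix$present[, beta_ca, drop = FALSE]) > 0)
  structure(out, class = "ccm_summary")
}

#' @export
print.ccm_summary <- function(x, ...) {
  cat(sprintf("CCM summary over %d strains\n", x$n_strains))
  if (!is.null(x$genotype_counts)) {
    gc <- x$genotype_counts
    cat(sprintf("  genotypes: I=%d II=%d III=%d unclassified=%d\n",
                gc[["I"]], gc[["II"]], gc[["III"]], gc[["unclassified"]]))
    cat(sprintf("  strains lacking BCT1: %d\n", x$n_bct1_absent))
  }
  if (!is.null(x$n_beta_ca))
    cat(sprintf("  strains with a beta-CA (ccaA/ecaB): %d\n", x$n_beta_ca))
  invisible(x)
}

# coarse physicochemical residue classes used for domain-position matching
.residue_class <- function(ch) {
  classes <- c(G = "tiny", A = "tiny", S = "tiny", T = "tiny",
               C = "cys",
               V = "aliphatic", I = "aliphatic", L = "aliphatic",
               M = "aliphatic",
               F = "aromatic", Y = "aromatic", W = "aromatic",
               H = "basic", K = "basic", R = "basic",
               D = "acidic", E = "acidic", N = "amide", Q = "amide",
               P = "proline", X = "any")
  unname(classes[ch])
}

#' Default gamma-CA domain position configuration
#'
#' Curator-supplied coordinates (not taken from any printed table) on the
#' numbering of the active reference sequence: three conserved-region
#' windows in the N-terminal gamma-CA-like domain whose residues must match
#' the active reference by physicochemical class, plus two cysteines
#' required for the stabilizing disulfide bond.
#'
#' @param domain_window Length of the N-terminal domain window (aa).
#' @param conserved_positions Positions (active-reference numbering) that
#'   must match the active reference residue class.
#' @param cysteine_positions Positions that must be cysteine in the query.
#' @param min_matched Minimum matching conserved positions for an
#'   active-like verdict (default: all of them).
#' @return A list of class \code{gamma_ca_config}.
#' @export
gamma_ca_config <- function(domain_window = 200L,
                            conserved_positions = c(20:26, 60:66, 100:106),
                            cysteine_positions = c(160L, 190L),
                            min_matched = length(conserved_positions)) {
  structure(list(domain_window = as.integer(domain_window),
                 conserved_positions = as.integer(conserved_positions),
                 cysteine_positions = as.integer(cysteine_positions),
                 min_matched = as.integer(min_matched)),
            class = "gamma_ca_config")
}

# map active-reference positions to query residues through an alignment
.map_positions <- function(aln, positions) {
  # aln: query = a, active ref = b; aligned_pairs maps pos_a <-> pos_b
  pairs <- aln$aligned_pairs
  idx <- match(positions, pairs[, "pos_b"])
  pairs[idx, "pos_a"]   # NA where the position is unaligned/deleted
}

#' Assess the gamma-CA-like domain of a ccmM protein
#'
#' Aligns the N-terminal domain window of the query to the active
#' reference and checks (i) that the configured conserved-region positions
#' match the active reference by residue class and (ii) that the
#' configured disulfide cysteines are present.  The verdict is
#' "active-like" when both hold, "inactive-like" when the match count does
#' not exceed what the supplied inactive references themselves achieve (or
#' the cysteines are missing), and "indeterminate" otherwise.
#'
#' @param ccmm_seq Query ccmM amino-acid sequence.
#' @param active_ref Active-reference ccmM sequence (functional gamma-CA).
#' @param inactive_refs Character vector of sequences whose gamma-CA-like
#'   domain is known to be non-functional.
#' @param config A \code{\link{gamma_ca_config}}.
#' @param scheme A protein \code{\link{scoring_scheme}}.
#' @return A list of class \code{gamma_ca_verdict}: \code{verdict},
#'   \code{matched_positions}, \code{n_positions},
#'   \code{cysteines_present}.
#' @export
gamma_ca_check <- function(ccmm_seq, active_ref,
                           inactive_refs = character(0),
                           config = gamma_ca_config(),
                           scheme = scoring_scheme()) {
  w <- config$domain_window
  if (nchar(active_ref) < w)
    stop("active reference shorter than the domain window (", w, " aa)")
  if (nchar(ccmm_seq) < w)
    stop("sequence shorter than the domain window (", w, " aa)")
  ref_dom <- substr(active_ref, 1, w)
  score_one <- function(seq) {
    dom <- substr(seq, 1, w)
    aln <- align_local(dom, ref_dom, scheme)
    if (aln$n_columns == 0L)
      return(list(matched = 0L, cys = FALSE))
    qchars <- strsplit(toupper(dom), "")[[1]]
    rchars <- strsplit(toupper(ref_dom), "")[[1]]
    qpos <- .map_positions(aln, config$conserved_positions)
    ok <- !is.na(qpos) &
      .residue_class(qchars[ifelse(is.na(qpos), 1L, qpos)]) ==
      .residue_class(rchars[config$conserved_positions])
    cpos <- .map_positions(aln, config$cysteine_positions)
    cys <- all(!is.na(cpos)) && all(qchars[cpos] == "C")
    list(matched = sum(ok), cys = cys)
  }
  q <- score_one(ccmm_seq)
  inactive_matched <- vapply(inactive_refs,
                             function(s) score_one(s)$matched, integer(1))
  verdict <-
    if (q$cys && q$matched >= config$min_matched) "active-like"
    else if ((length(inactive_matched) &&
              q$matched <= max(inactive_matched)) || !q$cys) "inactive-like"
    else "indeterminate"
  structure(list(verdict = verdict,
                 matched_positions = q$matched,
                 n_positions = length(config$conserved_positions),
                 cysteines_present = q$cys),
            class = "gamma_ca_verdict")
}

#' Carbonic anhydrase complement of a strain
#'
#' Lists the CAs present (carboxysomal beta-CA ccaA, non-carboxysomal
#' beta-CA ecaB, alpha-CA ecaA, and the gamma-CA-like domain of ccmM) and
#' flags the strain as a ccmM-compensation candidate when ccaA is absent
#' but the ccmM gamma-CA-like domain looks active.
#'
#' @param row Per-strain call data frame or named logical vector.
#' @param gamma_verdict Optional \code{gamma_ca_verdict} for the strain's
#'   ccmM.
#' @return A list of class \code{ca_complement}: \code{cas_present},
#'   \code{ccm_m_compensation_candidate}, \code{note}.
#' @export
ca_complement <- function(row, gamma_verdict = NULL) {
  pres <- .row_presence(row)
  cas <- intersect(c("ccaA", "ecaB", "ecaA"), names(pres))
  cas <- cas[pres[cas]]
  active_ccmm <- !is.null(gamma_verdict) &&
    gamma_verdict$verdict == "active-like"
  if (active_ccmm && isTRUE(pres[["ccmM"]]))
    cas <- c(cas, "ccmM(gamma)")
  ccaa_absent <- !isTRUE(pres[["ccaA"]])
  candidate <- ccaa_absent && active_ccmm
  note <- if (length(cas) == 0) "no CA detected"
    else if (candidate) "ccmM-compensation candidate"
    else paste(cas, collapse = ", ")
  structure(list(cas_present = cas,
                 ccm_m_compensation_candidate = candidate,
                 note = note),
            class = "ca_complement")
}
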