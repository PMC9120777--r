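#' Bidirectional best-hit ortholog detection
#'
#' Orthologs of the CCM reference proteins are called by the bidirectional
#' best hit (BBH) criterion: a reference protein r and a strain protein p
#' form an ortholog pair when p is the best surviving hit of r in the
#' strain proteome and r is the best surviving hit of p in the reference
#' proteome.  A hit survives when E <= 1e-6, identity >= 30 percent and
#' coverage >= 70 percent (defaults; all configurable).  Coverage is
#' required of the query sequence in each search direction by default,
#' which blocks short-fragment calls; a stricter both-sequences mode is
#' available.
#'
#' @name orthology
NULL

#' BBH filtering thresholds
#'
#' @param evalue Maximum expectation value (default 1e-6).
#' @param identity Minimum percent identity over aligned columns (default 30).
#' @param coverage Minimum percent coverage (default 70).
#' @param coverage_mode "query" (coverage of the query sequence in each
#'   direction, the default) or "both" (both sequences).
#' @return A list of class \code{bbh_thresholds}.
#' @export
bbh_thresholds <- function(evalue = 1e-6, identity = 30, coverage = 70,
                           coverage_mode = c("query", "both")) {
  coverage_mode <- match.arg(coverage_mode)
  stopifnot(evalue > 0, identity >= 0, identity <= 100,
            coverage >= 0, coverage <= 100)
  structure(list(evalue = evalue, identity = identity, coverage = coverage,
                 coverage_mode = coverage_mode),
            class = "bbh_thresholds")
}

#' The CCM reference-protein manifest
#'
#' Gene symbol to locus tag mapping of the 29 reference proteins used for
#' ortholog detection: 28 CCM proteins of Synechocystis sp. PCC 6803 plus
#' the experimentally confirmed alpha-CA ecaA (all2929) of Anabaena sp.
#' PCC 7120.  The reference amino-acid sequences themselves are supplied by
#' the user (or generated synthetically for testing).
#'
#' @return Data frame with columns \code{symbol}, \code{locus_tag},
#'   \code{organism}.
#' @export
ccm_reference_manifest <- function() {
  read.delim(.extdata("ccm_reference_manifest.tsv"),
             stringsAsFactors = FALSE)
}

#' Build a reference set from a proteome
#'
#' @param proteome A \code{\link{proteome}} whose record ids are either
#'   gene symbols or locus tags from the manifest.
#' @param manifest Symbol/locus-tag table; defaults to
#'   \code{\link{ccm_reference_manifest}}.
#' @return A list of class \code{reference_set} with fields
#'   \code{symbols}, \code{proteome} (records renamed to symbols) and
#'   \code{manifest}.
#' @export
reference_set <- function(proteome, manifest = ccm_reference_manifest()) {
  ids <- proteome$ids
  sym <- ifelse(ids %in% manifest$symbol, ids,
                manifest$symbol[match(ids, manifest$locus_tag)])
  if (anyNA(sym))
    stop("reference ids not in manifest: ",
         paste(head(ids[is.na(sym)], 3), collapse = ", "))
  if (anyDuplicated(sym))
    stop("duplicate reference symbol: ", sym[duplicated(sym)][1])
  seqs <- setNames(unname(proteome$seqs), sym)
  structure(list(symbols = sym,
                 proteome = cyanoccm::proteome(seqs, strain = "reference"),
                 manifest = manifest),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("CCM reference set: %d of 29 symbols\n", length(x$symbols)))
  invisible(x)
}

.hit_passes <- function(aln, thresholds) {
  if (aln$n_columns == 0L) return(FALSE)
  cov <- if (thresholds$coverage_mode == "both")
    min(aln$cov_a, aln$cov_b) else aln$cov_a
  aln$evalue <= thresholds$evalue &&
    aln$identity_pct >= thresholds$identity &&
    cov >= thresholds$coverage
}

#' Best surviving hit of a query in a proteome
#'
#' Aligns the query against every record, discards hits failing the E-value,
#' identity or coverage thresholds, and returns the best survivor.  Ties are
#' broken by higher score, then lower E-value, then lexicographically
#' smallest subject id.
#'
#' @param query Single amino-acid string (the query sequence).
#' @param target A \code{\link{proteome}}.
#' @param scheme A \code{\link{scoring_scheme}}.
#' @param thresholds A \code{\link{bbh_thresholds}}.
#' @return A one-row data frame (\code{subject_id}, \code{score},
#'   \code{evalue}, \code{identity_pct}, \code{cov_query},
#'   \code{cov_subject}) or \code{NULL} when no hit survives.
#' @export
best_hit <- function(query, target, scheme = scoring_scheme(),
                     thresholds = bbh_thresholds()) {
  if (!inherits(target, "proteome")) stop("target must be a proteome")
  if (length(target) == 0) stop("target proteome is empty")
  best <- NULL
  for (id in target$ids) {
    aln <- align_local(query, target$seqs[[id]], scheme)
    if (!.hit_passes(aln, thresholds)) next
    cand <- list(subject_id = id, score = aln$score, evalue = aln$evalue,
                 identity_pct = aln$identity_pct,
                 cov_query = aln$cov_a, cov_subject = aln$cov_b)
    if (is.null(best) ||
        cand$score > best$score ||
        (cand$score == best$score && cand$evalue < best$evalue) ||
        (cand$score == best$score && cand$evalue == best$evalue &&
         cand$subject_id < best$subject_id))
      best <- cand
  }
  if (is.null(best)) return(NULL)
  as.data.frame(best, stringsAsFactors = FALSE)
}

#' BBH ortholog calls for one strain
#'
#' For every reference symbol, searches the strain proteome for the best
#' surviving hit and confirms reciprocity against the reference proteome
#' (by default the reference set itself; pass \code{reverse_target} to use
#' the full reference-organism proteome instead).  Identity is taken from
#' the forward alignment, matching how presence/identity tables are built.
#'
#' @param refset A \code{\link{reference_set}}.
#' @param strain_proteome A \code{\link{proteome}}.
#' @param scheme,thresholds As in \code{\link{best_hit}}.
#' @param reverse_target Optional \code{proteome} for the reverse search.
#' @return Data frame with one row per reference symbol: \code{gene_symbol},
#'   \code{strain}, \code{subject_id}, \code{identity_pct}, \code{present}.
#' @export
bidirectional_best_hits <- function(refset, strain_proteome,
                                    scheme = scoring_scheme(),
                                    thresholds = bbh_thresholds(),
                                    reverse_target = NULL) {
  if (!inherits(refset, "reference_set")) stop("refset must be a reference_set")
  if (length(strain_proteome) == 0) stop("strain proteome is empty")
  if (is.null(reverse_target)) reverse_target <- refset$proteome
  out <- data.frame(gene_symbol = refset$symbols,
                    strain = strain_proteome$strain,
                    subject_id = NA_character_,
                    identity_pct = NA_real_,
                    present = FALSE,
                    stringsAsFactors = FALSE)
  rev_cache <- new.env(parent = emptyenv())
  for (k in seq_along(refset$symbols)) {
    sym <- refset$symbols[k]
    fwd <- best_hit(refset$proteome$seqs[[sym]], strain_proteome,
                    scheme, thresholds)
    if (is.null(fwd)) next
    sid <- fwd$subject_id
    rev <- if (!is.null(rev_cache[[sid]])) rev_cache[[sid]] else {
      r <- best_hit(strain_proteome$seqs[[sid]], reverse_target,
                    scheme, thresholds)
      rev_cache[[sid]] <- if (is.null(r)) list(NULL) else r
      rev_cache[[sid]]
    }
    if (is.null(rev) || is.null(rev$subject_id)) next
    # reverse best must map back to this reference (by symbol or locus tag)
    back <- rev$subject_id
    back_sym <- if (back %in% refset$manifest$locus_tag)
      refset$manifest$symbol[match(back, refset$manifest$locus_tag)] else back
    if (identical(back_sym, sym)) {
      out$subject_id[k] <- sid
      out$identity_pct[k] <- fwd$identity_pct
      out$present[k] <- TRUE
    }
  }
  out
}

#' Presence/identity profile of one strain
#'
#' Runs \code{\link{bidirectional_best_hits}} and orders the calls in the
#' canonical reporting order (\code{\link{ccm_symbols}}): Ci-uptake block
#' first, then the carboxysome block.  Symbols missing from the reference
#' set are reported as absent with a note.
#'
#' @inheritParams bidirectional_best_hits
#' @return Data frame of ortholog calls in reporting order.
#' @export
profile_strain <- function(strain_proteome, refset,
                           scheme = scoring_scheme(),
                           thresholds = bbh_thresholds(),
                           reverse_target = NULL) {
  calls <- bidirectional_best_hits(refset, strain_proteome, scheme,
                                   thresholds, reverse_target)
  order_syms <- intersect(ccm_symbols(), calls$gene_symbol)
  extra <- setdiff(calls$gene_symbol, order_syms)
  calls <- calls[match(c(order_syms, extra), calls$gene_symbol), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  calls
}
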