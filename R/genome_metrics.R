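#' Genome relatedness metrics and taxon delimitation
#'
#' Average amino-acid identity (AAI) over reciprocal best-hit protein
#' pairs, percentage of conserved proteins (POCP), and a BLAST-style
#' fragment average nucleotide identity (ANIb-style: 1020-bp fragments,
#' 70/70 retention), plus the decision rules used to delimit species and
#' genera from these metrics.
#'
#' @name genome_metrics
NULL

#' Average amino-acid identity between two proteomes
#'
#' Reciprocal best-hit pairs are collected with the same engine as ortholog
#' detection, filtered at identity >= 30 percent and coverage >= 70 percent
#' (the AAI convention, configurable), and the mean percent identity of the
#' surviving pairs is returned.
#'
#' @param proteome_a,proteome_b \code{\link{proteome}} objects.
#' @param scheme A \code{\link{scoring_scheme}}.
#' @param thresholds A \code{\link{bbh_thresholds}} (E-value ignored unless
#'   set; default keeps the 1e-6 / 30 / 70 convention).
#' @return A list of class \code{aai_result}: \code{aai} (percent),
#'   \code{n_rbh_pairs}, \code{pairs} (data frame).
#' @export
aai <- function(proteome_a, proteome_b, scheme = scoring_scheme(),
                thresholds = bbh_thresholds()) {
  if (length(proteome_a) == 0 || length(proteome_b) == 0)
    stop("both proteomes must be nonempty")
  fwd <- lapply(proteome_a$ids, function(id)
    best_hit(proteome_a$seqs[[id]], proteome_b, scheme, thresholds))
  names(fwd) <- proteome_a$ids
  pairs <- list()
  rev_cache <- new.env(parent = emptyenv())
  for (id in proteome_a$ids) {
    h <- fwd[[id]]
    if (is.null(h)) next
    sid <- h$subject_id
    rev <- if (!is.null(rev_cache[[sid]])) rev_cache[[sid]] else {
      r <- best_hit(proteome_b$seqs[[sid]], proteome_a, scheme, thresholds)
      rev_cache[[sid]] <- if (is.null(r)) list(NULL) else r
      rev_cache[[sid]]
    }
    if (is.null(rev) || is.null(rev$subject_id)) next
    if (identical(rev$subject_id, id))
      pairs[[length(pairs) + 1L]] <-
        data.frame(id_a = id, id_b = sid, identity_pct = h$identity_pct,
                   stringsAsFactors = FALSE)
  }
  if (length(pairs) == 0)
    stop("AAI undefined: no reciprocal best-hit pairs pass the filters")
  pairs <- do.call(rbind, pairs)
  structure(list(aai = mean(pairs$identity_pct),
                 n_rbh_pairs = nrow(pairs), pairs = pairs),
            class = "aai_result")
}

#' Percentage of conserved proteins between two proteomes
#'
#' A protein is conserved when it has a hit in the other proteome with
#' E < 1e-5, identity > 40 percent and an aligned region covering more than
#' half of its own length.  POCP = 100 * (C1 + C2) / (T1 + T2).
#'
#' @param proteome_a,proteome_b \code{\link{proteome}} objects.
#' @param scheme A \code{\link{scoring_scheme}}.
#' @param evalue,identity,coverage Conservation thresholds (strict
#'   inequalities, POCP convention).
#' @return A list of class \code{pocp_result}: \code{pocp}, \code{c1},
#'   \code{c2}, \code{t1}, \code{t2}.
#' @export
pocp <- function(proteome_a, proteome_b, scheme = scoring_scheme(),
                 evalue = 1e-5, identity = 40, coverage = 50) {
  if (length(proteome_a) == 0 || length(proteome_b) == 0)
    stop("both proteomes must be nonempty")
  conserved_in <- function(px, py) {
    sum(vapply(px$ids, function(id) {
      q <- px$seqs[[id]]
      for (t in py$ids) {
        aln <- align_local(q, py$seqs[[t]], scheme)
        if (aln$n_columns == 0L) next
        if (aln$evalue < evalue && aln$identity_pct > identity &&
            aln$cov_a > coverage) return(TRUE)
      }
      FALSE
    }, logical(1)))
  }
  c1 <- conserved_in(proteome_a, proteome_b)
  c2 <- conserved_in(proteome_b, proteome_a)
  t1 <- length(proteome_a); t2 <- length(proteome_b)
  structure(list(pocp = 100 * (c1 + c2) / (t1 + t2),
                 c1 = c1, c2 = c2, t1 = t1, t2 = t2),
            class = "pocp_result")
}

.chop_fragments <- function(seqs, fragment_len, min_len = 100L) {
  frags <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    starts <- seq(1L, n, by = fragment_len)
    f <- substring(s, starts, pmin(starts + fragment_len - 1L, n))
    frags <- c(frags, f[nchar(f) >= min_len])
  }
  frags
}

#' Fragment-based average nucleotide identity (ANIb-style)
#'
#' Chops genome A into consecutive fragments (1020 bp by default), locally
#' aligns each fragment against genome B, retains fragments aligning at
#' >= 70 percent identity over >= 70 percent of the fragment length, and
#' averages the retained identities.  The two-way value is the mean of the
#' A->B and B->A one-way values.
#'
#' @param genome_a,genome_b Named character vectors of contig sequences
#'   (or single unnamed sequences).
#' @param scheme A DNA \code{\link{scoring_scheme}}.
#' @param fragment_len Fragment size in bp (default 1020).
#' @param min_identity,min_coverage Retention thresholds in percent.
#' @param two_way Average both directions (default TRUE).
#' @return A list of class \code{ani_result}: \code{ani}, per-direction
#'   values \code{ani_ab}/\code{ani_ba}, and retained fragment counts.
#' @export
ani_fragment <- function(genome_a, genome_b,
                         scheme = scoring_scheme("DNA"),
                         fragment_len = 1020L,
                         min_identity = 70, min_coverage = 70,
                         two_way = TRUE) {
  if (length(genome_a) == 0 || length(genome_b) == 0 ||
      any(!nzchar(genome_a)) || any(!nzchar(genome_b)))
    stop("both genomes must be nonempty")
  if (max(nchar(genome_a)) < fragment_len ||
      max(nchar(genome_b)) < fragment_len)
    stop("genome shorter than one fragment (", fragment_len, " bp)")
  one_way <- function(ga, gb) {
    frags <- .chop_fragments(toupper(ga), fragment_len)
    idents <- numeric(0)
    for (f in frags) {
      best <- NULL
      for (contig in toupper(gb)) {
        aln <- align_local(f, contig, scheme)
        if (is.null(best) || aln$score > best$score) best <- aln
      }
      if (best$n_columns == 0L) next
      if (best$identity_pct >= min_identity &&
          best$cov_a >= min_coverage)
        idents <- c(idents, best$identity_pct)
    }
    list(ani = if (length(idents)) mean(idents) else NA_real_,
         n_retained = length(idents), n_fragments = length(frags))
  }
  ab <- one_way(genome_a, genome_b)
  ba <- if (two_way) one_way(genome_b, genome_a) else
    list(ani = NA_real_, n_retained = NA_integer_, n_fragments = NA_integer_)
  vals <- c(ab$ani, if (two_way) ba$ani)
  if (all(is.na(vals)))
    stop("ANI undefined: no fragments retained at the 70/70 thresholds")
  structure(list(ani = mean(vals, na.rm = TRUE),
                 ani_ab = ab$ani, ani_ba = ba$ani,
                 n_retained_ab = ab$n_retained,
                 n_retained_ba = ba$n_retained,
                 n_fragments_ab = ab$n_fragments,
                 n_fragments_ba = ba$n_fragments,
                 method = "ANIb-style (internal exact aligner)"),
            class = "ani_result")
}

#' Taxon assessment from relatedness metrics
#'
#' Applies the delimitation rules: genomes are redundant duplicates when
#' ANI > 99.9 percent; the same species when ANI > 96 or AAI >= 95; the
#' same genus when ANI >= 83, AAI > 70 or POCP >= 50.  When ANI falls in
#' the species/genus gray zone the assessment is flagged inconclusive at
#' species rank while the genus bound still applies.  The rationale string
#' names the inequality that fired.
#'
#' @param ani,aai,pocp Metric values in percent; \code{NA} when not
#'   computed.  At least one must be provided.
#' @return A list of class \code{taxon_assessment}: \code{same_species},
#'   \code{same_genus}, \code{redundant}, \code{inconclusive_species},
#'   \code{rationale}.
#' @export
assess_taxon <- function(ani = NA, aai = NA, pocp = NA) {
  if (all(is.na(c(ani, aai, pocp))))
    stop("at least one of ANI, AAI, POCP must be provided")
  rules <- character(0)
  redundant <- isTRUE(!is.na(ani) && ani > 99.9)
  if (redundant) rules <- c(rules, sprintf("ANI %.2f > 99.9 (redundant)", ani))
  same_species <- redundant ||
    isTRUE(!is.na(ani) && ani > 96) || isTRUE(!is.na(aai) && aai >= 95)
  if (!redundant && same_species) {
    if (!is.na(ani) && ani > 96)
      rules <- c(rules, sprintf("ANI %.2f > 96 (same species)", ani))
    if (!is.na(aai) && aai >= 95)
      rules <- c(rules, sprintf("AAI %.2f >= 95 (same species)", aai))
  }
  genus_hits <- c(
    if (!is.na(ani) && ani >= 83) sprintf("ANI %.2f >= 83 (same genus)", ani),
    if (!is.na(aai) && aai > 70) sprintf("AAI %.2f > 70 (same genus)", aai),
    if (!is.na(pocp) && pocp >= 50) sprintf("POCP %.2f >= 50 (same genus)", pocp))
  same_genus <- same_species || length(genus_hits) > 0
  rules <- c(rules, genus_hits)
  inconclusive <- !same_species && !is.na(ani) && ani > 83 && ani <= 96
  if (inconclusive)
    rules <- c(rules, sprintf("ANI %.2f in (83, 96]: species rank inconclusive", ani))
  if (length(rules) == 0)
    rules <- "all available metrics below genus bounds (different genus)"
  structure(list(same_species = same_species, same_genus = same_genus,
                 redundant = redundant,
                 inconclusive_species = inconclusive,
                 rationale = paste(rules, collapse = "; ")),
            class = "taxon_assessment")
}

#' @export
print.taxon_assessment <- function(x, ...) {
  cat(sprintf("taxon assessment: species=%s genus=%s redundant=%s\n  %s\n",
              x$same_species, x$same_genus, x$redundant, x$rationale))
  invisible(x)
}

#' Full relatedness report for a genome/proteome pair
#'
#' Convenience wrapper computing any of ANI, AAI and POCP and applying
#' \code{\link{assess_taxon}}.
#'
#' @param proteome_a,proteome_b Optional proteomes (for AAI/POCP).
#' @param genome_a,genome_b Optional nucleotide sequences (for ANI).
#' @param metrics Character subset of c("ani", "aai", "pocp").
#' @param ... Passed to the metric functions.
#' @return A list of class \code{relatedness_report}.
#' @export
relatedness_report <- function(proteome_a = NULL, proteome_b = NULL,
                               genome_a = NULL, genome_b = NULL,
                               metrics = c("ani", "aai", "pocp"), ...) {
  out <- list(ani = NA_real_, aai = NA_real_, pocp = NA_real_,
              n_rbh_pairs = NA_integer_,
              c1 = NA_integer_, c2 = NA_integer_,
              t1 = NA_integer_, t2 = NA_integer_)
  if ("ani" %in% metrics && !is.null(genome_a))
    out$ani <- ani_fragment(genome_a, genome_b, ...)$ani
  if ("aai" %in% metrics && !is.null(proteome_a)) {
    r <- aai(proteome_a, proteome_b)
    out$aai <- r$aai; out$n_rbh_pairs <- r$n_rbh_pairs
  }
  if ("pocp" %in% metrics && !is.null(proteome_a)) {
    r <- pocp(proteome_a, proteome_b)
    out$pocp <- r$pocp
    out$c1 <- r$c1; out$c2 <- r$c2; out$t1 <- r$t1; out$t2 <- r$t2
  }
  out$assessment <- assess_taxon(out$ani, out$aai, out$pocp)
  structure(out, class = "relatedness_report")
}
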