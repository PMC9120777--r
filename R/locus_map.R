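#' Genomic organization of CCM genes
#'
#' Clusters co-located CCM genes into loci and classifies them: the main
#' carboxysome locus (MCL: ccmK1/2 + ccmL, ccmM, ccmN, often terminated by
#' ccmO), satellite loci (ccmP, ccmK3-ccmK4, solitary ccmO), the Rubisco
#' rbcLSX cluster, and Ci-uptake operons.
#'
#' @name locus_map
NULL

#' Cluster CCM genes into loci
#'
#' Two CCM-labeled genes join the same locus when they lie on the same
#' contig, are separated by at most \code{max_gap_bp} of intergenic
#' distance and by at most \code{max_intervening} non-CCM genes.  Clusters
#' are maximal chains under this relation; input order is irrelevant
#' (features are sorted internally).
#'
#' @param annotation A \code{\link{genome_annotation}}.
#' @param symbols CCM symbols to consider (default: every labeled gene).
#' @param max_gap_bp Maximum intergenic gap in bp (default 5000).
#' @param max_intervening Maximum number of intervening non-CCM genes
#'   (default 2).
#' @return List of \code{locus_cluster} objects (possibly empty), each with
#'   \code{strain}, \code{contig}, \code{genes} (ordered feature rows),
#'   \code{span_bp} and \code{label} from \code{\link{classify_locus}}.
#' @export
cluster_loci <- function(annotation, symbols = NULL,
                         max_gap_bp = 5000L, max_intervening = 2L) {
  if (max_gap_bp <= 0 || max_intervening < 0)
    stop("thresholds must be positive")
  f <- annotation$features
  f <- f[order(f$contig, f$start), , drop = FALSE]
  is_ccm <- !is.na(f$symbol) &
    (if (is.null(symbols)) TRUE else f$symbol %in% symbols)
  if (!any(is_ccm)) return(list())
  clusters <- list()
  for (contig in unique(f$contig)) {
    fc <- f[f$contig == contig, , drop = FALSE]
    ccm_idx <- which(!is.na(fc$symbol) &
                       (if (is.null(symbols)) TRUE
                        else fc$symbol %in% symbols))
    if (!length(ccm_idx)) next
    current <- ccm_idx[1]
    flush <- function(idx) {
      genes <- fc[idx, , drop = FALSE]
      rownames(genes) <- NULL
      cl <- structure(list(strain = annotation$strain, contig = contig,
                           genes = genes,
                           span_bp = max(genes$end) - min(genes$start),
                           label = NA_character_),
                      class = "locus_cluster")
      cl$label <- classify_locus(cl)
      cl
    }
    if (length(ccm_idx) > 1) {
      for (k in 2:length(ccm_idx)) {
        i_prev <- tail(current, 1)
        i_next <- ccm_idx[k]
        gap <- fc$start[i_next] - fc$end[i_prev]
        intervening <- i_next - i_prev - 1L
        if (gap <= max_gap_bp && intervening <= max_intervening) {
          current <- c(current, i_next)
        } else {
          clusters[[length(clusters) + 1L]] <- flush(current)
          current <- i_next
        }
      }
    }
    clusters[[length(clusters) + 1L]] <- flush(current)
  }
  clusters
}

#' @export
print.locus_cluster <- function(x, ...) {
  cat(sprintf("[%s] %s: %s (%d bp)\n", x$label, x$contig,
              paste(x$genes$symbol, collapse = "-"), x$span_bp))
  invisible(x)
}

#' Classify a locus cluster
#'
#' Labels: \code{MCL} (at least one of ccmK1/ccmK2 plus all of ccmL, ccmM,
#' ccmN); \code{rubisco} (rbcL, rbcS and rbcX together);
#' \code{satellite:ccmK3K4} (exactly the ccmK3-ccmK4 pair);
#' \code{satellite:ccmO} (a solitary ccmO away from the MCL);
#' \code{satellite:ccmP} (ccmP without any MCL core gene);
#' \code{ci-uptake:<system>} when every member belongs to one Ci-uptake
#' system; \code{other} otherwise.
#'
#' @param cluster A \code{locus_cluster}.
#' @return Label string.
#' @export
classify_locus <- function(cluster) {
  syms <- cluster$genes$symbol
  syms <- syms[!is.na(syms)]
  has <- function(...) all(c(...) %in% syms)
  mcl_core <- c("ccmK1", "ccmK2", "ccmL", "ccmM", "ccmN")
  if ((has("ccmK1") || has("ccmK2")) && has("ccmL", "ccmM", "ccmN"))
    return("MCL")
  if (has("rbcL", "rbcS", "rbcX")) return("rubisco")
  if (setequal(syms, c("ccmK3", "ccmK4"))) return("satellite:ccmK3K4")
  if (setequal(syms, "ccmO")) return("satellite:ccmO")
  if ("ccmP" %in% syms && !any(mcl_core %in% syms))
    return("satellite:ccmP")
  ci <- ccm_systems()[c("NDH-1_3", "NDH-1_4", "BicA", "Sbt", "BCT1")]
  for (s in names(ci))
    if (all(syms %in% ci[[s]])) return(paste0("ci-uptake:", s))
  "other"
}

#' Per-strain MCL report
#'
#' Describes the main carboxysome locus of a strain: whether one exists,
#' its gene order, whether ccmO sits inside it and at its boundary, and
#' which satellite loci accompany it.  Multiple MCL candidates are all
#' reported with an ambiguity flag.
#'
#' @param clusters List of classified \code{locus_cluster} objects for one
#'   strain (from \code{\link{cluster_loci}}).
#' @return A list of class \code{mcl_report}: \code{has_mcl},
#'   \code{ambiguous}, \code{mcl_gene_order}, \code{ccmo_in_mcl},
#'   \code{ccmo_terminal}, \code{satellites}.
#' @export
mcl_report <- function(clusters) {
  labels <- vapply(clusters, `[[`, character(1), "label")
  mcls <- clusters[labels == "MCL"]
  sats <- sort(labels[startsWith(labels, "satellite:")])
  if (length(mcls) == 0)
    return(structure(list(has_mcl = FALSE, ambiguous = FALSE,
                          mcl_gene_order = character(0),
                          ccmo_in_mcl = FALSE, ccmo_terminal = FALSE,
                          satellites = sats),
                     class = "mcl_report"))
  mcl <- mcls[[1]]
  order_syms <- mcl$genes$symbol[!is.na(mcl$genes$symbol)]
  ccmo_in <- "ccmO" %in% order_syms
  ccmo_term <- ccmo_in &&
    ("ccmO" == order_syms[1] || "ccmO" == tail(order_syms, 1))
  structure(list(has_mcl = TRUE, ambiguous = length(mcls) > 1,
                 mcl_gene_order = order_syms,
                 ccmo_in_mcl = ccmo_in, ccmo_terminal = ccmo_term,
                 satellites = sats),
            class = "mcl_report")
}

#' @export
print.mcl_report <- function(x, ...) {
  if (!x$has_mcl) cat("no MCL detected\n")
  else cat(sprintf("MCL: %s%s | ccmO terminal: %s | satellites: %s\n",
                   paste(x$mcl_gene_order, collapse = "-"),
                   if (x$ambiguous) " (ambiguous: multiple candidates)" else "",
                   x$ccmo_terminal,
                   if (length(x$satellites))
                     paste(x$satellites, collapse = ", ") else "none"))
  invisible(x)
}
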