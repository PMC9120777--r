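#' Scoring schemes for local alignment
#'
#' A scoring scheme bundles a substitution matrix, affine gap penalties and
#' the gapped Karlin-Altschul parameters used to convert raw scores into
#' expectation values.  The protein default is BLOSUM62 with gap open -11 /
#' extend -1 and the standard gapped constants (lambda = 0.267, K = 0.041),
#' i.e. the BLASTP defaults.  The DNA scheme scores +1 match / -1 mismatch
#' with gaps -2 / -1.
#'
#' A gap of length L scores \code{gap_open + L * gap_extend}; both penalties
#' are non-positive and \code{gap_open <= gap_extend}.  The ambiguity residue
#' \code{X} scores 0 against everything (including itself), so masked or
#' unknown residues neither help nor hurt an alignment.
#'
#' @param name "BLOSUM62" (protein) or "DNA".
#' @param gap_open,gap_extend Non-positive gap penalties on the score scale.
#' @param lambda_ka,k_ka Karlin-Altschul parameters (both > 0).
#' @return An object of class \code{scoring_scheme}.
#' @export
scoring_scheme <- function(name = c("BLOSUM62", "DNA"),
                           gap_open = NULL, gap_extend = NULL,
                           lambda_ka = NULL, k_ka = NULL) {
  name <- match.arg(name)
  if (name == "BLOSUM62") {
    mat <- .blosum62_x0()
    if (is.null(gap_open)) gap_open <- -11
    if (is.null(gap_extend)) gap_extend <- -1
    if (is.null(lambda_ka)) lambda_ka <- 0.267
    if (is.null(k_ka)) k_ka <- 0.041
  } else {
    alpha <- c("A", "C", "G", "T", "N")
    mat <- matrix(-1L, 5, 5, dimnames = list(alpha, alpha))
    diag(mat) <- 1L
    mat["N", ] <- 0L
    mat[, "N"] <- 0L
    if (is.null(gap_open)) gap_open <- -2
    if (is.null(gap_extend)) gap_extend <- -1
    if (is.null(lambda_ka)) lambda_ka <- 1.28
    if (is.null(k_ka)) k_ka <- 0.46
  }
  stopifnot(gap_open <= gap_extend, gap_extend <= 0,
            lambda_ka > 0, k_ka > 0)
  structure(list(name = name, matrix = mat,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda_ka = lambda_ka, k_ka = k_ka,
                 alphabet = rownames(mat)),
            class = "scoring_scheme")
}

# BLOSUM62 from Biostrings with the X row/column forced to 0.
.blosum62_x0 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62
  keep <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V", "X")
  m <- m[keep, keep]
  m["X", ] <- 0L
  m[, "X"] <- 0L
  storage.mode(m) <- "integer"
  m
}

.encode_seq <- function(s, scheme, what = "sequence") {
  if (!is.character(s) || length(s) != 1L || !nzchar(s))
    stop(what, " must be a nonempty character scalar")
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  idx <- match(chars, scheme$alphabet)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop(what, " contains residues outside the scheme alphabet: ",
         paste(bad, collapse = ", "))
  }
  idx - 1L
}

#' Optimal local alignment of two sequences
#'
#' Exact Smith-Waterman alignment under the Gotoh affine-gap recurrence,
#' with deterministic traceback (ties: diagonal > up > left).  Identity is
#' computed over all aligned columns including gap columns (the BLAST
#' convention); coverage is the aligned span of each sequence as a
#' percentage of its full length, reported per sequence.
#'
#' @param a,b Residue strings (protein or nucleotide, per \code{scheme}).
#' @param scheme A \code{\link{scoring_scheme}}.
#' @return An object of class \code{alignment_result} with fields
#'   \code{score}, \code{n_columns}, \code{n_identical}, \code{identity_pct},
#'   \code{cov_a}, \code{cov_b}, \code{evalue}, \code{start_a/end_a},
#'   \code{start_b/end_b} (1-based inclusive), \code{aligned_a},
#'   \code{aligned_b} (gapped strings) and \code{aligned_pairs} (two-column
#'   matrix of matched residue positions).
#' @export
align_local <- function(a, b, scheme = scoring_scheme()) {
  ai <- .encode_seq(a, scheme, "a")
  bi <- .encode_seq(b, scheme, "b")
  raw <- .sw_align_cpp(ai, bi, scheme$matrix,
                       scheme$gap_open, scheme$gap_extend)
  len_a <- length(ai); len_b <- length(bi)
  achars <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  bchars <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  ncol <- raw$n_columns
  if (ncol > 0L) {
    ag <- ifelse(raw$a_gapped == 0L, "-", achars[pmax(raw$a_gapped, 1L)])
    bg <- ifelse(raw$b_gapped == 0L, "-", bchars[pmax(raw$b_gapped, 1L)])
    pairs <- cbind(pos_a = raw$a_gapped, pos_b = raw$b_gapped)
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0, , drop = FALSE]
    identity_pct <- 100 * raw$n_identical / ncol
    cov_a <- 100 * (raw$end_a - raw$start_a + 1L) / len_a
    cov_b <- 100 * (raw$end_b - raw$start_b + 1L) / len_b
  } else {
    ag <- bg <- character(0)
    pairs <- cbind(pos_a = integer(0), pos_b = integer(0))
    identity_pct <- NA_real_
    cov_a <- cov_b <- 0
  }
  structure(list(
    score = raw$score,
    n_columns = ncol,
    n_identical = raw$n_identical,
    identity_pct = identity_pct,
    cov_a = cov_a, cov_b = cov_b,
    evalue = alignment_evalue(raw$score, len_a, len_b, scheme),
    start_a = raw$start_a, end_a = raw$end_a,
    start_b = raw$start_b, end_b = raw$end_b,
    len_a = len_a, len_b = len_b,
    aligned_a = paste(ag, collapse = ""),
    aligned_b = paste(bg, collapse = ""),
    aligned_pairs = pairs
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("local alignment: score %.0f, %d columns, %.1f%% identity\n",
              x$score, x$n_columns,
              ifelse(is.na(x$identity_pct), 0, x$identity_pct)))
  cat(sprintf("  a[%s-%s] cov %.1f%% | b[%s-%s] cov %.1f%% | E = %.3g\n",
              x$start_a, x$end_a, x$cov_a, x$start_b, x$end_b, x$cov_b,
              x$evalue))
  invisible(x)
}

#' Karlin-Altschul expectation value
#'
#' \eqn{E = K \cdot m \cdot n \cdot e^{-\lambda S}} with full sequence
#' lengths as the search-space sizes.
#'
#' @param score Raw alignment score (>= 0).
#' @param len_a,len_b Full sequence lengths (> 0).
#' @param scheme A \code{\link{scoring_scheme}} carrying lambda and K.
#' @return The expectation value (numeric scalar >= 0).
#' @export
alignment_evalue <- function(score, len_a, len_b, scheme = scoring_scheme()) {
  if (len_a <= 0 || len_b <= 0)
    stop("sequence lengths must be positive")
  if (score < 0) stop("score must be non-negative")
  scheme$k_ka * len_a * len_b * exp(-scheme$lambda_ka * score)
}

#' Identity and coverage statistics of an alignment
#'
#' @param result An \code{alignment_result}.
#' @param len_a,len_b Full sequence lengths; defaults to those recorded in
#'   the result.
#' @return Named numeric vector \code{identity_pct}, \code{cov_a},
#'   \code{cov_b}.
#' @export
identity_and_coverage <- function(result, len_a = result$len_a,
                                  len_b = result$len_b) {
  if (result$n_columns == 0L)
    stop("identity undefined: alignment has zero aligned columns")
  c(identity_pct = 100 * result$n_identical / result$n_columns,
    cov_a = 100 * (result$end_a - result$start_a + 1) / len_a,
    cov_b = 100 * (result$end_b - result$start_b + 1) / len_b)
}
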