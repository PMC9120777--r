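#' Packaged study fixtures
#'
#' Transcriptions of the published presence/identity matrices and strain
#' metadata for the 17 well-described thermophilic cyanobacteria: the
#' Ci-uptake matrix (14 transporter/complex genes), the carboxysome matrix
#' (14 shell/Rubisco/CA genes) and the strain metadata table (niche
#' temperature, niche pH, assembly accession).  Identity percentages are
#' relative to the Synechocystis sp. PCC 6803 reference proteins; "x"
#' cells mark absent genes.
#'
#' @param which One of "ci_uptake", "carboxysome", "strains".
#' @return A \code{\link{build_presence_matrix}}-shaped
#'   \code{presence_matrix} for the two gene matrices, or a data frame for
#'   the strain metadata.
#' @export
load_fixture <- function(which = c("ci_uptake", "carboxysome", "strains")) {
  which <- match.arg(which)
  if (which == "strains")
    return(read.delim(.extdata("strain_metadata.tsv"),
                      stringsAsFactors = FALSE, na.strings = "NA"))
  file <- switch(which,
                 ci_uptake = "ci_uptake_matrix.tsv",
                 carboxysome = "carboxysome_matrix.tsv")
  raw <- read.delim(.extdata(file), stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  strains <- raw$strain
  symbols <- setdiff(names(raw), "strain")
  cells <- as.matrix(raw[, symbols, drop = FALSE])
  present <- cells != "x"
  identity <- suppressWarnings(
    matrix(as.numeric(ifelse(present, cells, NA)),
           nrow = nrow(cells),
           dimnames = list(strains, symbols)))
  dimnames(present) <- list(strains, symbols)
  structure(list(strains = strains, symbols = symbols,
                 present = present, identity = identity),
            class = "presence_matrix")
}

#' Combine the two fixture matrices into one presence matrix
#'
#' @return A \code{presence_matrix} over all 28 tabulated symbols.
#' @export
load_fixture_combined <- function() {
  ci <- load_fixture("ci_uptake")
  cb <- load_fixture("carboxysome")
  stopifnot(identical(ci$strains, cb$strains))
  structure(list(strains = ci$strains,
                 symbols = c(ci$symbols, cb$symbols),
                 present = cbind(ci$present, cb$present),
                 identity = cbind(ci$identity, cb$identity)),
            class = "presence_matrix")
}

#' Write a presence matrix as TSV
#'
#' Cells carry the identity percent where present and "x" where absent —
#' the same layout as the packaged fixture matrices.
#'
#' @param matrix A \code{presence_matrix}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_presence_matrix <- function(matrix, path) {
  cells <- ifelse(matrix$present,
                  ifelse(is.na(matrix$identity), "+",
                         formatC(matrix$identity, format = "fg")),
                  "x")
  df <- data.frame(strain = matrix$strains, cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("strain", matrix$symbols)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
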