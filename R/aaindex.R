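#' @keywords internal
"_PACKAGE"

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "W", "Y", "V")

AAINDEX_ACCESSIONS <- c("FASG760101", "FASG760102", "GOLD730102", "WOLR790101",
                        "BHAR880101", "BULH740101", "FAUJ880108", "ZIMJ680103",
                        "ZIMJ680104")

AAINDEX_CATEGORIES <- c("Size", "MeltingPoint", "Hydrophobicity", "Flexibility",
                        "TransferEnergy", "ElectricEffect", "Polarity",
                        "IsoelectricPoint")

#' Load the nine embedded physicochemical descriptor scales
#'
#' Returns the curated set of nine AAindex scales used to project residue
#' trajectories into physicochemical feature space: molecular weight, melting
#' point, residue volume, hydrophobicity, average flexibility, transfer free
#' energy to the surface, localized electrical effect, polarity, and
#' isoelectric point. Values are raw AAindex units; each scale maps the 20
#' standard amino acids to a real number and carries a category label used
#' for prediction bundling.
#'
#' @return An object of class `aaindex_table`: a named list of
#'   `aaindex_scale` objects, each with elements `accession`, `property`,
#'   `category`, and `values` (named numeric vector of length 20).
#' @examples
#' tab <- load_default_indices()
#' length(tab)               # 9
#' tab[["FASG760101"]]$values[["G"]]
#' @export
load_default_indices <- function() {
  path <- system.file("extdata", "aaindex9.tsv", package = "ssp", mustWork = TRUE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(identical(names(raw), c("accession", "property", "category", "residue", "value")))
  scales <- lapply(AAINDEX_ACCESSIONS, function(acc) {
    sub <- raw[raw$accession == acc, , drop = FALSE]
    if (nrow(sub) != 20L || anyDuplicated(sub$residue) ||
        !setequal(sub$residue, AA_ALPHABET) || anyNA(sub$value)) {
      stop("embedded descriptor data corrupt for accession ", acc)
    }
    values <- stats::setNames(sub$value, sub$residue)[AA_ALPHABET]
    new_aaindex_scale(acc, sub$property[1L], sub$category[1L], values)
  })
  names(scales) <- AAINDEX_ACCESSIONS
  structure(scales, class = "aaindex_table")
}

new_aaindex_scale <- function(accession, property, category, values) {
  stopifnot(is.character(accession), nzchar(accession),
            category %in% AAINDEX_CATEGORIES,
            length(values) == 20L, !anyNA(values),
            setequal(names(values), AA_ALPHABET))
  structure(list(accession = accession, property = property,
                 category = category, values = values),
            class = "aaindex_scale")
}

#' @export
print.aaindex_table <- function(x, ...) {
  cat("Descriptor table:", length(x), "AAindex scales\n")
  for (s in x) cat(sprintf("  %s  %-18s %s\n", s$accession, s$category, s$property))
  invisible(x)
}

#' @export
print.aaindex_scale <- function(x, ...) {
  cat(sprintf("%s (%s): %s\n", x$accession, x$category, x$property))
  print(x$values)
  invisible(x)
}

#' Pearson correlation matrix of the descriptor scales
#'
#' Diagnostic for redundancy among the descriptor set: pairwise Pearson
#' correlation of the 20 residue values of every pair of scales. The two
#' size-like scales (molecular weight, residue volume) are expected to show
#' the strongest off-diagonal correlation.
#'
#' @param table An `aaindex_table`, e.g. from [load_default_indices()].
#' @return A symmetric numeric matrix (one row/column per accession) with
#'   unit diagonal and entries in `[-1, 1]`.
#' @export
descriptor_correlation <- function(table) {
  stopifnot(inherits(table, "aaindex_table"))
  mat <- vapply(table, function(s) s$values[AA_ALPHABET], numeric(20L))
  colnames(mat) <- unname(vapply(table, `[[`, character(1L), "accession"))
  stats::cor(mat)
}

#' Invert a descriptor value to its closest amino acid
#'
#' Finds the residue whose scale value is nearest (absolute difference) to a
#' query value; this realises the final step of trend extrapolation, mapping
#' a predicted descriptor value back to a concrete amino acid. Ties are broken
#' alphabetically on the one-letter code.
#'
#' @param value Numeric query value, in the scale's units.
#' @param scale An `aaindex_scale`.
#' @param exclude Optional character vector of residues to exclude from the
#'   search (e.g. the current residue, to force a substitution).
#' @return A single one-letter amino-acid code.
#' @export
nearest_residue <- function(value, scale, exclude = NULL) {
  stopifnot(inherits(scale, "aaindex_scale"), is.numeric(value), length(value) == 1L,
            is.finite(value))
  candidates <- setdiff(AA_ALPHABET, exclude)
  if (length(candidates) == 0L) stop("all residues excluded")
  vals <- scale$values[candidates]
  d <- abs(vals - value)
  hits <- candidates[d == min(d)]
  sort(hits)[1L]
}

scale_category <- function(table, accession) {
  table[[accession]]$category
}
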