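#' Bundle aggregated predictions into Prediction / SAP / MAP tiers
#'
#' Consolidates per-index predictions into the three-tier reporting scheme:
#' a mutation supported by two or more descriptor indices is a Mutation
#' Agreeing Prediction (MAP) and is consolidated into a single record; when
#' several indices predict different residues at the same site, those
#' single-index residues are Site Agreeing Predictions (SAP); a lone
#' prediction at a site is tier Prediction. A mutation can be both
#' mutation-agreeing and at a conflicted site; the MAP tier wins while the
#' conflicting other residues stay SAP.
#'
#' @param aggregated A data.frame from [aggregate_across_trees()].
#' @return A data.frame with one row per (site, mutation): `mutation`
#'   (e.g. `"E3K"`), `tier` (`"MAP"`, `"SAP"`, `"Prediction"`),
#'   `position`, `wild_type`, `predicted`, `n_support`, `accessions` and
#'   `categories` (semicolon-joined), averaged `sequentiality` and
#'   `fluctuation`, `break_trend` (any supporting index flagged), `n_trees`
#'   (max over supports), and `site_group` (shared id linking SAP members of
#'   one site). Ordered MAP first (support desc, then score), then SAP,
#'   then Prediction.
#' @export
bundle <- function(aggregated) {
  stopifnot(is.data.frame(aggregated),
            all(c("position", "wild_type", "predicted", "accession",
                  "category", "sequentiality", "fluctuation",
                  "break_trend", "n_trees") %in% names(aggregated)))
  if (nrow(aggregated) == 0L) {
    return(data.frame(mutation = character(0), tier = character(0),
                      position = integer(0), wild_type = character(0),
                      predicted = character(0), n_support = integer(0),
                      accessions = character(0), categories = character(0),
                      sequentiality = numeric(0), fluctuation = numeric(0),
                      break_trend = logical(0), n_trees = integer(0),
                      site_group = character(0), stringsAsFactors = FALSE))
  }
  key <- interaction(aggregated$position, aggregated$predicted, drop = TRUE)
  per_mut <- do.call(rbind, lapply(split(aggregated, key), function(p) {
    accs <- sort(unique(p$accession))
    cats <- unique(p$category[order(p$accession)])
    data.frame(mutation = to_mutation_notation(p$wild_type[1L], p$position[1L],
                                               p$predicted[1L]),
               position = p$position[1L], wild_type = p$wild_type[1L],
               predicted = p$predicted[1L],
               n_support = length(accs),
               accessions = paste(accs, collapse = ";"),
               categories = paste(cats, collapse = ";"),
               sequentiality = mean(p$sequentiality),
               fluctuation = mean(p$fluctuation),
               break_trend = any(p$break_trend),
               n_trees = max(p$n_trees),
               stringsAsFactors = FALSE)
  }))
  muts_per_site <- table(per_mut$position)
  per_mut$tier <- ifelse(per_mut$n_support >= 2L, "MAP",
                         ifelse(muts_per_site[as.character(per_mut$position)] >= 2L,
                                "SAP", "Prediction"))
  per_mut$site_group <- paste0("site_", per_mut$position)
  tier_order <- match(per_mut$tier, c("MAP", "SAP", "Prediction"))
  ord <- order(tier_order, -per_mut$n_support, -per_mut$sequentiality,
               per_mut$position, per_mut$predicted)
  out <- per_mut[ord, c("mutation", "tier", "position", "wild_type",
                        "predicted", "n_support", "accessions", "categories",
                        "sequentiality", "fluctuation", "break_trend",
                        "n_trees", "site_group")]
  rownames(out) <- NULL
  out
}

#' Number of descriptor indices supporting a bundled mutation
#'
#' @param bundled One or more rows of the [bundle()] output.
#' @return Integer vector of distinct supporting indices per row; `>= 2`
#'   exactly for MAP-tier rows.
#' @export
support_count <- function(bundled) {
  stopifnot(is.data.frame(bundled), "accessions" %in% names(bundled))
  lengths(strsplit(bundled$accessions, ";", fixed = TRUE))
}

#' Protein mutation notation
#'
#' @param wild_type Single wild-type residue code.
#' @param position 1-based position on the ungapped target sequence.
#' @param predicted Single predicted residue code.
#' @param target Optional ungapped target sequence; when given, `wild_type`
#'   is checked against the residue at `position` (guards against
#'   coordinate bugs).
#' @return String like `"E3K"`.
#' @seealso [parse_mutation()]
#' @export
to_mutation_notation <- function(wild_type, position, predicted, target = NULL) {
  stopifnot(all(wild_type %in% AA_ALPHABET), all(predicted %in% AA_ALPHABET),
            all(position >= 1L), all(position == round(position)))
  if (!is.null(target)) {
    at <- substring(gsub("-", "", target), position, position)
    if (any(at != wild_type)) {
      stop("wild-type residue does not match the target sequence at position(s) ",
           paste(position[at != wild_type], collapse = ", "))
    }
  }
  paste0(wild_type, as.integer(position), predicted)
}

#' Parse protein mutation notation
#'
#' Inverse of [to_mutation_notation()].
#'
#' @param notation Character vector like `c("E3K", "A12L")`.
#' @return data.frame with columns `wild_type`, `position`, `predicted`.
#' @export
parse_mutation <- function(notation) {
  m <- regmatches(notation, regexec("^([A-Z])([0-9]+)([A-Z])$", notation))
  bad <- lengths(m) != 4L
  if (any(bad)) stop("malformed mutation notation: ",
                     paste(notation[bad], collapse = ", "))
  data.frame(wild_type = vapply(m, `[`, character(1L), 2L),
             position = as.integer(vapply(m, `[`, character(1L), 3L)),
             predicted = vapply(m, `[`, character(1L), 4L),
             stringsAsFactors = FALSE)
}
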