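group_values <- function(traj, scale) {
  g <- traj$groups
  keep <- g$residue %in% AA_ALPHABET
  unname(scale$values[g$residue[keep]])
}

#' Sequentiality of a trajectory under one descriptor
#'
#' Scored out of 100: the fraction of group transitions whose descriptor
#' change has the same sign as the fitted trend direction. A perfect score
#' means every transition of a positive trend increased the feature's value
#' relative to the previous group (and symmetrically for negative trends).
#'
#' @param traj A `trajectory` with at least one transition.
#' @param scale An `aaindex_scale`.
#' @param slope Fitted trend slope; its sign defines the trend direction.
#' @return Numeric in `[0, 100]`.
#' @export
sequentiality <- function(traj, scale, slope) {
  stopifnot(inherits(traj, "trajectory"), inherits(scale, "aaindex_scale"),
            is.numeric(slope), length(slope) == 1L)
  y <- group_values(traj, scale)
  if (length(y) < 2L) stop("sequentiality undefined: trajectory has no transitions")
  dy <- diff(y)
  100 * sum(sign(dy) == sign(slope)) / length(dy)
}

#' Fluctuation of a trajectory
#'
#' Number of distinct residues divided by the number of residue groups; 1
#' means every group introduced a new residue (a steadily exploring
#' trajectory), lower values mean residues recur (oscillation).
#'
#' @param traj A `trajectory` with at least one group.
#' @return Numeric in `(0, 1]`.
#' @export
fluctuation <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  n_groups <- nrow(traj$groups)
  if (n_groups < 1L) stop("fluctuation undefined: empty trajectory")
  length(unique(traj$groups$residue)) / n_groups
}

#' Break-trend flag
#'
#' Flags a trajectory whose most recent descriptor change contradicts the
#' fitted trend: a final drop on a rising trend (or rise on a falling one)
#' suggests the trend has already broken and the extrapolation is suspect.
#' Zero-change transitions (two residues with equal scale value) are
#' consistent. With fewer than two transitions the flag is undefined and
#' treated as no-break, with a warning.
#'
#' @param traj A `trajectory`.
#' @param scale An `aaindex_scale`.
#' @param slope Fitted trend slope.
#' @param mode `"last"` (default) inspects the most recent group
#'   transition; `"penultimate"` the one before it.
#' @return Logical scalar.
#' @export
break_trend <- function(traj, scale, slope, mode = c("last", "penultimate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(traj, "trajectory"), inherits(scale, "aaindex_scale"))
  y <- group_values(traj, scale)
  dy <- diff(y)
  if (length(dy) < 2L) {
    warning("break-trend undefined with fewer than two transitions; treating as no-break")
    return(FALSE)
  }
  d <- if (mode == "last") dy[length(dy)] else dy[length(dy) - 1L]
  if (d == 0) return(FALSE)
  if (slope == 0) return(TRUE)
  sign(d) == -sign(slope)
}

#' Rank predictions
#'
#' Total order over per-site predictions: unbroken trends first, then
#' sequentiality descending, then fluctuation descending, with a
#' deterministic tie-break on (position ascending, accession ascending) so
#' ranking is stable across runs and input permutations.
#'
#' @param predictions A data.frame as returned by [predict_site()] /
#'   [aggregate_across_trees()] (columns `break_trend`, `sequentiality`,
#'   `fluctuation`, `position`, `accession`).
#' @return The same data.frame reordered, with a `rank` column prepended.
#' @export
rank_predictions <- function(predictions) {
  stopifnot(is.data.frame(predictions),
            all(c("break_trend", "sequentiality", "fluctuation",
                  "position", "accession") %in% names(predictions)))
  ord <- order(predictions$break_trend,            # FALSE < TRUE
               -predictions$sequentiality,
               -predictions$fluctuation,
               predictions$position,
               predictions$accession)
  out <- predictions[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Aggregate predictions across trees
#'
#' Predictions are expressed in 1-based ungapped target coordinates, so the
#' same site is comparable across trees built from different sequence
#' files. Tuples sharing (position, wild type, predicted residue,
#' accession) are merged: scores are arithmetically averaged and the number
#' of supporting trees recorded. A site whose wild-type residue differs
#' between trees indicates an alignment/coordinate inconsistency and is an
#' error.
#'
#' @param per_tree A data.frame of per-site predictions from several trees,
#'   with a `tree_id` column in addition to the [predict_site()] columns.
#' @return A data.frame with one row per merged tuple: averaged
#'   `sequentiality`, `fluctuation`, `slope`, the fraction of trees flagging
#'   a break (`break_frac`), `break_trend` (any tree flagged), and
#'   `n_trees`.
#' @export
aggregate_across_trees <- function(per_tree) {
  stopifnot(is.data.frame(per_tree), "tree_id" %in% names(per_tree))
  if (nrow(per_tree) == 0L) {
    return(data.frame(position = integer(0), wild_type = character(0),
                      predicted = character(0), accession = character(0),
                      category = character(0), slope = numeric(0),
                      sequentiality = numeric(0), fluctuation = numeric(0),
                      break_frac = numeric(0), break_trend = logical(0),
                      n_trees = integer(0), stringsAsFactors = FALSE))
  }
  wt_by_pos <- tapply(per_tree$wild_type, per_tree$position,
                      function(w) length(unique(w)))
  if (any(wt_by_pos > 1L)) {
    bad <- names(wt_by_pos)[wt_by_pos > 1L]
    stop("wild-type residue differs across trees at position(s) ",
         paste(bad, collapse = ", "), "; alignments are inconsistent")
  }
  key <- interaction(per_tree$position, per_tree$wild_type,
                     per_tree$predicted, per_tree$accession, drop = TRUE)
  pieces <- split(per_tree, key)
  out <- do.call(rbind, lapply(pieces, function(p) {
    data.frame(position = p$position[1L], wild_type = p$wild_type[1L],
               predicted = p$predicted[1L], accession = p$accession[1L],
               category = p$category[1L],
               slope = mean(p$slope),
               sequentiality = mean(p$sequentiality),
               fluctuation = mean(p$fluctuation),
               break_frac = mean(p$break_trend),
               break_trend = any(p$break_trend),
               n_trees = length(unique(p$tree_id)),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$position, out$predicted, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}
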