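#' Run the full successor-prediction pipeline
#'
#' For every tree: extract the root-to-target main path, build the residue
#' trajectory of every alignment column, fit the nine descriptor trends at
#' eligible sites, and score them. Predictions are then expressed in
#' 1-based ungapped target coordinates, averaged across trees, ranked, and
#' bundled into MAP / SAP / Prediction tiers.
#'
#' @param trees A rooted [ape::phylo] with labelled internal nodes, or a
#'   list of them (one per sequence file).
#' @param sequences A named character vector of aligned node sequences, or
#'   a list of them parallel to `trees`.
#' @param target_id Label of the target leaf (same in every tree).
#' @param table An `aaindex_table`.
#' @param config An `ssp_config`.
#' @return Object of class `ssp_result`: list with `per_site` (all
#'   per-tree, per-site, per-index predictions), `aggregated`, `ranked`,
#'   `bundled`, `config`, and `n_trees`.
#' @export
ssp_predict <- function(trees, sequences, target_id,
                        table = load_default_indices(),
                        config = ssp_config()) {
  if (inherits(trees, "phylo")) {
    trees <- list(trees)
    sequences <- list(sequences)
  }
  if (length(trees) == 0L) stop("no trees supplied")
  stopifnot(length(trees) == length(sequences))
  if (is.null(names(trees))) names(trees) <- paste0("tree", seq_along(trees))
  names(sequences) <- names(trees)
  per_tree <- lapply(names(trees), function(id) {
    path <- extract_main_path(trees[[id]], sequences[[id]], target_id)
    width <- nchar(path$sequences[1L])
    rows <- lapply(seq_len(width) - 1L, predict_site,
                   path = path, table = table, config = config)
    out <- do.call(rbind, rows)
    if (nrow(out) > 0L) cbind(tree_id = id, out, stringsAsFactors = FALSE)
    else cbind(tree_id = character(0), out)
  })
  per_site <- do.call(rbind, per_tree)
  rownames(per_site) <- NULL
  aggregated <- aggregate_across_trees(per_site)
  ranked <- if (nrow(aggregated) > 0L) rank_predictions(aggregated) else aggregated
  structure(list(per_site = per_site, aggregated = aggregated,
                 ranked = ranked, bundled = bundle(aggregated),
                 config = config, n_trees = length(trees)),
            class = "ssp_result")
}

#' @export
print.ssp_result <- function(x, ...) {
  tiers <- table(factor(x$bundled$tier, levels = c("MAP", "SAP", "Prediction")))
  cat(sprintf("Successor predictions from %d tree(s): %d site/index/mutation records\n",
              x$n_trees, nrow(x$per_site)))
  cat(sprintf("  bundled: %d MAP, %d SAP, %d Prediction\n",
              tiers[["MAP"]], tiers[["SAP"]], tiers[["Prediction"]]))
  invisible(x)
}

#' Average amino-acid enrichment (AAC) of a mutational dataset
#'
#' Arithmetic mean of all enrichment values across every condition
#' (antibiotics and their concentrations), optionally restricted to a
#' mutation subset. Wild-type-like fitness corresponds to ~1; an AAC above
#' 1 for a predicted set indicates preferential selection of enriched
#' (fitter) variants.
#'
#' @param table data.frame with columns `mutation`, `condition`,
#'   `enrichment` (see [read_enrichment()]).
#' @param subset Optional character vector of mutations to restrict to.
#' @return Numeric scalar.
#' @export
compute_aac <- function(table, subset = NULL) {
  stopifnot(is.data.frame(table),
            all(c("mutation", "enrichment") %in% names(table)))
  if (nrow(table) == 0L) stop("empty enrichment table")
  rows <- table
  if (!is.null(subset)) {
    extra <- setdiff(subset, table$mutation)
    if (length(extra) > 0L) {
      stop("subset mutations absent from the table: ",
           paste(extra, collapse = ", "))
    }
    rows <- table[table$mutation %in% subset, , drop = FALSE]
  }
  if (nrow(rows) == 0L) stop("empty selection")
  stopifnot(all(is.finite(rows$enrichment)))
  mean(rows$enrichment)
}

#' Read a mutational-enrichment TSV
#'
#' @param path TSV path.
#' @param columns Named character vector mapping the required names
#'   (`mutation`, `condition`, `enrichment`) to the file's column names,
#'   for files with non-standard layouts.
#' @return data.frame with columns `mutation`, `condition`, `enrichment`.
#' @export
read_enrichment <- function(path, columns = c(mutation = "mutation",
                                              condition = "condition",
                                              enrichment = "enrichment")) {
  stopifnot(all(c("mutation", "enrichment") %in% names(columns)))
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(columns), names(raw))
  if (length(missing) > 0L) {
    stop("enrichment file lacks column(s): ", paste(missing, collapse = ", "))
  }
  out <- data.frame(mutation = raw[[columns[["mutation"]]]],
                    enrichment = as.numeric(raw[[columns[["enrichment"]]]]),
                    stringsAsFactors = FALSE)
  out$condition <- if ("condition" %in% names(columns)) {
    raw[[columns[["condition"]]]]
  } else "all"
  out[, c("mutation", "condition", "enrichment")]
}

#' Overlap between predicted and experimentally covered mutations
#'
#' @param predictions Character vector of predicted mutation notations.
#' @param experimental Character vector of experimentally measured
#'   mutation notations.
#' @param total_space_size Optional size of the full single-mutation space
#'   (19 x target length), for context.
#' @return List with `n_predicted`, `n_experimental`, `n_overlap`,
#'   `overlap` (the shared notations), and `total_space_size`.
#' @export
overlap_report <- function(predictions, experimental, total_space_size = NULL) {
  check <- function(x, label) {
    ok <- grepl("^[A-Z][0-9]+[A-Z]$", x)
    if (any(!ok)) {
      warning("dropping malformed ", label, " notation(s): ",
              paste(unique(x[!ok]), collapse = ", "))
    }
    unique(x[ok])
  }
  p <- check(predictions, "prediction")
  e <- check(experimental, "experimental")
  shared <- intersect(p, e)
  list(n_predicted = length(p), n_experimental = length(e),
       n_overlap = length(shared), overlap = shared,
       total_space_size = total_space_size)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a prediction report to disk
#'
#' Emits `per_site.tsv`, `ranked.tsv`, `bundled.tsv` and `report.json`
#' (bundled predictions plus the full configuration echo and its hash, for
#' provenance: two runs with the same hash are identical).
#'
#' @param result An `ssp_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ssp_report <- function(result, dir) {
  stopifnot(inherits(result, "ssp_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(result$per_site, "per_site.tsv")
  wr(result$ranked, "ranked.tsv")
  wr(result$bundled, "bundled.tsv")
  payload <- list(config = unclass(result$config),
                  config_hash = config_hash(result$config),
                  n_trees = result$n_trees,
                  bundled = result$bundled)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
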