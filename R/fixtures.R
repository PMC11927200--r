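#' Specification of one planted descriptor trend
#'
#' Describes a synthetic evolutionary signal at one site: along the
#' root-to-target chain, the residue at `site` walks a ladder of amino
#' acids whose values on `accession` are monotone in `direction`, with
#' exactly `n_transitions` group changes and optional Gaussian noise (in
#' scale units) on the intended descriptor values before they are snapped
#' back to residues.
#'
#' @param site 1-based site (fixtures are gap-free, so site equals both the
#'   alignment column and the ungapped target position).
#' @param accession One of the nine embedded descriptor accessions.
#' @param direction `+1` (increasing) or `-1` (decreasing).
#' @param n_transitions Number of group transitions (`>= 3` to survive the
#'   eligibility filter).
#' @param noise_sd Standard deviation of the value noise, in scale units.
#' @return Object of class `plant_spec`.
#' @export
plant_spec <- function(site, accession, direction = 1L, n_transitions = 3L,
                       noise_sd = 0) {
  stopifnot(site >= 1L, accession %in% AAINDEX_ACCESSIONS,
            direction %in% c(-1L, 1L), n_transitions >= 1L, noise_sd >= 0)
  structure(list(site = as.integer(site), accession = accession,
                 direction = as.integer(direction),
                 n_transitions = as.integer(n_transitions),
                 noise_sd = noise_sd),
            class = "plant_spec")
}

# ladder of residues with strictly monotone values on a scale
# (duplicated values keep the alphabetically first residue)
scale_ladder <- function(scale, direction) {
  v <- sort(scale$values)                # ties keep name order (alphabetical)
  v <- v[!duplicated(unname(v))]
  if (direction < 0) v <- rev(v)
  v
}

plant_chain <- function(spec, scale, path_length) {
  n_groups <- spec$n_transitions + 1L
  if (n_groups > path_length) {
    stop("impossible spec at site ", spec$site,
         ": n_transitions + 1 exceeds the number of path nodes")
  }
  ladder <- scale_ladder(scale, spec$direction)
  # leave headroom at the recent end so a successor residue exists
  top <- max(n_groups, ceiling(0.75 * length(ladder)))
  if (top > length(ladder)) {
    stop("impossible spec at site ", spec$site,
         ": scale has too few distinct values for ", n_groups, " groups")
  }
  idx <- unique(round(seq(1, top, length.out = n_groups)))
  if (length(idx) < n_groups) {
    stop("impossible spec at site ", spec$site,
         ": cannot place ", n_groups, " strictly monotone groups")
  }
  ideal <- unname(ladder[idx])
  residues <- character(n_groups)
  prev <- NULL
  for (g in seq_len(n_groups)) {
    value <- ideal[g] + if (spec$noise_sd > 0) stats::rnorm(1L, 0, spec$noise_sd) else 0
    residues[g] <- nearest_residue(value, scale, exclude = prev)
    prev <- residues[g]
  }
  # spread groups over the path nodes, earlier groups absorb the remainder
  sizes <- rep(path_length %/% n_groups, n_groups)
  extra <- path_length %% n_groups
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  list(column = rep(residues, times = sizes), groups = residues,
       ideal = ideal)
}

#' Generate a synthetic evolutionary history with planted trends
#'
#' Builds a fully self-contained toy input for the predictor: a rooted
#' caterpillar tree whose internal spine is the root-to-target main path
#' (each spine node also bears a short dummy leaf), aligned gap-free
#' sequences for every spine node and the target, and a truth table of the
#' planted trends. Non-planted sites are constant (default) or i.i.d.
#' random down the path. Deterministic under a fixed seed.
#'
#' @param specs A list of [plant_spec()] objects (distinct sites).
#' @param n_sites Total alignment columns.
#' @param path_length Number of nodes on the main path (root, ancestors,
#'   target).
#' @param seed Integer seed.
#' @param edge_range Branch lengths of the spine are drawn uniformly from
#'   this range (substitutions/site).
#' @param background `"constant"` or `"iid"` residues at non-planted sites.
#' @param target_id Label of the target leaf.
#' @param table An `aaindex_table` supplying the scales.
#' @return Object of class `ssp_history`: list with `newick` (string),
#'   `tree` (parsed [ape::phylo]), `sequences` (named vector: spine nodes
#'   root-first, then target), `truth` (data.frame: `site`, `accession`,
#'   `direction`, `n_transitions`, `wild_type`, `last_value`), and `seed`.
#' @export
make_history <- function(specs, n_sites = 50L, path_length = 8L, seed = 1L,
                         edge_range = c(0.05, 0.3),
                         background = c("constant", "iid"),
                         target_id = "target",
                         table = load_default_indices()) {
  background <- match.arg(background)
  if (inherits(specs, "plant_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1L), "plant_spec")),
            path_length >= 2L, n_sites >= 1L)
  sites <- vapply(specs, `[[`, integer(1L), "site")
  if (anyDuplicated(sites)) stop("planted sites must be distinct")
  if (any(sites > n_sites)) stop("planted site beyond n_sites")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  mat <- matrix("", nrow = path_length, ncol = n_sites)
  for (j in seq_len(n_sites)) {
    if (background == "constant") {
      mat[, j] <- sample(AA_ALPHABET, 1L)
    } else {
      mat[, j] <- sample(AA_ALPHABET, path_length, replace = TRUE)
    }
  }
  truth <- data.frame(site = integer(0), accession = character(0),
                      direction = integer(0), n_transitions = integer(0),
                      wild_type = character(0), last_value = numeric(0),
                      stringsAsFactors = FALSE)
  for (spec in specs) {
    chain <- plant_chain(spec, table[[spec$accession]], path_length)
    mat[, spec$site] <- chain$column
    truth <- rbind(truth, data.frame(
      site = spec$site, accession = spec$accession,
      direction = spec$direction, n_transitions = spec$n_transitions,
      wild_type = chain$groups[length(chain$groups)],
      last_value = unname(table[[spec$accession]]$values[chain$groups[length(chain$groups)]]),
      stringsAsFactors = FALSE))
  }

  edges <- stats::runif(path_length - 1L, edge_range[1L], edge_range[2L])
  spine <- paste0("A", seq_len(path_length - 1L))
  nwk <- paste0(target_id, ":", format(edges[path_length - 1L], digits = 10))
  if (path_length > 2L) {
    for (i in seq(path_length - 1L, 2L)) {
      nwk <- paste0("(", nwk, ",D", i, ":0.05)", spine[i], ":",
                    format(edges[i - 1L], digits = 10))
    }
  }
  nwk <- paste0("(", nwk, ",D1:0.05)", spine[1L], ";")

  seqs <- apply(mat, 1L, paste, collapse = "")
  names(seqs) <- c(spine, target_id)
  structure(list(newick = nwk, tree = read_newick(nwk), sequences = seqs,
                 truth = truth, seed = as.integer(seed)),
            class = "ssp_history")
}

#' @export
print.ssp_history <- function(x, ...) {
  cat(sprintf("Synthetic history: %d-node main path, %d sites, %d planted trend(s), seed %d\n",
              length(x$sequences), nchar(x$sequences[1L]), nrow(x$truth), x$seed))
  invisible(x)
}

#' Generate a synthetic mutational-enrichment table
#'
#' Emulates a deep-mutational-scanning readout across antibiotic/condition
#' panels: every mutation gets one enrichment value per condition,
#' log-normally scattered around `baseline` (wild-type-like fitness ~1
#' corresponds to `baseline = 1`), with mutations in `predicted` boosted to
#' `baseline + boost`. With `noise_sd = 0` the group means are exact, which
#' gives closed-form expected AAC values.
#'
#' @param mutations Character vector of mutation notations.
#' @param predicted Subset of `mutations` to boost.
#' @param baseline Mean enrichment of unboosted mutations (> 0).
#' @param boost Additive mean enrichment for `predicted` (> 0).
#' @param noise_sd sdlog of the multiplicative log-normal noise.
#' @param conditions Character vector of condition labels.
#' @param seed Integer seed.
#' @return data.frame with columns `mutation`, `condition`, `enrichment`.
#' @export
make_enrichment_table <- function(mutations, predicted = character(0),
                                  baseline = 0.8, boost = 0.6,
                                  noise_sd = 0,
                                  conditions = paste0(
                                    rep(c("kanamycin", "neomycin", "paromomycin",
                                          "ribostamycin", "butirosin", "gentamicinB"),
                                        each = 2L),
                                    "_", c("1x", "4x")),
                                  seed = 1L) {
  stopifnot(baseline > 0, boost > 0, all(predicted %in% mutations))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  grid <- expand.grid(mutation = mutations, condition = conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- ifelse(grid$mutation %in% predicted, baseline + boost, baseline)
  noise <- if (noise_sd > 0) exp(stats::rnorm(nrow(grid), 0, noise_sd)) else 1
  grid$enrichment <- mu * noise
  grid
}
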