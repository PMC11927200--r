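#' Read an amino-acid FASTA file
#'
#' @param path Path to a FASTA file. Gapped (aligned) sequences are allowed.
#' @return Named character vector of sequences (names are record ids). An
#'   empty file yields an empty vector.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "X-]"), seqs)
  if (any(bad)) {
    stop("non amino-acid characters in record(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of (possibly gapped) sequences.
#' @param path Output path.
#' @return `path`, invisibly. `read_fasta(write_fasta(x, p))` recovers `x`.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Sanitize sequence headers for downstream tree/alignment tools
#'
#' Phylogenetics toolchains commonly break on parentheses, colons, semicolons
#' or headers starting with a digit. Every character outside
#' `[A-Za-z0-9_.-]` is replaced with `_`; a header starting with a digit is
#' prefixed `s_`; collisions after cleaning are disambiguated with numeric
#' suffixes so the old-to-new mapping stays bijective.
#'
#' @param ids Character vector of headers, or a named character vector of
#'   sequences (in which case names are cleaned and the sequences returned
#'   renamed).
#' @return A list with `ids` (or `seqs` when sequences were given) and `map`,
#'   a data.frame with columns `old`, `new`.
#' @export
sanitize_headers <- function(ids) {
  seqs <- NULL
  if (!is.null(names(ids)) && any(nzchar(names(ids)))) {
    seqs <- ids
    ids <- names(ids)
  }
  stopifnot(is.character(ids), all(nzchar(ids)))
  new <- gsub("[^A-Za-z0-9_.-]", "_", ids)
  starts_digit <- grepl("^[0-9]", new)
  new[starts_digit] <- paste0("s_", new[starts_digit])
  # de-duplicate while keeping the first occurrence untouched
  while (anyDuplicated(new)) {
    for (dup in unique(new[duplicated(new)])) {
      at <- which(new == dup)
      new[at[-1L]] <- paste0(dup, "_", seq_along(at[-1L]))
    }
  }
  map <- data.frame(old = ids, new = new, stringsAsFactors = FALSE)
  if (is.null(seqs)) list(ids = new, map = map)
  else list(seqs = stats::setNames(unname(seqs), new), map = map)
}

#' Read a rooted Newick tree with labelled internal nodes
#'
#' Trees must carry branch lengths and unique labels on every internal node,
#' as emitted by ancestral-reconstruction pipelines (each internal label must
#' be resolvable to a reconstructed sequence).
#'
#' @param path Path to a Newick file, or a Newick string.
#' @return An [ape::phylo] object, validated.
#' @export
read_newick <- function(path) {
  tree <- if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
  if (is.null(tree)) stop("could not parse Newick input")
  validate_rooted_tree(tree)
  tree
}

validate_rooted_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree is not rooted")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree is missing branch lengths")
  }
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label)) ||
      anyNA(tree$node.label)) {
    stop("internal nodes must all be labelled; relabel the tree ",
         "(ancestral-reconstruction tools emit labelled nodes)")
  }
  labels <- c(tree$tip.label, tree$node.label)
  if (anyDuplicated(labels)) {
    stop("duplicate node labels: ", paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  invisible(tree)
}

#' Extract the main path (root to target) from a rooted tree
#'
#' The main path is the ordered chain of nodes from the root down to the
#' target leaf; trajectories are read column-wise along it. Every node on
#' the path must have an attached sequence and all such sequences must be
#' mutually aligned (equal gapped length).
#'
#' @param tree A validated rooted [ape::phylo] with labelled internal nodes.
#' @param node_sequences Named character vector mapping node labels to
#'   aligned sequences (ancestors and target at minimum).
#' @param target_id Tip label of the target protein.
#' @return An object of class `main_path`: list with `nodes` (labels,
#'   root first), `edge_lengths`, `cumulative` (prefix sums, `cumulative[1]
#'   = 0`), and `sequences` (aligned, parallel to `nodes`).
#' @export
extract_main_path <- function(tree, node_sequences, target_id) {
  validate_rooted_tree(tree)
  stopifnot(is.character(node_sequences), !is.null(names(node_sequences)))
  tip <- match(target_id, tree$tip.label)
  if (is.na(tip)) stop("target '", target_id, "' is not a leaf of the tree")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  idx_path <- ape::nodepath(tree, from = root, to = tip)
  label_of <- function(i) {
    if (i <= ntip) tree$tip.label[i] else tree$node.label[i - ntip]
  }
  nodes <- vapply(idx_path, label_of, character(1L))
  edge_key <- paste(tree$edge[, 1L], tree$edge[, 2L])
  edges <- vapply(seq_len(length(idx_path) - 1L), function(k) {
    e <- match(paste(idx_path[k], idx_path[k + 1L]), edge_key)
    tree$edge.length[e]
  }, numeric(1L))
  missing <- setdiff(nodes, names(node_sequences))
  if (length(missing) > 0L) {
    stop("no sequence for path node(s): ", paste(missing, collapse = ", "))
  }
  seqs <- unname(node_sequences[nodes])
  if (length(unique(nchar(seqs))) != 1L) {
    stop("path sequences are not aligned (unequal lengths); ",
         "provide a pre-aligned set (see the dataset-preparation vignette)")
  }
  structure(list(nodes = nodes, edge_lengths = edges,
                 cumulative = c(0, cumsum(edges)), sequences = seqs),
            class = "main_path")
}

#' @export
print.main_path <- function(x, ...) {
  cat(sprintf("Main path: %d nodes, root '%s' -> target '%s', depth %.4g subst/site\n",
              length(x$nodes), x$nodes[1L], x$nodes[length(x$nodes)],
              x$cumulative[length(x$cumulative)]))
  invisible(x)
}

#' Mean evolutionary step along a main path
#'
#' The extrapolation step used to place the predicted successor: the average
#' branch length between consecutive nodes of the main path (all edges, in
#' substitutions/site).
#'
#' @param path A `main_path`.
#' @return Positive scalar.
#' @export
mean_step <- function(path) {
  stopifnot(inherits(path, "main_path"))
  if (length(path$nodes) < 2L) stop("main path has a single node; no steps to average")
  mean(path$edge_lengths)
}

#' Map alignment columns to 1-based ungapped target positions
#'
#' @param path A `main_path`.
#' @return Integer vector, one entry per alignment column: the 1-based
#'   position on the ungapped target sequence, or `NA` where the target has
#'   a gap.
#' @keywords internal
target_positions <- function(path) {
  target <- strsplit(path$sequences[length(path$sequences)], "")[[1L]]
  pos <- cumsum(target != "-")
  pos[target == "-"] <- NA_integer_
  as.integer(pos)
}
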