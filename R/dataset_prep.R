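#' Homolog-filter and partitioning configuration
#'
#' Defaults reproduce the published dataset-curation settings: homologs at
#' 30-90% identity to the target, 80-120% of its length, clustering at 90%
#' identity into up to 150 clusters, and 150-sequence files.
#'
#' @param min_identity,max_identity Identity window (fractions, inclusive).
#' @param min_length_frac,max_length_frac Length window relative to the
#'   ungapped target length (inclusive).
#' @param cluster_identity Clustering identity used upstream (recorded for
#'   provenance; clustering itself is consumed as input).
#' @param seqs_per_file Sequences per partition file.
#' @param n_clusters Maximum number of clusters.
#' @param seed Integer seed for the randomised file construction.
#' @return Object of class `homolog_filter_config`.
#' @export
homolog_filter_config <- function(min_identity = 0.30, max_identity = 0.90,
                                  min_length_frac = 0.80, max_length_frac = 1.20,
                                  cluster_identity = 0.90,
                                  seqs_per_file = 150L, n_clusters = 150L,
                                  seed = 1L) {
  stopifnot(0 < min_identity, min_identity < max_identity, max_identity <= 1,
            0 < min_length_frac, min_length_frac < max_length_frac,
            seqs_per_file >= 1L, n_clusters >= 1L)
  structure(list(min_identity = min_identity, max_identity = max_identity,
                 min_length_frac = min_length_frac,
                 max_length_frac = max_length_frac,
                 cluster_identity = cluster_identity,
                 seqs_per_file = as.integer(seqs_per_file),
                 n_clusters = as.integer(n_clusters),
                 seed = as.integer(seed)),
            class = "homolog_filter_config")
}

#' Pairwise sequence identity
#'
#' Fraction of identical positions over a global pairwise alignment. When
#' no alignment is supplied one is computed (Needleman-Wunsch via
#' `Biostrings::pairwiseAlignment`, BLOSUM62, affine gaps). The default
#' denominator is the full alignment length including gap columns;
#' `denominator = "shorter"` divides by the shorter ungapped sequence
#' instead.
#'
#' @param a,b Amino-acid sequences (plain strings, gaps ignored).
#' @param alignment Optional length-2 character vector of pre-aligned
#'   (equal-length, gapped) versions of `a` and `b`.
#' @param denominator `"alignment"` (default) or `"shorter"`.
#' @return Identity in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, alignment = NULL,
                              denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  a <- gsub("-", "", a); b <- gsub("-", "", b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (is.null(alignment)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
    pa <- as.character(Biostrings::alignedPattern(aln))
    pb <- as.character(Biostrings::alignedSubject(aln))
  } else {
    stopifnot(length(alignment) == 2L, nchar(alignment[1L]) == nchar(alignment[2L]))
    pa <- alignment[1L]; pb <- alignment[2L]
  }
  ca <- strsplit(pa, "")[[1L]]
  cb <- strsplit(pb, "")[[1L]]
  matches <- sum(ca == cb & ca != "-")
  denom <- switch(denominator,
                  alignment = length(ca),
                  shorter = min(nchar(a), nchar(b)))
  matches / denom
}

#' Filter candidate homologs on identity and length windows
#'
#' Retains candidates whose identity to the target lies in
#' `[min_identity, max_identity]` (too-similar sequences carry no trend
#' information; too-divergent ones are unreliable) and whose ungapped
#' length is within `[min_length_frac, max_length_frac]` of the target's.
#' Boundaries are inclusive.
#'
#' @param target Target sequence (string).
#' @param candidates Named character vector of candidate sequences.
#' @param cfg A [homolog_filter_config()].
#' @param identities Optional named numeric vector of precomputed
#'   target-candidate identities (e.g. from an upstream search tool); any
#'   candidate not covered is aligned internally.
#' @return List with `retained` (named character vector) and `rejected`
#'   (data.frame `id`, `reason`).
#' @export
filter_homologs <- function(target, candidates, cfg = homolog_filter_config(),
                            identities = NULL) {
  stopifnot(inherits(cfg, "homolog_filter_config"),
            is.character(candidates), !is.null(names(candidates)))
  len_target <- nchar(gsub("-", "", target))
  ids <- names(candidates)
  reasons <- character(0); rejected_ids <- character(0)
  keep <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    id <- ids[i]
    len_frac <- nchar(gsub("-", "", candidates[i])) / len_target
    pid <- if (!is.null(identities) && id %in% names(identities)) {
      identities[[id]]
    } else {
      pairwise_identity(target, candidates[i])
    }
    reason <- NULL
    if (pid < cfg$min_identity) reason <- "identity below minimum"
    else if (pid > cfg$max_identity) reason <- "identity above maximum (too similar)"
    else if (len_frac < cfg$min_length_frac) reason <- "too short"
    else if (len_frac > cfg$max_length_frac) reason <- "too long"
    if (is.null(reason)) keep[i] <- TRUE
    else { rejected_ids <- c(rejected_ids, id); reasons <- c(reasons, reason) }
  }
  list(retained = candidates[keep],
       rejected = data.frame(id = rejected_ids, reason = reasons,
                             stringsAsFactors = FALSE))
}

#' Partition clustered sequences into diversity-maximising sequence files
#'
#' Builds the per-tree sequence files from a cluster assignment: each file
#' takes one sequence from every cluster, the target appears in every file,
#' and within a cluster sequences are drawn without replacement across
#' files until the cluster is exhausted, then its pool resets (with a fresh
#' shuffle). Enough files are generated to exhaust the largest cluster, so
#' every input sequence appears in at least one file. Deterministic under a
#' fixed seed.
#'
#' @param clusters Data.frame with columns `id`, `cluster`, or a named
#'   vector mapping id to cluster.
#' @param target_id Id of the target sequence (must be assigned).
#' @param cfg A [homolog_filter_config()] (supplies the seed).
#' @param n_files Number of files; defaults to the size of the largest
#'   cluster.
#' @return List of character vectors of sequence ids, one per file. If the
#'   draw for the target's cluster is not the target itself, the target is
#'   appended (file size may exceed one-per-cluster by one).
#' @export
build_sequence_files <- function(clusters, target_id,
                                 cfg = homolog_filter_config(),
                                 n_files = NULL) {
  if (!is.data.frame(clusters)) {
    clusters <- data.frame(id = names(clusters), cluster = unname(clusters),
                           stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "cluster") %in% names(clusters)),
            !anyDuplicated(clusters$id))
  if (nrow(clusters) == 0L) stop("zero clusters")
  if (!target_id %in% clusters$id) stop("target '", target_id, "' not assigned to a cluster")
  by_cluster <- split(clusters$id, clusters$cluster)
  if (is.null(n_files)) n_files <- max(lengths(by_cluster))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)
  # per-cluster pick streams: repeated shuffles, consumed one per file
  picks <- lapply(by_cluster, function(ids) {
    stream <- character(0)
    while (length(stream) < n_files) {
      stream <- c(stream, if (length(ids) == 1L) ids else sample(ids))
    }
    stream[seq_len(n_files)]
  })
  lapply(seq_len(n_files), function(f) {
    members <- vapply(picks, `[`, character(1L), f)
    if (!target_id %in% members) members <- c(members, target_id)
    unname(members)
  })
}
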