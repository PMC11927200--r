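# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# textbook Pearson correlation
pearson_hand <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# weighted least squares by the normal equations
wols_hand <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x * x); sxy <- sum(w * x * y)
  slope <- (sw * sxy - sx * sy) / (sw * sxx - sx * sx)
  intercept <- (sy - slope * sx) / sw
  c(intercept = intercept, slope = slope)
}

# loop-based run-length grouping
rle_hand <- function(chars) {
  if (length(chars) == 0L) return(data.frame(residue = character(0),
                                             first = integer(0), last = integer(0)))
  res <- list()
  start <- 1L
  for (i in seq_along(chars)[-1L]) {
    if (chars[i] != chars[i - 1L]) {
      res[[length(res) + 1L]] <- c(chars[start], start, i - 1L)
      start <- i
    }
  }
  res[[length(res) + 1L]] <- c(chars[start], start, length(chars))
  data.frame(residue = vapply(res, `[`, character(1L), 1L),
             first = as.integer(vapply(res, `[`, character(1L), 2L)),
             last = as.integer(vapply(res, `[`, character(1L), 3L)),
             stringsAsFactors = FALSE)
}

# minimal recursive-descent Newick reader: returns data.frame
# (node, parent, length); root has parent NA
newick_hand <- function(text) {
  text <- sub(";\\s*$", "", trimws(text))
  pos <- 1L
  chars <- strsplit(text, "")[[1L]]
  peek <- function() if (pos <= length(chars)) chars[pos] else ""
  take_label <- function() {
    out <- ""
    while (pos <= length(chars) && !peek() %in% c("(", ")", ",", ":")) {
      out <- paste0(out, chars[pos]); pos <<- pos + 1L
    }
    out
  }
  rows <- NULL
  parse_node <- function(parent) {
    children <- character(0)
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        parse_node(NA)      # parent patched below via closure list
        children <- c(children, last_label)
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("parse error")
      }
    }
    label <- take_label()
    len <- NA_real_
    if (peek() == ":") {
      pos <<- pos + 1L
      len <- as.numeric(take_label())
    }
    for (ch in children) rows$parent[rows$node == ch] <<- label
    rows <<- rbind(rows, data.frame(node = label, parent = NA_character_,
                                    length = len, stringsAsFactors = FALSE))
    last_label <<- label
    invisible(label)
  }
  last_label <- NA_character_
  parse_node(NA)
  rows
}

# root-to-tip path by repeated parent lookups on the ape edge matrix
parent_chase_hand <- function(tree, target_label) {
  ntip <- length(tree$tip.label)
  label_of <- function(i) if (i <= ntip) tree$tip.label[i] else tree$node.label[i - ntip]
  node <- match(target_label, tree$tip.label)
  path <- node
  repeat {
    row <- which(tree$edge[, 2L] == node)
    if (length(row) == 0L) break
    node <- tree$edge[row, 1L]
    path <- c(node, path)
  }
  vapply(path, label_of, character(1L))
}

# a small scale object for synthetic tests
toy_scale <- function(values, accession = "FASG760101",
                      category = "Size", property = "toy") {
  tab <- load_default_indices()
  s <- tab[[1L]]
  s$accession <- accession
  s$category <- category
  s$property <- property
  s$values[names(values)] <- values
  s
}

# trajectory built directly from a residue column and node distances
toy_trajectory <- function(residues, positions = seq_along(residues) - 1) {
  path <- toy_path(residues, positions)
  build_trajectory(path, 0L)
}

# single-column main path with given residues down the chain
toy_path <- function(residues, positions = seq_along(residues) - 1) {
  structure(list(nodes = paste0("n", seq_along(residues)),
                 edge_lengths = diff(positions),
                 cumulative = positions,
                 sequences = residues),
            class = "main_path")
}
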