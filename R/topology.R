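#' Canonical topology key of a leaf-labelled tree
#'
#' Encodes a tree topology as a canonical string that is invariant to child
#' order, internal node identity, and (for unrooted input) tree orientation:
#' every internal node is written as its children's keys sorted
#' lexicographically inside parentheses, a leaf as its label. Two trees yield
#' equal keys iff they have the same leaf set and the same topology.
#'
#' When `outgroup` is given, the tree is rooted on that leaf and the outgroup
#' is *excluded* from the key: the key describes the rooted topology of the
#' remaining leaves. With no outgroup, a rooted tree is encoded as rooted, and
#' an unrooted tree is canonically anchored at its lexicographically smallest
#' leaf. Branch lengths never enter the key.
#'
#' @param tree a `phylo` tree.
#' @param outgroup optional leaf label used to root the tree; excluded from
#'   the key.
#' @return a character topology key.
#' @examples
#' t1 <- ape::read.tree(text = "((A,B),C,O);")
#' canonical_key(t1, outgroup = "O")  # "((A,B),C)"
#' @export
canonical_key <- function(tree, outgroup = NULL) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  ntip <- length(tips)
  nb <- adjacency_list(tree)
  dfs <- function(node, parent) {
    kids <- nb[[node]]
    kids <- kids[kids != parent]
    if (!length(kids)) return(tips[node])
    keys <- vapply(kids, dfs, character(1L), parent = node)
    if (length(keys) == 1L) return(keys)          # collapse unary passthrough
    paste0("(", paste(sort(keys, method = "radix"), collapse = ","), ")")
  }
  if (!is.null(outgroup)) {
    og <- which(tips == outgroup)
    if (length(og) != 1L)
      ts_error(sprintf("outgroup '%s' is not a leaf of the tree", outgroup),
               "treestab_lookup_error")
    start <- nb[[og]]
    if (length(start) != 1L)
      ts_error("malformed tree: leaf with degree != 1", "treestab_input_error")
    return(dfs(start, og))
  }
  if (ape::is.rooted(tree)) {
    return(dfs(ntip + 1L, 0L))
  }
  a <- sort(tips, method = "radix")[1L]
  an <- which(tips == a)
  rest <- dfs(nb[[an]], an)
  paste0("(", paste(sort(c(a, rest), method = "radix"), collapse = ","), ")")
}

# undirected adjacency list over node ids of a phylo tree
adjacency_list <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  nb <- vector("list", nn)
  e <- tree$edge
  for (k in seq_len(nrow(e))) {
    nb[[e[k, 1L]]] <- c(nb[[e[k, 1L]]], e[k, 2L])
    nb[[e[k, 2L]]] <- c(nb[[e[k, 2L]]], e[k, 1L])
  }
  nb
}

# parse a topology key string into nested lists of labels
parse_key <- function(key) {
  toks <- regmatches(key, gregexpr("[(),]|[^(),]+", key))[[1L]]
  pos <- 1L
  parse_node <- function() {
    if (pos > length(toks))
      ts_error("malformed topology key", "treestab_format_error")
    tk <- toks[pos]
    if (tk == "(") {
      pos <<- pos + 1L
      kids <- list(parse_node())
      while (pos <= length(toks) && toks[pos] == ",") {
        pos <<- pos + 1L
        kids[[length(kids) + 1L]] <- parse_node()
      }
      if (pos > length(toks) || toks[pos] != ")")
        ts_error("malformed topology key: unbalanced parentheses",
                 "treestab_format_error")
      pos <<- pos + 1L
      kids
    } else if (tk == ")" || tk == ",") {
      ts_error("malformed topology key", "treestab_format_error")
    } else {
      pos <<- pos + 1L
      tk
    }
  }
  out <- parse_node()
  if (pos <= length(toks))
    ts_error("malformed topology key: trailing text", "treestab_format_error")
  out
}

serialize_key <- function(node) {
  if (is.character(node)) return(node)
  paste0("(", paste(sort(vapply(node, serialize_key, character(1L)),
                         method = "radix"),
                    collapse = ","), ")")
}

key_leaves_rec <- function(node) {
  if (is.character(node)) return(node)
  unlist(lapply(node, key_leaves_rec), use.names = FALSE)
}

#' Leaf labels appearing in a topology key
#' @param key a topology key string.
#' @return character vector of leaf labels (sorted).
#' @export
key_leaves <- function(key) sort(key_leaves_rec(parse_key(key)), method = "radix")

#' Re-serialize a topology key into canonical form
#' @param key a topology key (or Newick-like string without branch lengths).
#' @return the canonical key string.
#' @export
canonicalize_key <- function(key) {
  serialize_key(parse_key(sub(";$", "", key)))
}

#' Transport a topology key into another family's label universe
#'
#' Relabels every leaf of `key` through the paralog `map` and re-canonicalizes,
#' so that topologies of family A can be compared with those of family B.
#'
#' @param key a topology key.
#' @param map a `label_map` whose domain covers the key's leaves.
#' @return the relabelled canonical key.
#' @export
map_labels <- function(key, map) {
  stopifnot(inherits(map, "label_map"))
  relabel <- function(node) {
    if (is.character(node)) {
      if (!node %in% names(map))
        ts_error(sprintf("label map does not cover leaf '%s'", node),
                 "treestab_lookup_error")
      return(unname(map[[node]]))
    }
    lapply(node, relabel)
  }
  serialize_key(relabel(parse_key(key)))
}

#' Closest outgroup of a clade
#'
#' The sequence outside the ingroup with the smallest mean p-distance to the
#' ingroup members; ties are broken by lexicographic label order.
#'
#' @param dm labelled distance matrix containing the ingroup and at least one
#'   other label.
#' @param ingroup character vector of ingroup labels.
#' @return the selected outgroup label.
#' @export
closest_outgroup <- function(dm, ingroup) {
  labs <- rownames(dm)
  missing <- setdiff(ingroup, labs)
  if (length(missing))
    ts_error(sprintf("ingroup label(s) not in matrix: %s",
                     paste(missing, collapse = ", ")),
             "treestab_lookup_error")
  cand <- sort(setdiff(labs, ingroup), method = "radix")
  if (!length(cand))
    ts_error("no label outside the ingroup to serve as outgroup",
             "treestab_input_error")
  md <- vapply(cand, function(x) mean(dm[x, ingroup]), numeric(1L))
  cand[which.min(md)]
}

#' Number of rooted binary topologies for n leaves
#'
#' The count of distinct rooted, leaf-labelled binary tree shapes,
#' `(2n - 3)!!`: 1 for two leaves, 3 for three, 105 for five.
#'
#' @param n_leaves integer >= 2.
#' @return the topology count (numeric; exact up to ordinary double range).
#' @export
n_rooted_topologies <- function(n_leaves) {
  if (length(n_leaves) != 1L || is.na(n_leaves) || n_leaves < 2 ||
      n_leaves != floor(n_leaves))
    ts_error("n_leaves must be a single integer >= 2", "treestab_input_error")
  if (n_leaves == 2) return(1)
  prod(seq(3, 2 * n_leaves - 3, by = 2))
}

#' Define a clade to analyse
#'
#' @param ingroup character vector of at least two alignment labels.
#' @param outgroup optional single label outside the ingroup; when `NULL` the
#'   closest outgroup is chosen from the full alignment's distance matrix at
#'   analysis time.
#' @return a `clade_spec`.
#' @export
clade_spec <- function(ingroup, outgroup = NULL) {
  ingroup <- as.character(ingroup)
  if (length(ingroup) < 2L || anyDuplicated(ingroup))
    ts_error("ingroup must contain at least two distinct labels",
             "treestab_input_error")
  if (!is.null(outgroup)) {
    if (length(outgroup) != 1L)
      ts_error("outgroup must be a single label", "treestab_input_error")
    if (outgroup %in% ingroup)
      ts_error("outgroup must not be part of the ingroup", "treestab_input_error")
  }
  structure(list(ingroup = ingroup, outgroup = outgroup), class = "clade_spec")
}
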