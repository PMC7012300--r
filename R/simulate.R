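#' Evolve an alignment along a tree under the Jukes-Cantor model
#'
#' Sites evolve independently. Along a branch of length `b` (expected
#' substitutions per site) each site changes with probability
#' `3/4 * (1 - exp(-4 b / 3))`, and a changing site picks one of the other
#' three bases uniformly — the JC69 transition probability. Leaf labels become
#' the alignment labels.
#'
#' @param tree a rooted `phylo` with non-negative branch lengths.
#' @param n_sites number of alignment columns to simulate.
#' @param root_sequence optional root sequence (string over `ACGT` of length
#'   `n_sites`); uniform random when `NULL`.
#' @param seed optional RNG seed; when `NULL` the current RNG state is used
#'   (so composite generators can seed once).
#' @return a `dna_alignment` with one row per leaf, in tip-label order.
#' @export
evolve_jc69 <- function(tree, n_sites, root_sequence = NULL, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    ts_error("tree needs branch lengths", "treestab_input_error")
  if (any(tree$edge.length < 0))
    ts_error("negative branch length", "treestab_input_error")
  if (length(n_sites) != 1L || n_sites < 1)
    ts_error("n_sites must be a positive integer", "treestab_input_error")
  n_sites <- as.integer(n_sites)
  if (!is.null(seed)) set.seed(seed)
  nt <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  if (is.null(root_sequence)) {
    rootv <- sample.int(4L, n_sites, replace = TRUE)
  } else {
    ch <- strsplit(toupper(root_sequence), "", fixed = TRUE)[[1L]]
    if (length(ch) != n_sites || !all(ch %in% nt))
      ts_error("root_sequence must be an ACGT string of length n_sites",
               "treestab_input_error")
    rootv <- match(ch, nt)
  }
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- rootv
  tr <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1L]; child <- tr$edge[k, 2L]
    b <- tr$edge.length[k]
    p <- 0.75 * (1 - exp(-4 * b / 3))
    s <- seqs[[par]]
    mut <- which(runif(n_sites) < p)
    if (length(mut))
      s[mut] <- ((s[mut] - 1L + sample.int(3L, length(mut), replace = TRUE)) %% 4L) + 1L
    seqs[[child]] <- s
  }
  out <- vapply(seq_len(ntip),
                function(i) paste(nt[seqs[[i]]], collapse = ""),
                character(1L))
  dna_alignment(out, tree$tip.label)
}

# tip labels descending from a node of a rooted phylo
tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, tips_under, tree = tree), use.names = FALSE)
}

subtree_min_label <- function(tree, node) {
  sort(tips_under(tree, node), method = "radix")[1L]
}

#' Nearest-neighbor interchange around an internal branch
#'
#' Rearranges the four subtrees meeting at the branch above internal node
#' `node`: one of `node`'s two child subtrees (chosen by `partner`) is moved
#' up to become `node`'s sibling, and the current sibling subtree moves down
#' in its place. Branch lengths travel with their subtrees. Performing the
#' rearrangement and then, on the result, requesting the original sibling's
#' label as `partner` restores the original topology.
#'
#' @param tree a rooted binary `phylo`.
#' @param node internal node id (not the root) identifying the branch from
#'   its parent; `NULL` picks one at random.
#' @param partner the smallest leaf label of the child subtree of `node` to
#'   exchange with `node`'s sibling; `NULL` picks one of the two at random.
#' @return the rearranged `phylo`, with attribute `"nni"` recording
#'   `node`, `moved_out` and `moved_in` (smallest-leaf labels).
#' @export
nni_perturb <- function(tree, node = NULL, partner = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 4L || !ape::is.rooted(tree))
    ts_error("NNI needs a rooted binary tree with at least 4 leaves",
             "treestab_input_error")
  if (ape::Nnode(tree) != ntip - 1L)
    ts_error("NNI needs a strictly binary tree", "treestab_input_error")
  root <- ntip + 1L
  internal <- setdiff(unique(tree$edge[, 2L]), seq_len(ntip))
  if (!length(internal))
    ts_error("tree has no internal branch", "treestab_input_error")
  if (is.null(node)) {
    node <- if (length(internal) == 1L) internal
            else internal[sample.int(length(internal), 1L)]
  }
  node <- as.integer(node)
  if (node <= ntip || node == root || !node %in% internal)
    ts_error("node must identify a non-root internal node (an internal branch)",
             "treestab_input_error")
  e <- tree$edge
  par <- e[e[, 2L] == node, 1L]
  kids <- e[e[, 1L] == node, 2L]
  sib <- setdiff(e[e[, 1L] == par, 2L], node)
  if (length(kids) != 2L || length(sib) != 1L)
    ts_error("NNI needs a strictly binary tree", "treestab_input_error")
  kid_labels <- vapply(kids, subtree_min_label, character(1L), tree = tree)
  sib_label <- subtree_min_label(tree, sib)
  if (is.null(partner)) partner <- kid_labels[sample.int(2L, 1L)]
  if (!partner %in% kid_labels) {
    if (identical(partner, sib_label))
      ts_error("partner already is the sibling subtree; choose a child of 'node'",
               "treestab_input_error")
    ts_error(sprintf(
      "partner '%s' does not identify a child subtree of node %d (children: %s)",
      partner, node, paste(kid_labels, collapse = ", ")),
      "treestab_input_error")
  }
  moved <- kids[kid_labels == partner]
  e[e[, 2L] == moved, 1L] <- par
  e[e[, 2L] == sib, 1L] <- node
  tree$edge <- e
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "nni") <- list(node = node, moved_out = partner,
                            moved_in = sib_label)
  tree
}

#' Simulate a duplicated gene-family pair
#'
#' Emulates an original and a duplicated gene family (e.g. alpha/beta chain
#' paralogs): family A evolves on `species_tree`; family B evolves on the same
#' tree when `agree = TRUE`, or on a copy perturbed by one nearest-neighbor
#' interchange when `agree = FALSE`. Labels are prefixed `A_` / `B_` and the
#' returned label map pairs them by species.
#'
#' @param species_tree rooted binary `phylo` with >= 4 leaves and branch
#'   lengths in substitutions/site.
#' @param agree should family B share family A's topology?
#' @param n_sites alignment length for each family (default 1000).
#' @param seed master RNG seed for the whole pair.
#' @param nni_node,partner passed to [nni_perturb()] when `agree = FALSE`
#'   (random internal branch by default).
#' @return a `family_pair` list: `alignment_a`, `alignment_b`, `map`,
#'   `tree_a`, `tree_b`, `seed`.
#' @export
make_family_pair <- function(species_tree, agree = TRUE, n_sites = 1000,
                             seed = 1, nni_node = NULL, partner = NULL) {
  stopifnot(inherits(species_tree, "phylo"))
  if (length(species_tree$tip.label) < 4L)
    ts_error("species_tree needs at least 4 leaves", "treestab_input_error")
  set.seed(seed)
  species <- species_tree$tip.label
  aln_a <- evolve_jc69(species_tree, n_sites)
  rownames(aln_a) <- paste0("A_", species)
  tree_b <- if (agree) species_tree
            else nni_perturb(species_tree, node = nni_node, partner = partner)
  aln_b <- evolve_jc69(tree_b, n_sites)
  rownames(aln_b) <- paste0("B_", tree_b$tip.label)
  tree_a <- species_tree
  tree_a$tip.label <- paste0("A_", species)
  tree_b2 <- tree_b
  tree_b2$tip.label <- paste0("B_", tree_b$tip.label)
  structure(list(alignment_a = aln_a,
                 alignment_b = aln_b,
                 map = label_map(paste0("A_", species), paste0("B_", species)),
                 tree_a = tree_a,
                 tree_b = tree_b2,
                 seed = seed),
            class = "family_pair")
}

#' A 9-species primate-like fixture tree
#'
#' A rooted binary tree mirroring the scale of typical primate gene-family
#' datasets: three hominoid-like species, three Old-World-monkey-like species,
#' two New-World-monkey-like species and one basal prosimian-like species,
#' with branch lengths in substitutions/site giving moderate signal at
#' ~1000 sites.
#'
#' @return a rooted `phylo` with 9 tips.
#' @export
example_species_tree <- function() {
  ape::read.tree(text = paste0(
    "(((((hom1:0.02,hom2:0.02):0.015,hom3:0.035):0.04,",
    "((owm1:0.02,owm2:0.02):0.015,owm3:0.035):0.04):0.05,",
    "(nwm1:0.06,nwm2:0.06):0.055):0.08,pro1:0.19);"))
}
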