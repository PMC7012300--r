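# Independent oracles and fixture builders used across the suite.

# edge ids along the path between two nodes of a phylo (BFS over the
# undirected edge graph); independent of the package's own tree code
path_edges <- function(tree, from, to) {
  e <- tree$edge
  nn <- length(tree$tip.label) + tree$Nnode
  adj <- vector("list", nn)
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1]]] <- rbind(adj[[e[k, 1]]], c(e[k, 2], k))
    adj[[e[k, 2]]] <- rbind(adj[[e[k, 2]]], c(e[k, 1], k))
  }
  prev_node <- rep(NA_integer_, nn)
  prev_edge <- rep(NA_integer_, nn)
  queue <- from
  prev_node[from] <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == to) break
    for (r in seq_len(nrow(adj[[v]] %||% matrix(0, 0, 2)))) {
      w <- adj[[v]][r, 1]
      if (is.na(prev_node[w])) {
        prev_node[w] <- v
        prev_edge[w] <- adj[[v]][r, 2]
        queue <- c(queue, w)
      }
    }
  }
  out <- integer(0)
  v <- to
  while (v != from) {
    out <- c(out, prev_edge[v])
    v <- prev_node[v]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ordinary least-squares fit of branch lengths for a fixed topology;
# returns the residual sum of squares against the distance matrix
ls_rss <- function(tree, dm) {
  tips <- tree$tip.label
  n <- length(tips)
  pairs <- t(combn(n, 2))
  A <- matrix(0, nrow(pairs), nrow(tree$edge))
  d <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    A[r, path_edges(tree, pairs[r, 1], pairs[r, 2])] <- 1
    d[r] <- dm[tips[pairs[r, 1]], tips[pairs[r, 2]]]
  }
  qrA <- qr(A)
  b <- qr.coef(qrA, d)
  b[is.na(b)] <- 0
  sum((A %*% b - d)^2)
}

# exhaustive best-fit topology: enumerate every unrooted topology on the
# matrix labels and pick the one with minimal least-squares RSS
ls_best_topology_key <- function(dm) {
  labs <- rownames(dm)
  all_t <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  rss <- vapply(all_t, ls_rss, numeric(1), dm = dm)
  canonical_key(all_t[[which.min(rss)]])
}

# a random additive distance matrix with its generating unrooted topology key
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.5))
  dm <- ape::cophenetic.phylo(tr)
  dm <- dm[order(rownames(dm)), order(rownames(dm))]
  list(dm = dm, key = canonical_key(ape::unroot(tr)), tree = tr)
}

# shuffle the representation of a rooted tree without changing its topology:
# random child rotations plus a Newick round-trip
shuffle_tree <- function(tree) {
  ntip <- length(tree$tip.label)
  for (node in (ntip + 1):(ntip + tree$Nnode)) {
    if (runif(1) < 0.5) tree <- tryCatch(ape::rotate(tree, node),
                                         error = function(e) tree)
  }
  ape::read.tree(text = ape::write.tree(tree))
}

# five-taxon fixture: four ingroup species plus one outgroup, internal
# branches of 0.05 substitutions/site
pair_fixture_tree <- function() {
  ape::read.tree(
    text = "(((s1:0.05,s2:0.05):0.05,(s3:0.05,s4:0.05):0.05):0.05,og:0.15);")
}

fixture_clades <- function() {
  list(a = clade_spec(paste0("A_", c("s1", "s2", "s3", "s4")), "A_og"),
       b = clade_spec(paste0("B_", c("s1", "s2", "s3", "s4")), "B_og"))
}
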