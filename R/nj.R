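#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou–Nei neighbor joining with the Q-criterion, written for
#' deterministic, label-order-invariant output: when several pairs tie for the
#' minimal Q value, the pair whose (sorted) cluster representative labels are
#' lexicographically smallest is joined (a cluster is represented by the
#' smallest leaf label it contains). Branch lengths come from the usual NJ
#' formulas; negative estimates are clamped to zero in the output only, after
#' the topology has been decided, and are never redistributed.
#'
#' @param dm symmetric labelled distance matrix (e.g. from
#'   [p_distance_matrix()]), at least 3 labels.
#' @return an unrooted binary `phylo` tree over the matrix labels.
#' @examples
#' aln <- dna_alignment(c(a = "AAAA", b = "AAAT", c = "ATTT"))
#' nj_tree(p_distance_matrix(aln))
#' @export
nj_tree <- function(dm) {
  if (!is.matrix(dm) || is.null(rownames(dm)))
    ts_error("dm must be a labelled square matrix", "treestab_input_error")
  n <- nrow(dm)
  if (n < 3L)
    ts_error("neighbor joining needs at least 3 labels", "treestab_input_error")
  if (!isTRUE(all.equal(unname(dm), unname(t(dm)), tolerance = 1e-8)) ||
      any(!is.finite(dm)))
    ts_error("dm must be symmetric and finite", "treestab_input_error")

  D <- unname(dm)
  reps <- rownames(dm)            # smallest leaf label in each cluster
  nwk <- rownames(dm)             # growing Newick fragment per cluster
  fmt <- function(x) formatC(max(x, 0), digits = 10, format = "g")
  N <- n
  while (N > 3L) {
    r <- rowSums(D)
    Q <- (N - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    tie <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    tie <- tie[tie[, 1L] < tie[, 2L], , drop = FALSE]
    k1 <- pmin(reps[tie[, 1L]], reps[tie[, 2L]])
    k2 <- pmax(reps[tie[, 1L]], reps[tie[, 2L]])
    pick <- order(k1, k2)[1L]
    i <- tie[pick, 1L]; j <- tie[pick, 2L]
    dij <- D[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (N - 2))
    lj <- dij - li
    # print the cluster with the smaller representative first
    if (reps[i] <= reps[j]) {
      merged <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    } else {
      merged <- sprintf("(%s:%s,%s:%s)", nwk[j], fmt(lj), nwk[i], fmt(li))
    }
    others <- setdiff(seq_len(N), c(i, j))
    dnew <- (D[i, others] + D[j, others] - dij) / 2
    keep <- c(others, i)
    D <- D[keep, keep, drop = FALSE]
    D[N - 1L, seq_len(N - 2L)] <- dnew
    D[seq_len(N - 2L), N - 1L] <- dnew
    D[N - 1L, N - 1L] <- 0
    reps <- c(reps[others], min(reps[i], reps[j]))
    nwk <- c(nwk[others], merged)
    N <- N - 1L
  }
  # final three clusters join at a single internal node
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  o <- order(reps)
  lens <- c(l1, l2, l3)[o]
  parts <- nwk[o]
  text <- sprintf("(%s:%s,%s:%s,%s:%s);",
                  parts[1], fmt(lens[1]),
                  parts[2], fmt(lens[2]),
                  parts[3], fmt(lens[3]))
  ape::read.tree(text = text)
}
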