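#' Bootstrap configuration
#'
#' @param n_replicates number of bootstrap replications (default 1000).
#' @param seed integer RNG seed; recorded in every result so that stochastic
#'   outputs are bit-reproducible.
#' @param deletion missing-data handling for p-distances, as in
#'   [p_distance_matrix()].
#' @return a `bootstrap_config`.
#' @export
bootstrap_config <- function(n_replicates = 1000, seed = 1,
                             deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  if (length(n_replicates) != 1L || is.na(n_replicates) || n_replicates < 1)
    ts_error("n_replicates must be a positive integer", "treestab_input_error")
  if (length(seed) != 1L || is.na(seed))
    ts_error("seed must be a single integer", "treestab_input_error")
  structure(list(n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 deletion = deletion),
            class = "bootstrap_config")
}

#' Resample alignment columns with replacement
#'
#' One bootstrap replicate: draws `n_sites` column indices with replacement
#' and applies the same indices to every sequence, preserving record order.
#' Uses the current RNG state; callers seed once per replicate stream.
#'
#' @param alignment a `dna_alignment`.
#' @return a resampled `dna_alignment` of identical dimensions.
#' @export
resample_columns <- function(alignment) {
  stopifnot(inherits(alignment, "dna_alignment"))
  n <- ncol(alignment)
  idx <- sample.int(n, n, replace = TRUE)
  structure(unclass(alignment)[, idx, drop = FALSE], class = "dna_alignment")
}

# canonical encodings of the internal-edge bipartitions of an unrooted tree:
# each split is written as the sorted labels of the side NOT containing the
# lexicographically smallest leaf, joined by "|".
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  ntip <- length(tips)
  anchor <- sort(tips, method = "radix")[1L]
  e <- tree$edge
  nn <- ntip + tree$Nnode
  below <- vector("list", nn)
  for (i in seq_len(ntip)) below[[i]] <- tips[i]
  # edges in postorder so children are filled before parents
  for (k in ape::postorder(tree)) {
    # accumulate child tip sets into parents
    below[[e[k, 1L]]] <- c(below[[e[k, 1L]]], below[[e[k, 2L]]])
  }
  out <- character(0)
  for (k in seq_len(nrow(e))) {
    child <- e[k, 2L]
    if (child <= ntip) next                      # pendant edge
    side <- below[[child]]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (anchor %in% side) side <- setdiff(tips, side)
    out <- c(out, paste(sort(side, method = "radix"), collapse = "|"))
  }
  unique(out)
}

#' Per-branch bootstrap support (Pb) of an NJp tree
#'
#' Builds the point-estimate neighbor-joining tree on p-distances, then for
#' each bootstrap replicate resamples the alignment columns, rebuilds the NJp
#' tree, and counts how often each interior branch (bipartition) of the
#' point-estimate tree recurs. Pb is that percentage, annotated onto the
#' point-estimate tree's internal nodes.
#'
#' @param alignment a `dna_alignment` with at least 4 sequences.
#' @param config a [bootstrap_config()].
#' @return a `pb_result`: list with `tree` (the `phylo` point estimate with Pb
#'   values as node labels), `support` (data frame: bipartition, count, pb),
#'   plus `n_replicates`, `seed`, `deletion`.
#' @export
compute_pb <- function(alignment, config = bootstrap_config()) {
  stopifnot(inherits(alignment, "dna_alignment"),
            inherits(config, "bootstrap_config"))
  if (nrow(alignment) < 4L)
    ts_error("Pb needs at least 4 sequences (no interior branch otherwise)",
             "treestab_input_error")
  tree <- nj_tree(p_distance_matrix(alignment, config$deletion))
  parts <- tree_bipartitions(tree)
  counts <- stats::setNames(integer(length(parts)), parts)
  set.seed(config$seed)
  for (r in seq_len(config$n_replicates)) {
    rep_tree <- nj_tree(p_distance_matrix(resample_columns(alignment),
                                          config$deletion))
    hit <- parts %in% tree_bipartitions(rep_tree)
    counts[hit] <- counts[hit] + 1L
  }
  pb <- 100 * counts / config$n_replicates
  tree <- annotate_pb(tree, pb)
  structure(list(tree = tree,
                 support = data.frame(bipartition = parts,
                                      count = unname(counts),
                                      pb = unname(pb),
                                      stringsAsFactors = FALSE),
                 n_replicates = config$n_replicates,
                 seed = config$seed,
                 deletion = config$deletion),
            class = "pb_result")
}

# write Pb values into the node labels of the point-estimate tree
annotate_pb <- function(tree, pb) {
  tips <- tree$tip.label
  ntip <- length(tips)
  anchor <- sort(tips, method = "radix")[1L]
  labs <- rep("", tree$Nnode)
  e <- tree$edge
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tips[i]
  for (k in ape::postorder(tree))
    below[[e[k, 1L]]] <- c(below[[e[k, 1L]]], below[[e[k, 2L]]])
  for (k in seq_len(nrow(e))) {
    child <- e[k, 2L]
    if (child <= ntip) next
    side <- below[[child]]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (anchor %in% side) side <- setdiff(tips, side)
    enc <- paste(sort(side, method = "radix"), collapse = "|")
    if (enc %in% names(pb))
      labs[child - ntip] <- formatC(pb[[enc]], digits = 1, format = "f")
  }
  tree$node.label <- labs
  tree
}

#' @export
print.pb_result <- function(x, ...) {
  cat(sprintf("NJp bootstrap support (Pb): %d replicates, seed %d, %s deletion\n",
              x$n_replicates, x$seed, x$deletion))
  print(x$support, row.names = FALSE)
  invisible(x)
}

#' Construct a subtree topology frequency table directly
#'
#' Mostly used internally and in worked examples: wraps an explicit tally of
#' rooted subtree topologies (one key per replicate) into the object returned
#' by [topology_frequencies()].
#'
#' @param keys character vector of topology keys (canonicalized on entry).
#' @param counts integer replicate counts, one per key.
#' @param outgroup,seed,deletion optional metadata.
#' @return a `topology_freq` object.
#' @examples
#' ft <- frequency_table(c("((A,B),C)", "((B,C),A)", "((A,C),B)"),
#'                       c(850, 100, 50))
#' compute_ps(ft)$ps  # 85
#' @export
frequency_table <- function(keys, counts, outgroup = NA_character_,
                            seed = NA_integer_, deletion = NA_character_) {
  if (length(keys) != length(counts) || !length(keys))
    ts_error("keys and counts must be non-empty and of equal length",
             "treestab_input_error")
  if (any(counts < 0) || any(counts != floor(counts)))
    ts_error("counts must be non-negative integers", "treestab_input_error")
  keys <- vapply(keys, canonicalize_key, character(1L), USE.NAMES = FALSE)
  if (anyDuplicated(keys))
    ts_error("duplicate topology keys in frequency table", "treestab_input_error")
  leafsets <- vapply(keys, function(k) paste(key_leaves(k), collapse = ","),
                     character(1L))
  if (length(unique(leafsets)) != 1L)
    ts_error("all keys in a frequency table must share one leaf set",
             "treestab_input_error")
  o <- order(keys, method = "radix")
  keys <- keys[o]; counts <- as.integer(counts[o])
  total <- sum(counts)
  structure(list(key = keys,
                 count = counts,
                 percent = 100 * counts / total,
                 n_replicates = total,
                 ingroup = key_leaves(keys[1L]),
                 outgroup = outgroup,
                 seed = seed,
                 deletion = deletion),
            class = "topology_freq")
}

#' Bootstrap frequency of each rooted subtree topology of a clade
#'
#' The shared primitive under Ps and Pr. The clade's ingroup plus one outgroup
#' (given, or the closest by mean p-distance on the full alignment) form a
#' reduced alignment. For each replicate the reduced alignment's columns are
#' resampled, an NJp tree is built, rooted on the outgroup, and the canonical
#' rooted topology key of the ingroup recorded. Every replicate yields exactly
#' one binary key (NJ tie-breaking is canonical, so no replicate is
#' discarded), hence the percentages sum to 100.
#'
#' @param alignment a `dna_alignment` containing the clade and outgroup
#'   candidates.
#' @param clade a [clade_spec()] with an ingroup of at least 3 labels.
#' @param config a [bootstrap_config()].
#' @return a `topology_freq`: keys, integer counts, percents, plus the
#'   outgroup used, seed, deletion mode and replicate total.
#' @export
topology_frequencies <- function(alignment, clade, config = bootstrap_config()) {
  stopifnot(inherits(alignment, "dna_alignment"),
            inherits(config, "bootstrap_config"))
  if (!inherits(clade, "clade_spec")) clade <- clade_spec(clade)
  if (length(clade$ingroup) < 3L)
    ts_error("subtree topology frequencies need an ingroup of at least 3 labels",
             "treestab_stability_undefined")
  og <- resolve_outgroup(alignment, clade, config$deletion)
  reduced <- subset_alignment(alignment, c(clade$ingroup, og))
  keys <- character(config$n_replicates)
  set.seed(config$seed)
  for (r in seq_len(config$n_replicates)) {
    rep_tree <- nj_tree(p_distance_matrix(resample_columns(reduced),
                                          config$deletion))
    keys[r] <- canonical_key(rep_tree, outgroup = og)
  }
  tab <- table(keys)
  frequency_table(names(tab), as.integer(tab), outgroup = og,
                  seed = config$seed, deletion = config$deletion)
}

resolve_outgroup <- function(alignment, clade, deletion) {
  missing <- setdiff(clade$ingroup, rownames(alignment))
  if (length(missing))
    ts_error(sprintf("ingroup label(s) not in alignment: %s",
                     paste(missing, collapse = ", ")),
             "treestab_lookup_error")
  if (!is.null(clade$outgroup)) {
    if (!clade$outgroup %in% rownames(alignment))
      ts_error(sprintf("outgroup '%s' not in alignment", clade$outgroup),
               "treestab_lookup_error")
    return(clade$outgroup)
  }
  closest_outgroup(p_distance_matrix(alignment, deletion), clade$ingroup)
}

#' @export
print.topology_freq <- function(x, ...) {
  cat(sprintf(
    "Subtree topology frequencies: %d replicates, outgroup %s, seed %s\n",
    x$n_replicates, x$outgroup, x$seed))
  df <- data.frame(topology = x$key, count = x$count,
                   percent = round(x$percent, 1))
  print(df[order(-df$count), ], row.names = FALSE)
  invisible(x)
}

#' Serialize a frequency or support table as TSV
#'
#' Writes metadata header lines (prefixed `#`: seed, replicates, outgroup,
#' deletion mode) followed by the tabulated counts and percents.
#'
#' @param x a `topology_freq` or `pb_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "topology_freq")) {
    writeLines(c(sprintf("# replicates\t%d", x$n_replicates),
                 sprintf("# outgroup\t%s", x$outgroup),
                 sprintf("# seed\t%s", x$seed),
                 sprintf("# deletion\t%s", x$deletion)), con)
    df <- data.frame(topology = x$key, count = x$count, percent = x$percent)
  } else if (inherits(x, "pb_result")) {
    writeLines(c(sprintf("# replicates\t%d", x$n_replicates),
                 sprintf("# seed\t%s", x$seed),
                 sprintf("# deletion\t%s", x$deletion)), con)
    df <- x$support
  } else {
    ts_error("unsupported object for TSV serialization", "treestab_input_error")
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
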