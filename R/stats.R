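#' Stability (Ps) of a clade's subtree topology
#'
#' Ps is the bootstrap frequency of the modal rooted subtree topology of a
#' clade, computed from the reduced alignment of the ingroup plus its closest
#' outgroup. A high Pb for a branch says the branch recurs under resampling; a
#' high Ps says the whole subtree topology it subtends is settled. Ps is
#' undefined for 2-leaf ingroups: a rooted 2-leaf subtree has a single
#' possible topology, so its modal frequency is vacuously 100.
#'
#' @param x a `dna_alignment`, or a precomputed `topology_freq` table.
#' @param clade a [clade_spec()] (alignment method only), ingroup >= 3.
#' @param config a [bootstrap_config()] (alignment method only).
#' @param ... unused.
#' @return a `stability_result`: `ps` (percent), `modal_key`, `freq` (the full
#'   `topology_freq`), `outgroup`, `n_replicates`, `seed`.
#' @examples
#' ft <- frequency_table(c("((A,B),C)", "((B,C),A)", "((A,C),B)"),
#'                       c(850, 100, 50))
#' compute_ps(ft)$ps  # 85
#' @export
compute_ps <- function(x, ...) UseMethod("compute_ps")

#' @rdname compute_ps
#' @export
compute_ps.dna_alignment <- function(x, clade, config = bootstrap_config(), ...) {
  if (!inherits(clade, "clade_spec")) clade <- clade_spec(clade)
  if (length(clade$ingroup) < 3L)
    ts_error("Ps is undefined for a 2-leaf ingroup", "treestab_stability_undefined")
  compute_ps(topology_frequencies(x, clade, config))
}

#' @rdname compute_ps
#' @export
compute_ps.topology_freq <- function(x, ...) {
  ps <- max(x$percent)
  modal <- sort(x$key[x$percent == ps], method = "radix")[1L]
  structure(list(ps = ps,
                 modal_key = modal,
                 freq = x,
                 outgroup = x$outgroup,
                 n_replicates = x$n_replicates,
                 seed = x$seed),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Ps = %.1f%%  (modal topology %s; %d replicates, outgroup %s)\n",
              x$ps, x$modal_key, x$n_replicates, x$outgroup))
  invisible(x)
}

#' Bootstrap frequency of one target subtree topology (Pr1)
#'
#' The percent of bootstrap replicates in which the clade's rooted subtree
#' topology equals `target` — 0 if the target never occurs. This is the
#' directed half of the reproducibility statistic: with `target` set to the
#' other family's topology (transported through the label map), it measures
#' how often this family reproduces it.
#'
#' @param x a `dna_alignment`, or a precomputed `topology_freq` table.
#' @param target a topology key over the clade's ingroup labels.
#' @param clade a [clade_spec()] (alignment method only).
#' @param config a [bootstrap_config()] (alignment method only).
#' @param ... unused.
#' @return percent in `[0, 100]`.
#' @export
compute_pr1 <- function(x, ...) UseMethod("compute_pr1")

#' @rdname compute_pr1
#' @export
compute_pr1.dna_alignment <- function(x, clade, target,
                                      config = bootstrap_config(), ...) {
  compute_pr1(topology_frequencies(x, clade, config), target)
}

#' @rdname compute_pr1
#' @export
compute_pr1.topology_freq <- function(x, target, ...) {
  target <- canonicalize_key(target)
  if (!identical(key_leaves(target), x$ingroup))
    ts_error("target topology's leaf set does not match the clade ingroup",
             "treestab_input_error")
  hit <- x$key == target
  if (any(hit)) x$percent[hit] else 0
}

#' Reproducibility (Pr) between two paralogous gene-family clades
#'
#' For families A and B whose clade members correspond one-to-one through
#' `map` (e.g. alpha- and beta-chain paralogs matched by species): T1 and T2
#' are the rooted point-estimate subtree topologies of the two clades; Pr1 is
#' the bootstrap frequency with which family A's subtree yields T2 (carried
#' into A's labels through the inverse map), Pr2 the frequency with which
#' family B yields T1, and Pr = (Pr1 + Pr2) / 2 exactly. Each family is rooted
#' on its own closest outgroup unless the clade specifies one.
#'
#' `alignment_a` and `alignment_b` may be the same object for within-family
#' comparisons of two different clades.
#'
#' @param alignment_a,alignment_b `dna_alignment`s of the two families.
#' @param clade_a,clade_b [clade_spec()]s with ingroups of >= 3 labels.
#' @param map a `label_map` carrying clade A ingroup labels to clade B's, or
#'   `NULL` for a within-family comparison of two clades over the same labels
#'   (the identity correspondence).
#' @param config a [bootstrap_config()]; the same seed is applied to each
#'   family's replicate stream, so Ps and Pr1 computed at one seed share
#'   replicates.
#' @param topology_source where T1/T2 come from: `"subtree"` (default) reads
#'   them off the point-estimate NJp trees of the reduced clade+outgroup
#'   sub-alignments; `"full-tree"` reads them off the NJp trees of the full
#'   alignments, restricted to the clade; `"given"` takes them from `t1`/`t2`.
#' @param t1,t2 topology keys (or `phylo` trees, rooted or with the clade
#'   outgroup present) used when `topology_source = "given"`.
#' @return a `reproducibility_result`: `pr1`, `pr2`, `pr`, `t1`, `t2`,
#'   `outgroup_a`, `outgroup_b`, `freq_a`, `freq_b`, `n_replicates`, `seed`.
#' @export
compute_pr <- function(alignment_a, clade_a, alignment_b, clade_b, map,
                       config = bootstrap_config(),
                       topology_source = c("subtree", "full-tree", "given"),
                       t1 = NULL, t2 = NULL) {
  stopifnot(inherits(alignment_a, "dna_alignment"),
            inherits(alignment_b, "dna_alignment"),
            inherits(config, "bootstrap_config"))
  topology_source <- match.arg(topology_source)
  if (!inherits(clade_a, "clade_spec")) clade_a <- clade_spec(clade_a)
  if (!inherits(clade_b, "clade_spec")) clade_b <- clade_spec(clade_b)
  if (length(clade_a$ingroup) < 3L || length(clade_b$ingroup) < 3L)
    ts_error("Pr needs ingroups of at least 3 labels",
             "treestab_stability_undefined")
  if (is.null(map)) {
    # within-family comparison: the two clades share one label universe
    if (!setequal(clade_a$ingroup, clade_b$ingroup))
      ts_error("map = NULL needs clades over identical ingroup labels",
               "treestab_input_error")
    ing_map <- structure(stats::setNames(clade_a$ingroup, clade_a$ingroup),
                         class = "label_map")
  } else {
    stopifnot(inherits(map, "label_map"))
    if (!all(clade_a$ingroup %in% names(map)))
      ts_error("label map does not cover clade A's ingroup",
               "treestab_input_error")
    if (!setequal(unname(map[clade_a$ingroup]), clade_b$ingroup))
      ts_error("label map does not carry clade A's ingroup onto clade B's",
               "treestab_input_error")
    ing_map <- structure(stats::setNames(unname(map[clade_a$ingroup]),
                                         clade_a$ingroup),
                         class = "label_map")
  }
  ing_map_inv <- structure(stats::setNames(names(ing_map), unname(ing_map)),
                           class = "label_map")

  og_a <- resolve_outgroup(alignment_a, clade_a, config$deletion)
  og_b <- resolve_outgroup(alignment_b, clade_b, config$deletion)

  point_key <- function(alignment, clade, og) {
    reduced <- subset_alignment(alignment, c(clade$ingroup, og))
    canonical_key(nj_tree(p_distance_matrix(reduced, config$deletion)),
                  outgroup = og)
  }
  full_key <- function(alignment, clade, og) {
    tree <- nj_tree(p_distance_matrix(alignment, config$deletion))
    pruned <- ape::keep.tip(tree, c(clade$ingroup, og))
    canonical_key(pruned, outgroup = og)
  }
  as_key <- function(t, clade, og, which) {
    if (is.null(t))
      ts_error(sprintf("topology_source = 'given' requires %s", which),
               "treestab_input_error")
    if (inherits(t, "phylo")) {
      t <- if (og %in% t$tip.label) canonical_key(t, outgroup = og)
           else canonical_key(t)
    } else t <- canonicalize_key(t)
    if (!identical(key_leaves(t), sort(clade$ingroup, method = "radix")))
      ts_error(sprintf("%s leaf set does not match the clade ingroup", which),
               "treestab_input_error")
    t
  }
  t1 <- switch(topology_source,
               "subtree"   = point_key(alignment_a, clade_a, og_a),
               "full-tree" = full_key(alignment_a, clade_a, og_a),
               "given"     = as_key(t1, clade_a, og_a, "t1"))
  t2 <- switch(topology_source,
               "subtree"   = point_key(alignment_b, clade_b, og_b),
               "full-tree" = full_key(alignment_b, clade_b, og_b),
               "given"     = as_key(t2, clade_b, og_b, "t2"))

  clade_a <- clade_spec(clade_a$ingroup, og_a)
  clade_b <- clade_spec(clade_b$ingroup, og_b)
  freq_a <- topology_frequencies(alignment_a, clade_a, config)
  freq_b <- topology_frequencies(alignment_b, clade_b, config)
  pr1 <- compute_pr1(freq_a, map_labels(t2, ing_map_inv))
  pr2 <- compute_pr1(freq_b, map_labels(t1, ing_map))

  structure(list(pr1 = pr1, pr2 = pr2, pr = (pr1 + pr2) / 2,
                 t1 = t1, t2 = t2,
                 outgroup_a = og_a, outgroup_b = og_b,
                 freq_a = freq_a, freq_b = freq_b,
                 topology_source = topology_source,
                 n_replicates = config$n_replicates,
                 seed = config$seed),
            class = "reproducibility_result")
}

#' @export
print.reproducibility_result <- function(x, ...) {
  cat(sprintf("Pr1 = %.1f%%  Pr2 = %.1f%%  Pr = %.1f%%\n", x$pr1, x$pr2, x$pr))
  cat(sprintf("  T1 = %s (outgroup %s)\n", x$t1, x$outgroup_a))
  cat(sprintf("  T2 = %s (outgroup %s)\n", x$t2, x$outgroup_b))
  cat(sprintf("  %d replicates, seed %d, T1/T2 from %s\n",
              x$n_replicates, x$seed, x$topology_source))
  invisible(x)
}

# round half-up at one decimal (report formatting; raw values stay unrounded)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' All-pairs reproducibility table
#'
#' Runs [compute_pr()] for every requested pair of families and tabulates Pr1,
#' Pr2 and Pr (percent, rounded half-up to one decimal as in standard
#' reporting).
#'
#' @param families named list; each element is `list(alignment =, clade =)`.
#' @param pairs two-column character matrix/data frame of family names (ordered
#'   pairs); default all unordered pairs in list order.
#' @param maps how to map labels between ordered pairs: `NULL` (default)
#'   matches species tokens via [build_species_map()] with `delim`; or a
#'   function `(name_a, name_b) -> label_map`; or a named list of `label_map`s
#'   keyed `"A-B"`.
#' @param config a [bootstrap_config()].
#' @param delim species-token delimiter for the default map builder.
#' @param topology_source passed to [compute_pr()].
#' @return data frame with columns `pair`, `pr1`, `pr2`, `pr`.
#' @export
pairwise_pr <- function(families, pairs = NULL, maps = NULL,
                        config = bootstrap_config(), delim = "_",
                        topology_source = "subtree") {
  if (is.null(names(families)) || any(!nzchar(names(families))))
    ts_error("families must be a named list", "treestab_input_error")
  if (length(families) < 2L)
    ts_error("need at least two families", "treestab_input_error")
  if (is.null(pairs)) {
    pairs <- t(utils::combn(names(families), 2L))
  } else {
    pairs <- as.matrix(pairs)
    if (ncol(pairs) != 2L)
      ts_error("pairs must have two columns", "treestab_input_error")
  }
  get_map <- function(a, b) {
    fa <- families[[a]]; fb <- families[[b]]
    ca <- if (inherits(fa$clade, "clade_spec")) fa$clade else clade_spec(fa$clade)
    cb <- if (inherits(fb$clade, "clade_spec")) fb$clade else clade_spec(fb$clade)
    if (is.null(maps)) {
      if (identical(a, b)) NULL
      else build_species_map(ca$ingroup, cb$ingroup, delim = delim)
    } else if (is.function(maps)) {
      maps(a, b)
    } else {
      key <- paste0(a, "-", b)
      if (is.null(maps[[key]]))
        ts_error(sprintf("no label map provided for pair %s", key),
                 "treestab_input_error")
      maps[[key]]
    }
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]
    if (!a %in% names(families) || !b %in% names(families))
      ts_error(sprintf("unknown family in pair %s-%s", a, b),
               "treestab_input_error")
    res <- compute_pr(families[[a]]$alignment, families[[a]]$clade,
                      families[[b]]$alignment, families[[b]]$clade,
                      get_map(a, b), config,
                      topology_source = topology_source)
    data.frame(pair = paste0(a, "-", b),
               pr1 = round_half_up(res$pr1),
               pr2 = round_half_up(res$pr2),
               pr = round_half_up(res$pr),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
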