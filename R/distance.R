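#' p-distance matrix of an alignment
#'
#' The p-distance between two aligned sequences is the proportion of compared
#' sites at which they differ. Sites containing `-` or `N` are treated as
#' missing: under complete deletion every column with any missing character is
#' dropped before comparison; under pairwise deletion only the columns missing
#' in one of the two sequences being compared are dropped, per pair.
#'
#' @param alignment a `dna_alignment`.
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return symmetric numeric matrix with zero diagonal, entries in `[0, 1]`,
#'   dimnames = alignment labels, and a `"deletion"` attribute.
#' @examples
#' aln <- dna_alignment(c(a = "ACGT", b = "ACGA"))
#' p_distance_matrix(aln)["a", "b"]  # 0.25
#' @export
p_distance_matrix <- function(alignment, deletion = c("complete", "pairwise")) {
  stopifnot(inherits(alignment, "dna_alignment"))
  deletion <- match.arg(deletion)
  m <- unclass(alignment)
  if (nrow(m) < 2L)
    ts_error("need at least two sequences", "treestab_input_error")
  miss <- m == "-" | m == "N"
  if (deletion == "complete") {
    keep <- colSums(miss) == 0L
    m <- m[, keep, drop = FALSE]
    miss <- miss[, keep, drop = FALSE]
    if (ncol(m) == 0L)
      ts_error("no complete columns left after complete deletion",
               "treestab_data_error")
  }
  ok <- !miss
  same <- matrix(0, nrow(m), nrow(m))
  for (b in c("A", "C", "G", "T"))
    same <- same + tcrossprod((m == b) * 1)
  comp <- tcrossprod(ok * 1)
  off <- which(comp == 0 & !diag(nrow(m)), arr.ind = TRUE)
  if (nrow(off)) {
    labs <- rownames(m)
    ts_error(sprintf("no comparable sites between '%s' and '%s'",
                     labs[off[1L, 1L]], labs[off[1L, 2L]]),
             "treestab_data_error")
  }
  d <- 1 - same / comp
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  attr(d, "deletion") <- deletion
  d
}

#' Write a distance matrix as a PHYLIP-style square TSV
#' @param dm symmetric labelled distance matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distmat <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(dm)), con)
  for (i in seq_len(nrow(dm)))
    writeLines(paste(c(rownames(dm)[i],
                       formatC(dm[i, ], digits = 6, format = "g")),
                     collapse = "\t"), con)
  invisible(path)
}
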