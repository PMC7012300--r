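ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Construct an aligned DNA sequence set
#'
#' An alignment is stored as a character matrix (one row per sequence, one
#' column per site) of class `dna_alignment`. Sequences are case-folded to
#' upper case; the alphabet is restricted to `A C G T N -`, with `N` and `-`
#' both treated as missing for distance purposes.
#'
#' @param sequences character vector of aligned sequences (equal lengths).
#' @param labels unique, non-empty sequence labels. Labels may not contain
#'   Newick metacharacters (`( ) , ; :`) or whitespace, so that they can be
#'   embedded verbatim in Newick strings and topology keys.
#' @return a `dna_alignment` object.
#' @examples
#' aln <- dna_alignment(c(a = "ACGT", b = "ACGA"))
#' n_sites(aln)
#' @export
dna_alignment <- function(sequences, labels = names(sequences)) {
  if (!is.character(sequences) || length(sequences) < 1L)
    ts_error("sequences must be a non-empty character vector", "treestab_format_error")
  if (is.null(labels) || any(is.na(labels)) || any(!nzchar(labels)))
    ts_error("every record needs a non-empty label", "treestab_format_error")
  if (anyDuplicated(labels))
    ts_error(sprintf("duplicate label '%s'", labels[duplicated(labels)][1L]),
             "treestab_format_error")
  if (any(grepl("[(),;:[:space:]]", labels)))
    ts_error("labels may not contain '(', ')', ',', ';', ':' or whitespace",
             "treestab_format_error")
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    ts_error(sprintf("sequences are not aligned: lengths %s",
                     paste(sort(unique(lens)), collapse = ", ")),
             "treestab_alignment_error")
  mat <- matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
                nrow = length(sequences), byrow = TRUE,
                dimnames = list(labels, NULL))
  bad <- which(!(mat %in% ALN_ALPHABET))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(mat)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(mat)) + 1L
    ts_error(sprintf("illegal character '%s' in record '%s' at column %d",
                     mat[bad[1L]], labels[i], j),
             "treestab_format_error")
  }
  structure(mat, class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("DNA alignment: %d sequences x %d sites\n", nrow(x), ncol(x)))
  show <- utils::head(rownames(x), 8L)
  for (lab in show) {
    s <- paste(x[lab, seq_len(min(ncol(x), 50L))], collapse = "")
    cat(sprintf("  %-20s %s%s\n", lab, s, if (ncol(x) > 50L) "..." else ""))
  }
  if (nrow(x) > 8L) cat(sprintf("  ... and %d more\n", nrow(x) - 8L))
  invisible(x)
}

#' Number of alignment columns
#' @param alignment a `dna_alignment`.
#' @return integer site count.
#' @export
n_sites <- function(alignment) {
  stopifnot(inherits(alignment, "dna_alignment"))
  ncol(alignment)
}

#' Alignment sequence labels, in record order
#' @param alignment a `dna_alignment`.
#' @return character vector of labels.
#' @export
alignment_labels <- function(alignment) {
  stopifnot(inherits(alignment, "dna_alignment"))
  rownames(alignment)
}

#' Read an aligned FASTA file
#'
#' Parsing goes through [Biostrings::readDNAStringSet()]; the result is then
#' validated against the package's alignment contract (equal lengths, unique
#' labels, `A C G T N -` alphabet). The label is the first whitespace-separated
#' token of each header.
#'
#' @param path path to an aligned FASTA file with at least two records.
#' @return a `dna_alignment`, records in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    ts_error(sprintf("file not found: %s", path), "treestab_input_error")
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) ts_error(sprintf("failed to parse FASTA '%s': %s",
                                         path, conditionMessage(e)),
                                 "treestab_format_error"))
  if (length(set) < 2L)
    ts_error("an alignment needs at least two records", "treestab_format_error")
  labels <- sub("[[:space:]].*$", "", names(set))
  w <- Biostrings::width(set)
  if (length(unique(w)) != 1L)
    ts_error(sprintf("sequences are not aligned: lengths %s",
                     paste(sort(unique(w)), collapse = ", ")),
             "treestab_alignment_error")
  dna_alignment(as.character(set), labels)
}

#' Read a relaxed sequential PHYLIP alignment
#'
#' Accepts the relaxed variant: a header line `n_seq n_sites`, then for each
#' record a whitespace-separated name followed by sequence chunks (possibly
#' spanning lines) until `n_sites` characters have been read.
#'
#' @param path path to a PHYLIP file.
#' @return a `dna_alignment`.
#' @export
read_phylip <- function(path) {
  if (!file.exists(path))
    ts_error(sprintf("file not found: %s", path), "treestab_input_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    ts_error("empty PHYLIP file", "treestab_format_error")
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]))
  if (length(hdr) < 2L || any(is.na(hdr[1:2])) || hdr[1L] < 2L || hdr[2L] < 1L)
    ts_error("malformed PHYLIP header (expected 'n_seq n_sites')",
             "treestab_format_error")
  n_seq <- hdr[1L]; len <- hdr[2L]
  toks <- unlist(strsplit(trimws(lines[-1L]), "[[:space:]]+"), use.names = FALSE)
  labels <- character(n_seq); seqs <- character(n_seq)
  k <- 1L
  for (i in seq_len(n_seq)) {
    if (k > length(toks))
      ts_error(sprintf("PHYLIP file truncated: expected %d records", n_seq),
               "treestab_format_error")
    labels[i] <- toks[k]; k <- k + 1L
    s <- ""
    while (nchar(s) < len) {
      if (k > length(toks))
        ts_error(sprintf("sequence '%s' shorter than declared %d sites",
                         labels[i], len), "treestab_format_error")
      s <- paste0(s, toks[k]); k <- k + 1L
    }
    if (nchar(s) != len)
      ts_error(sprintf("sequence '%s' longer than declared %d sites",
                       labels[i], len), "treestab_format_error")
    seqs[i] <- s
  }
  if (k <= length(toks))
    ts_error("trailing data after the declared number of records",
             "treestab_format_error")
  dna_alignment(seqs, labels)
}

#' Write an alignment as FASTA
#' @param alignment a `dna_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(alignment, path) {
  stopifnot(inherits(alignment, "dna_alignment"))
  seqs <- apply(unclass(alignment), 1L, paste, collapse = "")
  writeLines(paste0(">", rownames(alignment), "\n", seqs), path)
  invisible(path)
}

#' Extract a sub-alignment by label
#'
#' @param alignment a `dna_alignment`.
#' @param labels labels to keep, in the requested order.
#' @return a `dna_alignment` with exactly those records; site count unchanged.
#' @export
subset_alignment <- function(alignment, labels) {
  stopifnot(inherits(alignment, "dna_alignment"))
  missing <- setdiff(labels, rownames(alignment))
  if (length(missing))
    ts_error(sprintf("label(s) not in alignment: %s",
                     paste(missing, collapse = ", ")),
             "treestab_lookup_error")
  if (anyDuplicated(labels))
    ts_error("requested labels contain duplicates", "treestab_input_error")
  structure(unclass(alignment)[labels, , drop = FALSE], class = "dna_alignment")
}

#' Construct a paralog label map
#'
#' A bijection from family-A labels to family-B labels, stored as a named
#' character vector (names = A, values = B). Domain and range must be disjoint.
#'
#' @param from,to equal-length character vectors of labels.
#' @return a `label_map`.
#' @export
label_map <- function(from, to) {
  if (length(from) != length(to) || !length(from))
    ts_error("label map needs equal-length, non-empty 'from' and 'to'",
             "treestab_format_error")
  if (anyDuplicated(from))
    ts_error(sprintf("duplicate map key '%s'", from[duplicated(from)][1L]),
             "treestab_format_error")
  if (anyDuplicated(to))
    ts_error(sprintf("duplicate map value '%s'", to[duplicated(to)][1L]),
             "treestab_format_error")
  if (length(intersect(from, to)))
    ts_error("label map domain and range overlap; families must use distinct labels",
             "treestab_format_error")
  structure(stats::setNames(as.character(to), as.character(from)),
            class = "label_map")
}

#' Read a two-column TSV paralog label map
#' @param path TSV with family-A labels in column 1, family-B in column 2.
#' @return a `label_map`.
#' @export
read_label_map <- function(path) {
  if (!file.exists(path))
    ts_error(sprintf("file not found: %s", path), "treestab_input_error")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", comment.char = "#",
                          quote = "", strip.white = TRUE)
  if (ncol(df) < 2L)
    ts_error("label map file must have two tab-separated columns",
             "treestab_format_error")
  label_map(df[[1L]], df[[2L]])
}

#' Invert a label map
#' @param map a `label_map`.
#' @return the inverse `label_map`.
#' @export
invert_map <- function(map) {
  stopifnot(inherits(map, "label_map"))
  label_map(unname(map), names(map))
}

#' Build a label map by matching species tokens
#'
#' Paralog families are commonly labelled `<family>_<species>`; this derives
#' the species token from each label (by default the last `delim`-separated
#' field) and pairs labels with equal tokens.
#'
#' @param labels_a,labels_b labels of the two families.
#' @param delim field delimiter (default `"_"`).
#' @return a `label_map` from `labels_a` to `labels_b`.
#' @export
build_species_map <- function(labels_a, labels_b, delim = "_") {
  tok <- function(x) vapply(strsplit(x, delim, fixed = TRUE),
                            function(p) p[length(p)], character(1L))
  ta <- tok(labels_a); tb <- tok(labels_b)
  if (anyDuplicated(ta) || anyDuplicated(tb))
    ts_error("species tokens are not unique within a family",
             "treestab_format_error")
  if (!setequal(ta, tb))
    ts_error(sprintf("species token sets differ: %s",
                     paste(union(setdiff(ta, tb), setdiff(tb, ta)), collapse = ", ")),
             "treestab_format_error")
  label_map(labels_a, labels_b[match(ta, tb)])
}
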