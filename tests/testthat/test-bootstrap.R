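test_that("column resampling preserves shape, labels and single-column identity", {
  aln <- dna_alignment(c(a = "ACGTACGT", b = "TGCATGCA"))
  set.seed(1)
  b <- resample_columns(aln)
  expect_s3_class(b, "dna_alignment")
  expect_equal(dim(b), dim(aln))
  expect_equal(alignment_labels(b), alignment_labels(aln))

  one <- dna_alignment(c(a = "A", b = "C"))
  expect_identical(resample_columns(one), one)
})

test_that("each column is drawn with mean frequency one across many replicates", {
  # columns are identifiable by unique patterns
  aln <- dna_alignment(c(x = "ACGT", y = "AACC"))
  n_rep <- 10000
  counts <- numeric(4)
  patterns <- apply(unclass(aln), 2, paste, collapse = "")
  set.seed(123)
  for (r in seq_len(n_rep)) {
    b <- apply(unclass(resample_columns(aln)), 2, paste, collapse = "")
    tab <- table(factor(b, levels = patterns))
    counts <- counts + as.numeric(tab)
  }
  means <- counts / n_rep
  # MC standard error of the mean count is sqrt(p(1-p)n)/sqrt(n_rep) ~ 0.0087
  expect_true(all(abs(means - 1) < 4 * sqrt(0.25 * 0.75 * 4 / n_rep)))
})

test_that("a perfectly partitioned alignment gets Pb = 100 for its cherry", {
  half <- strrep("A", 30)
  other <- strrep("C", 30)
  aln <- dna_alignment(c(p1 = paste0(half, other), p2 = paste0(half, other),
                         q1 = paste0(other, half), q2 = paste0(other, half)))
  res <- compute_pb(aln, bootstrap_config(100, seed = 4))
  expect_equal(nrow(res$support), 1L)  # 4 taxa: one interior branch
  expect_equal(res$support$pb, 100)
})

test_that("a single replicate forces every Pb into {0, 100}", {
  set.seed(8)
  aln <- evolve_jc69(example_species_tree(), 200)
  res <- compute_pb(aln, bootstrap_config(1, seed = 9))
  expect_true(all(res$support$pb %in% c(0, 100)))
  expect_equal(nrow(res$support), 9 - 3)  # n - 3 interior branches
})

test_that("Pb is invariant to the order of input records", {
  set.seed(21)
  aln <- evolve_jc69(example_species_tree(), 300)
  cfg <- bootstrap_config(50, seed = 13)
  res1 <- compute_pb(aln, cfg)
  perm <- subset_alignment(aln, rev(alignment_labels(aln)))
  res2 <- compute_pb(perm, cfg)
  o1 <- order(res1$support$bipartition)
  o2 <- order(res2$support$bipartition)
  expect_equal(res1$support[o1, ], res2$support[o2, ],
               ignore_attr = TRUE)
})

test_that("compute_pb refuses alignments without interior branches", {
  aln <- dna_alignment(c(a = "ACGT", b = "ACGA", c = "AATT"))
  expect_error(compute_pb(aln), class = "treestab_input_error")
})

test_that("subtree topology frequencies normalize to 100 and record metadata", {
  set.seed(31)
  aln <- evolve_jc69(pair_fixture_tree(), 300)
  cfg <- bootstrap_config(200, seed = 17)
  ft <- topology_frequencies(aln, clade_spec(c("s1", "s2", "s3", "s4")), cfg)
  expect_s3_class(ft, "topology_freq")
  expect_equal(sum(ft$percent), 100)
  expect_equal(sum(ft$count), 200L)
  expect_equal(ft$outgroup, "og")     # forced: only non-ingroup label
  expect_equal(ft$seed, 17L)
  # percents derive exactly from integer counts
  expect_equal(ft$percent, 100 * ft$count / 200)
})

test_that("overwhelming signal concentrates the frequency on one topology", {
  # long internal branch: ((A,B),C) should be near-certain
  tr <- ape::read.tree(text = "((A:0.02,B:0.02):0.3,C:0.05,O:0.4);")
  tr <- ape::root(tr, "O", resolve.root = TRUE)
  set.seed(41)
  aln <- evolve_jc69(tr, 2000)
  ft <- topology_frequencies(aln, clade_spec(c("A", "B", "C"), "O"),
                             bootstrap_config(500, seed = 5))
  modal <- ft$key[which.max(ft$percent)]
  expect_equal(modal, "((A,B),C)")
  expect_gt(max(ft$percent), 99)
})

test_that("a star-like ingroup spreads frequency near the 1/3 expectation", {
  # zero-length internal branch: no resolution is favoured, so the average
  # bootstrap frequency of any fixed rooted topology over independent
  # datasets sits near 1/3 (a single dataset can still carry chance signal)
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.0,C:0.1,O:0.3);")
  tr <- ape::root(tr, "O", resolve.root = TRUE)
  set.seed(51)
  freqs <- vapply(1:24, function(i) {
    aln <- evolve_jc69(tr, 1000)
    ft <- topology_frequencies(aln, clade_spec(c("A", "B", "C"), "O"),
                               bootstrap_config(250, seed = i))
    hit <- ft$key == "((A,B),C)"
    if (any(hit)) ft$percent[hit] else 0
  }, numeric(1))
  expect_lt(abs(mean(freqs) - 100 / 3), 15)
})

test_that("identical seeds reproduce frequency and support tables bit-identically", {
  set.seed(61)
  aln <- evolve_jc69(pair_fixture_tree(), 400)
  cfg <- bootstrap_config(100, seed = 23)
  f1 <- topology_frequencies(aln, clade_spec(c("s1", "s2", "s3", "s4")), cfg)
  f2 <- topology_frequencies(aln, clade_spec(c("s1", "s2", "s3", "s4")), cfg)
  expect_identical(f1, f2)
  p1 <- compute_pb(aln, cfg)
  p2 <- compute_pb(aln, cfg)
  expect_identical(p1$support, p2$support)
})

test_that("frequency tables serialize as annotated TSV", {
  ft <- frequency_table(c("((A,B),C)", "((B,C),A)"), c(9, 1),
                        outgroup = "O", seed = 3L, deletion = "complete")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_table_tsv(ft, p)
  lines <- readLines(p)
  expect_true(any(grepl("^# outgroup\tO$", lines)))
  body <- read.delim(p, comment.char = "#")
  expect_equal(sum(body$percent), 100)
})
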