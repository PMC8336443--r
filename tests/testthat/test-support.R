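test_that("non-trivial bipartitions are enumerated canonically", {
  expect_identical(bipartitions(toy_quartet()), "c,d")
  expect_length(bipartitions(parse_newick("(a,b,c);")), 0)

  # unrooted binary n-leaf tree has exactly n - 3 non-trivial splits
  set.seed(13)
  for (n in 4:8) {
    tr <- ape::unroot(ape::rtree(n))
    expect_length(bipartitions(tr), n - 3)
  }

  # rooting does not change the set
  tr <- parse_newick("(((a,b),(c,d)),(e,f));")
  expect_setequal(bipartitions(ape::root(tr, "c")), bipartitions(tr))
})

test_that("displays matches bipartition membership and canonicalization", {
  expect_true(displays(toy_quartet(), "c,d"))
  expect_true(displays(toy_quartet(), c("a", "b")))  # complement side
  expect_false(displays(parse_newick("((a,c),(b,d));"), "c,d"))
  expect_true(displays(ape::root(toy_quartet(), "c"), "c,d"))
  expect_error(displays(toy_quartet(), "c,z"), "absent")
})

test_that("support is the displaying fraction, an exact multiple of 1/k", {
  ann <- parse_newick("((a,b),((c,d),(e,f)));")
  alt <- parse_newick("((a,c),((b,d),(e,f)));")
  trees <- c(replicate(4, ann, simplify = FALSE),
             replicate(6, alt, simplify = FALSE))
  sm <- compute_support(ann, trees)
  expect_setequal(sm$bipartition, bipartitions(ann))
  expect_true(all(sm$support * 10 == round(sm$support * 10)))
  expect_equal(sm$support[sm$bipartition == "e,f"], 1.0)
  ab_key <- sm$bipartition[vapply(sm$bipartition, function(k)
    setequal(strsplit(k, ",")[[1]], c("c", "d", "e", "f")), logical(1))]
  expect_equal(sm$support[sm$bipartition == ab_key], 0.4)

  expect_error(compute_support(ann, list()), "empty")
  expect_error(compute_support(ann, list(parse_newick("(a,b,c,x);"))),
               "taxon set")
})

test_that("constant re-estimation gives unit support in all three pipelines", {
  sim <- toy_sim(n_taxa = 6, height = 0.15, indel = 0.05, len = 150, seed = 3)
  aln <- align(sim$seqs)
  t0 <- infer_tree(aln)
  cb <- constant_tree_backend(t0)

  for (mode in c("rawr", "teleport")) {
    res <- rawr_support(sim$seqs, treeb = cb, mode = mode, k = 5, seed = 10)
    expect_true(all(res$support$support == 1))
    expect_identical(res$k_effective, 5L)
  }
  resb <- bootstrap_support(aln, treeb = cb, k = 5, seed = 10)
  expect_true(all(resb$support$support == 1))

  resm <- multilocus_support(list(p1 = aln), treeb = cb, k = 4, seed = 10)
  expect_true(all(resm$support$support == 1))
})

test_that("rawr support separates true from false bipartitions on easy data", {
  set.seed(91)
  diffs <- numeric(0)
  for (trial in 1:5) {
    sim <- toy_sim(n_taxa = 8, height = 0.7, indel = 0.1, len = 300,
                   seed = 400 + trial)
    res <- rawr_support(sim$seqs, k = 10, seed = trial)
    ref <- ape::unroot(sim$tree)
    in_ref <- res$support$bipartition %in% bipartitions(ref)
    if (any(in_ref) && any(!in_ref)) {
      diffs <- c(diffs, mean(res$support$support[in_ref]) -
                   mean(res$support$support[!in_ref]))
    }
  }
  expect_gt(mean(diffs), 0)
})

test_that("single-column bootstrap replicates are deterministic", {
  aln <- seqs_to_matrix(c(a = "A", b = "A", c = "C", d = "C"))
  res <- bootstrap_support(aln, k = 5, seed = 2)
  expect_true(all(res$support$support %in% c(0, 1)))
})

test_that("partition filtering keeps only nucleotide-complete partitions", {
  full <- seqs_to_matrix(c(a = "ACGT", b = "ACGT"))
  partial <- seqs_to_matrix(c(a = "ACGA", b = "ACGC"))  # no T
  out <- filter_partitions(list(p1 = full, p2 = partial, p3 = full))
  expect_identical(names(out), c("p1", "p3"))
  expect_identical(filter_partitions(list(a = full, b = full)),
                   list(a = full, b = full))
  expect_error(filter_partitions(list(p = partial)), "four nucleotides")
})

test_that("multi-locus replicates concatenate only surviving partitions", {
  sim <- toy_sim(n_taxa = 6, height = 0.15, indel = 0, len = 120, seed = 55)
  aln <- sim$alignment
  # partition 2 lacks T everywhere, so it can never survive the filter
  p1 <- aln
  p2 <- aln
  p2[p2 == "T"] <- "A"
  widths <- integer(0)
  cb <- tree_backend(name = "probe", fn = function(a) {
    widths <<- c(widths, ncol(a))
    builtin_tree(a)
  })
  res <- multilocus_support(list(p1 = p1, p2 = p2), treeb = cb, k = 3, seed = 9)
  # first call is the annotation concatenation; replicate supermatrices
  # must have exactly partition 1's width
  expect_identical(widths[1], ncol(p1) + ncol(p2))
  expect_true(all(widths[-1] == ncol(p1)))
  expect_s3_class(res$support, "data.frame")
})

test_that("replicate failure policy aborts by default and renormalizes on skip", {
  sim <- toy_sim(n_taxa = 5, height = 0.15, indel = 0, len = 100, seed = 6)
  aln <- align(sim$seqs)
  calls <- 0L
  flaky <- tree_backend(name = "flaky", fn = function(a) {
    calls <<- calls + 1L
    if (calls %% 3L == 0L) stop("backend blew up")
    builtin_tree(a)
  })
  expect_error(bootstrap_support(aln, treeb = flaky, k = 5, seed = 4),
               "replicate")
  calls <- 0L
  expect_warning(
    res <- bootstrap_support(aln, treeb = flaky, k = 6, seed = 4,
                             on_error = "skip"),
    "renormalized"
  )
  expect_lt(res$k_effective, 6L)
  expect_true(all(res$support$support * res$k_effective ==
                    round(res$support$support * res$k_effective)))
})
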