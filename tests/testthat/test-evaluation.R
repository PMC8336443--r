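# Two six-taxon trees sharing some but not all splits, with hand-set supports.
eval_fixture <- function() {
  est <- parse_newick("((a,b),((c,d),(e,f)));")
  ref <- parse_newick("((a,c),((b,d),(e,f)));")
  keys <- bipartitions(est)
  support <- structure(
    data.frame(bipartition = keys,
               n_displaying = NA_integer_, k = 10L,
               support = seq(0.9, 0.3, length.out = length(keys)),
               stringsAsFactors = FALSE),
    class = c("support_map", "data.frame"))
  list(est = est, ref = ref, support = support)
}

test_that("confusion classes partition the estimated bipartitions at any threshold", {
  est <- toy_quartet()
  ref <- toy_quartet()
  sm <- compute_support(est, list(ref))  # support 1.0 on c,d
  cc <- confusion_at_threshold(est, sm, ref, 0.5)
  expect_identical(unlist(cc[c("tp", "fp", "fn", "tn")], use.names = FALSE),
                   c(1L, 0L, 0L, 0L))

  # two bipartitions: one in ref (0.9), one not (0.4), threshold 0.5
  est2 <- parse_newick("((a,b),((c,d),e));")
  ref2 <- parse_newick("((a,e),((c,d),b));")
  keys <- bipartitions(est2)
  in_ref <- keys %in% bipartitions(ref2)
  sm2 <- data.frame(bipartition = keys, support = ifelse(in_ref, 0.9, 0.4))
  cc2 <- confusion_at_threshold(est2, sm2, ref2, 0.5)
  expect_identical(unlist(cc2[c("tp", "fp", "fn", "tn")], use.names = FALSE),
                   c(1L, 0L, 0L, 1L))

  fx <- eval_fixture()
  nbip <- length(bipartitions(fx$est))
  for (thr in c(0, 0.31, 0.5, 0.89, 1, 1.1)) {
    cc <- confusion_at_threshold(fx$est, fx$support, fx$ref, thr)
    expect_identical(cc$tp + cc$fp + cc$fn + cc$tn, nbip)
  }
  # threshold 0: everything is a positive
  cc0 <- confusion_at_threshold(fx$est, fx$support, fx$ref, 0)
  expect_identical(cc0$fn + cc0$tn, 0L)
  # est == ref: no negative-class splits exist
  same <- confusion_at_threshold(fx$est, fx$support, fx$est, 0.5)
  expect_identical(same$fp + same$tn, 0L)

  expect_error(confusion_at_threshold(fx$est, fx$support,
                                      parse_newick("((a,b),(c,z));"), 0.5),
               "taxon")
})

test_that("PR curves match brute-force enumeration and reach AUC 1 on perfect separation", {
  fx <- eval_fixture()
  keys <- bipartitions(fx$est)
  in_ref <- keys %in% bipartitions(fx$ref)

  # perfect separation: in-ref splits all above the others
  sep <- fx$support
  sep$support <- ifelse(in_ref, 0.9, 0.1)
  pc <- pr_curve(fx$est, sep, fx$ref)
  expect_equal(pc$auc, 1.0)

  # all supports equal, some in ref: single threshold point
  flat <- fx$support
  flat$support <- rep(0.7, length(keys))
  pcf <- pr_curve(fx$est, flat, fx$ref)
  real_pts <- pcf$points[is.finite(pcf$points$threshold), ]
  expect_identical(nrow(real_pts), 1L)
  expect_equal(real_pts$recall, 1.0)
  expect_equal(real_pts$precision, mean(in_ref))

  # random supports agree with the independent oracle
  set.seed(17)
  for (trial in 1:20) {
    s <- sample(seq(0, 1, 0.1), length(keys), replace = TRUE)
    sm <- fx$support
    sm$support <- s
    expect_equal(pr_curve(fx$est, sm, fx$ref)$auc, oracle_pr_auc(s, in_ref))
  }

  # AUC invariant under monotone transformation of supports
  sm <- fx$support
  sm$support <- c(0.9, 0.5, 0.2)[seq_along(keys) %% 3 + 1]
  a1 <- pr_curve(fx$est, sm, fx$ref)$auc
  sm$support <- sm$support^3
  expect_equal(pr_curve(fx$est, sm, fx$ref)$auc, a1)

  # no reference-positive bipartitions: recall undefined
  disjoint <- parse_newick("((a,e),((c,b),(d,f)));")
  expect_error(pr_curve(fx$est, fx$support, disjoint), "recall is undefined")
})

test_that("aggregate PR-AUC pools confusion counts rather than averaging", {
  fx <- eval_fixture()
  one <- list(est = fx$est, support = fx$support, ref = fx$ref)
  expect_equal(aggregate_pr_auc(list(one)),
               pr_curve(fx$est, fx$support, fx$ref)$auc)
  expect_equal(aggregate_pr_auc(list(one, one)), aggregate_pr_auc(list(one)))

  # opposite separations: pooled and mean-of-AUCs must differ
  keys <- bipartitions(fx$est)
  in_ref <- keys %in% bipartitions(fx$ref)
  good <- fx$support
  good$support <- ifelse(in_ref, 0.9, 0.1)
  bad <- fx$support
  bad$support <- ifelse(in_ref, 0.1, 0.9)
  cases <- list(list(est = fx$est, support = good, ref = fx$ref),
                list(est = fx$est, support = bad, ref = fx$ref))
  pooled <- aggregate_pr_auc(cases)
  meanauc <- aggregate_pr_auc(cases, method = "mean")
  expect_false(isTRUE(all.equal(pooled, meanauc)))
})

test_that("normalized RF distance matches split-set arithmetic and phangorn", {
  t1 <- parse_newick("((a,b),((c,d),e));")
  expect_equal(nrf_distance(t1, t1), 0)

  # five-leaf binary trees sharing one of two splits
  t2 <- parse_newick("((a,b),((c,e),d));")
  expect_equal(nrf_distance(t1, t2), 0.5)

  # fully incompatible quartets
  expect_equal(nrf_distance(toy_quartet(), parse_newick("((a,c),(b,d));")), 1)

  # symmetry and cross-check against phangorn on random binary trees
  set.seed(23)
  for (trial in 1:10) {
    n <- sample(5:9, 1)
    x <- ape::unroot(ape::rtree(n))
    y <- ape::unroot(ape::rtree(n))
    d <- nrf_distance(x, y)
    expect_equal(d, nrf_distance(y, x))
    expect_equal(d, as.numeric(phangorn::RF.dist(x, y)) / (2 * (n - 3)))
  }
})

test_that("sum-of-pairs errors match the naive homology oracle", {
  truth <- parse_fasta(">x\nACG-T\n>y\nAC-GT", aligned = TRUE)
  est <- parse_fasta(">x\nACGT-\n>y\nAC-GT", aligned = TRUE)
  expect_equal(unname(sp_errors(truth, truth)), c(0, 0))

  # disjoint homology sets: the same sequences paired entirely differently
  a <- parse_fasta(">x\nAC-\n>y\n-AC", aligned = TRUE)
  b <- parse_fasta(">x\n-AC\n>y\nAC-", aligned = TRUE)
  expect_equal(unname(sp_errors(a, a)), c(0, 0))
  expect_equal(unname(sp_errors(a, b)), c(1, 1))

  # random gapped alignments vs oracle
  set.seed(29)
  for (trial in 1:10) {
    n <- sample(3:5, 1)
    L <- sample(6:12, 1)
    m <- matrix(sample(c("A", "C", "G", "T", "-", "-"), n * L, replace = TRUE),
                n, L, dimnames = list(paste0("s", 1:n), NULL))
    if (length(oracle_homologies(m)) == 0 || any(rowSums(m != "-") == 0)) next
    # homologies depend only on within-column co-occurrence: padding with
    # all-gap columns changes nothing
    at <- sample(L, 2)
    padded <- m
    for (cc in sort(at, decreasing = TRUE)) {
      padded <- cbind(padded[, seq_len(cc - 1), drop = FALSE],
                      matrix("-", n, 1),
                      padded[, cc:ncol(padded), drop = FALSE])
    }
    expect_equal(unname(sp_errors(m, padded)), c(0, 0))
    # and against an independently built estimate: realign the unaligned rows
    est2 <- align(unalign(m))
    ph_t <- oracle_homologies(m)
    ph_e <- oracle_homologies(est2)
    expect_equal(unname(sp_errors(m, est2)),
                 c(sum(!(ph_t %in% ph_e)) / length(ph_t),
                   sum(!(ph_e %in% ph_t)) / length(ph_e)))
  }

  expect_error(sp_errors(truth, parse_fasta(">x\nACGA\n>y\nACGT", aligned = TRUE)),
               "unaligned")
})

test_that("ANHD and gappiness follow their definitions", {
  expect_equal(anhd(parse_fasta(">a\nACGT\n>b\nACGT", aligned = TRUE)), 0)
  expect_equal(anhd(parse_fasta(">a\nAAAA\n>b\nTTTT", aligned = TRUE)), 1)
  expect_equal(anhd(parse_fasta(">a\nAAAA\n>b\nAAT-", aligned = TRUE)), 1 / 3)
  # N counts as mismatch
  expect_equal(anhd(parse_fasta(">a\nAN\n>b\nAN", aligned = TRUE)), 0.5)
  expect_warning(
    v <- anhd(parse_fasta(">a\nA--\n>b\n-A-\n>c\nAA-", aligned = TRUE)),
    "no comparable"
  )
  expect_equal(v, 0)

  expect_equal(gappiness(parse_fasta(">a\nACGT\n>b\nACGT", aligned = TRUE)), 0)
  expect_equal(gappiness(parse_fasta(">a\nAC--\n>b\nACGT", aligned = TRUE)), 0.25)
  expect_equal(gappiness(parse_fasta(">a\n----\n>b\nACGT", aligned = TRUE)), 0.5)
})
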