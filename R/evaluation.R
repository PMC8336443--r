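# Benchmarking metrics for support estimates and alignments.
#
# Confusion classes over the estimated tree's non-trivial bipartitions at a
# support threshold t (thresholding uses >=):
#   TP: support >= t and present in the reference tree
#   FP: support >= t and absent
#   FN: support <  t and present
#   TN: support <  t and absent
# Sweeping t over the observed support values traces the precision-recall
# curve; PR-AUC is its trapezoidal area over recall-ordered points, with the
# conventional (recall 0, precision 1) endpoint contributed by a sentinel
# threshold above the maximum support.

.check_same_taxa <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees are over different taxon sets", call. = FALSE)
  }
}

#' Bipartition confusion counts at a support threshold
#'
#' @param est Estimated (annotation) tree.
#' @param support `support_map` over `est`'s non-trivial bipartitions (from
#'   [compute_support()]).
#' @param ref Reference tree (model tree or curated reference) over the same
#'   taxa.
#' @param threshold Support threshold; positives have `support >= threshold`.
#' @return One-row data frame with `tp`, `fp`, `fn`, `tn`, `threshold`; the
#'   four counts sum to the number of non-trivial bipartitions of `est`.
#' @export
confusion_at_threshold <- function(est, support, ref, threshold) {
  .check_same_taxa(est, ref)
  keys <- bipartitions(est)
  if (!setequal(support$bipartition, keys)) {
    stop("support map domain does not match the estimated tree's bipartitions",
         call. = FALSE)
  }
  s <- support$support[match(keys, support$bipartition)]
  in_ref <- keys %in% bipartitions(ref)
  pos <- s >= threshold
  data.frame(tp = sum(pos & in_ref), fp = sum(pos & !in_ref),
             fn = sum(!pos & in_ref), tn = sum(!pos & !in_ref),
             threshold = threshold)
}

# pooled PR points over a list of (in_ref, support) pairs
.pr_points <- function(in_ref, s) {
  if (!any(in_ref)) {
    stop("no estimated bipartition occurs in the reference tree; ",
         "recall is undefined", call. = FALSE)
  }
  thr <- sort(unique(s), decreasing = TRUE)
  pts <- vapply(thr, function(t) {
    pos <- s >= t
    tp <- sum(pos & in_ref)
    c(recall = tp / sum(in_ref), precision = tp / sum(pos), threshold = t)
  }, numeric(3))
  out <- as.data.frame(t(pts))
  # sentinel above the maximum support: no positives; precision 1 by the
  # usual convention, anchoring the curve at recall 0
  rbind(data.frame(recall = 0, precision = 1, threshold = Inf), out)
}

.trapezoid_auc <- function(recall, precision) {
  o <- order(recall, -precision)
  r <- recall[o]
  p <- precision[o]
  sum(diff(r) * (head(p, -1) + tail(p, -1)) / 2)
}

#' Precision-recall curve and PR-AUC for support estimates
#'
#' Thresholds sweep the sorted unique support values (plus a sentinel above
#' the maximum); precision is `TP/(TP+FP)`, recall `TP/(TP+FN)`; the AUC is
#' the trapezoidal integral over recall-ordered points.
#'
#' @inheritParams confusion_at_threshold
#' @return List with `points` (data frame `recall`, `precision`, `threshold`)
#'   and `auc`.
#' @export
pr_curve <- function(est, support, ref) {
  conf0 <- confusion_at_threshold(est, support, ref, 0)  # validates inputs
  keys <- bipartitions(est)
  s <- support$support[match(keys, support$bipartition)]
  in_ref <- keys %in% bipartitions(ref)
  pts <- .pr_points(in_ref, s)
  list(points = pts, auc = .trapezoid_auc(pts$recall, pts$precision))
}

#' Aggregate PR-AUC over several datasets
#'
#' Confusion counts are pooled across cases at each threshold before
#' computing precision and recall (an aggregate curve, not a mean of
#' per-case AUCs); `method = "mean"` gives the mean of per-case AUCs instead.
#'
#' @param cases List of cases, each a list with elements `est`, `support`,
#'   `ref` as in [pr_curve()].
#' @param method `"pooled"` (default) or `"mean"`.
#' @return Single numeric PR-AUC.
#' @export
aggregate_pr_auc <- function(cases, method = c("pooled", "mean")) {
  method <- match.arg(method)
  stopifnot(length(cases) >= 1)
  if (method == "mean") {
    return(mean(vapply(cases, function(cs) {
      pr_curve(cs$est, cs$support, cs$ref)$auc
    }, numeric(1))))
  }
  in_ref <- logical(0)
  s <- numeric(0)
  for (cs in cases) {
    conf0 <- confusion_at_threshold(cs$est, cs$support, cs$ref, 0)
    keys <- bipartitions(cs$est)
    s <- c(s, cs$support$support[match(keys, cs$support$bipartition)])
    in_ref <- c(in_ref, keys %in% bipartitions(cs$ref))
  }
  pts <- .pr_points(in_ref, s)
  .trapezoid_auc(pts$recall, pts$precision)
}

#' Normalized Robinson-Foulds distance
#'
#' Size of the symmetric difference of the two trees' non-trivial bipartition
#' sets, divided by the total number of non-trivial bipartitions across both
#' trees (equal to `2(n-3)` for two binary trees). 0 iff the topologies are
#' identical; 1 when they share no bipartition.
#'
#' @param t1,t2 Trees over the same taxon set (at least 4 taxa).
#' @return Numeric in `[0, 1]`.
#' @export
nrf_distance <- function(t1, t2) {
  .check_same_taxa(t1, t2)
  stopifnot(length(t1$tip.label) >= 4)
  b1 <- bipartitions(t1)
  b2 <- bipartitions(t2)
  denom <- length(b1) + length(b2)
  if (denom == 0) return(0)
  (sum(!(b1 %in% b2)) + sum(!(b2 %in% b1))) / denom
}

# residue-pair homology set of an alignment: for each unordered taxon pair
# and each column where both are ungapped, the pair of residue indices.
# Encoded as strings "taxA|taxB|i|j" with taxA < taxB.
.homology_pairs <- function(aln) {
  taxa <- sort(rownames(aln))
  residx <- lapply(taxa, function(tx) {
    r <- aln[tx, ]
    ifelse(r == "-", NA_integer_, cumsum(r != "-"))
  })
  names(residx) <- taxa
  out <- character(0)
  for (i in seq_len(length(taxa) - 1L)) {
    for (j in (i + 1L):length(taxa)) {
      both <- !is.na(residx[[i]]) & !is.na(residx[[j]])
      if (any(both)) {
        out <- c(out, paste(taxa[i], taxa[j],
                            residx[[i]][both], residx[[j]][both], sep = "|"))
      }
    }
  }
  out
}

#' Sum-of-pairs alignment error (SP-FN and SP-FP)
#'
#' A homology is an unordered pair of residues (one from each of two taxa)
#' placed in the same column. SP-FN is the proportion of true homologies
#' missing from the estimated alignment; SP-FP the proportion of estimated
#' homologies absent from the truth.
#'
#' @param true_aln,est_aln Alignments over the same taxa whose unaligned
#'   sequences are identical.
#' @return Named numeric vector `c(sp_fn =, sp_fp =)`.
#' @export
sp_errors <- function(true_aln, est_aln) {
  stopifnot(is.matrix(true_aln), is.matrix(est_aln))
  if (!setequal(rownames(true_aln), rownames(est_aln))) {
    stop("alignments are over different taxa", call. = FALSE)
  }
  u1 <- unalign(true_aln)
  u2 <- unalign(est_aln)[names(u1)]
  if (!identical(unname(u1), unname(u2))) {
    stop("alignments do not share the same underlying unaligned sequences",
         call. = FALSE)
  }
  ph_true <- .homology_pairs(true_aln)
  ph_est <- .homology_pairs(est_aln)
  if (length(ph_true) == 0 || length(ph_est) == 0) {
    stop("degenerate alignment: no residue-pair homologies", call. = FALSE)
  }
  c(sp_fn = sum(!(ph_true %in% ph_est)) / length(ph_true),
    sp_fp = sum(!(ph_est %in% ph_true)) / length(ph_est))
}

#' Average normalized Hamming distance of an alignment
#'
#' Mean over all unordered row pairs of the mismatch proportion, where sites
#' gapped in either row are excluded from both numerator and denominator and
#' any comparison involving `N` counts as a mismatch. Pairs with zero
#' comparable sites are excluded from the mean with a warning.
#'
#' @param aln Character matrix alignment with at least 2 rows.
#' @return Numeric in `[0, 1]`.
#' @export
anhd <- function(aln) {
  stopifnot(is.matrix(aln), nrow(aln) >= 2)
  n <- nrow(aln)
  vals <- numeric(0)
  skipped <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      x <- aln[i, ]
      y <- aln[j, ]
      comp <- x != "-" & y != "-"
      if (!any(comp)) {
        skipped <- skipped + 1L
        next
      }
      mism <- x[comp] != y[comp] | x[comp] == "N" | y[comp] == "N"
      vals <- c(vals, mean(mism))
    }
  }
  if (skipped > 0) {
    warning(skipped, " row pair(s) with no comparable sites excluded from ANHD",
            call. = FALSE)
  }
  if (length(vals) == 0) stop("no comparable row pairs", call. = FALSE)
  mean(vals)
}

#' Gappiness of an alignment
#'
#' Proportion of the alignment matrix consisting of gap characters.
#'
#' @param aln Non-empty character matrix alignment.
#' @return Numeric in `[0, 1]`.
#' @export
gappiness <- function(aln) {
  stopifnot(is.matrix(aln), length(aln) > 0)
  mean(aln == "-")
}

#' Summary statistics of an estimated alignment against the truth
#'
#' The benchmark column set: ANHD, gappiness and length of both alignments,
#' plus SP-FN/SP-FP of the estimate.
#'
#' @inheritParams sp_errors
#' @return Named list of statistics.
#' @export
alignment_stats <- function(true_aln, est_aln) {
  sp <- sp_errors(true_aln, est_aln)
  list(true_anhd = anhd(true_aln), true_gappiness = gappiness(true_aln),
       true_length = ncol(true_aln), est_length = ncol(est_aln),
       sp_fn = unname(sp["sp_fn"]), sp_fp = unname(sp["sp_fp"]))
}
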