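# Bipartition bookkeeping and support calculation. A bipartition (split) is
# the two-way partition of the taxon set induced by removing an internal
# edge. Canonical form: the side NOT containing the lexicographically
# smallest taxon, sorted and comma-joined, so equality is invariant to
# rooting and taxon order. Support for a bipartition of the annotation tree
# is the fraction of re-estimated trees that display it.

# one key per internal node of `tree` (prop.part order); NA where the induced
# split is trivial
.node_bipartition_keys <- function(tree) {
  n <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  ref <- min(tree$tip.label)
  vapply(pp, function(tips) {
    if (length(tips) < 2 || length(tips) > n - 2) return(NA_character_)
    side <- tree$tip.label[tips]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    paste(sort(side), collapse = ",")
  }, character(1))
}

#' Non-trivial bipartitions of a tree
#'
#' @param tree An `ape::phylo` tree (interpreted as unrooted).
#' @return Character vector of canonical bipartition keys: for each internal
#'   edge, the side of the split not containing the lexicographically
#'   smallest taxon, sorted and comma-joined. Empty for trees with fewer than
#'   4 leaves.
#' @examples
#' bipartitions(parse_newick("((a,b),(c,d));"))  # "c,d"
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 4) return(character(0))
  keys <- .node_bipartition_keys(tree)
  unique(keys[!is.na(keys)])
}

#' Does a tree display a bipartition?
#'
#' @param tree An `ape::phylo` tree.
#' @param split Either a canonical key (see [bipartitions()]) or a character
#'   vector of taxon labels forming one side of the split.
#' @return `TRUE` iff some internal edge of `tree` induces the split.
#' @export
displays <- function(tree, split) {
  stopifnot(inherits(tree, "phylo"))
  side <- if (length(split) > 1) split else strsplit(split, ",", fixed = TRUE)[[1]]
  if (!all(side %in% tree$tip.label)) {
    stop("split references taxa absent from the tree: ",
         paste(setdiff(side, tree$tip.label), collapse = ", "), call. = FALSE)
  }
  if (min(tree$tip.label) %in% side) {
    side <- setdiff(tree$tip.label, side)
  }
  paste(sort(side), collapse = ",") %in% bipartitions(tree)
}

#' Bipartition support from a set of re-estimated trees
#'
#' @param annotation The annotation tree whose internal edges are scored.
#' @param reestimates Non-empty list of re-estimated `phylo` trees over the
#'   same taxon set.
#' @return A data frame of class `support_map` with columns `bipartition`
#'   (canonical key), `n_displaying`, `k` and `support` (= `n_displaying/k`,
#'   an exact multiple of `1/k`).
#' @export
compute_support <- function(annotation, reestimates) {
  stopifnot(inherits(annotation, "phylo"))
  if (length(reestimates) == 0) {
    stop("empty re-estimate list: support is undefined", call. = FALSE)
  }
  taxa <- sort(annotation$tip.label)
  for (tr in reestimates) {
    if (!identical(sort(tr$tip.label), taxa)) {
      stop("re-estimated tree taxon set differs from the annotation tree",
           call. = FALSE)
    }
  }
  keys <- bipartitions(annotation)
  k <- length(reestimates)
  counts <- integer(length(keys))
  for (tr in reestimates) {
    counts <- counts + (keys %in% bipartitions(tr))
  }
  structure(
    data.frame(bipartition = keys, n_displaying = counts, k = k,
               support = counts / k, stringsAsFactors = FALSE),
    class = c("support_map", "data.frame")
  )
}

#' Attach support values to a tree's internal-node labels
#'
#' @param tree The annotation tree.
#' @param support A `support_map` from [compute_support()].
#' @param percent Write percentages (0-100, no decimals) instead of
#'   proportions with 3 decimals.
#' @return The tree with `node.label` set on internal nodes whose bipartition
#'   is in the support map (others get an empty label).
#' @export
attach_support <- function(tree, support, percent = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  keys <- .node_bipartition_keys(tree)
  val <- support$support[match(keys, support$bipartition)]
  lab <- ifelse(is.na(val), "",
                if (percent) sprintf("%.0f", 100 * val) else sprintf("%.3f", val))
  tree$node.label <- lab
  tree
}

#' RAWR (or teleport) phylogenetic support estimation
#'
#' The full pipeline: estimate an annotation alignment and tree on the input
#' sequences, draw `k` random-walk replicates from the annotation alignment,
#' unalign each, re-estimate alignment and tree on each replicate, and score
#' each non-trivial bipartition of the annotation tree by the fraction of
#' re-estimated trees displaying it.
#'
#' @param seqs Named character vector of at least 4 unaligned sequences.
#' @param aligner An [aligner_backend()].
#' @param treeb A [tree_backend()].
#' @param mode `"rawr"` (reversal walk) or `"teleport"`.
#' @param gamma Reversal/teleport probability (study default 0.1).
#' @param k Number of replicates (study protocol 100; 10 for the reduced
#'   protocol).
#' @param seed Master RNG seed for the replicate streams.
#' @param on_error `"abort"` (default) stops on any replicate backend
#'   failure; `"skip"` drops the failing replicate with a warning and
#'   renormalizes support by the number of successful re-estimates.
#' @return List with elements `tree` (annotation tree with support labels),
#'   `support` (a `support_map`), `annotation_alignment`, and `k_effective`.
#' @export
rawr_support <- function(seqs, aligner = aligner_backend("builtin"),
                         treeb = tree_backend("builtin"),
                         mode = c("rawr", "teleport"), gamma = 0.1, k = 100L,
                         seed = NULL, on_error = c("abort", "skip")) {
  mode <- match.arg(mode)
  on_error <- match.arg(on_error)
  stopifnot(length(seqs) >= 4)
  A <- align(seqs, aligner)
  T0 <- infer_tree(A, treeb)
  reps <- resample_many(A, mode = mode, gamma = gamma, k = k, seed = seed)
  trees <- .reestimate_trees(reps, aligner, treeb, on_error, realign = TRUE)
  supp <- compute_support(T0, trees)
  list(tree = attach_support(T0, supp), support = supp,
       annotation_alignment = A, k_effective = length(trees))
}

#' Bootstrap phylogenetic support estimation
#'
#' Classical phylogenetic bootstrap: replicates are i.i.d. column resamples
#' of the (already aligned) input; no re-alignment is performed — only tree
#' re-estimation. Support calculation matches [rawr_support()].
#'
#' @param aln Character matrix alignment over at least 4 taxa.
#' @inheritParams rawr_support
#' @return As [rawr_support()] (without `annotation_alignment`).
#' @export
bootstrap_support <- function(aln, treeb = tree_backend("builtin"), k = 100L,
                              seed = NULL, on_error = c("abort", "skip")) {
  on_error <- match.arg(on_error)
  stopifnot(is.matrix(aln), nrow(aln) >= 4)
  T0 <- infer_tree(aln, treeb)
  reps <- resample_many(aln, mode = "bootstrap", k = k, seed = seed)
  trees <- .reestimate_trees(reps, aligner = NULL, treeb, on_error,
                             realign = FALSE)
  supp <- compute_support(T0, trees)
  list(tree = attach_support(T0, supp), support = supp,
       k_effective = length(trees))
}

.reestimate_trees <- function(reps, aligner, treeb, on_error, realign) {
  trees <- list()
  failed <- 0L
  for (i in seq_along(reps)) {
    tr <- tryCatch({
      a <- if (realign) align(reps[[i]]$unaligned, aligner) else reps[[i]]$aligned
      infer_tree(a, treeb)
    }, error = function(e) e)
    if (inherits(tr, "error")) {
      if (on_error == "abort") {
        stop("re-estimation failed on replicate ", i, ": ",
             conditionMessage(tr), call. = FALSE)
      }
      failed <- failed + 1L
    } else {
      trees[[length(trees) + 1L]] <- tr
    }
  }
  if (failed > 0) {
    warning(failed, " replicate(s) dropped; support renormalized to k = ",
            length(trees), call. = FALSE)
  }
  if (length(trees) == 0) stop("all replicates failed", call. = FALSE)
  trees
}

#' Filter partitions by nucleotide completeness
#'
#' Retains partitions whose (resampled) alignment contains at least one of
#' each nucleotide A, C, G and T (gaps and N do not count), avoiding
#' degeneracy when substitution model parameters are re-learned per
#' partition.
#'
#' @param partitions Named list of character matrix alignments.
#' @return The surviving partitions, in order.
#' @export
filter_partitions <- function(partitions) {
  stopifnot(is.list(partitions))
  keep <- vapply(partitions, function(a) all(c("A", "C", "G", "T") %in% a),
                 logical(1))
  if (!any(keep)) {
    stop("no partition contains all four nucleotides", call. = FALSE)
  }
  partitions[keep]
}

#' Multi-locus (partitioned) RAWR support
#'
#' Per replicate, each partition's columns are independently resampled by a
#' RAWR walk and kept aligned (no unalign/re-align step); partitions missing
#' any of the four nucleotides are dropped; survivors are concatenated into a
#' supermatrix on which the tree is re-estimated. Support is computed against
#' the annotation tree estimated on the full concatenation.
#'
#' @param partitions Named list of character matrix alignments sharing one
#'   taxon set.
#' @inheritParams rawr_support
#' @return As [rawr_support()], plus `annotation_alignment` (the full
#'   concatenation).
#' @export
multilocus_support <- function(partitions, treeb = tree_backend("builtin"),
                               gamma = 0.1, k = 100L, seed = NULL,
                               on_error = c("abort", "skip")) {
  on_error <- match.arg(on_error)
  stopifnot(is.list(partitions), length(partitions) >= 1)
  taxa <- rownames(partitions[[1]])
  for (p in partitions) {
    if (!setequal(rownames(p), taxa)) {
      stop("partitions do not share a common taxon set", call. = FALSE)
    }
  }
  partitions <- lapply(partitions, function(p) p[taxa, , drop = FALSE])
  concat <- do.call(cbind, partitions)
  T0 <- infer_tree(concat, treeb)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, k)
  trees <- list()
  failed <- 0L
  for (j in seq_len(k)) {
    set.seed(rep_seeds[j])
    tr <- tryCatch({
      resampled <- lapply(partitions, function(p) {
        p[, rawr_walk(ncol(p), gamma), drop = FALSE]
      })
      supermatrix <- do.call(cbind, filter_partitions(resampled))
      infer_tree(supermatrix, treeb)
    }, error = function(e) e)
    if (inherits(tr, "error")) {
      if (on_error == "abort") {
        stop("re-estimation failed on replicate ", j, ": ",
             conditionMessage(tr), call. = FALSE)
      }
      failed <- failed + 1L
    } else {
      trees[[length(trees) + 1L]] <- tr
    }
  }
  if (failed > 0) {
    warning(failed, " replicate(s) dropped; support renormalized to k = ",
            length(trees), call. = FALSE)
  }
  if (length(trees) == 0) stop("all replicates failed", call. = FALSE)
  supp <- compute_support(T0, trees)
  list(tree = attach_support(T0, supp), support = supp,
       annotation_alignment = concat, k_effective = length(trees))
}
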