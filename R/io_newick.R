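# Newick input/output. Trees are `ape::phylo` objects; support values travel
# as internal-node labels, the convention RAxML-style pipelines use.

#' Parse a Newick string into a phylogenetic tree
#'
#' Branch lengths and internal-node labels (used for support values) are
#' preserved. All downstream bipartition work treats trees as unrooted.
#'
#' @param text Newick string (must end with `;`).
#' @return An `ape::phylo` tree.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop("unbalanced parentheses in Newick string", call. = FALSE)
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("failed to parse Newick string", call. = FALSE)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels in Newick tree", call. = FALSE)
  }
  tr
}

#' Serialize a tree to Newick
#'
#' @param tree An `ape::phylo` tree.
#' @param include_support Keep internal-node labels (support values) in the
#'   output. When `FALSE` they are stripped.
#' @return A Newick string.
#' @export
write_newick <- function(tree, include_support = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (!include_support) tree$node.label <- NULL
  ape::write.tree(tree)
}

#' Numeric support values carried on a tree's internal-node labels
#'
#' @param tree An `ape::phylo` tree whose `node.label` holds support values.
#' @return Named numeric vector keyed by canonical bipartition (see
#'   [bipartitions()]); internal nodes without a numeric label are omitted.
#' @export
tree_support_values <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label)) return(setNames(numeric(0), character(0)))
  keys <- .node_bipartition_keys(tree)
  val <- suppressWarnings(as.numeric(tree$node.label))
  keep <- !is.na(val) & !is.na(keys)
  setNames(val[keep], keys[keep])
}
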