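# Built-in distance tree estimator: neighbor joining on Jukes-Cantor-corrected
# pairwise distances with pairwise gap deletion (via ape::dist.dna). Saturated
# or undefined distances (no comparable sites, or p >= 3/4) are capped at a
# fixed value so NJ always runs; the cap is documented rather than hidden.

.JC_DIST_CAP <- 5

#' Built-in neighbor-joining tree estimation
#'
#' Pairwise Jukes-Cantor-corrected distances are computed on gap-excluded
#' pairwise sites; saturated or undefined distances are capped at 5
#' substitutions per site. The tree is estimated by neighbor joining and
#' returned unrooted. Three taxa yield the star tree.
#'
#' @param aln Character matrix alignment over `{A,C,G,T,N,-}` with at least 3
#'   rows. Rows consisting entirely of gaps are rejected: resampling retains
#'   such taxa for bookkeeping, but they carry no signal to place — filter
#'   them (or use a minimum-length filter upstream) before tree estimation.
#' @return Unrooted `ape::phylo` tree over the alignment's taxa.
#' @export
builtin_tree <- function(aln) {
  stopifnot(is.matrix(aln), nrow(aln) >= 3)
  allgap <- rownames(aln)[rowSums(aln != "-") == 0]
  if (length(allgap) > 0) {
    stop("taxa with zero ungapped sites cannot be placed: ",
         paste(allgap, collapse = ", "),
         "; apply a minimum-length filter before tree estimation",
         call. = FALSE)
  }
  if (nrow(aln) == 3) {
    return(parse_newick(paste0("(", paste(rownames(aln), collapse = ","), ");")))
  }
  dna <- ape::as.DNAbin(tolower(aln))
  d <- ape::dist.dna(dna, model = "JC69", pairwise.deletion = TRUE)
  d[!is.finite(d)] <- .JC_DIST_CAP
  ape::unroot(ape::nj(d))
}
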