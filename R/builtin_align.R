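# Built-in progressive aligner. Guide tree: neighbor joining on a normalized
# shared k-mer distance, midpoint-rooted; profiles are merged bottom-up with a
# global profile-profile Needleman-Wunsch (linear gap penalty, C++ kernel).
# Deterministic given input order: all tie-breaks are fixed.

.KMER_K <- 4L
.NW_MATCH <- 2
.NW_MISMATCH <- -1
.NW_GAP <- -2

.kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(s)
  unique(substring(s, 1:(n - k + 1L), k:n))
}

.kmer_dist_matrix <- function(seqs) {
  k <- max(1L, min(.KMER_K, min(nchar(seqs))))
  sets <- lapply(seqs, .kmer_set, k = k)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- length(intersect(sets[[i]], sets[[j]]))
      denom <- min(length(sets[[i]]), length(sets[[j]]))
      d[i, j] <- d[j, i] <- 1 - shared / denom
    }
  }
  d
}

.profile_of <- function(aln) {
  letters5 <- c("A", "C", "G", "T", "N")
  p <- matrix(0, 5, ncol(aln), dimnames = list(letters5, NULL))
  for (x in seq_along(letters5)) {
    p[x, ] <- colMeans(aln == letters5[x])
  }
  p
}

.merge_alignments <- function(a, b) {
  path <- nw_profile_path(.profile_of(a), .profile_of(b),
                          .NW_MATCH, .NW_MISMATCH, .NW_GAP)
  L <- length(path$a)
  out <- matrix("-", nrow(a) + nrow(b), L)
  out[seq_len(nrow(a)), path$a != 0L] <- a[, path$a[path$a != 0L], drop = FALSE]
  out[nrow(a) + seq_len(nrow(b)), path$b != 0L] <-
    b[, path$b[path$b != 0L], drop = FALSE]
  rownames(out) <- c(rownames(a), rownames(b))
  out
}

# post-order merge schedule from a rooted guide tree: a list of
# list(left = <labels>, right = <labels>) pairs; multifurcations are merged
# left to right in child order.
.guide_merge_order <- function(tree) {
  n <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  merges <- list()
  walk <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    kids <- children[[as.character(node)]]
    acc <- walk(kids[1])
    for (kid in kids[-1]) {
      g <- walk(kid)
      merges[[length(merges) + 1L]] <<- list(left = acc, right = g)
      acc <- c(acc, g)
    }
    acc
  }
  walk(n + 1L)
  merges
}

#' Built-in progressive multiple sequence alignment
#'
#' Pairwise normalized shared k-mer distances feed a neighbor-joining guide
#' tree (midpoint-rooted); sub-alignments are merged bottom-up with a global
#' profile-profile Needleman-Wunsch under linear gap penalties
#' (match 2, mismatch -1, gap -2). Fully deterministic given input order.
#' Zero-length input sequences are carried through as all-gap rows.
#'
#' @param seqs Named character vector of gap-free sequences (at least 2).
#' @return Character matrix alignment with rows in input order.
#' @export
builtin_align <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 2, !is.null(names(seqs)))
  if (all(nchar(seqs) == 0)) stop("all input sequences are empty", call. = FALSE)
  empty <- nchar(seqs) == 0
  live <- seqs[!empty]
  if (length(live) == 1 || length(unique(live)) == 1) {
    aln <- seqs_to_matrix(live)  # single or identical sequences: gapless stack
  } else if (length(live) == 2) {
    aln <- .merge_alignments(seqs_to_matrix(live[1]), seqs_to_matrix(live[2]))
  } else {
    d <- .kmer_dist_matrix(live)
    guide <- ape::nj(stats::as.dist(d))
    if (length(live) > 3) guide <- phangorn::midpoint(guide)
    key <- function(labs) paste(sort(labs), collapse = "\r")
    acc <- setNames(lapply(names(live), function(nm) seqs_to_matrix(live[nm])),
                    vapply(names(live), key, character(1)))
    for (m in .guide_merge_order(guide)) {
      kl <- key(m$left); kr <- key(m$right)
      merged <- .merge_alignments(acc[[kl]], acc[[kr]])
      acc[[kl]] <- NULL
      acc[[kr]] <- NULL
      acc[[key(c(m$left, m$right))]] <- merged
    }
    stopifnot(length(acc) == 1)
    aln <- acc[[1]]
  }
  if (any(empty)) {
    gaps <- matrix("-", sum(empty), ncol(aln),
                   dimnames = list(names(seqs)[empty], NULL))
    aln <- rbind(aln, gaps)
  }
  aln[names(seqs), , drop = FALSE]
}
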