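# Synthetic benchmark generator: random birth-process model trees of a given
# height, and GTR sequence evolution with insertion/deletion events along the
# branches. Residue homology is tracked exactly (each residue carries a
# global column coordinate), so the generator emits a true alignment, the
# unaligned leaf sequences and the model tree for every replicate.

#' GTR substitution model parameters with an indel process
#'
#' Builds the scaled GTR rate matrix (one expected substitution per unit
#' branch length at stationarity). Defaults are Jukes-Cantor (uniform base
#' frequencies, equal exchangeabilities) with no indels and no rate
#' heterogeneity; arbitrary GTR parameters are accepted.
#'
#' @param base_freqs Stationary frequencies of A, C, G, T (sum to 1).
#' @param rates Six exchangeabilities in order AC, AG, AT, CG, CT, GT.
#' @param gamma_shape Optional shape for discrete-gamma (4 category)
#'   among-site rate variation; `NULL` disables it.
#' @param insertion_rate,deletion_rate Per-site indel event rates per unit
#'   branch length: on a branch of length `t` each site (or insertion
#'   junction) experiences an event with probability `1 - exp(-rate * t)`.
#' @param indel_mean_length Mean of the geometric indel length distribution.
#' @return An object of class `gtr_params` carrying the scaled rate matrix
#'   and its eigendecomposition.
#' @export
gtr_params <- function(base_freqs = rep(0.25, 4), rates = rep(1, 6),
                       gamma_shape = NULL, insertion_rate = 0,
                       deletion_rate = 0, indel_mean_length = 2) {
  stopifnot(length(base_freqs) == 4, all(base_freqs >= 0),
            abs(sum(base_freqs) - 1) < 1e-9,
            length(rates) == 6, all(rates > 0),
            indel_mean_length >= 1)
  if (!is.null(gamma_shape)) stopifnot(gamma_shape > 0)
  R <- matrix(0, 4, 4)
  R[lower.tri(R)] <- rates[c(1, 2, 3, 4, 5, 6)]
  # order AC,AG,AT,CG,CT,GT fills (2,1),(3,1),(4,1),(3,2),(4,2),(4,3)
  R <- R + t(R)
  Q <- R * rep(base_freqs, each = 4)  # Q[i,j] = r_ij * pi_j for i != j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(base_freqs * diag(Q))
  Q <- Q / scale
  # reversible Q is diagonalizable via the symmetrized matrix
  sp <- sqrt(base_freqs)
  S <- diag(sp) %*% Q %*% diag(1 / sp)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  U <- diag(1 / sp) %*% es$vectors
  Uinv <- t(es$vectors) %*% diag(sp)
  structure(list(base_freqs = base_freqs, rates = rates, Q = Q,
                 eigenvalues = es$values, U = U, Uinv = Uinv,
                 gamma_shape = gamma_shape,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 indel_mean_length = indel_mean_length),
            class = "gtr_params")
}

#' Substitution probability matrix P(t) = exp(Qt)
#'
#' @param params A [gtr_params()] object.
#' @param t Branch length (expected substitutions per site).
#' @return 4x4 transition probability matrix over A, C, G, T.
#' @export
gtr_prob_matrix <- function(params, t) {
  stopifnot(inherits(params, "gtr_params"), t >= 0)
  P <- params$U %*% diag(exp(params$eigenvalues * t)) %*% params$Uinv
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Sample a random birth-process model tree of a given height
#'
#' The topology is grown by uniform random leaf splitting (starting from a
#' two-leaf root, a uniformly chosen current leaf is repeatedly split until
#' `n_taxa` leaves exist). Every branch length is drawn uniformly from (0,1)
#' and all lengths are rescaled so the maximum root-to-leaf path length
#' equals `height` exactly. Non-ultrametric by construction.
#'
#' @param n_taxa Number of leaves (>= 4).
#' @param height Target tree height (> 0).
#' @param seed Optional RNG seed.
#' @return Rooted binary `ape::phylo` tree with tips `t1 ... tn`.
#' @export
sample_model_tree <- function(n_taxa, height, seed = NULL) {
  stopifnot(n_taxa >= 4, height > 0)
  if (!is.null(seed)) set.seed(seed)
  # children[[id]] holds the two child ids of node id; leaves have none
  children <- vector("list", 2L * n_taxa - 1L)
  next_id <- 4L
  children[[1L]] <- c(2L, 3L)
  leaves <- c(2L, 3L)
  while (length(leaves) < n_taxa) {
    v <- leaves[sample.int(length(leaves), 1L)]
    kids <- c(next_id, next_id + 1L)
    next_id <- next_id + 2L
    children[[v]] <- kids
    leaves <- c(setdiff(leaves, v), kids)
  }
  # renumber to ape convention: tips 1..n, root n+1, internals in preorder
  is_leaf <- vapply(seq_len(next_id - 1L), function(i) is.null(children[[i]]),
                    logical(1))
  tip_ids <- which(is_leaf)
  int_ids <- which(!is_leaf)
  newnum <- integer(next_id - 1L)
  newnum[tip_ids] <- seq_along(tip_ids)
  newnum[int_ids] <- n_taxa + seq_along(int_ids)  # internal ids are in preorder
  edge <- do.call(rbind, lapply(int_ids, function(v) {
    cbind(newnum[v], newnum[children[[v]]])
  }))
  tree <- structure(list(edge = edge, Nnode = length(int_ids),
                         tip.label = paste0("t", seq_len(n_taxa)),
                         edge.length = runif(nrow(edge))),
                    class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  depths <- ape::node.depth.edgelength(tree)
  tree$edge.length <- tree$edge.length * height / max(depths[seq_len(n_taxa)])
  tree
}

# evolve one branch: substitutions, then deletions, then insertions
.evolve_branch <- function(states, positions, cats, t, params, registry) {
  L <- length(states)
  rate_mult <- if (is.null(params$gamma_shape)) 1 else .gamma_cat_rates(params$gamma_shape)
  if (L > 0 && t > 0) {
    ncat <- length(rate_mult)
    for (cc in seq_len(ncat)) {
      idx <- if (ncat == 1) seq_len(L) else which(cats == cc)
      if (length(idx) == 0) next
      P <- gtr_prob_matrix(params, t * rate_mult[cc])
      parent <- states  # snapshot: each site evolves from its parent state once
      for (s in 1:4) {
        here <- idx[parent[idx] == s]
        if (length(here) > 0) {
          states[here] <- sample.int(4, length(here), replace = TRUE,
                                     prob = P[s, ])
        }
      }
    }
  }
  if (t > 0 && params$deletion_rate > 0 && L > 0) {
    p_del <- 1 - exp(-params$deletion_rate * t)
    keep <- runif(L) >= p_del
    states <- states[keep]
    positions <- positions[keep]
    cats <- cats[keep]
  }
  if (t > 0 && params$insertion_rate > 0) {
    p_ins <- 1 - exp(-params$insertion_rate * t)
    L2 <- length(states)
    bounds <- c(registry$lo, positions, registry$hi)
    at <- which(runif(L2 + 1L) < p_ins)  # junction before site `at`
    if (length(at) > 0) {
      ins_states <- vector("list", length(at))
      ins_pos <- vector("list", length(at))
      ins_cats <- vector("list", length(at))
      for (q in seq_along(at)) {
        len <- rgeom(1, 1 / params$indel_mean_length) + 1L
        lo <- bounds[at[q]]
        hi <- bounds[at[q] + 1L]
        ins_states[[q]] <- sample.int(4, len, replace = TRUE,
                                      prob = params$base_freqs)
        ins_pos[[q]] <- sort(.fresh_positions(len, lo, hi, registry))
        ins_cats[[q]] <- if (is.null(params$gamma_shape)) rep(1L, len) else
          sample.int(4, len, replace = TRUE)
      }
      # splice insertions in position order
      states <- c(states, unlist(ins_states))
      positions <- c(positions, unlist(ins_pos))
      cats <- c(cats, unlist(ins_cats))
      o <- order(positions)
      states <- states[o]
      positions <- positions[o]
      cats <- cats[o]
    }
  }
  list(states = states, positions = positions, cats = cats)
}

.gamma_cat_rates <- function(shape) {
  # 4-category discrete gamma (category means, Yang 1994 style via quantiles)
  q <- stats::qgamma(c(0.125, 0.375, 0.625, 0.875), shape = shape, rate = shape)
  q / mean(q)
}

.fresh_positions <- function(n, lo, hi, registry) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      p <- runif(1, lo, hi)
      if (!p %in% registry$used) break
    }
    registry$used <- c(registry$used, p)
    out[i] <- p
  }
  out
}

#' Simulate sequence evolution with indels on a model tree
#'
#' The root sequence (`root_length` sites) is drawn from the stationary base
#' frequencies. Along each branch, sites substitute under the scaled GTR
#' matrix exponential at the branch length; each site is deleted with
#' probability `1 - exp(-deletion_rate * t)`; each inter-site junction
#' receives an insertion (geometric length, fresh stationary residues) with
#' probability `1 - exp(-insertion_rate * t)`. Every residue carries a global
#' column coordinate, so the true alignment of all surviving residues is
#' recovered exactly and `unalign(true_aln)` equals the leaf sequences.
#'
#' @param tree Rooted `ape::phylo` model tree with branch lengths.
#' @param params A [gtr_params()] object.
#' @param root_length Root sequence length (study design: 1000).
#' @param seed Optional RNG seed.
#' @return List with `alignment` (true alignment, character matrix), `seqs`
#'   (unaligned leaf sequences) and `tree` (the input tree).
#' @export
evolve_sequences <- function(tree, params = gtr_params(), root_length = 1000L,
                             seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(params, "gtr_params"))
  if (root_length < 1) stop("root_length must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  registry <- new.env(parent = emptyenv())
  registry$lo <- 0
  registry$hi <- root_length + 1
  registry$used <- as.numeric(seq_len(root_length))
  root_states <- sample.int(4, root_length, replace = TRUE,
                            prob = params$base_freqs)
  root_cats <- if (is.null(params$gamma_shape)) rep(1L, root_length) else
    sample.int(4, root_length, replace = TRUE)
  leaf_data <- vector("list", n)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  descend <- function(node, states, positions, cats) {
    kids <- children[[as.character(node)]]
    if (is.null(kids)) {
      leaf_data[[node]] <<- list(states = states, positions = positions)
      return(invisible())
    }
    for (e in kids) {
      res <- .evolve_branch(states, positions, cats, tree$edge.length[e],
                            params, registry)
      descend(tree$edge[e, 2], res$states, res$positions, res$cats)
    }
  }
  descend(n + 1L, root_states, as.numeric(seq_len(root_length)), root_cats)
  all_pos <- sort(unique(unlist(lapply(leaf_data, `[[`, "positions"))))
  nt <- c("A", "C", "G", "T")
  aln <- matrix("-", n, length(all_pos),
                dimnames = list(tree$tip.label, NULL))
  for (i in seq_len(n)) {
    cols <- match(leaf_data[[i]]$positions, all_pos)
    aln[i, cols] <- nt[leaf_data[[i]]$states]
  }
  list(alignment = aln, seqs = unalign(aln), tree = tree)
}

#' Generate replicate fixtures for a model condition
#'
#' A model condition follows the benchmark design: number of taxa, tree
#' height, per-site indel rate, 1 kb root sequences, and a number of
#' independent replicates. Each replicate draws a fresh model tree and
#' evolves sequences on it; per-replicate seeds are derived deterministically
#' from the master seed.
#'
#' @param n_taxa Number of leaves.
#' @param height Model tree height.
#' @param indel_prob Per-site insertion and deletion rate per unit branch
#'   length (applied to both processes).
#' @param root_length Root sequence length.
#' @param n_replicates Number of independent replicates (study design: 20).
#' @param seed Master RNG seed.
#' @param gtr Substitution model; defaults to Jukes-Cantor with the condition's
#'   indel rates. If supplied, its indel rates are overridden by `indel_prob`.
#' @return List of replicate fixtures (each as [evolve_sequences()] output),
#'   with a `manifest` attribute recording all parameters and per-replicate
#'   seeds.
#' @export
make_condition_fixtures <- function(n_taxa, height, indel_prob,
                                    root_length = 1000L, n_replicates = 20L,
                                    seed = 1L, gtr = NULL) {
  if (is.null(gtr)) gtr <- gtr_params()
  gtr$insertion_rate <- indel_prob
  gtr$deletion_rate <- indel_prob
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
  fixtures <- lapply(seq_len(n_replicates), function(i) {
    set.seed(rep_seeds[i])
    tree <- sample_model_tree(n_taxa, height)
    evolve_sequences(tree, gtr, root_length)
  })
  attr(fixtures, "manifest") <- list(
    n_taxa = n_taxa, height = height, indel_prob = indel_prob,
    root_length = root_length, n_replicates = n_replicates,
    master_seed = seed, replicate_seeds = rep_seeds,
    base_freqs = gtr$base_freqs, rates = gtr$rates,
    gamma_shape = gtr$gamma_shape, indel_mean_length = gtr$indel_mean_length
  )
  fixtures
}
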