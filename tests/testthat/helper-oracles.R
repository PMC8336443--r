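# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the sweep oracle is a literal step-by-step
# simulation, the homology and PR oracles are naive enumerations.

# Deterministic mirrored sweep with boundary reflection: the gamma = 0 walk.
oracle_mirror_sweep <- function(n_cols, start, direction) {
  out <- integer(n_cols)
  i <- start
  d <- direction
  for (s in seq_len(n_cols)) {
    out[s] <- i
    if (s == n_cols) break
    if ((i == 1 && d == -1) || (i == n_cols && d == 1)) d <- -d
    i <- i + d
  }
  out
}

# one transition of the reflecting reversal walk: reversal draw first, then
# reflection applied to the post-draw direction
oracle_walk_step <- function(i, d, n_cols, reversed) {
  if (reversed) d <- -d
  if ((i == 1 && d == -1) || (i == n_cols && d == 1)) d <- -d
  c(i + d, d)
}

# Exact distribution over complete traces of the reversal walk, by exhaustive
# enumeration of the (column, direction) Markov chain. Returns a named
# numeric vector: trace string (indices comma-joined) -> probability.
oracle_walk_distribution <- function(n_cols, gamma) {
  probs <- new.env(parent = emptyenv())
  add <- function(key, p) {
    assign(key, p + (if (exists(key, probs)) get(key, probs) else 0), probs)
  }
  recurse <- function(trace, i, d, p) {
    trace <- c(trace, i)
    if (length(trace) == n_cols) {
      add(paste(trace, collapse = ","), p)
      return(invisible())
    }
    for (reversed in c(TRUE, FALSE)) {
      pr <- if (reversed) gamma else 1 - gamma
      if (pr > 0) {
        nxt <- oracle_walk_step(i, d, n_cols, reversed)
        recurse(trace, nxt[1], nxt[2], p * pr)
      }
    }
  }
  for (i in seq_len(n_cols)) {
    for (d in c(-1, 1)) {
      recurse(integer(0), i, d, 1 / (2 * n_cols))
    }
  }
  unlist(as.list(probs))
}

# Naive residue-pair homology set: character keys "ti|tj|ri|rj", ti < tj.
oracle_homologies <- function(aln) {
  taxa <- sort(rownames(aln))
  out <- character(0)
  for (i in seq_len(length(taxa) - 1)) {
    for (j in (i + 1):length(taxa)) {
      ri <- 0L
      rj <- 0L
      for (col in seq_len(ncol(aln))) {
        a <- aln[taxa[i], col]
        b <- aln[taxa[j], col]
        if (a != "-") ri <- ri + 1L
        if (b != "-") rj <- rj + 1L
        if (a != "-" && b != "-") {
          out <- c(out, paste(taxa[i], taxa[j], ri, rj, sep = "|"))
        }
      }
    }
  }
  out
}

# Brute-force PR curve from labeled supports: threshold sweep over unique
# values (>= rule) with the (0, 1) sentinel, trapezoidal AUC.
oracle_pr_auc <- function(support, in_ref) {
  thr <- sort(unique(support), decreasing = TRUE)
  rec <- 0
  prec <- 1
  for (t in thr) {
    pos <- support >= t
    rec <- c(rec, sum(pos & in_ref) / sum(in_ref))
    prec <- c(prec, sum(pos & in_ref) / sum(pos))
  }
  o <- order(rec)
  sum(diff(rec[o]) * (head(prec[o], -1) + tail(prec[o], -1)) / 2)
}

# Small fixed test trees/alignments built in code.
toy_quartet <- function() parse_newick("((a,b),(c,d));")

# A low-divergence simulated dataset for pipeline tests.
toy_sim <- function(n_taxa = 6, height = 0.1, indel = 0.05, len = 200,
                    seed = 11) {
  set.seed(seed)
  tr <- sample_model_tree(n_taxa, height)
  evolve_sequences(tr, gtr_params(insertion_rate = indel, deletion_rate = indel),
                   len)
}
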