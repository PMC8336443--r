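# Column resampling of an alignment. Three modes:
#  - rawr:      reversal random walk; consecutive sampled columns are always
#               neighbors in the source alignment (neighbor preservation)
#  - teleport:  as rawr, but a successful gamma draw restarts the walk at a
#               uniform random column and direction instead of reversing
#  - bootstrap: i.i.d. uniform column sampling with replacement
# All modes stop once the number of sampled columns equals the alignment
# length (sequence-length convergence), so every trace has length n_cols.

.check_walk_args <- function(n_cols, gamma) {
  if (!is.numeric(n_cols) || length(n_cols) != 1 || n_cols < 1) {
    stop("n_cols must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma < 0 || gamma > 1) {
    stop("gamma must lie in [0, 1]", call. = FALSE)
  }
}

#' Reversal random walk over alignment columns
#'
#' The walk starts at a uniformly random column with a uniformly random
#' direction and samples one column per step. At each step, after sampling,
#' the direction reverses if a Bernoulli(`gamma`) draw succeeds; boundary
#' reflection is then applied to the resulting direction, so the walk
#' reverses with certainty at the first and last column and never steps
#' outside the alignment. The walk then moves one column and sampling stops
#' once `n_cols` columns have been sampled.
#'
#' @param n_cols Number of columns in the source alignment (walk length).
#' @param gamma Reversal probability in `[0, 1]`. With `gamma = 0` the walk is
#'   the deterministic mirrored sweep with boundary reflection.
#' @param start,direction Optional fixed start column (1-based) and direction
#'   (`+1` right, `-1` left); both are drawn uniformly when `NULL`.
#' @return Integer vector of 1-based column indices of length `n_cols`, with
#'   attributes `start`, `direction`, `mode` and `gamma`.
#' @examples
#' rawr_walk(5, gamma = 0, start = 3, direction = 1)  # 3 4 5 4 3
#' @export
rawr_walk <- function(n_cols, gamma = 0.1, start = NULL, direction = NULL) {
  .check_walk_args(n_cols, gamma)
  n_cols <- as.integer(n_cols)
  if (is.null(start)) start <- sample.int(n_cols, 1L)
  if (is.null(direction)) direction <- sample(c(-1L, 1L), 1L)
  stopifnot(start >= 1, start <= n_cols, direction %in% c(-1L, 1L))
  trace <- integer(n_cols)
  i <- as.integer(start)
  d <- as.integer(direction)
  rev_draw <- runif(n_cols) < gamma
  for (s in seq_len(n_cols)) {
    trace[s] <- i
    if (s == n_cols) break
    if (rev_draw[s]) d <- -d
    # reflection applies to the post-draw direction, so the walk never steps
    # outside the alignment even when a reversal fires at a boundary
    if ((i == 1L && d == -1L) || (i == n_cols && d == 1L)) d <- -d
    i <- i + d
  }
  structure(trace, start = as.integer(start), direction = as.integer(direction),
            mode = "rawr", gamma = gamma)
}

#' Teleportation random walk over alignment columns
#'
#' Identical to [rawr_walk()], except that a successful Bernoulli(`gamma`)
#' draw relocates the walk to a uniformly random column and direction instead
#' of reversing it. Boundary reflection still applies between teleports, so
#' consecutive sampled columns within a walk segment remain neighbors. At
#' `gamma = 1` every sampled column is an independent uniform draw, making the
#' mode an intermediate between RAWR and bootstrap resampling.
#'
#' @inheritParams rawr_walk
#' @return As [rawr_walk()], with an extra attribute `jumps`: the trace
#'   positions after which a teleport occurred (segment boundaries).
#' @export
teleport_walk <- function(n_cols, gamma = 0.1, start = NULL, direction = NULL) {
  .check_walk_args(n_cols, gamma)
  n_cols <- as.integer(n_cols)
  if (is.null(start)) start <- sample.int(n_cols, 1L)
  if (is.null(direction)) direction <- sample(c(-1L, 1L), 1L)
  stopifnot(start >= 1, start <= n_cols, direction %in% c(-1L, 1L))
  trace <- integer(n_cols)
  jumps <- integer(0)
  i <- as.integer(start)
  d <- as.integer(direction)
  for (s in seq_len(n_cols)) {
    trace[s] <- i
    if (s == n_cols) break
    if (runif(1) < gamma) {
      i <- sample.int(n_cols, 1L)
      d <- sample(c(-1L, 1L), 1L)
      jumps <- c(jumps, s)
    } else {
      if ((i == 1L && d == -1L) || (i == n_cols && d == 1L)) d <- -d
      i <- i + d
    }
  }
  structure(trace, start = as.integer(start), direction = as.integer(direction),
            mode = "teleport", gamma = gamma, jumps = jumps)
}

#' Bootstrap column resampling
#'
#' Classical phylogenetic bootstrap: `n_cols` i.i.d. uniform draws from the
#' columns, with replacement. No adjacency structure is preserved.
#'
#' @inheritParams rawr_walk
#' @return Integer vector of 1-based column indices of length `n_cols`.
#' @export
bootstrap_columns <- function(n_cols) {
  .check_walk_args(n_cols, 0)
  n_cols <- as.integer(n_cols)
  structure(sample.int(n_cols, n_cols, replace = TRUE), mode = "bootstrap")
}

#' Drop gaps from an alignment
#'
#' Removes `-` characters from each row, preserving residue order; resulting
#' sequences may have differing lengths. Taxa whose row is entirely gaps are
#' retained with a zero-length sequence.
#'
#' @param aln Character matrix alignment.
#' @return Named character vector of unaligned sequences.
#' @export
unalign <- function(aln) {
  stopifnot(is.matrix(aln))
  setNames(apply(aln, 1, function(r) paste(r[r != "-"], collapse = "")),
           rownames(aln))
}

#' Materialize a resampled replicate from a walk trace
#'
#' Gathers alignment columns in walk order (the walk order defines the site
#' order of the replicate) and unaligns the result.
#'
#' @param aln Character matrix alignment.
#' @param trace Integer vector of 1-based column indices (from [rawr_walk()],
#'   [teleport_walk()] or [bootstrap_columns()]).
#' @return A list of class `rawr_replicate` with elements `aligned` (resampled
#'   columns, still a matrix), `unaligned` (gap-dropped sequences) and `trace`.
#' @export
extract_replicate <- function(aln, trace) {
  stopifnot(is.matrix(aln))
  idx <- as.integer(trace)
  if (any(idx < 1L) || any(idx > ncol(aln))) {
    stop("trace index out of range [1, ", ncol(aln), "]", call. = FALSE)
  }
  res <- aln[, idx, drop = FALSE]
  structure(list(aligned = res, unaligned = unalign(res), trace = trace),
            class = "rawr_replicate")
}

#' Generate many resampled replicates
#'
#' Each replicate is produced from an independent RNG stream derived
#' deterministically from `seed` and the replicate index, so a replicate set
#' is fully reproducible from the master seed.
#'
#' @param aln Character matrix alignment.
#' @param mode One of `"rawr"`, `"teleport"`, `"bootstrap"`.
#' @param gamma Reversal (rawr) or teleport probability; ignored for
#'   bootstrap.
#' @param k Number of replicates.
#' @param seed Master RNG seed.
#' @return List of `k` `rawr_replicate` objects.
#' @export
resample_many <- function(aln, mode = c("rawr", "teleport", "bootstrap"),
                          gamma = 0.1, k = 100L, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(aln), k >= 1)
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, k)
  lapply(seq_len(k), function(i) {
    set.seed(rep_seeds[i])
    trace <- switch(mode,
      rawr = rawr_walk(ncol(aln), gamma),
      teleport = teleport_walk(ncol(aln), gamma),
      bootstrap = bootstrap_columns(ncol(aln))
    )
    extract_replicate(aln, trace)
  })
}
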