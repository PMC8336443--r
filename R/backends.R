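# Alignment and tree estimation backends. A backend is a small object pairing
# a name with an invoke function; `align()` / `infer_tree()` validate the
# backend contracts (taxon preservation, unalign identity) so every backend —
# built-in or external — is interchangeable downstream.
#
# External adapters shell out with a configurable executable path and argument
# template; tests involving external binaries skip when the binary is absent.

#' Construct an aligner backend
#'
#' @param name `"builtin"` for the package's progressive aligner, `"mafft"`
#'   for an external MAFFT adapter, or a custom name combined with `fn`.
#' @param exec Executable path for external backends.
#' @param args Character vector of extra command-line arguments (MAFFT
#'   defaults to `--auto --quiet`).
#' @param fn Custom invoke function `function(seqs) -> alignment matrix` used
#'   when `name` is not a known adapter.
#' @return An object of class `aligner_backend`.
#' @export
aligner_backend <- function(name = "builtin", exec = name, args = NULL,
                            fn = NULL) {
  invoke <- if (!is.null(fn)) fn else switch(name,
    builtin = builtin_align,
    mafft = function(seqs) .mafft_align(seqs, exec = exec,
                                        args = args %||% c("--auto", "--quiet")),
    stop("unknown aligner backend '", name, "'; supply fn=", call. = FALSE)
  )
  structure(list(name = name, invoke = invoke), class = "aligner_backend")
}

#' Construct a tree estimation backend
#'
#' @param name `"builtin"` for neighbor joining on Jukes-Cantor distances,
#'   `"fasttree"` for an external FastTree adapter (approximate maximum
#'   likelihood under GTR), `"raxml"` for an external RAxML adapter, or a
#'   custom name combined with `fn`.
#' @param exec Executable path for external backends.
#' @param args Character vector of extra command-line arguments.
#' @param fn Custom invoke function `function(aln) -> phylo`.
#' @return An object of class `tree_backend`.
#' @export
tree_backend <- function(name = "builtin", exec = name, args = NULL,
                         fn = NULL) {
  invoke <- if (!is.null(fn)) fn else switch(name,
    builtin = builtin_tree,
    fasttree = function(aln) .fasttree_tree(aln, exec = exec,
                                            args = args %||% c("-nt", "-gtr", "-quiet", "-nopr")),
    raxml = function(aln) .raxml_tree(aln, exec = exec, args = args),
    stop("unknown tree backend '", name, "'; supply fn=", call. = FALSE)
  )
  structure(list(name = name, invoke = invoke), class = "tree_backend")
}

#' A tree backend that always returns a fixed tree
#'
#' Useful for pipeline identity checks: under a constant re-estimator every
#' bipartition of the annotation tree receives support 1.
#'
#' @param tree The `phylo` tree to return for every input.
#' @return A `tree_backend`.
#' @export
constant_tree_backend <- function(tree) {
  tree_backend(name = "constant", fn = function(aln) tree)
}

#' Align sequences through a backend, enforcing the aligner contract
#'
#' The output must contain exactly the input taxa and unaligning it must
#' reproduce every input sequence.
#'
#' @param seqs Named character vector of at least 2 gap-free sequences.
#' @param backend An [aligner_backend()]; default is the built-in aligner.
#' @return Character matrix alignment.
#' @export
align <- function(seqs, backend = aligner_backend("builtin")) {
  stopifnot(inherits(backend, "aligner_backend"), length(seqs) >= 2)
  aln <- backend$invoke(seqs)
  if (!is.matrix(aln) || !setequal(rownames(aln), names(seqs))) {
    stop("aligner backend '", backend$name, "' violated the taxon-set contract",
         call. = FALSE)
  }
  back <- unalign(aln)[names(seqs)]
  if (!identical(unname(back), unname(seqs))) {
    stop("aligner backend '", backend$name,
         "' violated the unalign identity contract", call. = FALSE)
  }
  aln
}

#' Estimate a tree through a backend, enforcing the tree contract
#'
#' @param aln Character matrix alignment.
#' @param backend A [tree_backend()]; default is the built-in NJ estimator.
#' @return Unrooted `phylo` tree whose leaf set equals the alignment's taxa.
#' @export
infer_tree <- function(aln, backend = tree_backend("builtin")) {
  stopifnot(inherits(backend, "tree_backend"), is.matrix(aln))
  tr <- backend$invoke(aln)
  if (!inherits(tr, "phylo") || !setequal(tr$tip.label, rownames(aln))) {
    stop("tree backend '", backend$name, "' violated the leaf-set contract",
         call. = FALSE)
  }
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.run_tool <- function(exec, args, stdin = "", stdout = TRUE) {
  if (Sys.which(exec) == "" && !file.exists(exec)) {
    stop("executable '", exec, "' not found on PATH", call. = FALSE)
  }
  out <- suppressWarnings(system2(exec, args, stdout = stdout, stderr = FALSE,
                                  stdin = stdin))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("'", exec, "' exited with status ", status, call. = FALSE)
  }
  out
}

.mafft_align <- function(seqs, exec = "mafft", args = c("--auto", "--quiet")) {
  if (any(nchar(seqs) == 0)) {
    stop("mafft backend cannot align zero-length sequences; filter them first",
         call. = FALSE)
  }
  fin <- tempfile(fileext = ".fasta")
  on.exit(unlink(fin))
  write_fasta_file(seqs, fin)
  out <- .run_tool(exec, c(args, fin))
  aln <- parse_fasta(paste(out, collapse = "\n"), aligned = TRUE)
  aln[names(seqs), , drop = FALSE]
}

.fasttree_tree <- function(aln, exec = "fasttree",
                           args = c("-nt", "-gtr", "-quiet", "-nopr")) {
  fin <- tempfile(fileext = ".fasta")
  on.exit(unlink(fin))
  write_fasta_file(aln, fin)
  out <- .run_tool(exec, args, stdin = fin)
  tr <- parse_newick(paste(out, collapse = ""))
  tr$node.label <- NULL  # fasttree's own local supports are not ours to keep
  ape::unroot(tr)
}

.raxml_tree <- function(aln, exec = "raxmlHPC", args = NULL) {
  dir <- tempfile("raxml")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  fin <- file.path(dir, "aln.fasta")
  write_fasta_file(aln, fin)
  .run_tool(exec, c(args %||% c("-m", "GTRGAMMA", "-p", "12345"),
                    "-s", fin, "-n", "run", "-w", dir))
  tree_file <- file.path(dir, "RAxML_bestTree.run")
  if (!file.exists(tree_file)) {
    stop("raxml did not produce a best tree", call. = FALSE)
  }
  ape::unroot(parse_newick(paste(readLines(tree_file), collapse = "")))
}
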