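# RAxML-style partition files: lines of the form "DNA, name = start-end" with
# 1-based inclusive column coordinates, which is also the package's internal
# convention (native R indexing).

#' Parse a RAxML-style partition file
#'
#' @param text Partition file contents; one `DNA, name = start-end` line per
#'   locus, 1-based inclusive coordinates.
#' @return A data frame with columns `name`, `start`, `end` (1-based
#'   inclusive), in file order.
#' @export
parse_partition_file <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  lines <- strsplit(text, "\r?\n")[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(name = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  pat <- "^\\s*DNA\\s*,\\s*(\\S+)\\s*=\\s*([0-9]+)\\s*-\\s*([0-9]+)\\s*$"
  m <- regmatches(lines, regexec(pat, lines))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) {
    stop("unparseable partition line: '", lines[bad][1], "'", call. = FALSE)
  }
  out <- data.frame(
    name = vapply(m, `[`, character(1), 2),
    start = as.integer(vapply(m, `[`, character(1), 3)),
    end = as.integer(vapply(m, `[`, character(1), 4)),
    stringsAsFactors = FALSE
  )
  if (any(out$start < 1) || any(out$end < out$start)) {
    stop("invalid partition interval (start must be >= 1 and <= end)",
         call. = FALSE)
  }
  cover <- unlist(Map(seq.int, out$start, out$end))
  if (anyDuplicated(cover)) {
    stop("overlapping partition intervals", call. = FALSE)
  }
  out
}

#' Split a concatenated alignment by a partition scheme
#'
#' @param aln Character matrix alignment.
#' @param scheme Data frame from [parse_partition_file()].
#' @return Named list of alignments, one per partition.
#' @export
split_partitions <- function(aln, scheme) {
  stopifnot(is.matrix(aln))
  if (nrow(scheme) > 0 && max(scheme$end) > ncol(aln)) {
    stop("partition scheme extends past alignment width", call. = FALSE)
  }
  setNames(lapply(seq_len(nrow(scheme)), function(i) {
    aln[, scheme$start[i]:scheme$end[i], drop = FALSE]
  }), scheme$name)
}
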