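# FASTA input/output on the package's two sequence containers:
#  - a sequence set: named character vector of gap-free strings over {A,C,G,T,N}
#  - an alignment:   character matrix (rows = taxa) over {A,C,G,T,N,-}
# The strict 5-letter alphabet (plus N) is part of the resampling contract, so
# parsing normalizes case and maps IUPAC ambiguity codes to N at the boundary.

.IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U", "N")

.normalize_seq <- function(s, label, allow_gap) {
  s <- toupper(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  chars[chars %in% .IUPAC_AMBIG] <- "N"
  ok <- c("A", "C", "G", "T", "N", if (allow_gap) "-")
  bad <- setdiff(unique(chars), ok)
  if (length(bad) > 0) {
    stop("sequence '", label, "' contains unsupported character(s): ",
         paste(bad, collapse = " "), call. = FALSE)
  }
  paste(chars, collapse = "")
}

#' Parse FASTA text
#'
#' @param text A single string of FASTA-formatted text (possibly line-wrapped,
#'   case-insensitive). IUPAC ambiguity codes are mapped to `N`; the gap
#'   character is `-` (a `.` is rejected).
#' @param aligned If `TRUE`, all sequences must have equal length and a
#'   character matrix (rows = taxa) is returned; otherwise sequences must be
#'   gap-free and a named character vector is returned.
#' @return A named character vector (`aligned = FALSE`) or character matrix
#'   with taxon row names (`aligned = TRUE`).
#' @examples
#' parse_fasta(">a\nACGT\n>b\nAC-T", aligned = TRUE)
#' @export
parse_fasta <- function(text, aligned = FALSE) {
  stopifnot(is.character(text), length(text) == 1)
  lines <- strsplit(text, "\r?\n")[[1]]
  lines <- lines[nzchar(trimws(lines))]
  is_hdr <- startsWith(lines, ">")
  if (length(lines) > 0 && !is_hdr[1]) {
    stop("malformed FASTA: content before first header", call. = FALSE)
  }
  labels <- character(0)
  seqs <- character(0)
  if (any(is_hdr)) {
    grp <- cumsum(is_hdr)
    labels <- trimws(sub("^>", "", lines[is_hdr]))
    # first whitespace-delimited token is the label
    labels <- vapply(strsplit(labels, "\\s+"), `[`, character(1), 1)
    labels[is.na(labels)] <- ""
    seqs <- vapply(seq_along(labels), function(i) {
      paste(lines[!is_hdr & grp == i], collapse = "")
    }, character(1))
  }
  if (any(!nzchar(labels))) stop("empty taxon label in FASTA", call. = FALSE)
  dup <- labels[duplicated(labels)]
  if (length(dup) > 0) {
    stop("duplicate taxon label(s) in FASTA: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  seqs <- vapply(seq_along(seqs), function(i) {
    .normalize_seq(seqs[i], labels[i], allow_gap = aligned)
  }, character(1))
  names(seqs) <- labels
  if (!aligned) {
    return(seqs)
  }
  lens <- nchar(seqs)
  if (length(lens) > 0 && length(unique(lens)) != 1) {
    off <- labels[lens != lens[1]][1]
    stop("ragged alignment: row '", off, "' has length ", nchar(seqs[off]),
         " but '", labels[1], "' has length ", lens[1], call. = FALSE)
  }
  seqs_to_matrix(seqs)
}

#' Serialize sequences or an alignment to FASTA text
#'
#' Inverse of [parse_fasta()]: `parse_fasta(write_fasta(x))` recovers `x`.
#'
#' @param x Named character vector of sequences, or a character matrix with
#'   taxon row names.
#' @param width Line-wrap width for sequence lines.
#' @return A single FASTA string.
#' @export
write_fasta <- function(x, width = 60L) {
  if (is.matrix(x)) x <- matrix_to_seqs(x)
  if (length(x) == 0) return("")
  chunks <- vapply(seq_along(x), function(i) {
    s <- x[[i]]
    body <- if (nchar(s) == 0) "" else {
      starts <- seq(1L, nchar(s), by = width)
      paste(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
            collapse = "\n")
    }
    paste0(">", names(x)[i], "\n", body)
  }, character(1))
  paste0(paste(chunks, collapse = "\n"), "\n")
}

#' @rdname parse_fasta
#' @param path Path of a FASTA file to read.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  parse_fasta(paste(readLines(path, warn = FALSE), collapse = "\n"), aligned)
}

#' @rdname write_fasta
#' @param path Path of a FASTA file to write.
#' @export
write_fasta_file <- function(x, path, width = 60L) {
  writeLines(sub("\n$", "", write_fasta(x, width)), path)
  invisible(path)
}

#' Convert between string and matrix sequence representations
#'
#' @param seqs Named character vector of equal-length strings.
#' @return `seqs_to_matrix`: a character matrix with one row per taxon;
#'   `matrix_to_seqs`: a named character vector.
#' @export
seqs_to_matrix <- function(seqs) {
  if (length(seqs) == 0) {
    return(matrix(character(0), nrow = 0, ncol = 0))
  }
  stopifnot(length(unique(nchar(seqs))) == 1)
  m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  if (is.null(m)) m <- matrix(character(0), nrow = length(seqs), ncol = 0)
  rownames(m) <- names(seqs)
  m
}

#' @rdname seqs_to_matrix
#' @param m Character matrix with taxon row names.
#' @export
matrix_to_seqs <- function(m) {
  setNames(apply(m, 1, paste, collapse = ""), rownames(m))
}
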