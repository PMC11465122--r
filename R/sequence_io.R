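#' Sequence collections and text assembly
#'
#' A sequence set is an ordered collection of named sequences (a pangenome:
#' several haplotypes or genomes to be indexed jointly).  [assemble_text()]
#' concatenates the records with a single `'#'` separator between
#' consecutive sequences, producing the text the parser indexes.  Two
#' symbols are reserved: `'$'` (used only as padding/terminator by the
#' parser) and `'#'` (the record separator), ordered `'$' < '#' <` all
#' sequence symbols.
#'
#' @name sequence_io
NULL

#' Create a sequence set
#'
#' @param ids character vector of unique record identifiers.
#' @param seqs character vector of non-empty sequences (uppercased).
#' @return A data.frame of class `rpfp_seqset` with columns `id` and `seq`.
#' @export
seq_set <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) rpfp_abort("rpfp_error_io", "ids and seqs differ in length")
  if (length(ids) == 0L) rpfp_abort("rpfp_error_io", "empty sequence set")
  if (anyDuplicated(ids)) {
    rpfp_abort("rpfp_error_io",
               sprintf("duplicate record identifier: '%s'", ids[duplicated(ids)][1L]))
  }
  empty <- !nzchar(seqs)
  if (any(empty)) {
    rpfp_abort("rpfp_error_io",
               sprintf("record '%s' has an empty sequence", ids[empty][1L]))
  }
  bad <- regexpr("[$#]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    rpfp_abort("rpfp_error_io",
               sprintf("reserved symbol in record '%s' at offset %d", ids[i], bad[i]))
  }
  structure(data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE),
            class = c("rpfp_seqset", "data.frame"))
}

#' Read a FASTA file into a sequence set
#'
#' Plain or line-wrapped FASTA (gzip accepted transparently); sequences are
#' uppercased.  Characters outside `{A,C,G,T,N}` are preserved verbatim but
#' reported in a warning.  Record order is the file order.
#'
#' @param path path to a FASTA file.
#' @return An `rpfp_seqset`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) rpfp_abort("rpfp_error_io", sprintf("file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) rpfp_abort("rpfp_error_io",
                    sprintf("cannot parse FASTA '%s': %s", path, conditionMessage(e))))
  if (length(set) == 0L) rpfp_abort("rpfp_error_io", sprintf("empty FASTA file: %s", path))
  seqs <- toupper(as.character(set))
  ids <- names(set)
  odd <- gsub("[ACGTN]", "", seqs)
  if (any(nzchar(odd))) {
    sym <- sort(unique(strsplit(paste(odd, collapse = ""), "")[[1L]]))
    warning(sprintf("non-ACGTN symbols kept verbatim: %s", paste(sym, collapse = " ")),
            call. = FALSE)
  }
  seq_set(ids, seqs)
}

#' Write a sequence set as FASTA
#'
#' @param seqs an `rpfp_seqset`.
#' @param path output path; 60-column line wrap.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(inherits(seqs, "rpfp_seqset"))
  x <- Biostrings::BStringSet(seqs$seq)
  names(x) <- seqs$id
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Assemble the indexable text from a sequence set
#'
#' Records are joined with a single `'#'` between consecutive sequences
#' (none at the ends); `'$'` padding is applied later by the parser.  The
#' symbol order is `'$' < '#' <` remaining symbols in byte order (so
#' `A < C < G < N < T` for DNA).
#'
#' @param seqs an `rpfp_seqset`.
#' @return An object of class `rpfp_text`: a list with `sym` (integer codes,
#'   `'#'` = 1, sequence symbols from 2 up; code 0 is the reserved `'$'`),
#'   `alphabet` (characters for codes `1..k`), and `n` (text length).
#' @export
assemble_text <- function(seqs) {
  stopifnot(inherits(seqs, "rpfp_seqset"))
  txt <- paste(seqs$seq, collapse = "#")
  chars <- sort(unique(strsplit(txt, "")[[1L]]), method = "radix")
  alphabet <- unique(c("#", chars))          # '#' first even if absent from txt
  sym <- match(strsplit(txt, "")[[1L]], alphabet)
  structure(list(sym = as.integer(sym), alphabet = alphabet, n = nchar(txt)),
            class = "rpfp_text")
}

#' @export
print.rpfp_text <- function(x, ...) {
  cat(sprintf("rpfp_text: n = %d, alphabet = {$, %s}\n",
              x$n, paste(x$alphabet, collapse = ", ")))
  invisible(x)
}

# Render an rpfp_text (or raw code vector) back to a character string,
# mapping the sentinel code 0 to '$'.
text_to_string <- function(x, alphabet = NULL) {
  if (inherits(x, "rpfp_text")) {
    alphabet <- x$alphabet
    x <- x$sym
  }
  paste(c("$", alphabet)[x + 1L], collapse = "")
}

# Build an rpfp_text straight from a single character string (test and
# example convenience; equivalent to a one-record sequence set).
text_from_string <- function(s) {
  assemble_text(seq_set("seq1", s))
}
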