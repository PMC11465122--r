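#' On-disk formats
#'
#' Plain-text, versioned formats for dictionaries, parses, bundles and the
#' final index.  Dictionary files carry one phrase per line (space-separated
#' integer token codes, lexicographic order) after a header recording the
#' format version, window length and — for character-level dictionaries —
#' the alphabet; parse files carry the ranks.  Loaders verify headers and
#' reconstruct objects bit-exactly.
#'
#' @name io_formats
NULL

DICT_HEADER <- "RPFPDICT 1"
PARSE_HEADER <- "RPFPPARSE 1"

#' Write / read a dictionary
#'
#' @param dict an `rpfp_dict`.
#' @param path file path.
#' @return `path` invisibly; `read_dictionary()` returns the `rpfp_dict`.
#' @export
write_dictionary <- function(dict, path) {
  alpha <- if (is.null(dict$alphabet)) "tokens" else paste(dict$alphabet, collapse = "")
  header <- sprintf("%s w=%d alphabet=%s", DICT_HEADER, dict$w, alpha)
  body <- vapply(dict$phrases, function(p) paste(p, collapse = " "), character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1L], DICT_HEADER))
    rpfp_abort("rpfp_error_io", sprintf("not a dictionary file (bad header): %s", path))
  fields <- strsplit(sub(paste0(DICT_HEADER, " "), "", lines[1L]), " ")[[1L]]
  w <- as.integer(sub("w=", "", fields[1L]))
  alpha <- sub("alphabet=", "", fields[2L])
  alphabet <- if (alpha == "tokens") NULL else strsplit(alpha, "")[[1L]]
  phrases <- lapply(strsplit(lines[-1L], " ", fixed = TRUE), as.integer)
  keys <- vapply(phrases, encode_key, character(1L))
  structure(list(keys = keys, phrases = phrases, lens = lengths(phrases),
                 w = w, alphabet = alphabet),
            class = "rpfp_dict")
}

#' Write / read a parse
#'
#' @param parse integer rank vector.
#' @param path file path.
#' @return `path` invisibly; `read_parse()` returns the integer vector.
#' @export
write_parse <- function(parse, path) {
  writeLines(c(PARSE_HEADER, paste(parse, collapse = " ")), path)
  invisible(path)
}

#' @rdname write_parse
#' @export
read_parse <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !identical(lines[1L], PARSE_HEADER))
    rpfp_abort("rpfp_error_io", sprintf("not a parse file (bad header): %s", path))
  as.integer(strsplit(lines[2L], " ", fixed = TRUE)[[1L]])
}

#' Write / read a recursive-parse bundle
#'
#' Writes `<prefix>.dt.dict`, `<prefix>.dp.dict`, `<prefix>.pp.parse` and a
#' JSON sidecar of parameters and sizes.  A retained first-level parse
#' (test mode) goes to `<prefix>.pt.parse`; index construction never reads
#' it, so deleting that file does not affect [rpfp_index()] on the re-read
#' bundle.
#'
#' @param bundle an `rpfp_bundle`.
#' @param prefix output path prefix.
#' @return The sidecar path invisibly; `read_bundle()` returns the bundle.
#' @export
write_bundle <- function(bundle, prefix) {
  write_dictionary(bundle$d_t, paste0(prefix, ".dt.dict"))
  write_dictionary(bundle$d_p, paste0(prefix, ".dp.dict"))
  write_parse(bundle$p_p, paste0(prefix, ".pp.parse"))
  if (!is.null(bundle$p_t)) write_parse(bundle$p_t, paste0(prefix, ".pt.parse"))
  meta <- list(w1 = bundle$w1, p1 = bundle$p1, w2 = bundle$w2, p2 = bundle$p2,
               n = bundle$n, alphabet = bundle$alphabet,
               sizes = bundle_sizes(bundle))
  jsonlite::write_json(meta, paste0(prefix, ".meta.json"), auto_unbox = TRUE)
  invisible(paste0(prefix, ".meta.json"))
}

#' @rdname write_bundle
#' @export
read_bundle <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".meta.json"), simplifyVector = TRUE)
  bundle <- list(d_t = read_dictionary(paste0(prefix, ".dt.dict")),
                 d_p = read_dictionary(paste0(prefix, ".dp.dict")),
                 p_p = read_parse(paste0(prefix, ".pp.parse")),
                 w1 = as.integer(meta$w1), p1 = as.integer(meta$p1),
                 w2 = as.integer(meta$w2), p2 = as.integer(meta$p2),
                 n = as.integer(meta$n), alphabet = meta$alphabet)
  pt_path <- paste0(prefix, ".pt.parse")
  if (file.exists(pt_path)) bundle$p_t <- read_parse(pt_path)
  structure(bundle, class = "rpfp_bundle")
}

# Token and byte sizes of the bundle components (|P_T| is recovered as the
# sum of phrase occurrence counts; the parse itself is not held).
bundle_sizes <- function(bundle) {
  list(d_t_phrases = length(bundle$d_t$keys),
       d_t_tokens = sum(bundle$d_t$lens),
       d_p_phrases = length(bundle$d_p$keys),
       d_p_tokens = sum(bundle$d_p$lens),
       p_p_tokens = length(bundle$p_p),
       p_t_tokens = sum(phrase_occurrence_counts(bundle)))
}

RLBWT_HEADER <- "RLBWT v1"
SSA_HEADER <- "RPFPSSA v1"
SLCP_HEADER <- "RPFPSLCP v1"

#' Serialize / load a built index
#'
#' Writes `<prefix>.rlbwt` (one `symbol<TAB>length` line per run),
#' `<prefix>.ssa` (TSV: run, start_row, sa_first, sa_last) and
#' `<prefix>.slcp` (TSV: run, start_row, lcp), each with a versioned header
#' line.  `load_index()` reconstructs the tables bit-exactly.
#'
#' @param idx an `rpfp_index`.
#' @param prefix output path prefix.
#' @return Written paths invisibly; `load_index()` returns an `rpfp_index`
#'   (without full arrays).
#' @export
serialize_index <- function(idx, prefix) {
  p1 <- paste0(prefix, ".rlbwt")
  writeLines(c(RLBWT_HEADER, sprintf("%s\t%d", idx$runs$symbol, idx$runs$length)), p1)
  p2 <- paste0(prefix, ".ssa")
  writeLines(c(SSA_HEADER, sprintf("%d\t%d\t%d\t%d", idx$ssa$run, idx$ssa$start_row,
                                   idx$ssa$sa_first, idx$ssa$sa_last)), p2)
  p3 <- paste0(prefix, ".slcp")
  writeLines(c(SLCP_HEADER, sprintf("%d\t%d\t%d", idx$slcp$run, idx$slcp$start_row,
                                    idx$slcp$lcp)), p3)
  invisible(c(p1, p2, p3))
}

#' @rdname serialize_index
#' @export
load_index <- function(prefix) {
  read_tsv_body <- function(path, header, cols) {
    lines <- readLines(path)
    if (length(lines) < 1L || !identical(lines[1L], header))
      rpfp_abort("rpfp_error_io", sprintf("bad header in %s (expected '%s')", path, header))
    if (length(lines) == 1L) return(NULL)
    m <- strsplit(lines[-1L], "\t", fixed = TRUE)
    out <- as.data.frame(do.call(rbind, m), stringsAsFactors = FALSE)
    names(out) <- cols
    out
  }
  rl <- read_tsv_body(paste0(prefix, ".rlbwt"), RLBWT_HEADER, c("symbol", "length"))
  rl$length <- as.integer(rl$length)
  ssa <- read_tsv_body(paste0(prefix, ".ssa"), SSA_HEADER,
                       c("run", "start_row", "sa_first", "sa_last"))
  ssa[] <- lapply(ssa, as.integer)
  slcp <- read_tsv_body(paste0(prefix, ".slcp"), SLCP_HEADER,
                        c("run", "start_row", "lcp"))
  slcp[] <- lapply(slcp, as.integer)
  structure(list(runs = structure(rl, class = c("rpfp_rlbwt", "data.frame")),
                 ssa = ssa, slcp = slcp,
                 n = sum(rl$length) - 1L, r = nrow(rl)),
            class = "rpfp_index")
}
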