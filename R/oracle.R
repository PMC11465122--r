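#' Brute-force oracle
#'
#' Ground truth for small texts: the full suffix array, inverse suffix
#' array, BWT and LCP array of `T$`, computed by direct comparison-based
#' sorting of the suffixes.  The oracle shares no parsing code with the
#' construction path, so agreement between the two is evidence of
#' correctness rather than tautology.
#'
#' @name oracle
NULL

ORACLE_MAX_N <- 100000L

#' Full SA, ISA, BWT and LCP by direct suffix sorting
#'
#' @param x an `rpfp_text`, `rpfp_seqset` or single character string.
#' @return An object of class `rpfp_oracle`: `sa` (permutation of
#'   `1..n+1`), `isa`, `bwt` (character string), `lcp` (`lcp[1] = 0`), `n`.
#' @export
naive_index <- function(x) {
  if (is.character(x)) x <- text_from_string(x)
  if (inherits(x, "rpfp_seqset")) x <- assemble_text(x)
  stopifnot(inherits(x, "rpfp_text"))
  v <- c(x$sym, 0L)
  np <- length(v)
  if (np > ORACLE_MAX_N)
    rpfp_abort("rpfp_error_oracle", sprintf("oracle limited to n+1 <= %d", ORACLE_MAX_N))
  key <- encode_key(v)
  sa <- key_order(substring(key, seq_len(np)))
  isa <- integer(np); isa[sa] <- seq_len(np)
  bwt_code <- ifelse(sa > 1L, v[pmax(sa - 1L, 1L)], v[np])
  lcp <- integer(np)
  for (i in seq.int(2L, length.out = np - 1L)) {
    lcp[i] <- vec_lcp(v[sa[i - 1L]:np], v[sa[i]:np])
  }
  structure(list(sa = sa, isa = isa,
                 bwt = paste(c("$", x$alphabet)[bwt_code + 1L], collapse = ""),
                 lcp = lcp, n = x$n, alphabet = x$alphabet),
            class = "rpfp_oracle")
}

#' @export
print.rpfp_oracle <- function(x, ...) {
  cat(sprintf("rpfp_oracle: n = %d (full SA/BWT/LCP of T$)\n", x$n))
  invisible(x)
}

#' Compare a constructed index against the oracle
#'
#' Checks the BWT string, the run decomposition, the SA samples at run
#' starts and ends, and the LCP samples at run starts; with full arrays
#' present, also the complete SA and LCP.  The report lists the first
#' mismatch of each kind.
#'
#' @param built an `rpfp_index`.
#' @param oracle an `rpfp_oracle` over the same text.
#' @return A list of class `rpfp_diff` with `equal` (logical) and
#'   `messages` (character; empty iff equal).
#' @export
compare_index <- function(built, oracle) {
  msg <- character(0L)
  note <- function(fmt, ...) msg <<- c(msg, sprintf(fmt, ...))
  ob_runs <- run_length_encode(oracle$bwt)
  built_bwt <- run_length_decode(built$runs)
  if (built_bwt != oracle$bwt) {
    d <- which(strsplit(built_bwt, "")[[1L]] != strsplit(oracle$bwt, "")[[1L]])[1L]
    note("BWT mismatch at row %d: built '%s' vs oracle '%s'",
         d, substr(built_bwt, d, d), substr(oracle$bwt, d, d))
  }
  if (nrow(built$runs) != nrow(ob_runs)) {
    note("run count mismatch: built %d vs oracle %d", nrow(built$runs), nrow(ob_runs))
  } else if (!identical(unname(as.integer(built$runs$length)),
                        unname(as.integer(ob_runs$length))) ||
             !identical(built$runs$symbol, ob_runs$symbol)) {
    bad <- which(built$runs$symbol != ob_runs$symbol |
                 built$runs$length != ob_runs$length)[1L]
    note("run %d mismatch: built (%s,%d) vs oracle (%s,%d)", bad,
         built$runs$symbol[bad], built$runs$length[bad],
         ob_runs$symbol[bad], ob_runs$length[bad])
  } else {
    start <- cumsum(c(1L, ob_runs$length[-nrow(ob_runs)]))
    end <- cumsum(ob_runs$length)
    bad <- which(built$ssa$sa_first != oracle$sa[start] |
                 built$ssa$sa_last != oracle$sa[end])
    if (length(bad)) {
      note("SA sample mismatch at run %d (rows %d..%d): built (%d,%d) vs oracle (%d,%d)",
           bad[1L], start[bad[1L]], end[bad[1L]],
           built$ssa$sa_first[bad[1L]], built$ssa$sa_last[bad[1L]],
           oracle$sa[start[bad[1L]]], oracle$sa[end[bad[1L]]])
    }
    bad <- which(built$slcp$lcp != oracle$lcp[start])
    if (length(bad)) {
      note("LCP sample mismatch at run %d (row %d): built %d vs oracle %d",
           bad[1L], start[bad[1L]], built$slcp$lcp[bad[1L]], oracle$lcp[start[bad[1L]]])
    }
  }
  if (!is.null(built$full)) {
    if (!identical(as.integer(built$full$sa), oracle$sa)) {
      bad <- which(built$full$sa != oracle$sa)[1L]
      note("full SA mismatch at row %d: built %d vs oracle %d",
           bad, built$full$sa[bad], oracle$sa[bad])
    }
    if (!identical(as.integer(built$full$lcp), oracle$lcp)) {
      bad <- which(built$full$lcp != oracle$lcp)[1L]
      note("full LCP mismatch at row %d: built %d vs oracle %d",
           bad, built$full$lcp[bad], oracle$lcp[bad])
    }
  }
  structure(list(equal = length(msg) == 0L, messages = msg), class = "rpfp_diff")
}

#' @export
print.rpfp_diff <- function(x, ...) {
  if (x$equal) cat("rpfp_diff: no differences\n")
  else cat("rpfp_diff:\n", paste0("  ", x$messages, collapse = "\n"), "\n", sep = "")
  invisible(x)
}
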