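#' Recursive prefix-free parsing
#'
#' Level 1 parses the text `T` with window `w1`, yielding dictionary `D_T`
#' and parse `P_T`.  Level 2 parses `P_T` itself (padded with the sentinel
#' token 0) with window `w2`, yielding `D_P` and `P_P`.  The first-level
#' parse is then discarded: index construction works from `(D_T, D_P, P_P)`
#' alone, whose combined size stays small on repetitive collections even
#' when `P_T` does not.  Every quantity the construction needs from `P_T` —
#' phrase occurrence counts, expansion lengths, ending positions — is
#' recovered from the second level.
#'
#' @name rpfp
NULL

#' Build the recursive PFP bundle
#'
#' Runs level-1 PFP on the text, level-2 PFP on the resulting parse, and
#' releases the first-level parse.  With `retain_parse = TRUE` (test mode
#' only) the bundle additionally carries `p_t` for oracle checks; the
#' construction itself never reads it.
#'
#' @param text an `rpfp_text` (see [assemble_text()]).
#' @param cfg1 level-1 [trigger_config()] (window `w1`, modulus `p1`).
#' @param cfg2 level-2 [trigger_config()] over the token alphabet.
#' @param retain_parse keep `P_T` in the bundle for testing.
#' @return A list of class `rpfp_bundle` with `d_t`, `d_p`, `p_p`, the
#'   parameters `w1, p1, w2, p2`, the text length `n` and its alphabet.
#' @export
build_rpfp <- function(text, cfg1, cfg2, retain_parse = FALSE) {
  stopifnot(inherits(text, "rpfp_text"))
  l1 <- build_pfp(text, cfg1)
  l2 <- build_pfp(l1$parse, cfg2)
  bundle <- list(d_t = l1$dict, d_p = l2$dict, p_p = l2$parse,
                 w1 = cfg1$w, p1 = cfg1$p, w2 = cfg2$w, p2 = cfg2$p,
                 n = text$n, alphabet = text$alphabet)
  if (retain_parse) bundle$p_t <- l1$parse
  structure(bundle, class = "rpfp_bundle")
}

#' @export
print.rpfp_bundle <- function(x, ...) {
  cat(sprintf(paste0("rpfp_bundle: n = %d, w1 = %d, p1 = %d, w2 = %d, p2 = %d\n",
                     "  |D_T| = %d phrases (%d tokens), |D_P| = %d meta-phrases (%d tokens), |P_P| = %d\n"),
              x$n, x$w1, x$p1, x$w2, x$p2,
              length(x$d_t$keys), sum(x$d_t$lens),
              length(x$d_p$keys), sum(x$d_p$lens), length(x$p_p)))
  if (!is.null(x$p_t)) cat(sprintf("  [test mode] |P_T| = %d retained\n", length(x$p_t)))
  invisible(x)
}

#' Occurrence count of every level-1 phrase, without the level-1 parse
#'
#' Counts each meta-character's occurrences in `P_T` by summing, over
#' meta-phrase occurrences in `P_P`, the token multiplicities at attributed
#' (non-overlap) offsets `2 .. |d'| - w2 + 1`.  Equals the direct count in
#' `P_T`.
#'
#' @param bundle an `rpfp_bundle`.
#' @return Integer vector of counts indexed by `D_T` rank.
#' @export
phrase_occurrence_counts <- function(bundle) {
  mT <- length(bundle$d_t$keys)
  mP <- length(bundle$d_p$keys)
  w2 <- bundle$w2
  pp_counts <- tabulate(bundle$p_p, nbins = mP)
  toks <- lapply(seq_len(mP), function(j) {
    ph <- bundle$d_p$phrases[[j]]
    v <- ph[2:(length(ph) - w2 + 1L)]
    v[v > 0L]
  })
  wt <- rep.int(pp_counts, lengths(toks))
  v <- unlist(toks)
  counts <- integer(mT)
  if (length(v)) {
    rs <- rowsum(wt, group = v)
    counts[as.integer(rownames(rs))] <- as.integer(rs[, 1L])
  }
  counts
}

#' Expansion length in the text of a meta-phrase
#'
#' A meta-phrase is a token sequence over `D_T` ranks; consecutive level-1
#' phrases overlap by `w1`, so its expansion length is
#' `sum(|d_t[token]|) - (k - 1) * w1`.  The sentinel token 0 counts `w1`
#' symbols (the padding).
#'
#' @param x an `rpfp_bundle`, an `rpfp_dict`, or a character vector of
#'   phrase strings.
#' @param tokens integer token sequence (`D_T` ranks; 0 allowed).
#' @param w1 phrase overlap window; taken from `x` when it carries one.
#' @return Expansion length in characters.
#' @export
meta_expansion_length <- function(x, tokens, w1 = NULL) {
  if (inherits(x, "rpfp_bundle")) {
    lens <- x$d_t$lens; w1 <- x$w1
  } else if (inherits(x, "rpfp_dict")) {
    lens <- x$lens; if (is.null(w1)) w1 <- x$w
  } else {
    lens <- nchar(as.character(x))
    if (is.null(w1)) rpfp_abort("rpfp_error_config", "w1 required with raw phrase strings")
  }
  tokens <- as.integer(tokens)
  if (length(tokens) < 1L) rpfp_abort("rpfp_error_config", "empty meta-phrase")
  if (any(tokens < 0L | tokens > length(lens)))
    rpfp_abort("rpfp_error_config", "unknown dictionary rank in meta-phrase")
  plen <- ifelse(tokens == 0L, w1, lens[pmax(tokens, 1L)])
  as.integer(sum(plen) - (length(tokens) - 1L) * w1)
}

# Per-meta-phrase expansion geometry: `full` is the expansion length of one
# occurrence; `adv` the symbols a subsequent occurrence adds beyond the
# w2-token overlap (tokens after the first w2 each add |phrase| - w1).
meta_phrase_geometry <- function(bundle) {
  lensT <- bundle$d_t$lens
  w1 <- bundle$w1; w2 <- bundle$w2
  plen <- function(t) ifelse(t == 0L, w1, lensT[pmax(t, 1L)])
  mP <- length(bundle$d_p$keys)
  adv <- integer(mP); full <- integer(mP)
  for (j in seq_len(mP)) {
    ph <- bundle$d_p$phrases[[j]]
    contrib <- plen(ph) - w1
    full[j] <- plen(ph[1L]) + sum(contrib[-1L])
    adv[j] <- sum(contrib[(w2 + 1L):length(ph)])
  }
  list(adv = adv, full = full)
}

#' Ending positions of meta-phrase occurrences
#'
#' One value per token position `k` of `P_P`: the ending position in the
#' padded text `T' = $^w1 T $^w1` of the expansion of the meta-phrase
#' occurrence at `k`.  A single left-to-right scan: the first occurrence
#' contributes its full expansion, each later one its advance beyond the
#' `w2`-token overlap.  The final value is `|T'| = n + 2 w1`.
#'
#' @param bundle an `rpfp_bundle`.
#' @return Integer vector of length `|P_P|`, class `rpfp_ep`.
#' @export
compute_ep <- function(bundle) {
  geo <- meta_phrase_geometry(bundle)
  pp <- bundle$p_p
  ep <- geo$full[pp[1L]] + cumsum(c(0L, geo$adv[pp[-1L]]))
  if (ep[length(ep)] != bundle$n + 2L * bundle$w1)
    rpfp_abort("rpfp_error_internal", "EP terminal value != n + 2*w1")
  structure(as.integer(ep), class = "rpfp_ep")
}
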