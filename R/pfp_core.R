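#' Prefix-free parsing core
#'
#' Prefix-free parsing (PFP) cuts a symbol sequence into overlapping phrases
#' delimited by *trigger strings*: windows of length `w` whose Karp-Rabin
#' hash is 0 modulo `p` (plus the sentinel window `$^w`).  The input is
#' padded to `$^w T $^w`; each phrase runs from one trigger start to the end
#' of the next trigger, so consecutive phrases overlap in exactly `w`
#' symbols.  The same machinery parses character texts (level 1) and integer
#' token sequences such as a parse (level 2): internally every sequence is a
#' vector of non-negative integer codes with 0 reserved for the sentinel.
#'
#' @name pfp_core
NULL

# Inner modulus for the Karp-Rabin hash: the Mersenne prime 2^31-1.  With
# the default base 2^16 and tokens below 2^21, every intermediate product
# stays below 2^53 and is exact in double arithmetic, so hashes are
# identical across platforms.
KR_MOD <- 2147483647
KR_MAX_TOKEN <- 2097151L  # 2^21 - 1

#' Trigger configuration
#'
#' @param w window length (>= 2).
#' @param p hash modulus for the trigger test (>= 2).
#' @param hash_base polynomial base of the Karp-Rabin hash.
#' @param override optional explicit trigger windows (testing hook): a
#'   character vector of windows over the text alphabet, or a list of
#'   integer token windows.  When set, a window triggers iff it is in the
#'   set or equals the sentinel window; the hash is not consulted.  An empty
#'   set forces sentinel-only triggers.
#' @return A list of class `rpfp_trigger_config`.
#' @export
trigger_config <- function(w, p, hash_base = 65536, override = NULL) {
  w <- as.integer(w); p <- as.integer(p)
  if (is.na(w) || w < 2L) rpfp_abort("rpfp_error_config", "window length w must be >= 2")
  if (is.na(p) || p < 2L) rpfp_abort("rpfp_error_config", "hash modulus p must be >= 2")
  if (!is.null(override)) {
    if (is.character(override)) override <- as.list(override)
    stopifnot(is.list(override))
  }
  structure(list(w = w, p = p, hash_base = as.numeric(hash_base), override = override),
            class = "rpfp_trigger_config")
}

# Resolve override windows to encoded keys; character windows need the text
# alphabet to map symbols to codes.
override_keys <- function(override, alphabet) {
  vapply(override, function(win) {
    if (is.character(win)) {
      if (is.null(alphabet))
        rpfp_abort("rpfp_error_config", "character override windows need an alphabet")
      v <- match(strsplit(win, "")[[1L]], alphabet)
      if (anyNA(v)) rpfp_abort("rpfp_error_config",
                               sprintf("override window '%s' uses symbols outside the alphabet", win))
      encode_key(as.integer(v))
    } else {
      encode_key(as.integer(win))
    }
  }, character(1L))
}

#' Karp-Rabin hash of one window
#'
#' Polynomial hash `sum(window[i] * base^(w-i)) mod (2^31-1)`, a function of
#' the window content only; [rolling_hash_update()] slides it in O(1).
#'
#' @param window integer vector (or `rpfp_text`) of length `cfg$w`.
#' @param cfg a [trigger_config()].
#' @return The hash as a double in `[0, 2^31-1)`.
#' @export
rolling_hash <- function(window, cfg) {
  if (inherits(window, "rpfp_text")) window <- window$sym
  window <- as.numeric(window)
  if (length(window) != cfg$w)
    rpfp_abort("rpfp_error_config",
               sprintf("window length %d != w = %d", length(window), cfg$w))
  h <- 0
  for (v in window) h <- (h * cfg$hash_base + v) %% KR_MOD
  h
}

#' Slide a Karp-Rabin hash one position
#'
#' @param h current hash of `c(out_sym, ...)`.
#' @param out_sym symbol leaving the window.
#' @param in_sym symbol entering the window.
#' @param cfg a [trigger_config()].
#' @return Updated hash, equal to [rolling_hash()] of the slid window.
#' @export
rolling_hash_update <- function(h, out_sym, in_sym, cfg) {
  pw <- kr_pow(cfg$hash_base, cfg$w - 1L)
  h2 <- (h - (as.numeric(out_sym) * pw) %% KR_MOD) %% KR_MOD
  (h2 * cfg$hash_base + as.numeric(in_sym)) %% KR_MOD
}

kr_pow <- function(base, e) {
  r <- 1
  for (i in seq_len(e)) r <- (r * base) %% KR_MOD
  r
}

# Hashes of all length-w windows of a padded sequence, vectorised over
# window starts (w passes over the data).
window_hashes <- function(tp, cfg) {
  w <- cfg$w
  nwin <- length(tp) - w + 1L
  v <- as.numeric(tp)
  h <- numeric(nwin)
  for (i in seq_len(w)) h <- (h * cfg$hash_base + v[i:(i + nwin - 1L)]) %% KR_MOD
  h
}

# Trigger starts on an already padded sequence tp = 0^w x 0^w.
find_triggers_padded <- function(tp, cfg, alphabet = NULL) {
  w <- cfg$w
  nwin <- length(tp) - w + 1L
  if (!is.null(cfg$override)) {
    ov <- override_keys(cfg$override, alphabet)
    full_key <- encode_key(tp)
    wins <- substring(full_key, seq_len(nwin), seq_len(nwin) + w - 1L)
    is_trig <- wins %in% ov
  } else {
    is_trig <- (window_hashes(tp, cfg) %% cfg$p) == 0
  }
  # the sentinel windows $^w at both ends always trigger
  is_trig[1L] <- TRUE
  is_trig[nwin] <- TRUE
  which(is_trig)
}

#' Find trigger-window start positions
#'
#' Operates on the padded sequence `$^w x $^w`; returns every window start
#' `s` whose window hashes to 0 mod `p` or equals `$^w` (positions 1 and
#' `n+w+1` always trigger).  With `cfg$override` set, membership in the
#' override set replaces the hash test.
#'
#' @param x an `rpfp_text` or a vector of positive integer tokens.
#' @param cfg a [trigger_config()].
#' @return Integer positions in the padded sequence.
#' @export
find_triggers <- function(x, cfg) {
  alphabet <- NULL
  if (inherits(x, "rpfp_text")) { alphabet <- x$alphabet; x <- x$sym }
  x <- check_tokens(x)
  find_triggers_padded(c(rep(0L, cfg$w), x, rep(0L, cfg$w)), cfg, alphabet)
}

check_tokens <- function(x) {
  x <- as.integer(x)
  if (length(x) < 1L) rpfp_abort("rpfp_error_config", "input sequence is empty")
  if (any(x <= 0L)) rpfp_abort("rpfp_error_config", "token 0 is reserved for the sentinel")
  if (max(x) > KR_MAX_TOKEN) rpfp_abort("rpfp_error_config", "token values above 2^21 unsupported")
  x
}

#' Prefix-free parse of a sequence
#'
#' Phrases are `T'[s_i .. s_{i+1}+w-1]` for consecutive trigger starts; the
#' dictionary is the lexicographically sorted set of distinct phrases and
#' the parse lists each phrase occurrence's rank in text order.
#' `pfp_expand(dict, parse)` reproduces the padded sequence `$^w x $^w`.
#'
#' @param x an `rpfp_text` or a vector of positive integer tokens.
#' @param cfg a [trigger_config()].
#' @return A list with `dict` (class `rpfp_dict`: sorted phrase list) and
#'   `parse` (integer ranks).
#' @export
build_pfp <- function(x, cfg) {
  alphabet <- NULL
  if (inherits(x, "rpfp_text")) { alphabet <- x$alphabet; x <- x$sym }
  x <- check_tokens(x)
  w <- cfg$w
  tp <- c(rep(0L, w), x, rep(0L, w))
  trigs <- find_triggers_padded(tp, cfg, alphabet)
  starts <- trigs[-length(trigs)]
  ends <- trigs[-1L] + w - 1L
  full_key <- encode_key(tp)
  pkeys <- substring(full_key, starts, ends)
  uk <- unique(pkeys)
  uk <- uk[key_order(uk)]
  dict <- structure(
    list(keys = uk, phrases = lapply(uk, decode_key),
         lens = nchar(uk), w = w, alphabet = alphabet),
    class = "rpfp_dict")
  list(dict = dict, parse = match(pkeys, uk))
}

#' @export
print.rpfp_dict <- function(x, ...) {
  cat(sprintf("rpfp_dict: %d phrases, w = %d, total length %d tokens\n",
              length(x$keys), x$w, sum(x$lens)))
  invisible(x)
}

#' Expand a dictionary and parse back to the padded sequence
#'
#' Concatenates the parsed phrases, dropping the first `w` symbols of every
#' phrase after the first (consecutive phrases share a `w`-overlap, which is
#' verified).
#'
#' @param dict an `rpfp_dict`.
#' @param parse integer ranks into `dict`.
#' @return Integer vector `$^w x $^w` (sentinel as 0).
#' @export
pfp_expand <- function(dict, parse) {
  if (any(parse < 1L | parse > length(dict$keys)))
    rpfp_abort("rpfp_error_parse", "parse rank out of dictionary range")
  w <- dict$w
  phr <- dict$phrases[parse]
  pieces <- vector("list", length(parse))
  pieces[[1L]] <- phr[[1L]]
  if (length(parse) > 1L) {
    for (k in 2:length(parse)) {
      prev <- phr[[k - 1L]]; cur <- phr[[k]]
      if (!identical(prev[(length(prev) - w + 1L):length(prev)], cur[seq_len(w)]))
        rpfp_abort("rpfp_error_parse",
                   sprintf("phrase overlap mismatch between parse positions %d and %d", k - 1L, k))
      pieces[[k]] <- cur[(w + 1L):length(cur)]
    }
  }
  unlist(pieces)
}

#' Distinct proper phrase suffixes of a dictionary
#'
#' All suffixes of every phrase with offset >= 2 and length >= `w`, merged
#' by string value, sorted lexicographically.  Suffixes of the sentinel-
#' leading phrase that start inside the leading `$^w` padding (offsets
#' `2..w`) are excluded: they do not correspond to positions of `T$`.  The
#' trailing `$^w` suffix is retained and becomes the terminator row.  The
#' resulting set is prefix-free, and every position of `T$` is represented
#' by exactly one (phrase occurrence, suffix) pair.
#'
#' @param dict an `rpfp_dict`.
#' @return A list of class `rpfp_suffixes`: `keys` (sorted distinct suffix
#'   strings, encoded), `len` (suffix length per key), `occ` (data.frame
#'   with one row per (phrase, offset) occurrence: `group`, `phrase`,
#'   `offset`, `prec` — the symbol at offset-1 — and `len`), and `w`.
#' @export
proper_suffixes <- function(dict) {
  w <- dict$w
  keys <- dict$keys
  lens <- dict$lens
  m <- length(keys)
  counts <- lens - w                       # offsets 2 .. len-w+1
  phrase_id <- rep.int(seq_len(m), counts)
  offset <- unlist(lapply(counts, function(k) seq.int(2L, length.out = k)))
  prec <- unlist(lapply(seq_len(m), function(i) dict$phrases[[i]][seq_len(counts[i])]))
  suffix_key <- substring(keys[phrase_id], offset)
  # leading-padding exclusion: a suffix starting with the sentinel begins
  # inside the leading $^w padding — except the exact terminator $^w, which
  # starts at the last position of T$ and is retained.  (Triggers may fire
  # inside the padding, so several phrases can start with sentinels.)
  sent_ch <- substr(encode_key(0L), 1L, 1L)
  term_key <- encode_key(rep.int(0L, w))
  drop <- substr(suffix_key, 1L, 1L) == sent_ch & suffix_key != term_key
  if (any(drop)) {
    phrase_id <- phrase_id[!drop]; offset <- offset[!drop]
    prec <- prec[!drop]; suffix_key <- suffix_key[!drop]
  }
  grp_keys <- unique(suffix_key)
  grp_keys <- grp_keys[key_order(grp_keys)]
  group <- match(suffix_key, grp_keys)
  occ <- data.frame(group = group, phrase = phrase_id, offset = offset,
                    prec = prec, len = lens[phrase_id] - offset + 1L)
  occ <- occ[order(occ$group, occ$phrase), , drop = FALSE]
  rownames(occ) <- NULL
  structure(list(keys = grp_keys, len = nchar(grp_keys), occ = occ, w = w),
            class = "rpfp_suffixes")
}

#' @export
print.rpfp_suffixes <- function(x, ...) {
  cat(sprintf("rpfp_suffixes: %d distinct suffixes, %d occurrences, w = %d\n",
              length(x$keys), nrow(x$occ), x$w))
  invisible(x)
}

# Render suffix keys of a character-level dictionary as readable strings.
suffix_strings <- function(sufs, alphabet) {
  vapply(sufs$keys, function(k) text_to_string(decode_key(k), alphabet), character(1L),
         USE.NAMES = FALSE)
}
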