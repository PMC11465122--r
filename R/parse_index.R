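#' Second-level support structures
#'
#' Everything the construction needs about the parse of the parse: the
#' suffix array, BWT and LCP array of `P_P` (terminated by the unique
#' smallest token 0); the grid `G` (for each meta-phrase, the positions in
#' `BWT(P_P)` where it appears — the lexicographic order of what follows
#' its occurrences); the tables `T_T` (BWT ranges of the text per proper
#' phrase suffix, with co-lexicographic sub-ranges per preceding character)
#' and `T_P` (co-lexicographic meta-phrase ranges and preceding
#' meta-characters per proper meta-phrase suffix); and an O(1) range-minimum
#' structure over `LCP(P_P)`.
#'
#' @name parse_index
NULL

#' Co-lexicographic order of a dictionary
#'
#' Lexicographic order of the reversed phrases; phrases sharing a suffix
#' occupy a contiguous co-lex range.
#'
#' @param dict an `rpfp_dict`.
#' @return A list with `perm` (phrase ranks in co-lex order) and `pos`
#'   (`pos[rank]` = co-lex position of that phrase).
#' @export
colex_order <- function(dict) {
  rev_keys <- vapply(dict$keys, function(s) intToUtf8(rev(utf8ToInt(s))),
                     character(1L), USE.NAMES = FALSE)
  perm <- key_order(rev_keys)
  pos <- integer(length(perm))
  pos[perm] <- seq_along(perm)
  list(perm = perm, pos = pos, rev_keys = rev_keys)
}

#' Phrases ending with a given suffix, as a co-lex range
#'
#' @param dict an `rpfp_dict`.
#' @param co result of [colex_order()] on `dict`.
#' @param suffix integer token vector.
#' @return Integer vector of co-lex positions (contiguous when non-empty).
#' @export
colex_range <- function(dict, co, suffix) {
  pre <- intToUtf8(rev(utf8ToInt(encode_key(as.integer(suffix)))))
  which(startsWith(co$rev_keys[co$perm], pre))
}

#' Suffix array, BWT and LCP of the second-level parse
#'
#' Plain comparison-based suffix sort over the integer tokens of
#' `P_P` terminated by the unique smallest token 0 (`P_P` is small by
#' design).  `bwt[i]` is the token preceding the i-th smallest suffix (0
#' for the row of the full sequence); the LCP array is computed Kasai-style.
#'
#' @param p_p integer parse (ranks into `D_P`).
#' @return A list of class `rpfp_parse_sa`: `seq` (terminated sequence),
#'   `sa`, `lcp`, `bwt`.
#' @export
build_parse_sa <- function(p_p) {
  seqv <- c(as.integer(p_p), 0L)
  np <- length(seqv)
  key <- encode_key(seqv)
  sufs <- substring(key, seq_len(np))
  sa <- key_order(sufs)
  bwt <- ifelse(sa > 1L, seqv[pmax(sa - 1L, 1L)], 0L)
  structure(list(seq = seqv, sa = sa, lcp = kasai_lcp(seqv, sa), bwt = as.integer(bwt)),
            class = "rpfp_parse_sa")
}

# Kasai's O(n) LCP construction from a suffix array.
kasai_lcp <- function(seqv, sa) {
  np <- length(sa)
  rk <- integer(np); rk[sa] <- seq_len(np)
  lcp <- integer(np)
  h <- 0L
  for (i in seq_len(np)) {
    r <- rk[i]
    if (r > 1L) {
      j <- sa[r - 1L]
      while (i + h <= np && j + h <= np && seqv[i + h] == seqv[j + h]) h <- h + 1L
      lcp[r] <- h
      if (h > 0L) h <- h - 1L
    } else {
      h <- 0L
    }
  }
  lcp
}

#' The grid G: occurrences of each meta-phrase in BWT(P_P)
#'
#' Inverted index of `BWT(P_P)` by token, lists sorted ascending.  Each
#' BWT position (except the terminator row) appears in exactly one list.
#'
#' @param psa an `rpfp_parse_sa`.
#' @param m_p number of meta-phrases (`|D_P|`).
#' @return A list of ascending integer vectors indexed by `D_P` rank.
#' @export
build_grid <- function(psa, m_p) {
  rows <- which(psa$sa >= 2L)
  tok <- psa$seq[psa$sa[rows] - 1L]
  unname(split(rows, factor(tok, levels = seq_len(m_p))))
}

#' Sparse-table range-minimum structure
#'
#' O(m log m) preprocessing, O(1) queries; used over `LCP(P_P)` to obtain
#' the token-LCP of any two sorted parse suffixes.
#'
#' @param v numeric vector.
#' @return An object of class `rpfp_rmq`.
#' @export
build_rmq <- function(v) {
  m <- length(v)
  K <- if (m > 1L) floor(log2(m)) else 0L
  tab <- matrix(NA_integer_, nrow = m, ncol = K + 1L)
  tab[, 1L] <- as.integer(v)
  if (K >= 1L) for (k in seq_len(K)) {
    span <- 2L^k; half <- 2L^(k - 1L)
    idx <- seq_len(m - span + 1L)
    tab[idx, k + 1L] <- pmin(tab[idx, k], tab[idx + half, k])
  }
  structure(list(tab = tab, m = m), class = "rpfp_rmq")
}

#' Range-minimum query
#'
#' @param rq an `rpfp_rmq`.
#' @param i,j row bounds, `1 <= i <= j <= m` (vectorised).
#' @return `min(v[i..j])` for each pair.
#' @export
rmq <- function(rq, i, j) {
  if (any(i > j) || any(i < 1L) || any(j > rq$m))
    rpfp_abort("rpfp_error_config", "RMQ bounds out of range")
  k <- floor(log2(j - i + 1))
  pmin(rq$tab[cbind(i, k + 1)], rq$tab[cbind(j - 2^k + 1, k + 1)])
}

#' Table T_T: BWT ranges of the text per proper phrase suffix
#'
#' For each distinct proper phrase suffix `alpha` in lexicographic order:
#' its half-open row interval `[b, e)` in the BWT of `T$` (b = prefix sum of
#' the frequencies of lexicographically smaller suffixes, per-row length =
#' frequency), whether all its occurrences share one preceding character
#' (an *easy* suffix), and the co-lex positions of the phrases carrying it,
#' grouped by preceding character.
#'
#' @param s_t `rpfp_suffixes` of `D_T`.
#' @param counts phrase occurrence counts from [phrase_occurrence_counts()].
#' @param co_t [colex_order()] of `D_T`.
#' @param n text length.
#' @return A list of class `rpfp_table_tt`.
#' @export
build_table_tt <- function(s_t, counts, co_t, n) {
  occ <- s_t$occ
  occ_freq <- counts[occ$phrase]
  freq <- integer(length(s_t$keys))
  rs <- rowsum(occ_freq, group = occ$group)
  freq[as.integer(rownames(rs))] <- as.integer(rs[, 1L])
  if (sum(freq) != n + 1L)
    rpfp_abort("rpfp_error_internal",
               sprintf("suffix frequencies sum to %d, expected n+1 = %d", sum(freq), n + 1L))
  e0 <- cumsum(freq)
  b0 <- c(0L, e0[-length(e0)])
  # easy iff one distinct preceding character among occurrences with freq > 0
  live <- occ_freq > 0L
  n_prec <- tapply(occ$prec[live], occ$group[live], function(v) length(unique(v)))
  easy <- rep(TRUE, length(freq))
  easy[as.integer(names(n_prec))] <- n_prec == 1L
  structure(list(keys = s_t$keys, len = s_t$len, freq = freq,
                 b0 = as.integer(b0), e0 = as.integer(e0), easy = easy,
                 occ = cbind(occ, colex = co_t$pos[occ$phrase], freq = occ_freq)),
            class = "rpfp_table_tt")
}

#' Table T_P: co-lex meta-phrase ranges per proper meta-phrase suffix
#'
#' For each distinct proper meta-phrase suffix `beta` in lexicographic
#' order: the meta-phrases ending in `beta` (their co-lex positions form a
#' contiguous range) and the meta-character preceding `beta` in each (the
#' token at position `|d'| - |beta|`).  Also carries an index from
#' preceding meta-character to occurrence rows, which drives the
#' per-`alpha` enumeration of the index builder.
#'
#' @param s_p `rpfp_suffixes` of `D_P`.
#' @param co_p [colex_order()] of `D_P`.
#' @param m_t number of level-1 phrases (`|D_T|`).
#' @return A list of class `rpfp_table_tp`.
#' @export
build_table_tp <- function(s_p, co_p, m_t) {
  occ <- s_p$occ   # group = beta (lex order), phrase = d', prec = preceding meta-character
  structure(list(keys = s_p$keys, len = s_p$len,
                 occ = cbind(occ, colex = co_p$pos[occ$phrase]),
                 prec_index = unname(split(seq_len(nrow(occ)),
                                           factor(occ$prec, levels = seq_len(m_t))))),
            class = "rpfp_table_tp")
}
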