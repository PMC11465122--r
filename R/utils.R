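# Internal helpers shared across modules: typed errors, the integer <-> key
# string encoding used for lexicographic sorting, and seed-scoped RNG.

rpfp_abort <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "rpfp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# Encode a non-negative integer vector as a single UTF-8 string whose byte
# order equals the elementwise numeric order (UTF-8 is order-preserving on
# codepoints).  Codepoint 0 is not representable and 0xD800..0xDFFF are
# surrogates, so token t maps to t+1, shifted past the surrogate block when
# needed.  Radix sorting these keys gives exact lexicographic order over the
# token alphabet, with the sentinel token 0 smallest.
encode_key <- function(x) {
  cp <- as.integer(x) + 1L
  hi <- cp >= 0xD800L
  if (any(hi)) cp[hi] <- cp[hi] + 0x800L
  intToUtf8(cp)
}

decode_key <- function(s) {
  cp <- utf8ToInt(s)
  hi <- cp >= 0xE000L
  if (any(hi)) cp[hi] <- cp[hi] - 0x800L
  cp - 1L
}

# Radix order: C-locale byte order, platform independent.
key_order <- function(keys, ...) order(keys, ..., method = "radix")

# Length of the common prefix of two integer vectors; vectorised scan.
vec_lcp <- function(a, b) {
  m <- min(length(a), length(b))
  if (m == 0L) return(0L)
  d <- which(a[seq_len(m)] != b[seq_len(m)])
  if (length(d) == 0L) m else d[1L] - 1L
}

# Evaluate `expr` under a fixed, named RNG state, restoring the caller's
# stream afterwards.  Mersenne-Twister + Inversion + Rejection is stable
# across platforms and R >= 3.6.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  old_kind <- RNGkind("Mersenne-Twister", "Inversion", "Rejection")
  on.exit({
    do.call(RNGkind, as.list(old_kind))
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}
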