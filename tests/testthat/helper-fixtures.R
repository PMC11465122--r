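# Shared fixtures and small independent oracles, built in code.

# FIX1: "GATTACAT" with the forced level-1 trigger "TA" (w1 = 2) and
# sentinel-only level-2 triggers (w2 = 2).  Oracle values for T$ =
# "GATTACAT$": SA = 9 5 7 2 6 1 8 4 3, BWT = "TTCGA$ATA",
# LCP = 0 0 1 2 0 0 0 1 1 (verified independently in test-oracle.R).
fix1_text <- function() rpfp:::text_from_string("GATTACAT")
fix1_cfg1 <- function() trigger_config(2L, 3L, override = list("TA"))
fix1_cfg2 <- function() trigger_config(2L, 3L, override = list())
fix1_bundle <- function(retain = FALSE) {
  build_rpfp(fix1_text(), fix1_cfg1(), fix1_cfg2(), retain_parse = retain)
}
FIX1_SA <- c(9L, 5L, 7L, 2L, 6L, 1L, 8L, 4L, 3L)
FIX1_BWT <- "TTCGA$ATA"
FIX1_LCP <- c(0L, 0L, 1L, 2L, 0L, 0L, 0L, 1L, 1L)

# Random text over a given alphabet (deterministic in the ambient RNG).
rand_string <- function(n, alpha = c("A", "C", "G", "T")) {
  paste(sample(alpha, n, replace = TRUE), collapse = "")
}

# A random (text, cfg1, cfg2) construction case drawn from the study grid.
rand_case <- function(n_range = c(50L, 400L)) {
  n <- sample(n_range[1L]:n_range[2L], 1L)
  alpha <- if (stats::runif(1) < 0.5) c("A", "C", "G", "T") else c("A", "B")
  list(txt = rpfp:::text_from_string(rand_string(n, alpha)),
       cfg1 = trigger_config(sample(2:4, 1L), sample(c(3L, 5L, 11L), 1L)),
       cfg2 = trigger_config(sample(2:3, 1L), sample(c(3L, 5L), 1L)))
}

# Strings rendered from integer code vectors (sentinel as '$').
codes_to_string <- function(v, alphabet) rpfp:::text_to_string(v, alphabet)

# Independent suffix comparison: fixed-width decimal rendering of token
# vectors, so string order equals token order without the package's UTF-8
# key encoding.
decimal_suffix_sort <- function(v) {
  enc <- formatC(v, width = 8, flag = "0")
  sufs <- vapply(seq_along(v), function(i) paste(enc[i:length(v)], collapse = ","),
                 character(1L))
  order(sufs, method = "radix")
}

# Prefix-freeness of a sorted key vector: with lexicographically sorted
# strings, any prefix relation appears between adjacent entries.
sorted_prefix_free <- function(keys) {
  if (length(keys) < 2L) return(TRUE)
  !any(startsWith(keys[-1L], keys[-length(keys)]))
}
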