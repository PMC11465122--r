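test_that("trigger configuration enforces its bounds", {
  expect_error(trigger_config(1, 3), class = "rpfp_error_config")
  expect_error(trigger_config(2, 1), class = "rpfp_error_config")
  expect_error(rolling_hash(c(1L, 2L, 3L), trigger_config(2, 3)),
               class = "rpfp_error_config")
})

test_that("sliding hash updates equal from-scratch recomputation", {
  set.seed(31)
  for (rep in 1:50) {
    w <- sample(2:6, 1)
    cfg <- trigger_config(w, sample(c(3L, 5L, 11L), 1))
    v <- sample(0:20, sample((w + 1):60, 1), replace = TRUE)
    h <- rolling_hash(v[1:w], cfg)
    for (s in 2:(length(v) - w + 1)) {
      h <- rolling_hash_update(h, v[s - 1], v[s + w - 1], cfg)
      expect_equal(h, rolling_hash(v[s:(s + w - 1)], cfg))
    }
  }
  # function of content only
  cfg <- trigger_config(3, 5)
  expect_identical(rolling_hash(c(2L, 4L, 1L), cfg), rolling_hash(c(2L, 4L, 1L), cfg))
})

test_that("trigger positions match an exhaustive per-window scan", {
  # forced-trigger fixture: "TA" occurs at padded position 6 (and the two
  # sentinel windows), giving the FIX1 phrases
  trig <- find_triggers(fix1_text(), fix1_cfg1())
  expect_equal(trig, c(1L, 6L, 11L))
  set.seed(37)
  for (rep in 1:60) {
    w <- sample(2:4, 1); p <- sample(c(3L, 5L, 11L), 1)
    cfg <- trigger_config(w, p)
    txt <- rpfp:::text_from_string(rand_string(sample(20:120, 1)))
    got <- find_triggers(txt, cfg)
    tp <- c(rep(0L, w), txt$sym, rep(0L, w))
    want <- which(vapply(seq_len(length(tp) - w + 1), function(s) {
      win <- tp[s:(s + w - 1)]
      all(win == 0L) || rolling_hash(win, cfg) %% p == 0
    }, logical(1)))
    expect_equal(got, want)
  }
})

test_that("parsing produces the fixture dictionary and inverts by expansion", {
  l1 <- build_pfp(fix1_text(), fix1_cfg1())
  alpha <- fix1_text()$alphabet
  expect_equal(vapply(l1$dict$phrases, codes_to_string, character(1), alphabet = alpha),
               c("$$GATTA", "TACAT$$"))
  expect_equal(l1$parse, c(1L, 2L))
  expect_equal(codes_to_string(pfp_expand(l1$dict, l1$parse), alpha), "$$GATTACAT$$")
  # no internal trigger: a single whole-text phrase
  l0 <- build_pfp(fix1_text(), trigger_config(2, 3, override = list()))
  expect_length(l0$dict$keys, 1L)
  expect_equal(l0$parse, 1L)
  expect_equal(pfp_expand(l0$dict, l0$parse), c(0L, 0L, fix1_text()$sym, 0L, 0L))
})

test_that("expansion round-trips random parses at both levels", {
  set.seed(41)
  for (rep in 1:60) {
    cs <- rand_case()
    l1 <- build_pfp(cs$txt, cs$cfg1)
    w1 <- cs$cfg1$w
    expect_identical(pfp_expand(l1$dict, l1$parse),
                     c(rep(0L, w1), cs$txt$sym, rep(0L, w1)))
    l2 <- build_pfp(l1$parse, cs$cfg2)
    w2 <- cs$cfg2$w
    expect_identical(pfp_expand(l2$dict, l2$parse),
                     c(rep(0L, w2), l1$parse, rep(0L, w2)))
  }
})

test_that("inconsistent phrase overlaps are detected on expansion", {
  l1 <- build_pfp(fix1_text(), fix1_cfg1())
  expect_error(pfp_expand(l1$dict, c(2L, 2L)), class = "rpfp_error_parse")
  expect_error(pfp_expand(l1$dict, c(1L, 5L)), class = "rpfp_error_parse")
})

test_that("proper suffixes: fixture set, prefix-freeness, position attribution", {
  l1 <- build_pfp(fix1_text(), fix1_cfg1())
  s <- proper_suffixes(l1$dict)
  expect_equal(rpfp:::suffix_strings(s, fix1_text()$alphabet),
               c("$$", "ACAT$$", "AT$$", "ATTA", "CAT$$", "GATTA", "T$$", "TA", "TTA"))
  expect_true(sorted_prefix_free(s$keys))
  # every position of T$ is attributed exactly once:
  # sum over suffix occurrences of the phrase frequency equals n + 1
  set.seed(43)
  for (rep in 1:40) {
    cs <- rand_case()
    l1 <- build_pfp(cs$txt, cs$cfg1)
    s <- proper_suffixes(l1$dict)
    freq <- tabulate(l1$parse, nbins = length(l1$dict$keys))
    expect_equal(sum(freq[s$occ$phrase]), cs$txt$n + 1L)
    expect_true(sorted_prefix_free(s$keys))
  }
})

test_that("parsing is alphabet-generic: isomorphic output on remapped tokens", {
  txt <- fix1_text()
  # render the characters as arbitrary (order-preserving) integer tokens
  remap <- txt$sym * 7L + 2L
  ov <- list(match(c("T", "A"), txt$alphabet) * 7L + 2L)
  l_chr <- build_pfp(txt, fix1_cfg1())
  l_tok <- build_pfp(remap, trigger_config(2, 3, override = ov))
  expect_identical(l_tok$parse, l_chr$parse)
  expect_identical(lengths(l_tok$dict$phrases), lengths(l_chr$dict$phrases))
  mapped <- lapply(l_chr$dict$phrases, function(p) ifelse(p == 0L, 0L, p * 7L + 2L))
  expect_identical(l_tok$dict$phrases, mapped)
})
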