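test_that("suffixes preceded by a single character are classified easy", {
  # two genomes sharing the ATTA context: every phrase carrying "ATTA"
  # is preceded by G, so its whole BWT range is G's
  txt <- assemble_text(seq_set(c("a", "b"), c("GATTACAT", "GGATTAGAT")))
  cfg1 <- trigger_config(2, 3, override = list("TA"))
  b <- build_rpfp(txt, cfg1, fix1_cfg2())
  st <- rpfp:::build_structures(b)
  cl <- classify(st)
  g <- match(rpfp:::encode_key(match(c("A", "T", "T", "A"), c("$", txt$alphabet)) - 1L),
             st$s_t$keys)
  expect_false(is.na(g))
  expect_true(all(cl$class[cl$alpha == g] == "easy"))
  occ <- st$tt$occ
  expect_equal(unique(occ$prec[occ$group == g]),
               match("G", c("$", txt$alphabet)) - 1L)
  # repeated phrases force hard-hard resolutions through the grid
  rep_txt <- assemble_text(generate_copies(60, 4, 17))
  idx <- rpfp_index(rep_txt, trigger_config(2, 3), trigger_config(2, 3))
  expect_gt(idx$hard_hard_consults, 0L)
})

test_that("ordered occurrences reproduce the oracle SA rows of each range", {
  b <- fix1_bundle()
  st <- rpfp:::build_structures(b)
  for (g in seq_along(st$s_t$keys)) {
    expect_equal(nrow(order_occurrences(st, g)), 1L)  # all frequencies 1
  }
  # alpha = "ATTA" starts at text position 2; the terminator row is n+1
  key_of <- function(s) rpfp:::encode_key(match(strsplit(s, "")[[1]],
                                                c("$", b$alphabet)) - 1L)
  expect_equal(order_occurrences(st, match(key_of("ATTA"), st$s_t$keys))$sa, 2L)
  expect_equal(order_occurrences(st, match(key_of("$$"), st$s_t$keys))$sa, 9L)
  set.seed(97)
  for (rep in 1:20) {
    cs <- rand_case(c(40L, 200L))
    b <- build_rpfp(cs$txt, cs$cfg1, cs$cfg2)
    st <- rpfp:::build_structures(b)
    orc <- naive_index(cs$txt)
    for (g in seq_along(st$s_t$keys)) {
      d <- order_occurrences(st, g)
      rows <- (st$tt$b0[g] + 1L):st$tt$e0[g]
      expect_identical(d$sa, orc$sa[rows])
    }
  }
})

test_that("run-length encoding is maximal and invertible", {
  r <- run_length_encode(FIX1_BWT)
  expect_equal(r$symbol, c("T", "C", "G", "A", "$", "A", "T", "A"))
  expect_equal(r$length, c(2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L))
  expect_equal(run_length_encode("AAAA")$length, 4L)
  set.seed(101)
  for (rep in 1:200) {
    s <- rand_string(sample(1:60, 1), c("A", "B", "C"))
    expect_equal(run_length_decode(run_length_encode(s)), s)
    expect_true(all(diff(as.integer(factor(run_length_encode(s)$symbol))) != 0) ||
                nrow(run_length_encode(s)) == 1)
  }
})

test_that("the fixture index matches the oracle row for row", {
  idx <- rpfp_index(fix1_bundle(), full_arrays = TRUE)
  expect_equal(idx$full$bwt, FIX1_BWT)
  expect_equal(idx$full$sa, FIX1_SA)
  expect_equal(idx$full$lcp, FIX1_LCP)
  expect_equal(idx$r, 8L)
  expect_equal(idx$ssa$start_row, c(1L, 3L, 4L, 5L, 6L, 7L, 8L, 9L))
  expect_equal(idx$ssa$sa_first, FIX1_SA[idx$ssa$start_row])
  expect_equal(idx$ssa$sa_last, FIX1_SA[c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L)])
  expect_equal(idx$slcp$lcp, FIX1_LCP[idx$ssa$start_row])
  # adjacent rows "AT$" and "ATTACAT$" share exactly two characters
  expect_equal(idx$full$lcp[4], 2L)
})

test_that("easy/hard BWT assembly equals the ordered-occurrence BWT", {
  set.seed(103)
  for (rep in 1:15) {
    cs <- rand_case(c(40L, 200L))
    b <- build_rpfp(cs$txt, cs$cfg1, cs$cfg2)
    bwt <- rpfp_bwt(b)
    expect_equal(as.character(bwt), naive_index(cs$txt)$bwt)
    cc <- attr(bwt, "class_counts")
    expect_gt(cc["easy"], 0L)
  }
})

test_that("construction equals the oracle across regimes", {
  set.seed(107)
  # random texts over both alphabets
  for (rep in 1:25) {
    cs <- rand_case(c(50L, 400L))
    idx <- rpfp_index(cs$txt, cs$cfg1, cs$cfg2, full_arrays = TRUE)
    expect_true(compare_index(idx, naive_index(cs$txt))$equal)
    expect_equal(sort(idx$full$sa), seq_len(cs$txt$n + 1L))  # SA permutation
  }
  # highly repetitive: identical copies and mutated haplotypes
  for (seed in 1:6) {
    set <- if (seed %% 2) generate_copies(70, 5, seed) else
      generate_pangenome(pangenome_spec(base_length = 100, n_haplotypes = 4,
                                        sub_rate = 0.02, indel_rate = 0.005,
                                        seed = seed))
    txt <- assemble_text(set)
    idx <- rpfp_index(txt, trigger_config(3, 5), trigger_config(2, 3),
                      full_arrays = TRUE)
    expect_true(compare_index(idx, naive_index(txt))$equal)
  }
  # degenerate inputs: single phrase, single symbol, tiny texts
  for (s in c("A", "AAAA", "AC")) {
    txt <- rpfp:::text_from_string(s)
    idx <- rpfp_index(txt, trigger_config(2, 3, override = list()),
                      trigger_config(2, 3, override = list()), full_arrays = TRUE)
    expect_true(compare_index(idx, naive_index(txt))$equal)
  }
})

test_that("character multiset of the RLBWT equals that of T$", {
  set.seed(109)
  for (rep in 1:10) {
    cs <- rand_case(c(30L, 150L))
    idx <- rpfp_index(cs$txt, cs$cfg1, cs$cfg2)
    got <- sort(strsplit(run_length_decode(idx$runs), "")[[1]])
    want <- sort(strsplit(paste0(codes_to_string(cs$txt$sym, cs$txt$alphabet), "$"),
                          "")[[1]])
    expect_equal(got, want)
    expect_equal(sum(idx$runs$length), cs$txt$n + 1L)
  }
})

test_that("index files round-trip and reject malformed headers", {
  idx <- rpfp_index(fix1_bundle())
  prefix <- file.path(withr::local_tempdir(), "fix1")
  serialize_index(idx, prefix)
  back <- load_index(prefix)
  expect_equal(back$runs$symbol, idx$runs$symbol)
  expect_equal(back$runs$length, idx$runs$length)
  expect_equal(back$ssa, idx$ssa)
  expect_equal(back$slcp[c("run", "start_row")], idx$slcp[c("run", "start_row")])
  expect_equal(back$slcp$lcp, as.integer(idx$slcp$lcp))
  expect_equal(nchar(run_length_decode(back$runs)), idx$n + 1L)
  writeLines(c("NOT A HEADER", "A\t3"), paste0(prefix, ".rlbwt"))
  expect_error(load_index(prefix), class = "rpfp_error_io")
})
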