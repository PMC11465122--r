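test_that("co-lexicographic order sorts by reversed phrases and groups suffixes", {
  b <- fix1_bundle()
  co <- colex_order(b$d_t)
  # reversed: "ATTAG$$" (phrase 1) vs "$$TACAT" (phrase 2) -> phrase 2 first
  expect_equal(co$perm, c(2L, 1L))
  expect_equal(colex_range(b$d_t, co, c(0L, 0L)), 1L)  # phrases ending "$$"
  set.seed(71)
  for (rep in 1:30) {
    cs <- rand_case(c(40L, 150L))
    d <- build_pfp(cs$txt, cs$cfg1)$dict
    co <- colex_order(d)
    s <- proper_suffixes(d)
    for (g in sample(seq_along(s$keys), min(10, length(s$keys)))) {
      ranks <- s$occ$phrase[s$occ$group == g]
      pos <- sort(co$pos[ranks])
      expect_equal(pos, seq.int(pos[1], length.out = length(pos)))  # contiguous
      rng <- colex_range(d, co, rpfp:::decode_key(s$keys[g]))
      expect_equal(sort(rng), pos)
    }
  }
  # singleton dictionary
  d1 <- build_pfp(fix1_text(), trigger_config(2, 3, override = list()))$dict
  expect_equal(colex_order(d1)$perm, 1L)
})

test_that("the parse suffix array matches an independent suffix sort", {
  psa <- build_parse_sa(1L)               # P_P = [1] plus terminator
  expect_equal(psa$sa, c(2L, 1L))
  expect_equal(psa$bwt, c(1L, 0L))
  set.seed(73)
  for (rep in 1:40) {
    pp <- sample(1:sample(2:12, 1), sample(3:60, 1), replace = TRUE)
    psa <- build_parse_sa(pp)
    v <- c(pp, 0L)
    expect_equal(psa$sa, decimal_suffix_sort(v))
    # LCP by direct prefix comparison of adjacent sorted suffixes
    for (i in 2:length(v)) {
      a <- v[psa$sa[i - 1]:length(v)]; b2 <- v[psa$sa[i]:length(v)]
      m <- min(length(a), length(b2))
      d <- which(a[1:m] != b2[1:m])
      expect_equal(psa$lcp[i], if (length(d)) d[1] - 1L else m)
    }
  }
})

test_that("the grid partitions BWT(P_P) by preceding meta-phrase", {
  set.seed(79)
  for (rep in 1:30) {
    pp <- sample(1:sample(2:10, 1), sample(3:50, 1), replace = TRUE)
    psa <- build_parse_sa(pp)
    grid <- build_grid(psa, max(pp))
    expect_equal(sort(unlist(grid)), which(psa$sa >= 2L))
    expect_equal(lengths(grid), tabulate(pp, nbins = max(pp)))
    expect_true(all(vapply(grid, function(g) !is.unsorted(g), logical(1))))
  }
})

test_that("table T_T holds consecutive BWT ranges with conserved frequencies", {
  b <- fix1_bundle()
  st <- rpfp:::build_structures(b)
  expect_length(st$tt$keys, 9L)
  expect_equal(st$tt$freq, rep(1L, 9))
  expect_equal(st$tt$b0, 0:8)
  expect_equal(st$tt$e0, 1:9)
  set.seed(83)
  for (rep in 1:25) {
    cs <- rand_case()
    st <- rpfp:::build_structures(build_rpfp(cs$txt, cs$cfg1, cs$cfg2))
    expect_equal(st$tt$e0[length(st$tt$e0)], cs$txt$n + 1L)
    expect_identical(st$tt$b0, c(0L, st$tt$e0[-length(st$tt$e0)]))
  }
})

test_that("table T_P covers exactly the meta-phrase suffixes, with preceding tokens", {
  # degenerate single meta-phrase: rows are that phrase's suffixes only
  b <- fix1_bundle()
  st <- rpfp:::build_structures(b)
  expect_true(all(st$tp$occ$phrase == 1L))
  # preceding meta-character sits |beta| + 1 from the phrase end
  dp <- b$d_p$phrases
  for (i in seq_len(nrow(st$tp$occ))) {
    row <- st$tp$occ[i, ]
    ph <- dp[[row$phrase]]
    expect_equal(ph[length(ph) - st$tp$len[row$group]], row$prec)
  }
})

test_that("sparse-table RMQ agrees with a linear scan", {
  set.seed(89)
  v <- sample(0:30, 400, replace = TRUE)
  rq <- build_rmq(v)
  i <- sample(400, 1e4, replace = TRUE)
  j <- pmin(400L, i + sample(0:100, 1e4, replace = TRUE))
  got <- rmq(rq, i, j)
  want <- vapply(seq_along(i), function(k) min(v[i[k]:j[k]]), integer(1))
  expect_equal(got, want)
  expect_equal(rmq(rq, 17L, 17L), v[17])
  expect_equal(rmq(rq, 1L, 400L), min(v))
  expect_error(rmq(rq, 0L, 5L), class = "rpfp_error_config")
})
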