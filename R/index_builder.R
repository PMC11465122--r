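#' Index construction from the recursive parse
#'
#' The central result: the BWT, sampled suffix array and sampled LCP array
#' of `T$` are computed from `(D_T, D_P, P_P)` alone.  Proper phrase
#' suffixes `alpha` of `D_T` partition the rows of the BWT into consecutive
#' lexicographic ranges (the suffix set is prefix-free).  Within one range,
#' the occurrences of `alpha` are ordered by what follows them in the text:
#' the proper meta-phrase suffix `beta` that follows the containing
#' meta-character (iterated in lexicographic order via `T_P`), ties broken
#' by the position of the containing meta-phrase occurrence in `BWT(P_P)`
#' (the grid `G`).  SA values come from the `EP` ending-position array;
#' LCP values from a staged comparison that descends from suffix strings to
#' meta-phrase tokens to characters, using the RMQ over `LCP(P_P)` for the
#' shared meta-phrase run.
#'
#' @name index_builder
NULL

# All derived structures needed by the construction, computed once per
# bundle.  This is the only entry point; nothing here reads P_T.
build_structures <- function(bundle) {
  d_t <- bundle$d_t; d_p <- bundle$d_p
  w1 <- bundle$w1; w2 <- bundle$w2
  counts <- phrase_occurrence_counts(bundle)
  s_t <- proper_suffixes(d_t)
  s_p <- proper_suffixes(d_p)
  co_t <- colex_order(d_t)
  co_p <- colex_order(d_p)
  psa <- build_parse_sa(bundle$p_p)
  grid <- build_grid(psa, length(d_p$keys))
  rq <- build_rmq(psa$lcp)
  ep <- compute_ep(bundle)
  geo <- meta_phrase_geometry(bundle)
  tt <- build_table_tt(s_t, counts, co_t, bundle$n)
  tp <- build_table_tp(s_p, co_p, length(d_t$keys))
  lensT <- d_t$lens
  plen <- function(t) ifelse(t == 0L, w1, lensT[pmax(t, 1L)])
  # decoded token vectors, cached for the LCP stages
  alpha_ints <- lapply(s_t$keys, decode_key)
  beta_ints <- lapply(s_p$keys, decode_key)
  beta_adv <- vapply(beta_ints, function(v) sum(plen(v) - w1), numeric(1L))
  list(bundle = bundle, counts = counts, s_t = s_t, s_p = s_p,
       co_t = co_t, co_p = co_p, psa = psa, grid = grid, rq = rq, ep = ep,
       geo = geo, tt = tt, tp = tp, plen = plen,
       alpha_ints = alpha_ints, beta_ints = beta_ints,
       beta_adv = as.integer(beta_adv))
}

#' Classify the proper phrase suffixes
#'
#' A suffix is *easy* when every phrase carrying it is preceded by the same
#' character (its BWT range is a single symbol and needs no ordering).
#' Hard suffixes are resolved per proper meta-phrase suffix `beta`:
#' *hard-easy* when exactly one (meta-character, meta-phrase occurrence)
#' is involved for that `beta`, *hard-hard* when the grid must order
#' several.
#'
#' @param st structures from an [rpfp_index()] build, or an `rpfp_bundle`.
#' @return A data.frame with one row per `(alpha, beta)` occurrence group:
#'   `alpha` (suffix rank in `S_T`), `beta` (suffix rank in `S_P`), `n_occ`
#'   and `class` (`easy`, `hard_easy`, `hard_hard`).
#' @export
classify <- function(st) {
  if (inherits(st, "rpfp_bundle")) st <- build_structures(st)
  res <- vector("list", length(st$s_t$keys))
  for (g in seq_along(st$s_t$keys)) {
    d <- order_occurrences(st, g)
    grp <- rle(d$beta)
    cls <- ifelse(grp$lengths == 1L, "hard_easy", "hard_hard")
    if (st$tt$easy[g]) cls[] <- "easy"
    res[[g]] <- data.frame(alpha = g, beta = grp$values, n_occ = grp$lengths,
                           class = cls)
  }
  do.call(rbind, res)
}

#' Lexicographically ordered occurrences of one proper phrase suffix
#'
#' Iterates the proper meta-phrase suffixes `beta` (lexicographic order)
#' restricted to those preceded by a meta-character whose phrase ends with
#' `alpha`; within one `beta`, merges the relevant meta-phrases' grid lists
#' by ascending `BWT(P_P)` position.  The concatenation is the
#' lexicographic order of the text suffixes beginning with `alpha`, and
#' each descriptor carries its BWT character and SA value.
#'
#' @param st structures from a build (internal; see [rpfp_index()]).
#' @param g rank of `alpha` in `S_T`.
#' @return A data.frame with one row per occurrence, in BWT-row order:
#'   `m` (meta-character), `beta`, `dprime`, `grid_pos`, `char` (preceding
#'   symbol code), `sa` (suffix position in `T$`).
#' @keywords internal
#' @export
order_occurrences <- function(st, g) {
  occ_t <- st$tt$occ
  rows_t <- which(occ_t$group == g)
  ranks <- occ_t$phrase[rows_t]
  prec_map <- integer(length(st$bundle$d_t$keys))
  prec_map[ranks] <- occ_t$prec[rows_t]
  rows_p <- sort(unlist(st$tp$prec_index[ranks], use.names = FALSE))
  occ_p <- st$tp$occ
  dprime <- occ_p$phrase[rows_p]
  glists <- st$grid[dprime]
  ll <- lengths(glists)
  beta <- rep.int(occ_p$group[rows_p], ll)
  mvec <- rep.int(occ_p$prec[rows_p], ll)
  dpr <- rep.int(dprime, ll)
  gpos <- unlist(glists, use.names = FALSE)
  if (is.null(gpos)) gpos <- integer(0L)
  o <- order(beta, gpos, method = "radix")
  beta <- beta[o]; mvec <- mvec[o]; dpr <- dpr[o]; gpos <- gpos[o]
  if (length(gpos) != sum(st$counts[ranks]))
    rpfp_abort("rpfp_error_internal",
               sprintf("ordered occurrences of suffix %d: got %d, expected %d",
                       g, length(gpos), sum(st$counts[ranks])))
  k <- st$psa$sa[gpos] - 1L
  sa <- st$ep[k] - st$s_t$len[g] - st$beta_adv[beta] + 1L - st$bundle$w1
  data.frame(m = mvec, beta = beta, dprime = dpr, grid_pos = gpos,
             char = prec_map[mvec], sa = as.integer(sa))
}

# LCP of the text suffixes at two adjacent BWT rows, from their descriptors.
# Three stages: different alpha -> character LCP of the suffix strings;
# same alpha, different beta -> token LCP of the betas, resolved inside the
# first differing phrases; same alpha and beta -> RMQ over LCP(P_P) counts
# the shared meta-phrases, then the first differing meta-phrase pair is
# resolved token-by-token and finally character-by-character.  Overlaps are
# subtracted per junction (w1 symbols per phrase junction; the first w2
# tokens of a meta-phrase belong to its predecessor).
lcp_adjacent <- function(st, a, b) {
  w1 <- st$bundle$w1; w2 <- st$bundle$w2
  plen <- st$plen
  if (a$alpha != b$alpha)
    return(vec_lcp(st$alpha_ints[[a$alpha]], st$alpha_ints[[b$alpha]]))
  base <- st$s_t$len[a$alpha]
  resolve_tokens <- function(ui, uj) {
    # first differing level-1 phrase pair; they share a w1-symbol trigger
    if (ui == 0L || uj == 0L) return(0L)
    cl <- vec_lcp(st$bundle$d_t$phrases[[ui]], st$bundle$d_t$phrases[[uj]])
    if (cl < w1) rpfp_abort("rpfp_error_internal", "differing phrases share < w1 symbols")
    cl - w1
  }
  if (a$beta != b$beta) {
    bi <- st$beta_ints[[a$beta]]; bj <- st$beta_ints[[b$beta]]
    t <- vec_lcp(bi, bj)
    if (t >= min(length(bi), length(bj)))
      rpfp_abort("rpfp_error_internal", "meta-phrase suffixes not prefix-free")
    common <- if (t > 0L) sum(plen(bi[seq_len(t)]) - w1) else 0L
    return(base + common + resolve_tokens(bi[t + 1L], bj[t + 1L]))
  }
  # same alpha and beta: descend through P_P
  gi <- a$grid_pos; gj <- b$grid_pos
  if (gi >= gj) rpfp_abort("rpfp_error_internal", "grid positions out of order")
  acc <- base + st$beta_adv[a$beta]
  t <- rmq(st$rq, gi + 1L, gj)
  sai <- st$psa$sa[gi]; saj <- st$psa$sa[gj]
  if (t > 0L) acc <- acc + sum(st$geo$adv[st$psa$seq[sai:(sai + t - 1L)]])
  Di <- st$psa$seq[sai + t]; Dj <- st$psa$seq[saj + t]
  if (is.na(Di) || is.na(Dj) || Di == 0L || Dj == 0L) return(acc)
  pi_ <- st$bundle$d_p$phrases[[Di]]; pj_ <- st$bundle$d_p$phrases[[Dj]]
  tl <- vec_lcp(pi_, pj_)
  if (tl < w2 || tl >= min(length(pi_), length(pj_)))
    rpfp_abort("rpfp_error_internal", "differing meta-phrases violate overlap/prefix-freeness")
  if (tl > w2) acc <- acc + sum(plen(pi_[(w2 + 1L):tl]) - w1)
  acc + resolve_tokens(pi_[tl + 1L], pj_[tl + 1L])
}

#' Run-length encode a symbol sequence
#'
#' @param bwt character string or character vector of symbols.
#' @return A data.frame of class `rpfp_rlbwt` with columns `symbol` and
#'   `length` (maximal runs).
#' @export
run_length_encode <- function(bwt) {
  if (length(bwt) == 1L && nchar(bwt) > 1L) bwt <- strsplit(bwt, "")[[1L]]
  if (length(bwt) == 0L) rpfp_abort("rpfp_error_config", "empty BWT")
  r <- rle(bwt)
  structure(data.frame(symbol = r$values, length = r$lengths),
            class = c("rpfp_rlbwt", "data.frame"))
}

#' Decode a run-length encoded sequence
#'
#' @param runs an `rpfp_rlbwt` (or data.frame with `symbol`, `length`).
#' @return The decoded character string.
#' @export
run_length_decode <- function(runs) {
  paste(rep.int(runs$symbol, runs$length), collapse = "")
}

#' Build the run-length BWT, sampled SA and sampled LCP of a text
#'
#' The full pipeline: level-1 and level-2 prefix-free parsing, release of
#' the first-level parse, then construction of the BWT of `T$` with SA
#' values sampled at the first and last row of every run and LCP values at
#' the first row of every run, all in one coordinated pass over the proper
#' phrase suffixes in lexicographic order.
#'
#' @param x an `rpfp_text`, `rpfp_seqset`, single character string, or an
#'   already built `rpfp_bundle`.
#' @param cfg1,cfg2 [trigger_config()]s for the two levels (ignored when
#'   `x` is a bundle).
#' @param full_arrays also return the complete BWT, SA and LCP arrays
#'   (debugging; linear space in `n`).
#' @return An object of class `rpfp_index`: `runs` (`symbol`, `length`),
#'   `ssa` (`run`, `start_row`, `sa_first`, `sa_last`), `slcp` (`run`,
#'   `start_row`, `lcp`), `n`, `r`, the parameters, and optionally `full`
#'   with `bwt`, `sa`, `lcp`.  Rows are 1-based; SA values are positions in
#'   `T$` (the terminator row has SA value `n + 1`).
#' @export
rpfp_index <- function(x, cfg1 = trigger_config(10L, 100L),
                       cfg2 = trigger_config(5L, 11L), full_arrays = FALSE) {
  bundle <- if (inherits(x, "rpfp_bundle")) {
    x
  } else {
    if (is.character(x)) x <- text_from_string(x)
    if (inherits(x, "rpfp_seqset")) x <- assemble_text(x)
    build_rpfp(x, cfg1, cfg2)
  }
  st <- build_structures(bundle)
  n <- bundle$n
  nr <- n + 1L
  bwt_code <- integer(nr); sa <- integer(nr)
  alpha_id <- integer(nr); beta_id <- integer(nr); gpos <- integer(nr)
  hard_hard_consults <- 0L
  pos <- 0L
  for (g in seq_along(st$s_t$keys)) {
    d <- order_occurrences(st, g)
    k <- nrow(d)
    if (k == 0L) next
    idx <- pos + seq_len(k)
    bwt_code[idx] <- d$char
    sa[idx] <- d$sa
    alpha_id[idx] <- g
    beta_id[idx] <- d$beta
    gpos[idx] <- d$grid_pos
    if (!st$tt$easy[g]) hard_hard_consults <- hard_hard_consults +
      sum(rle(d$beta)$lengths > 1L)
    pos <- pos + k
  }
  if (pos != nr)
    rpfp_abort("rpfp_error_internal", sprintf("emitted %d BWT rows, expected %d", pos, nr))
  bwt_chars <- c("$", bundle$alphabet)[bwt_code + 1L]
  runs <- run_length_encode(bwt_chars)
  r <- nrow(runs)
  run_start <- cumsum(c(1L, runs$length[-r]))
  run_end <- cumsum(runs$length)
  ssa <- data.frame(run = seq_len(r), start_row = run_start,
                    sa_first = sa[run_start], sa_last = sa[run_end])
  desc_at <- function(i) list(alpha = alpha_id[i], beta = beta_id[i], grid_pos = gpos[i])
  lcp_at <- function(i) if (i == 1L) 0L else lcp_adjacent(st, desc_at(i - 1L), desc_at(i))
  slcp <- data.frame(run = seq_len(r), start_row = run_start,
                     lcp = vapply(run_start, lcp_at, numeric(1L)))
  idx <- structure(list(runs = runs, ssa = ssa, slcp = slcp, n = n, r = r,
                        w1 = bundle$w1, p1 = bundle$p1, w2 = bundle$w2, p2 = bundle$p2,
                        alphabet = bundle$alphabet,
                        hard_hard_consults = hard_hard_consults),
                   class = "rpfp_index")
  if (full_arrays) {
    idx$full <- list(bwt = paste(bwt_chars, collapse = ""), sa = sa,
                     lcp = vapply(seq_len(nr), lcp_at, numeric(1L)))
  }
  idx
}

#' @export
print.rpfp_index <- function(x, ...) {
  cat(sprintf("rpfp_index: n = %d, r = %d runs (n/r = %.2f), w1 = %d, p1 = %d, w2 = %d, p2 = %d\n",
              x$n, x$r, (x$n + 1) / x$r, x$w1, x$p1, x$w2, x$p2))
  invisible(x)
}

#' Compute the BWT alone, using the easy/hard classification
#'
#' Easy suffix ranges are emitted directly as `frequency` copies of the
#' single preceding character; hard ranges go through the full occurrence
#' ordering.  Mainly of didactic and testing value — [rpfp_index()] orders
#' every range because SA and LCP sampling need the order anyway.
#'
#' @param bundle an `rpfp_bundle`.
#' @return Character string, the BWT of `T$`; attribute `class_counts`
#'   tallies easy/hard ranges.
#' @export
rpfp_bwt <- function(bundle) {
  st <- build_structures(bundle)
  out <- character(length(st$s_t$keys))
  n_easy <- 0L; n_hard <- 0L
  for (g in seq_along(st$s_t$keys)) {
    if (st$tt$easy[g]) {
      occ <- st$tt$occ
      rows <- which(occ$group == g & occ$freq > 0L)
      ch <- unique(occ$prec[rows])
      if (length(ch) != 1L) rpfp_abort("rpfp_error_internal", "easy range not uniform")
      out[g] <- strrep(c("$", bundle$alphabet)[ch + 1L], st$tt$freq[g])
      n_easy <- n_easy + 1L
    } else {
      d <- order_occurrences(st, g)
      out[g] <- paste(c("$", bundle$alphabet)[d$char + 1L], collapse = "")
      n_hard <- n_hard + 1L
    }
  }
  structure(paste(out, collapse = ""), class_counts = c(easy = n_easy, hard = n_hard))
}
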