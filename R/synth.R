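#' Synthetic pangenome generation
#'
#' Generators for the two repetition regimes the index targets: a pangenome
#' (one random base genome plus haplotypes derived from it by point
#' mutation and small indels) and the many-identical-copies regime (the
#' same genome appended repeatedly, as in viral collections of near-clonal
#' isolates).  All output is deterministic given the seed; the generator is
#' fixed to the Mersenne-Twister stream so the same spec yields the same
#' FASTA on every platform.
#'
#' @name synth
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Generate a uniform random base genome
#'
#' @param length number of symbols (>= 1).
#' @param seed integer seed.
#' @return A character string over `{A,C,G,T}`, i.i.d. uniform.
#' @export
generate_base <- function(length, seed) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) rpfp_abort("rpfp_error_synth", "length must be >= 1")
  with_seed(seed, paste(sample(DNA_BASES, length, replace = TRUE), collapse = ""))
}

#' Specification of a synthetic pangenome
#'
#' @param base_length length of the base genome (>= 10).
#' @param n_haplotypes number of records in the output (record 1 is the base).
#' @param sub_rate per-site substitution probability in `[0, 1)`.
#' @param indel_rate per-site indel probability in `[0, 1)`; an indel is an
#'   insertion or deletion (equiprobable) of length `Uniform{1..max_indel}`.
#' @param max_indel maximum indel length (>= 1).
#' @param seed integer seed.
#' @return A list of class `rpfp_pangenome_spec`.
#' @export
pangenome_spec <- function(base_length = 1000L, n_haplotypes = 8L,
                           sub_rate = 0.01, indel_rate = 0.001,
                           max_indel = 5L, seed = 1L) {
  base_length <- as.integer(base_length)
  n_haplotypes <- as.integer(n_haplotypes)
  max_indel <- as.integer(max_indel)
  if (base_length < 10L) rpfp_abort("rpfp_error_synth", "base_length must be >= 10")
  if (n_haplotypes < 1L) rpfp_abort("rpfp_error_synth", "n_haplotypes must be >= 1")
  if (max_indel < 1L) rpfp_abort("rpfp_error_synth", "max_indel must be >= 1")
  if (sub_rate < 0 || indel_rate < 0 || sub_rate + indel_rate >= 1)
    rpfp_abort("rpfp_error_synth", "need sub_rate + indel_rate < 1, both >= 0")
  structure(list(base_length = base_length, n_haplotypes = n_haplotypes,
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 max_indel = max_indel, seed = as.integer(seed)),
            class = "rpfp_pangenome_spec")
}

# One mutant of `base` (character vector of single bases) under the spec's
# per-site model.  Deletions are truncated at the sequence end and never
# empty the sequence.
mutate_haplotype <- function(base, sub_rate, indel_rate, max_indel) {
  L <- length(base)
  u <- stats::runif(L)
  out <- base
  subs <- which(u < sub_rate)
  if (length(subs)) {
    # substitute with one of the three other bases
    pick <- function(b) sample(setdiff(DNA_BASES, b), 1L)
    out[subs] <- vapply(base[subs], pick, character(1L))
  }
  indels <- which(u >= sub_rate & u < sub_rate + indel_rate)
  if (length(indels)) {
    is_ins <- stats::runif(length(indels)) < 0.5
    lens <- sample.int(max_indel, length(indels), replace = TRUE)
    ins_seq <- lapply(seq_along(indels), function(i) {
      if (is_ins[i]) sample(DNA_BASES, lens[i], replace = TRUE) else character(0L)
    })
    # apply right-to-left so earlier positions stay valid
    for (i in rev(seq_along(indels))) {
      pos <- indels[i]
      if (is_ins[i]) {
        out <- append(out, ins_seq[[i]], after = pos)
      } else {
        drop <- pos:min(pos + lens[i] - 1L, length(out))
        if (length(drop) < length(out)) out <- out[-drop]
      }
    }
  }
  out
}

#' Generate a synthetic pangenome
#'
#' Record 1 is the base genome; records `2..n_haplotypes` are independent
#' mutants of it.
#'
#' @param spec an [pangenome_spec()].
#' @return An `rpfp_seqset` with `n_haplotypes` records.
#' @export
generate_pangenome <- function(spec) {
  stopifnot(inherits(spec, "rpfp_pangenome_spec"))
  with_seed(spec$seed, {
    base <- sample(DNA_BASES, spec$base_length, replace = TRUE)
    seqs <- character(spec$n_haplotypes)
    seqs[1L] <- paste(base, collapse = "")
    if (spec$n_haplotypes > 1L) {
      for (h in 2:spec$n_haplotypes) {
        seqs[h] <- paste(
          mutate_haplotype(base, spec$sub_rate, spec$indel_rate, spec$max_indel),
          collapse = "")
      }
    }
    seq_set(sprintf("hap%d", seq_len(spec$n_haplotypes)), seqs)
  })
}

#' Generate identical copies of one random genome
#'
#' The maximally repetitive regime: `n_copies` identical records of a single
#' random base genome.
#'
#' @param genome_length length of the genome (>= 1).
#' @param n_copies number of identical records (>= 1).
#' @param seed integer seed.
#' @return An `rpfp_seqset`.
#' @export
generate_copies <- function(genome_length, n_copies, seed) {
  n_copies <- as.integer(n_copies)
  if (is.na(n_copies) || n_copies < 1L) rpfp_abort("rpfp_error_synth", "n_copies must be >= 1")
  g <- generate_base(genome_length, seed)
  seq_set(sprintf("copy%d", seq_len(n_copies)), rep(g, n_copies))
}
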