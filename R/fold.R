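#' Encode an RNA sequence as integer base codes
#'
#' Maps A, C, G, U to codes 0..3. T is mapped to U at parse time by the file
#' readers, so it is rejected here unless `allow_other` is set, in which
#' case any non-ACGU character becomes -1 (scoring skips windows containing
#' such positions).
#' @noRd
encode_rna <- function(seq, allow_other = FALSE) {
  chars <- strsplit(toupper(seq), "")[[1]]
  codes <- match(chars, RNA_BASES) - 1L
  if (anyNA(codes)) {
    if (!allow_other) {
      bad <- unique(chars[is.na(codes)])
      abort(paste0("invalid RNA sequence: illegal character(s) ",
                   paste(bad, collapse = ", ")))
    }
    codes[is.na(codes)] <- -1L
  }
  codes
}

#' Partition function over the Boltzmann ensemble of nested structures
#'
#' Computes inside weights for every subinterval of the sequence under the
#' energy model, such that the total weight over the full interval equals
#' the sum of exp(-beta * E(s)) over all legal nested structures s. These
#' tables drive exact stochastic traceback sampling.
#'
#' @param seq RNA string over ACGU (length >= 1).
#' @param model An [energy_model()].
#' @return A `fold_tables` object with fields `Z`, `Zp` (inside weight
#'   matrices), `total` (full-interval weight), plus the sequence codes and
#'   the model used.
#' @examples
#' ft <- compute_partition("GGGAAACCC", energy_model())
#' ft$total
#' @export
compute_partition <- function(seq, model = energy_model()) {
  codes <- encode_rna(seq)
  if (length(codes) < 1L) abort("sequence must have length >= 1.")
  tabs <- fold_partition_cpp(codes, model$pair_matrix, model$stacking,
                             model$min_hairpin, model$beta)
  structure(list(Z = tabs$Z, Zp = tabs$Zp, total = tabs$total,
                 codes = codes, seq = toupper(seq), model = model),
            class = "fold_tables")
}

#' @export
print.fold_tables <- function(x, ...) {
  cat("<fold_tables> n =", length(x$codes), " total weight =", x$total, "\n")
  invisible(x)
}

#' Exhaustively enumerate all legal nested structures
#'
#' Testing oracle for the partition function and the sampler: lists every
#' legal non-crossing structure exactly once together with its Boltzmann
#' weight exp(-beta * E). Refuses sequences longer than `max_len` to guard
#' against combinatorial explosion.
#'
#' @inheritParams compute_partition
#' @param max_len Length guard (default 16).
#' @return A tibble with columns `dotbracket`, `weight` and a `partner`
#'   list-column of 0-based partner vectors.
#' @export
enumerate_structures <- function(seq, model = energy_model(), max_len = 16L) {
  codes <- encode_rna(seq)
  if (length(codes) > max_len) {
    abort(paste0("sequence length ", length(codes), " exceeds enumeration ",
                 "guard (", max_len, ")."))
  }
  res <- enumerate_structures_cpp(codes, model$pair_matrix, model$stacking,
                                  model$min_hairpin, model$beta)
  tibble(
    dotbracket = vapply(res$partners, dotbracket_from_partner, character(1)),
    weight = as.numeric(res$weights),
    partner = lapply(res$partners, as.integer)
  )
}

#' Sample structures from the exact Boltzmann distribution
#'
#' Stochastic traceback through precomputed partition tables: draws
#' independent samples with probability exp(-beta * E(s)) / Z. Reproducible
#' given `seed` (a dedicated generator is used; R's RNG state is not
#' touched).
#'
#' @param tables A `fold_tables` object from [compute_partition()].
#' @param n_samples Number of structures to draw (>= 1).
#' @param seed Integer seed.
#' @return A tibble with columns `dotbracket` and `partner` (list-column).
#' @export
sample_structures <- function(tables, n_samples, seed = 1L) {
  stopifnot(inherits(tables, "fold_tables"))
  if (n_samples < 1L) abort("`n_samples` must be >= 1.")
  m <- tables$model
  mat <- sample_structures_cpp(tables$codes, tables, m$pair_matrix,
                               m$stacking, m$min_hairpin, m$beta,
                               as.integer(n_samples), as.double(seed))
  partners <- lapply(seq_len(nrow(mat)), function(i) as.integer(mat[i, ]))
  tibble(
    dotbracket = vapply(partners, dotbracket_from_partner, character(1)),
    partner = partners
  )
}

#' Classify every base of a structure by its loop context
#'
#' Paired bases get the paired category. Each unpaired base is classified
#' by the loop that contains it: enclosed by a pair with no inner helix is
#' a hairpin loop; not enclosed by any pair is external; a loop with one
#' inner helix is a bulge (unpaired bases on one side only) or an internal
#' loop (both sides); two or more inner helices make a multiloop. The
#' alphabet then maps categories to context letters.
#'
#' @param structure A `secondary_structure`, a partner vector or a
#'   dot-bracket string.
#' @param alphabet An [annotation_alphabet()].
#' @return Annotation string of length n.
#' @examples
#' classify_contexts("((((...))))")        # "PPPPLLLPPPP"
#' classify_contexts(".((...)).")          # "UPPLLLPPU"
#' @export
classify_contexts <- function(structure, alphabet = plum_alphabet()) {
  partner <- as_partner(structure)
  cats <- classify_contexts_cpp(partner)
  idx <- alphabet_category_index(alphabet)
  paste(alphabet$letters[idx[cats + 1L]], collapse = "")
}

as_partner <- function(structure) {
  if (inherits(structure, "secondary_structure")) return(structure$partner)
  if (is.character(structure)) return(partner_from_dotbracket(structure))
  as.integer(structure)
}

#' Per-base structural-context annotation profile
#'
#' Samples `n_samples` structures from the Boltzmann ensemble, classifies
#' every base in every sample, and returns the empirical annotation
#' frequencies: a |A| x n matrix whose column i is the context distribution
#' of base i (columns sum to 1 exactly, as counts / n_samples).
#'
#' @inheritParams compute_partition
#' @param alphabet An [annotation_alphabet()].
#' @param n_samples Ensemble sample count (default 1000).
#' @param seed Integer seed for the sampler.
#' @return Numeric matrix with one row per alphabet letter (rownames set)
#'   and one column per base; attribute `alphabet` carries the alphabet.
#' @examples
#' p <- annotation_profile("GGGGAAAACCCC", n_samples = 100, seed = 1)
#' colSums(p)
#' @export
annotation_profile <- function(seq, model = energy_model(),
                               alphabet = plum_alphabet(),
                               n_samples = 1000L, seed = 1L) {
  if (n_samples < 1L) abort("`n_samples` must be >= 1.")
  tables <- compute_partition(seq, model)
  m <- model
  counts <- annotation_counts_cpp(tables$codes, tables, m$pair_matrix,
                                  m$stacking, m$min_hairpin, m$beta,
                                  as.integer(n_samples), as.double(seed))
  profile_from_category_counts(counts, alphabet, n_samples)
}

profile_from_category_counts <- function(counts, alphabet, n_samples) {
  idx <- alphabet_category_index(alphabet)
  na <- n_letters(alphabet)
  prof <- matrix(0, na, ncol(counts),
                 dimnames = list(alphabet$letters, NULL))
  for (cat in seq_len(6L)) {
    prof[idx[cat], ] <- prof[idx[cat], ] + counts[cat, ]
  }
  prof <- prof / n_samples
  attr(prof, "alphabet") <- alphabet
  prof
}

#' Annotate a table of sequences with structure profiles
#'
#' Tidy entry point for the annotator: takes a data frame with a `seq`
#' column and adds a `profile` list-column of annotation-profile matrices.
#' Per-record sampler seeds are derived deterministically from `seed` and
#' the row number, so the result is reproducible and independent of
#' chunking.
#'
#' @param records Data frame with a character `seq` column.
#' @inheritParams annotation_profile
#' @return The input as a tibble with a `profile` list-column added.
#' @export
annotate_structure <- function(records, model = energy_model(),
                               alphabet = plum_alphabet(),
                               n_samples = 1000L, seed = 1L) {
  records <- as_tibble(records)
  if (!"seq" %in% names(records)) abort("`records` needs a `seq` column.")
  if (n_samples < 1L) abort("`n_samples` must be >= 1.")
  codes <- lapply(records$seq, encode_rna)
  seeds <- vapply(seq_len(nrow(records)), function(i) {
    as.double(derive_seed(seed, i))
  }, numeric(1))
  counts <- annotate_batch_cpp(codes, model$pair_matrix, model$stacking,
                               model$min_hairpin, model$beta,
                               as.integer(n_samples), seeds)
  records$profile <- lapply(counts, profile_from_category_counts,
                            alphabet = alphabet, n_samples = n_samples)
  records
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, index, stride = 1000003) {
  as.integer((as.double(seed) * stride + index) %% 2147483647)
}

#' Build an annotation profile from external folding output
#'
#' Adapter so structures predicted by an external folding program can stand
#' in for the built-in sampler. Accepts either a character vector of
#' sampled dot-bracket strings (empirical annotation frequencies are
#' computed over them) or a ready-made per-base probability table whose
#' columns sum to 1.
#'
#' @param x Character vector of dot-bracket strings, or a numeric matrix
#'   with one row per alphabet letter.
#' @param alphabet An [annotation_alphabet()].
#' @return Annotation-profile matrix as from [annotation_profile()].
#' @export
profile_from_external <- function(x, alphabet = plum_alphabet()) {
  if (is.character(x)) {
    if (!length(x)) abort("no structures supplied.")
    n <- nchar(x[1])
    counts <- matrix(0, 6L, n)
    for (k in seq_along(x)) {
      if (nchar(x[k]) != n) {
        abort(paste0("format error at structure ", k,
                     ": length mismatch (", nchar(x[k]), " vs ", n, ")."))
      }
      partner <- tryCatch(partner_from_dotbracket(x[k]), error = function(e) {
        abort(paste0("format error at structure ", k, ": ",
                     conditionMessage(e)))
      })
      cats <- classify_contexts_cpp(partner)
      for (i in seq_len(n)) {
        counts[cats[i] + 1L, i] <- counts[cats[i] + 1L, i] + 1
      }
    }
    return(profile_from_category_counts(counts, alphabet, length(x)))
  }
  x <- as.matrix(x)
  if (nrow(x) != n_letters(alphabet)) {
    abort("probability table must have one row per alphabet letter.")
  }
  bad <- which(abs(colSums(x) - 1) > 1e-6)
  if (length(bad)) {
    abort(paste0("format error: column ", bad[1], " sums to ",
                 format(colSums(x)[bad[1]]), " (not 1)."))
  }
  rownames(x) <- alphabet$letters
  attr(x, "alphabet") <- alphabet
  x
}
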