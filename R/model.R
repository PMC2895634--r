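#' Joint sequence + structural-context motif model
#'
#' The model scores a binding site of width w as the product of two
#' logistic terms: a sequence term sigma(b_seq + sum_j theta[base_j, j])
#' driven by a position weight matrix, and a structure term
#' sigma(b_str + sum_j sum_a gamma[a] * pi_a(j)) driven by per-context
#' preference parameters weighted by the site's annotation profile. A
#' sequence's score N is the noisy-OR over all windows: the probability
#' that at least one window is bound.
#'
#' Two conventions for the structure-term inner sum are supported: `"sum"`
#' (the default; a pure-context-a window has logit b_str + w * gamma[a])
#' and `"mean"` (profile mass averaged over positions, so the pure-context
#' logit is b_str + gamma[a]). The two differ only by a reparameterization
#' of gamma at fixed width but matter when comparing widths; every report
#' states which was used.
#'
#' @param theta 4 x w numeric matrix of sequence parameters, rows A, C, G, U.
#' @param gamma Numeric vector of structure parameters, one per alphabet
#'   letter (names optional; order follows the alphabet).
#' @param b_seq,b_str Bias of the sequence and structure terms.
#' @param alphabet An [annotation_alphabet()].
#' @param convention `"sum"` or `"mean"` (structure-term inner sum).
#' @return A `motif_model` object.
#' @examples
#' m <- motif_model(theta = matrix(0, 4, 6), gamma = c(0, 0, 0, 0))
#' m$width
#' @export
motif_model <- function(theta, gamma, b_seq = 0, b_str = 0,
                        alphabet = plum_alphabet(),
                        convention = c("sum", "mean")) {
  convention <- match.arg(convention)
  theta <- as.matrix(theta)
  if (nrow(theta) != 4L) abort("`theta` must have 4 rows (A, C, G, U).")
  if (ncol(theta) < 1L) abort("`theta` must have at least one column.")
  if (length(gamma) != n_letters(alphabet)) {
    abort("`gamma` needs one entry per alphabet letter.")
  }
  vals <- c(theta, gamma, b_seq, b_str)
  if (!all(is.finite(vals))) abort("all model parameters must be finite.")
  rownames(theta) <- RNA_BASES
  structure(list(width = ncol(theta), theta = theta,
                 gamma = setNames(as.numeric(gamma), alphabet$letters),
                 b_seq = as.numeric(b_seq), b_str = as.numeric(b_str),
                 alphabet = alphabet, convention = convention),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("<motif_model> width", x$width, "| alphabet",
      paste(x$alphabet$letters, collapse = ""),
      "| convention", x$convention, "\n")
  cat("  gamma:", paste(sprintf("%s=%.3g", names(x$gamma), x$gamma),
                        collapse = " "), "\n")
  cat("  b_seq:", format(x$b_seq), " b_str:", format(x$b_str), "\n")
  invisible(x)
}

#' Linear map from noisy-OR score to predicted affinity
#'
#' @param slope Strictly positive slope (predicted affinity increases with
#'   the score).
#' @param intercept Intercept.
#' @return An `affinity_map` object.
#' @export
affinity_map <- function(slope = 1, intercept = 0) {
  if (!is.numeric(slope) || slope <= 0) abort("`slope` must be > 0.")
  structure(list(slope = as.numeric(slope),
                 intercept = as.numeric(intercept)),
            class = "affinity_map")
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Sequence term of one k-mer
#'
#' @param kmer RNA string of length equal to the model width.
#' @param model A [motif_model()].
#' @return Probability in (0, 1).
#' @export
sequence_term <- function(kmer, model) {
  codes <- encode_rna(kmer)
  if (length(codes) != model$width) abort("kmer length must equal width.")
  logit <- model$b_seq +
    sum(model$theta[cbind(codes + 1L, seq_len(model$width))])
  logistic(logit)
}

#' Structure term of one window profile slice
#'
#' @param window_profile |A| x w matrix slice of an annotation profile
#'   (columns sum to 1).
#' @param model A [motif_model()].
#' @return Probability in (0, 1).
#' @export
structure_term <- function(window_profile, model) {
  window_profile <- as.matrix(window_profile)
  if (nrow(window_profile) != n_letters(model$alphabet)) {
    abort("profile alphabet does not match the model alphabet.")
  }
  mass <- rowSums(window_profile)
  if (model$convention == "mean") mass <- mass / ncol(window_profile)
  logistic(model$b_str + sum(model$gamma * mass))
}

#' Bound probability of one window
#'
#' Product of the sequence and structure terms: a strongly disfavored
#' context drives the probability to zero regardless of sequence, so the
#' context licenses binding.
#'
#' @inheritParams sequence_term
#' @inheritParams structure_term
#' @export
window_probability <- function(kmer, window_profile, model) {
  sequence_term(kmer, model) * structure_term(window_profile, model)
}

# |A| x (n - w + 1) matrix of window-summed profile mass (divided by w
# under the mean convention); core precomputation for scoring and fitting
window_profile_sums <- function(profile, width, convention = "sum") {
  n <- ncol(profile)
  nwin <- n - width + 1L
  cs <- cbind(0, t(apply(profile, 1L, cumsum)))
  out <- cs[, (width + 1L):(n + 1L), drop = FALSE] -
    cs[, 1L:nwin, drop = FALSE]
  if (convention == "mean") out <- out / width
  out
}

#' Noisy-OR score of a full sequence
#'
#' N = 1 - prod_i (1 - p_i) over all windows of the model width, with the
#' product accumulated in the logarithmic domain. Windows containing a
#' non-ACGU character contribute p = 0.
#'
#' @param seq RNA string (length >= model width).
#' @param profile Annotation-profile matrix for `seq`.
#' @param model A [motif_model()].
#' @return Score N in \[0, 1).
#' @export
score_sequence <- function(seq, profile, model) {
  codes <- encode_rna(seq, allow_other = TRUE)
  if (length(codes) < model$width) {
    abort(paste0("sequence '", substr(seq, 1, 20), "' is shorter (",
                 length(codes), ") than the model width (", model$width, ")."))
  }
  if (ncol(profile) != length(codes)) {
    abort("profile length must equal sequence length.")
  }
  winS <- window_profile_sums(profile, model$width, model$convention)
  score_batch_cpp(list(codes), list(winS), model$theta, unname(model$gamma),
                  model$b_seq, model$b_str)[[1]]
}

#' Predicted affinity of a sequence
#'
#' @inheritParams score_sequence
#' @param map An [affinity_map()].
#' @export
predict_affinity <- function(seq, profile, model, map) {
  map$slope * score_sequence(seq, profile, model) + map$intercept
}

#' Score a table of annotated records
#'
#' Adds a `score` column (noisy-OR N) and, when an affinity map is given, a
#' `predicted` column to a tibble of records carrying `seq` and `profile`
#' columns.
#'
#' @param records Data frame with `seq` and `profile` columns (see
#'   [annotate_structure()]).
#' @param model A [motif_model()].
#' @param map Optional [affinity_map()].
#' @return The records tibble with `score` (and `predicted`) added.
#' @export
score_records <- function(records, model, map = NULL) {
  records <- as_tibble(records)
  enc <- encode_records(records, model$width, model$convention,
                        model$alphabet)
  records$score <- score_batch_cpp(enc$seqs, enc$winS, model$theta,
                                   unname(model$gamma), model$b_seq,
                                   model$b_str)
  if (!is.null(map)) {
    records$predicted <- map$slope * records$score + map$intercept
  }
  records
}

# shared encoding step: integer codes + per-record window profile sums
encode_records <- function(records, width, convention, alphabet) {
  if (!all(c("seq", "profile") %in% names(records))) {
    abort("records need `seq` and `profile` columns.")
  }
  seqs <- lapply(records$seq, encode_rna, allow_other = TRUE)
  short <- which(vapply(seqs, length, integer(1)) < width)
  if (length(short)) {
    ids <- if ("id" %in% names(records)) records$id[short] else short
    abort(paste0("records shorter than width ", width, ": ",
                 paste(head(ids, 5), collapse = ", ")))
  }
  first <- attr(records$profile[[1]], "alphabet")
  if (!is.null(first) && !same_alphabet(first, alphabet)) {
    abort("profile alphabet does not match the model alphabet.")
  }
  winS <- lapply(records$profile, window_profile_sums, width = width,
                 convention = convention)
  list(seqs = seqs, winS = winS)
}
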