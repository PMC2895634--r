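#' Simplified nested-folding energy model
#'
#' Defines the pseudo-thermodynamics of the built-in Boltzmann-ensemble
#' sampler: per-pair pseudo-energies for the six canonical pair kinds
#' (GC/CG, AU/UA, GU/UG), an optional stacking bonus awarded when two pairs
#' are directly stacked, a minimum hairpin size and an inverse-temperature
#' scale. Structure weight is exp(-beta * E) with E the sum of pair
#' energies plus stacking bonuses; the empty structure has E = 0. Lonely
#' pairs are allowed, pseudoknots, dangling ends and coaxial stacking are
#' not modeled.
#'
#' @param pair_scores Named numeric vector with elements `GC`, `AU`, `GU`
#'   giving the pseudo-energy of a pair (applied symmetrically to both
#'   orientations). More negative is more stable.
#' @param stacking Pseudo-energy bonus added for each pair stacked directly
#'   on another pair.
#' @param min_hairpin Minimum number of unpaired bases enclosed by any pair
#'   (must be at least 3).
#' @param beta Inverse-temperature scale, strictly positive.
#' @return An `energy_model` object.
#' @examples
#' energy_model()
#' energy_model(pair_scores = c(GC = -4, AU = -2, GU = -0.5))
#' @export
energy_model <- function(pair_scores = c(GC = -3, AU = -2, GU = -1),
                         stacking = -1, min_hairpin = 3L, beta = 1) {
  need <- c("GC", "AU", "GU")
  if (!all(need %in% names(pair_scores))) {
    abort("`pair_scores` must name GC, AU and GU.")
  }
  if (min_hairpin < 3L) abort("`min_hairpin` must be >= 3.")
  if (!is.numeric(beta) || beta <= 0) abort("`beta` must be > 0.")
  # 4x4 energy matrix over base codes A,C,G,U; Inf marks a forbidden pair
  em <- matrix(Inf, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  em["G", "C"] <- em["C", "G"] <- pair_scores[["GC"]]
  em["A", "U"] <- em["U", "A"] <- pair_scores[["AU"]]
  em["G", "U"] <- em["U", "G"] <- pair_scores[["GU"]]
  structure(list(pair_scores = pair_scores[need],
                 pair_matrix = em,
                 stacking = stacking,
                 min_hairpin = as.integer(min_hairpin),
                 beta = beta),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> GC:", x$pair_scores[["GC"]],
      " AU:", x$pair_scores[["AU"]],
      " GU:", x$pair_scores[["GU"]],
      " stack:", x$stacking,
      " min_hairpin:", x$min_hairpin,
      " beta:", x$beta, "\n")
  invisible(x)
}
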