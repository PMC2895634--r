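#' Relative structural-context preference ratios
#'
#' For each context letter a, evaluates the structure term of a
#' hypothetical window with probability one for a at every position (logit
#' b_str + w * gamma\[a\] under the sum convention, b_str + gamma\[a\] under
#' the mean convention), and divides by the maximum over letters. The best
#' letter's ratio is 1; the convention used is recorded in the result.
#'
#' @param model A fitted [motif_model()].
#' @return A `context_preference` list: tibble `ratios` (letter, gamma,
#'   pure_term, ratio), `best_letter`, `convention`.
#' @export
context_preference_ratios <- function(model) {
  letters <- model$alphabet$letters
  mult <- if (model$convention == "sum") model$width else 1
  pure <- logistic(model$b_str + mult * model$gamma)
  ratios <- tibble(letter = letters,
                   gamma = unname(model$gamma),
                   pure_term = unname(pure),
                   ratio = unname(pure / max(pure)))
  structure(list(ratios = ratios,
                 best_letter = letters[which.max(pure)],
                 convention = model$convention),
            class = "context_preference")
}

#' @export
print.context_preference <- function(x, ...) {
  cat("<context_preference> best letter:", x$best_letter,
      "( convention:", x$convention, ")\n")
  print(x$ratios)
  invisible(x)
}

#' Per-position preferred-context track
#'
#' Ranks every window of the scored records by its bound probability,
#' takes the `top_n` best, averages their annotation-profile slices, and
#' reports per position the letter with the highest average frequency
#' (ties resolved toward the first letter in alphabet order).
#'
#' @param model A fitted [motif_model()].
#' @param records Annotated records (with `seq` and `profile`).
#' @param top_n Number of top windows to average (default 20).
#' @return A list: `track` (string of length w), `mean_profile`
#'   (|A| x w matrix), `windows` (tibble of the top windows).
#' @export
preferred_context_track <- function(model, records, top_n = 20L) {
  records <- as_tibble(records)
  w <- model$width
  all_windows <- list()
  for (t in seq_len(nrow(records))) {
    codes <- encode_rna(records$seq[t], allow_other = TRUE)
    if (length(codes) < w) next
    winS <- window_profile_sums(records$profile[[t]], w, model$convention)
    p <- window_probs_cpp(codes, winS, model$theta, unname(model$gamma),
                          model$b_seq, model$b_str)
    all_windows[[t]] <- tibble(record = t, start = seq_along(p), prob = p)
  }
  wins <- dplyr::bind_rows(all_windows)
  wins <- wins[order(-wins$prob), , drop = FALSE]
  if (nrow(wins) < top_n) {
    message("only ", nrow(wins), " windows available; using all.")
    top_n <- nrow(wins)
  }
  top <- wins[seq_len(top_n), , drop = FALSE]
  na <- n_letters(model$alphabet)
  acc <- matrix(0, na, w, dimnames = list(model$alphabet$letters, NULL))
  for (r in seq_len(nrow(top))) {
    prof <- records$profile[[top$record[r]]]
    acc <- acc + prof[, top$start[r]:(top$start[r] + w - 1L), drop = FALSE]
  }
  mean_profile <- acc / nrow(top)
  track <- paste(model$alphabet$letters[apply(mean_profile, 2L, which.max)],
                 collapse = "")
  list(track = track, mean_profile = mean_profile, windows = top)
}

#' Position frequency matrix for logo rendering
#'
#' Rescales theta so that the optimal site's logit is zero: a scalar c > 0
#' is chosen with c * sum_j max_b theta\[b, j\] + b_seq' = 0 (the shifted
#' bias absorbing the offset), which makes the rescaled sequence term of
#' the optimal site 0.5. Each rescaled column is then converted to base
#' frequencies by a per-column softmax, so columns sum to one. An all-zero
#' theta yields the uniform matrix.
#'
#' @param model A fitted [motif_model()].
#' @return 4 x w numeric matrix (rows A, C, G, U), columns summing to 1.
#' @export
pfm_for_logo <- function(model) {
  theta <- model$theta
  opt <- sum(apply(theta, 2L, max))
  if (opt <= 0) {
    if (all(theta == 0)) {
      message("theta is all zeros; returning the uniform PFM.")
      out <- matrix(0.25, 4L, model$width,
                    dimnames = list(RNA_BASES, NULL))
      return(out)
    }
    scale <- 1
  } else {
    # c solves b_seq + c * sum_j max_b theta[b, j] = 0, so the rescaled
    # optimal site has logit 0 and sequence term exactly 0.5
    scale <- -model$b_seq / opt
    if (!is.finite(scale) || scale <= 0) scale <- 1
  }
  resc <- theta * scale
  pfm <- apply(resc, 2L, function(col) {
    e <- exp(col - max(col))
    e / sum(e)
  })
  rownames(pfm) <- RNA_BASES
  pfm
}

#' Write a PFM as a MEME-minimal motif block
#'
#' @param pfm 4 x w frequency matrix from [pfm_for_logo()].
#' @param path Output file.
#' @param name Motif name written in the block.
#' @export
write_meme_pfm <- function(pfm, path, name = "motif1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGU", "",
               paste0("MOTIF ", name),
               paste0("letter-probability matrix: alength= 4 w= ",
                      ncol(pfm))), con)
  for (j in seq_len(ncol(pfm))) {
    writeLines(paste(sprintf("%.6f", pfm[, j]), collapse = " "), con)
  }
  invisible(path)
}

# ---- broom-style tidiers ---------------------------------------------------

#' Tidy a fitted motif model
#'
#' Long tibble of all parameters: one row per theta entry (term
#' "theta", base, position), per gamma entry (term "gamma", letter) and
#' for each bias.
#'
#' @param x A [motif_model()].
#' @param ... Unused.
#' @export
tidy.motif_model <- function(x, ...) {
  theta_tbl <- tidyr::expand_grid(base = RNA_BASES,
                                  position = seq_len(x$width))
  theta_tbl$term <- "theta"
  theta_tbl$estimate <- as.numeric(x$theta[cbind(
    match(theta_tbl$base, RNA_BASES), theta_tbl$position)])
  gamma_tbl <- tibble(term = "gamma", base = names(x$gamma),
                      position = NA_integer_, estimate = unname(x$gamma))
  bias_tbl <- tibble(term = c("b_seq", "b_str"), base = NA_character_,
                     position = NA_integer_,
                     estimate = c(x$b_seq, x$b_str))
  dplyr::bind_rows(theta_tbl[, c("term", "base", "position", "estimate")],
                   gamma_tbl, bias_tbl)
}

#' @export
glance.motif_model <- function(x, ...) {
  tibble(width = x$width,
         alphabet = paste(x$alphabet$letters, collapse = ""),
         convention = x$convention,
         best_context = context_preference_ratios(x)$best_letter)
}

#' Tidy a motif fit (one row per scanned candidate)
#'
#' @param x A `motif_fit` from [fit_motif()].
#' @param ... Unused.
#' @export
tidy.motif_fit <- function(x, ...) {
  out <- x$results
  out$slope <- vapply(out$map, function(m) m$slope, numeric(1))
  out$intercept <- vapply(out$map, function(m) m$intercept, numeric(1))
  out[, c("width", "subset", "objective", "converged", "train_aucpr",
          "slope", "intercept", "selected")]
}

#' @export
glance.motif_fit <- function(x, ...) {
  sel <- x$results[x$results$selected, ]
  tibble(width = sel$width, subset = sel$subset,
         objective = sel$objective, train_aucpr = sel$train_aucpr,
         converged = sel$converged,
         lambda_reg = x$config$lambda_reg,
         best_context = context_preference_ratios(x$model)$best_letter)
}

#' @export
tidy.pr_result <- function(x, ...) x$curve

#' @export
glance.pr_result <- function(x, ...) {
  tibble(auc_pr = x$auc_pr, n_pos = x$n_pos, n_neg = x$n_neg)
}

# ---- plots -----------------------------------------------------------------

#' @export
autoplot.pr_result <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("AUC-PR = %.3f", object$auc_pr),
                  x = "Recall", y = "Precision") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.context_preference <- function(object, ...) {
  ggplot2::ggplot(object$ratios,
                  ggplot2::aes(x = .data$letter, y = .data$ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Structural context", y = "Relative preference",
                  title = paste("Preferred context:", object$best_letter)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.motif_model <- function(object, ...) {
  pfm <- pfm_for_logo(object)
  df <- tidyr::expand_grid(base = factor(RNA_BASES, levels = rev(RNA_BASES)),
                           position = seq_len(ncol(pfm)))
  df$freq <- as.numeric(pfm[cbind(match(as.character(df$base), RNA_BASES),
                                  df$position)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$base,
                                   fill = .data$freq)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "Motif position", y = NULL, fill = "Frequency") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.motif_fit <- function(object, ...) {
  df <- tidy.motif_fit(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$width, y = .data$train_aucpr,
                                   colour = .data$subset)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$selected), size = 3) +
    ggplot2::labs(x = "Motif width", y = "Training AUC-PR",
                  colour = "Subset", shape = "Selected") +
    ggplot2::theme_minimal()
}
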