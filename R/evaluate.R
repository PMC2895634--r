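#' Positive-labeling rules
#'
#' The evaluation protocol labels the right tail of the affinity
#' distribution as positive and everything below the median affinity as
#' negative; records in between are "other" and excluded from
#' precision-recall scoring. Three rules describe the right tail:
#' a top quantile (selects `round((1 - q) * n)` records, ties broken by
#' record order), a fixed count, or an absolute affinity threshold
#' (inclusive, so affinity ties at the cutoff all become positive).
#'
#' @param q Quantile in (0, 1), e.g. 0.995 keeps the top 0.5%.
#' @return A rule object for [label_records()].
#' @export
positive_top_quantile <- function(q = 0.995) {
  stopifnot(q > 0, q < 1)
  structure(list(type = "quantile", q = q), class = "positive_rule")
}

#' @rdname positive_top_quantile
#' @param n Number of top-affinity records labeled positive.
#' @export
positive_top_n <- function(n) {
  stopifnot(n >= 1)
  structure(list(type = "top_n", n = as.integer(n)), class = "positive_rule")
}

#' @rdname positive_top_quantile
#' @param value Absolute affinity cutoff (records with affinity >= value
#'   are positive).
#' @export
positive_threshold <- function(value) {
  structure(list(type = "threshold", value = value), class = "positive_rule")
}

#' Label records as positive / negative / other
#'
#' Positives come from the right tail of the affinity distribution per the
#' rule; negatives are records with affinity strictly below the median
#' affinity of the set; everything else is "other". The rule must not
#' reach below the median (the two sets would overlap).
#'
#' @param records Data frame with an `affinity` column.
#' @param positive_rule A rule from [positive_top_quantile()] and friends.
#' @return The records tibble with a `label` factor column added.
#' @export
label_records <- function(records,
                          positive_rule = positive_top_quantile(0.995)) {
  records <- as_tibble(records)
  y <- records$affinity
  if (is.null(y)) abort("records need an `affinity` column.")
  if (length(y) < 3L) abort("need at least 3 records to label.")
  if (diff(range(y)) == 0) abort("degenerate affinity distribution (all equal).")
  med <- median(y)
  rule <- positive_rule
  if (rule$type == "threshold") {
    if (rule$value <= med) {
      abort("positive cutoff is at or below the median: rules would overlap.")
    }
    pos <- y >= rule$value
  } else {
    k <- if (rule$type == "top_n") rule$n
         else as.integer(round((1 - rule$q) * length(y)))
    k <- max(k, 1L)
    # ties at the boundary broken by record order
    ord <- rank(-y, ties.method = "first")
    pos <- ord <= k
    if (min(y[pos]) <= med) {
      abort("positive cutoff is at or below the median: rules would overlap.")
    }
  }
  label <- rep("other", length(y))
  label[y < med] <- "negative"
  label[pos] <- "positive"
  records$label <- factor(label, levels = c("positive", "negative", "other"))
  records
}

#' Area under the precision-recall curve (average precision)
#'
#' Computed as the mean, over positives taken in descending-score order, of
#' the precision at each positive's rank. Tied scores are handled as a
#' group: within a tied block the expected precision under a random
#' ordering of the block is used, so the result does not depend on record
#' order.
#'
#' @param scores Numeric scores (larger = more confidently positive).
#' @param labels Logical (or coercible) vector, TRUE for positives.
#' @return A `pr_result` list: `auc_pr`, `curve` (tibble of recall /
#'   precision at each distinct threshold), `n_pos`, `n_neg`.
#' @examples
#' average_precision(c(0.9, 0.8, 0.7, 0.6), c(TRUE, FALSE, TRUE, FALSE))$auc_pr
#' @export
average_precision <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) abort("length mismatch.")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    abort("need at least one positive and one negative.")
  }
  ord <- order(-scores)
  s <- scores[ord]
  l <- labels[ord]
  blocks <- rle(s)
  ap <- 0
  R <- 0L   # records above the current block
  P <- 0L   # positives above the current block
  curve <- vector("list", length(blocks$lengths))
  pos_idx <- 0L
  for (b in seq_along(blocks$lengths)) {
    g <- blocks$lengths[b]
    m <- sum(l[pos_idx + seq_len(g)])
    pos_idx <- pos_idx + g
    if (m > 0L) {
      if (g == 1L) {
        ap <- ap + (P + 1) / (R + 1)
      } else {
        # expected sum of precisions at the positives' ranks when the block
        # is ordered uniformly at random
        t <- seq_len(g)
        exp_prec <- (P + 1 + (t - 1) * (m - 1) / (g - 1)) / (R + t)
        ap <- ap + (m / g) * sum(exp_prec)
      }
    }
    R <- R + g
    P <- P + m
    curve[[b]] <- c(recall = P / n_pos, precision = P / R)
  }
  curve <- as_tibble(do.call(rbind, curve))
  structure(list(auc_pr = ap / n_pos, curve = curve,
                 n_pos = n_pos, n_neg = n_neg),
            class = "pr_result")
}

#' @export
print.pr_result <- function(x, ...) {
  cat(sprintf("<pr_result> AUC-PR %.4f (%d positives, %d negatives)\n",
              x$auc_pr, x$n_pos, x$n_neg))
  invisible(x)
}

#' Two-fold Set A / Set B cross-validation
#'
#' Trains on one designed half-pool and tests on the other, then swaps.
#' Model selection (width, subset) uses training-fold labels only; the
#' test AUC-PR is computed on the test fold's positives and negatives.
#'
#' @param pool_a,pool_b Disjoint annotated record sets with affinities.
#' @param config A [training_config()].
#' @return A `crossfold_result`: tibble `folds` (fold, width, subset,
#'   train_aucpr, test_aucpr), `mean_test_aucpr` (the headline statistic),
#'   and the two fitted `motif_fit` objects.
#' @export
crossfold <- function(pool_a, pool_b, config = training_config()) {
  folds <- list(list(name = "A->B", train = pool_a, test = pool_b),
                list(name = "B->A", train = pool_b, test = pool_a))
  rows <- list()
  fits <- list()
  for (f in folds) {
    fit <- fit_motif(f$train, config)
    test_aucpr <- evaluate_fit(fit, f$test, config$positive_rule)
    sel <- fit$results[fit$results$selected, ]
    rows[[f$name]] <- tibble(fold = f$name, width = sel$width,
                             subset = sel$subset,
                             train_aucpr = sel$train_aucpr,
                             test_aucpr = test_aucpr)
    fits[[f$name]] <- fit
  }
  folds_tbl <- dplyr::bind_rows(rows)
  structure(list(folds = folds_tbl,
                 mean_test_aucpr = mean(folds_tbl$test_aucpr),
                 fits = fits),
            class = "crossfold_result")
}

#' AUC-PR of a fitted model on a labeled test set
#'
#' Labels the test records, drops the "other" class, scores the remaining
#' records under the fit's selected model and returns the AUC-PR.
#'
#' @param fit A `motif_fit` from [fit_motif()].
#' @param test_records Annotated test records with affinities.
#' @param positive_rule Labeling rule (see [label_records()]).
#' @return Test AUC-PR (scalar).
#' @export
evaluate_fit <- function(fit, test_records,
                         positive_rule = positive_top_quantile(0.995)) {
  labeled <- label_records(test_records, positive_rule)
  keep <- labeled$label != "other"
  scored <- score_records(labeled[keep, ], fit$model)
  average_precision(scored$score, scored$label == "positive")$auc_pr
}

#' @export
print.crossfold_result <- function(x, ...) {
  print(x$folds)
  cat(sprintf("mean test AUC-PR: %.4f\n", x$mean_test_aucpr))
  invisible(x)
}

#' Bootstrap comparison of scoring functions
#'
#' Resamples the labeled test records with replacement `n_boot` times,
#' computes each scorer's AUC-PR on every replicate, and compares scorers
#' pairwise: win/loss counts, a paired Wilcoxon signed-rank test across
#' replicates, and a percentile 95% confidence interval of the AUC-PR
#' difference. Replicates that draw a single class are redrawn (to a retry
#' cap). Bit-reproducible for a fixed seed.
#'
#' @param records Labeled test records (see [label_records()]); rows with
#'   label "other" are dropped.
#' @param scorers Named list of functions, each taking the records tibble
#'   and returning one numeric score per row.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return A `bootstrap_comparison`: tibble `pairs` with columns scorer_a,
#'   scorer_b, wins_a, wins_b, p_wilcoxon, ci_lower, ci_upper,
#'   mean_diff; and matrix `aucpr` (n_boot x scorers).
#' @export
bootstrap_compare <- function(records, scorers, n_boot = 1000L, seed = 1L) {
  records <- as_tibble(records)
  if (!"label" %in% names(records)) abort("records must be labeled first.")
  records <- records[records$label != "other", , drop = FALSE]
  is_pos <- records$label == "positive"
  if (length(scorers) < 2L || is.null(names(scorers))) {
    abort("`scorers` must be a named list of at least two functions.")
  }
  score_mat <- vapply(scorers, function(f) as.numeric(f(records)),
                      numeric(nrow(records)))
  n <- nrow(records)
  aucpr <- matrix(NA_real_, n_boot, length(scorers),
                  dimnames = list(NULL, names(scorers)))
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- NULL
      for (try in 1:100) {
        cand <- sample.int(n, n, replace = TRUE)
        if (any(is_pos[cand]) && any(!is_pos[cand])) { idx <- cand; break }
      }
      if (is.null(idx)) abort("bootstrap retry cap reached (degenerate labels).")
      for (s in seq_along(scorers)) {
        aucpr[b, s] <- average_precision(score_mat[idx, s],
                                         is_pos[idx])$auc_pr
      }
    }
  })
  combos <- utils::combn(names(scorers), 2L)
  pairs <- lapply(seq_len(ncol(combos)), function(k) {
    a <- combos[1, k]; b <- combos[2, k]
    d <- aucpr[, a] - aucpr[, b]
    p <- if (all(d == 0)) 1.0 else
      suppressWarnings(wilcox.test(aucpr[, a], aucpr[, b],
                                   paired = TRUE, exact = FALSE)$p.value)
    ci <- unname(quantile(d, c(0.025, 0.975), type = 7))
    tibble(scorer_a = a, scorer_b = b,
           wins_a = sum(d > 0), wins_b = sum(d < 0),
           p_wilcoxon = p, ci_lower = ci[1], ci_upper = ci[2],
           mean_diff = mean(d))
  })
  structure(list(pairs = dplyr::bind_rows(pairs), aucpr = aucpr,
                 n_boot = n_boot, seed = seed),
            class = "bootstrap_comparison")
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  print(x$pairs)
  invisible(x)
}

#' Structure-naive ablation
#'
#' Trains the full-alphabet model and a single-letter-alphabet variant (all
#' bases share one structural annotation, so the structure term is a
#' constant per width) under the identical protocol, and evaluates both on
#' the test set. The AUC-PR gap measures the predictive value of
#' structural context.
#'
#' @param train_records,test_records Annotated record sets. The test
#'   records must carry profiles for the full alphabet; single-letter
#'   profiles are derived internally.
#' @param config A [training_config()] (its alphabet is used for the full
#'   variant).
#' @return An `ablation_result`: `fit_full`, `fit_single` (motif_fit
#'   objects), `aucpr_full`, `aucpr_single`, `gap`.
#' @export
ablation_single_letter <- function(train_records, test_records,
                                   config = training_config()) {
  fit_full <- fit_motif(train_records, config)
  cfg1 <- config
  cfg1$alphabet <- single_letter_alphabet()
  train1 <- replace_profiles_single(train_records)
  test1 <- replace_profiles_single(test_records)
  fit_single <- fit_motif(train1, cfg1)
  aucpr_full <- evaluate_fit(fit_full, test_records, config$positive_rule)
  aucpr_single <- evaluate_fit(fit_single, test1, config$positive_rule)
  structure(list(fit_full = fit_full, fit_single = fit_single,
                 aucpr_full = aucpr_full, aucpr_single = aucpr_single,
                 gap = aucpr_full - aucpr_single),
            class = "ablation_result")
}

replace_profiles_single <- function(records) {
  alpha1 <- single_letter_alphabet()
  records <- as_tibble(records)
  records$profile <- lapply(records$profile, function(p) {
    m <- matrix(1, 1L, ncol(p), dimnames = list(alpha1$letters, NULL))
    attr(m, "alphabet") <- alpha1
    m
  })
  records
}

#' @export
print.ablation_result <- function(x, ...) {
  cat(sprintf("<ablation_result> full %.4f vs single-letter %.4f (gap %+.4f)\n",
              x$aucpr_full, x$aucpr_single, x$gap))
  invisible(x)
}

# ---- fully-specified k-mer baseline ---------------------------------------

#' Fully specified k-mer affinity baseline
#'
#' Estimates a separate affinity for every k-mer as the trimmed mean of the
#' affinities of the (weakly structured) training sequences containing it.
#' K-mers never observed fall back to the global median affinity. Scoring a
#' sequence takes the mean of its windows' table values.
#'
#' @param records Training records with `seq` and `affinity`; conventionally
#'   restricted to the weakly structured group first.
#' @param k K-mer length (default 7).
#' @param trim Fraction trimmed from each tail of the per-k-mer affinity
#'   list (default 0.05).
#' @return A tibble with columns `kmer`, `affinity`, `n_seqs`,
#'   `observed`; attribute `k` records the width.
#' @export
kmer_baseline_train <- function(records, k = 7L, trim = 0.05) {
  records <- as_tibble(records)
  stopifnot(k >= 1L)
  # collect, per k-mer, the affinities of sequences containing it
  acc <- new.env(parent = emptyenv())
  for (t in seq_len(nrow(records))) {
    s <- records$seq[t]
    n <- nchar(s)
    if (n < k) next
    kmers <- unique(substring(s, 1:(n - k + 1L), k:n))
    for (km in kmers) {
      acc[[km]] <- c(acc[[km]], records$affinity[t])
    }
  }
  all_kmers <- sort(do.call(paste0, expand.grid(rep(list(RNA_BASES), k),
                                                stringsAsFactors = FALSE)[
    , k:1, drop = FALSE]))
  global_med <- median(records$affinity)
  vals <- vapply(all_kmers, function(km) {
    x <- acc[[km]]
    if (is.null(x)) return(NA_real_)
    mean(x, trim = trim)
  }, numeric(1))
  nseq <- vapply(all_kmers, function(km) length(acc[[km]]), integer(1))
  observed <- !is.na(vals)
  if (any(!observed)) {
    message(sum(!observed), " of ", length(all_kmers),
            " k-mers unobserved; assigned the global median affinity.")
  }
  vals[!observed] <- global_med
  out <- tibble(kmer = all_kmers, affinity = unname(vals),
                n_seqs = unname(nseq), observed = unname(observed))
  attr(out, "k") <- as.integer(k)
  out
}

#' @rdname kmer_baseline_train
#' @param seq RNA string of length >= k.
#' @param table Result of [kmer_baseline_train()].
#' @export
kmer_baseline_score <- function(seq, table) {
  k <- attr(table, "k")
  n <- nchar(seq)
  if (n < k) abort("sequence shorter than k.")
  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  vals <- table$affinity[match(kmers, table$kmer)]
  if (anyNA(vals)) vals[is.na(vals)] <- median(table$affinity)
  mean(vals)
}
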