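#' Training configuration
#'
#' Bundles every tunable of the fitting protocol: the motif widths scanned,
#' restarts per width, the L2 regularization constant, the half-width of
#' the uniform initialization interval, the lower bound keeping the
#' affinity-map slope positive, optimizer stopping rules, the base seed all
#' restart seeds derive from, which training subsets to fit (the full set
#' and/or only the weakly structured sequences), and the labeling rule used
#' for model selection.
#'
#' @param widths Integer vector of motif widths (sorted ascending).
#' @param restarts_per_width Restarts per width (>= 1; default 10).
#' @param lambda_reg L2 penalty constant on theta, gamma and both biases
#'   (default 0.01); the slope and intercept are not penalized.
#' @param init_range Initial parameters are drawn uniformly from
#'   \[-init_range, init_range\] (default 0.05).
#' @param slope_lower_bound Box constraint keeping the slope positive.
#' @param pgtol,maxit L-BFGS-B stopping rules: projected-gradient infinity
#'   norm tolerance and iteration cap.
#' @param factr L-BFGS-B relative objective-decrease stop (in units of
#'   machine epsilon).
#' @param base_seed Integer; restart seeds are derived as
#'   `base_seed + width * 1000 + restart_index`.
#' @param subsets Character vector out of `"full"`, `"weak"`; each subset
#'   gets its own width scan.
#' @param alphabet Annotation alphabet the fitted model uses.
#' @param convention Structure-term convention, `"sum"` or `"mean"`.
#' @param positive_rule Labeling rule for selection, see [label_records()].
#' @return A `training_config` list.
#' @export
training_config <- function(widths = 4:12, restarts_per_width = 10L,
                            lambda_reg = 0.01, init_range = 0.05,
                            slope_lower_bound = 1e-6, pgtol = 1e-6,
                            maxit = 500L, factr = 1e9, base_seed = 1L,
                            subsets = "full",
                            alphabet = plum_alphabet(),
                            convention = c("sum", "mean"),
                            positive_rule = positive_top_quantile(0.995)) {
  convention <- match.arg(convention)
  widths <- sort(unique(as.integer(widths)))
  if (any(widths < 1L)) abort("widths must be positive.")
  if (restarts_per_width < 1L) abort("restarts_per_width must be >= 1.")
  if (lambda_reg < 0) abort("lambda_reg must be >= 0.")
  if (slope_lower_bound <= 0) abort("slope_lower_bound must be > 0.")
  bad <- setdiff(subsets, c("full", "weak"))
  if (length(bad)) abort("subsets must be 'full' and/or 'weak'.")
  structure(list(widths = widths,
                 restarts_per_width = as.integer(restarts_per_width),
                 lambda_reg = lambda_reg, init_range = init_range,
                 slope_lower_bound = slope_lower_bound, pgtol = pgtol,
                 maxit = as.integer(maxit), factr = factr,
                 base_seed = as.integer(base_seed),
                 subsets = subsets, alphabet = alphabet,
                 convention = convention, positive_rule = positive_rule),
            class = "training_config")
}

# ---- parameter packing -----------------------------------------------------

pack_params <- function(p) {
  c(as.numeric(p$theta), p$gamma, p$b_seq, p$b_str, p$slope, p$intercept)
}

unpack_params <- function(par, width, na) {
  nt <- 4L * width
  list(theta = matrix(par[1:nt], 4L, width),
       gamma = par[(nt + 1L):(nt + na)],
       b_seq = par[nt + na + 1L], b_str = par[nt + na + 2L],
       slope = par[nt + na + 3L], intercept = par[nt + na + 4L])
}

#' Regularized least-squares objective
#'
#' Sum over records of (slope * N + intercept - affinity)^2 plus
#' lambda_reg * (||theta||^2 + ||gamma||^2 + b_seq^2 + b_str^2). The slope
#' and intercept are excluded from the penalty.
#'
#' @param records Data frame with `seq`, `profile` and `affinity` columns.
#' @param model A [motif_model()].
#' @param map An [affinity_map()].
#' @param lambda_reg Penalty constant.
#' @return The objective value (scalar).
#' @export
motif_objective <- function(records, model, map, lambda_reg = 0.01) {
  records <- as_tibble(records)
  if (!nrow(records)) abort("`records` is empty.")
  enc <- encode_records(records, model$width, model$convention,
                        model$alphabet)
  objective_grad_cpp(enc$seqs, enc$winS, records$affinity, model$theta,
                     unname(model$gamma), model$b_seq, model$b_str,
                     map$slope, map$intercept, lambda_reg,
                     FALSE)$value
}

#' Analytic gradient of the objective
#'
#' Chain-rule gradient through the linear affinity map, the noisy-OR, the
#' window product and both logistic terms.
#'
#' @inheritParams motif_objective
#' @return Named list with components `theta` (4 x w), `gamma`, `b_seq`,
#'   `b_str`, `slope`, `intercept`.
#' @export
motif_gradient <- function(records, model, map, lambda_reg = 0.01) {
  records <- as_tibble(records)
  enc <- encode_records(records, model$width, model$convention,
                        model$alphabet)
  g <- objective_grad_cpp(enc$seqs, enc$winS, records$affinity, model$theta,
                          unname(model$gamma), model$b_seq, model$b_str,
                          map$slope, map$intercept, lambda_reg, TRUE)
  list(theta = g$g_theta, gamma = g$g_gamma, b_seq = g$g_bseq,
       b_str = g$g_bstr, slope = g$g_slope, intercept = g$g_intercept)
}

# ---- initialization --------------------------------------------------------

#' Restart initializations for one width
#'
#' When a previous (smaller-width) optimum is available, the first two
#' initializations reuse its theta padded with a zero column on the left
#' and on the right respectively; all remaining theta entries and, in every
#' initialization, gamma, both biases, the slope and the intercept are
#' sampled uniformly from \[-init_range, init_range\] (the slope is then
#' clamped to the lower bound). Reproducible from the config's base seed.
#'
#' @param width Motif width.
#' @param parent_theta Previous best theta (4 x (width - 1)) or NULL.
#' @param config A [training_config()].
#' @return List of parameter lists (theta, gamma, b_seq, b_str, slope,
#'   intercept).
#' @export
initial_parameter_sets <- function(width, parent_theta = NULL, config) {
  na <- n_letters(config$alphabet)
  r <- config$init_range
  n_inits <- config$restarts_per_width
  lapply(seq_len(n_inits), function(k) {
    withr::with_seed(derive_seed(config$base_seed, width * 1000L + k), {
      theta <- matrix(runif(4L * width, -r, r), 4L, width)
      if (!is.null(parent_theta) && k <= 2L) {
        zero <- matrix(0, 4L, 1L)
        theta <- if (k == 1L) cbind(zero, parent_theta)
                 else cbind(parent_theta, zero)
      }
      list(theta = theta,
           gamma = runif(na, -r, r),
           b_seq = runif(1, -r, r), b_str = runif(1, -r, r),
           slope = max(runif(1, -r, r), config$slope_lower_bound),
           intercept = runif(1, -r, r))
    })
  })
}

# ---- fitting ---------------------------------------------------------------

# flat-encoded fast path shared by fit_single and fit_scan; `enc` carries
# theta_idx, winS_flat, rec_nwin (see encode_flat_records)
fit_single_enc <- function(enc, y, width, init, config, restart = NA_integer_,
                           subset = "full") {
  na <- n_letters(config$alphabet)
  par0 <- pack_params(init)
  npar <- length(par0)
  lower <- rep(-Inf, npar)
  lower[npar - 1L] <- config$slope_lower_bound  # slope box constraint
  cache <- new.env(parent = emptyenv())
  # L-BFGS-B requests fn and gr at the same point; compute both once
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) {
      return(cache$res)
    }
    res <- objective_grad_flat_cpp(enc$theta_idx, enc$winS_flat,
                                   enc$rec_nwin, y,
                                   par[1:(4L * width)],
                                   par[(4L * width + 1L):(4L * width + na)],
                                   par[npar - 3L], par[npar - 2L],
                                   par[npar - 1L], par[npar],
                                   config$lambda_reg, TRUE)
    cache$par <- par
    cache$res <- res
    res
  }
  fn <- function(par) evaluate(par)$value
  gr <- function(par) {
    g <- evaluate(par)
    c(g$g_theta, g$g_gamma, g$g_bseq, g$g_bstr, g$g_slope, g$g_intercept)
  }
  opt <- tryCatch(
    optim(par0, fn, gr, method = "L-BFGS-B", lower = lower,
          control = list(maxit = config$maxit, pgtol = config$pgtol,
                         factr = config$factr, lmm = 10)),
    error = function(e) NULL
  )
  if (is.null(opt)) {
    p <- init
    value <- fn(par0)
    converged <- FALSE
  } else {
    p <- unpack_params(opt$par, width, na)
    value <- opt$value
    converged <- opt$convergence == 0L
  }
  list(model = motif_model(p$theta, p$gamma, p$b_seq, p$b_str,
                           alphabet = config$alphabet,
                           convention = config$convention),
       map = affinity_map(max(p$slope, config$slope_lower_bound),
                          p$intercept),
       objective = value, converged = converged,
       provenance = list(width = width, restart = restart, subset = subset,
                         base_seed = config$base_seed))
}

#' Fit the model once from a given initialization
#'
#' Runs box-constrained L-BFGS-B from `init` (slope bounded below, all
#' other parameters free). An optimizer failure is reported as a
#' non-converged result, never an exception.
#'
#' @param records Annotated records with `seq`, `profile`, `affinity`.
#' @param width Motif width.
#' @param init Parameter list as produced by [initial_parameter_sets()].
#' @param config A [training_config()].
#' @return A fit-result list: `model`, `map`, `objective`, `converged`,
#'   `provenance`.
#' @export
fit_single <- function(records, width, init, config = training_config()) {
  records <- as_tibble(records)
  codes <- lapply(records$seq, encode_rna, allow_other = TRUE)
  enc <- encode_flat_records(codes, records$profile, width, config)
  fit_single_enc(enc, records$affinity, width, init, config)
}

# concatenate all windows of all records into flat arrays for the optimizer
encode_flat_records <- function(codes, profiles, width, config) {
  short <- which(vapply(codes, length, integer(1)) < width)
  if (length(short)) {
    abort(paste0("records shorter than width ", width, ": ",
                 paste(head(short, 5), collapse = ", ")))
  }
  flat <- encode_windows_cpp(codes, width)
  winS <- lapply(profiles, window_profile_sums, width = width,
                 convention = config$convention)
  flat$winS_flat <- do.call(cbind, winS)
  flat
}

subset_rows <- function(records, subset) {
  if (subset == "full") return(seq_len(nrow(records)))
  if (!"group" %in% names(records)) {
    abort("subset 'weak' requested but records carry no `group` column.")
  }
  which(records$group == "weak")
}

#' Width scan with multi-restart fitting
#'
#' For each requested subset and each width in ascending order, runs all
#' restarts and keeps the lowest-objective fit; the winning theta is fed
#' forward as the zero-column-padding parent for the next width. Returns
#' one best-of-restarts row per width x subset.
#'
#' @inheritParams fit_single
#' @param config A [training_config()].
#' @return A tibble with columns `width`, `subset`, `objective`,
#'   `converged`, `n_restarts`, and list-columns `model`, `map`.
#' @export
fit_scan <- function(records, config = training_config()) {
  records <- as_tibble(records)
  if (!nrow(records)) abort("`records` is empty.")
  out <- list()
  for (subset in config$subsets) {
    rows <- subset_rows(records, subset)
    sub <- records[rows, , drop = FALSE]
    codes <- lapply(sub$seq, encode_rna, allow_other = TRUE)
    parent_theta <- NULL
    for (width in config$widths) {
      enc <- encode_flat_records(codes, sub$profile, width, config)
      inits <- initial_parameter_sets(width, parent_theta, config)
      fits <- lapply(seq_along(inits), function(k) {
        fit_single_enc(enc, sub$affinity, width, inits[[k]], config,
                       restart = k, subset = subset)
      })
      objs <- vapply(fits, function(f) f$objective, numeric(1))
      if (all(!is.finite(objs))) {
        warn(paste0("all restarts failed for width ", width, ", subset ",
                    subset, "; width skipped."))
        next
      }
      best <- fits[[which.min(objs)]]
      parent_theta <- best$model$theta
      out[[length(out) + 1L]] <- tibble(
        width = width, subset = subset, objective = best$objective,
        converged = best$converged, n_restarts = length(inits),
        model = list(best$model), map = list(best$map)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Select the best model by training-set classification
#'
#' Labels the training records (positives from the right tail of the
#' affinity distribution, negatives below the median), scores them under
#' every candidate, and returns the candidate with the highest training
#' AUC-PR. Ties break toward the smaller width, then the full subset.
#'
#' @param scan Result of [fit_scan()].
#' @param records The training records the scan was fit on.
#' @param positive_rule Labeling rule (see [label_records()]).
#' @return The `scan` tibble with a `train_aucpr` column and a logical
#'   `selected` column (exactly one TRUE row).
#' @export
select_model <- function(scan, records,
                         positive_rule = positive_top_quantile(0.995)) {
  if (!nrow(scan)) abort("empty candidate list.")
  labeled <- label_records(records, positive_rule)
  keep <- labeled$label != "other"
  scan$train_aucpr <- vapply(seq_len(nrow(scan)), function(i) {
    scored <- score_records(labeled[keep, ], scan$model[[i]])
    average_precision(scored$score, scored$label == "positive")$auc_pr
  }, numeric(1))
  ord <- order(-scan$train_aucpr, scan$width,
               match(scan$subset, c("full", "weak")))
  scan$selected <- FALSE
  scan$selected[ord[1]] <- TRUE
  scan
}

#' Fit, scan and select a motif model
#'
#' One-call training front end: runs the width scan with restarts on the
#' training records and selects the final model by training AUC-PR.
#'
#' @inheritParams fit_scan
#' @return A `motif_fit` object: list with `results` (the scored scan
#'   tibble), `model`, `map` (the selected candidate) and `config`.
#' @examples
#' \dontrun{
#' pool <- simulate_pool(pool_design(n_stemloop = 200, n_weak = 200), seed = 1)
#' fit <- fit_motif(pool$records, training_config(widths = 5:7,
#'                                                restarts_per_width = 3))
#' glance(fit)
#' }
#' @export
fit_motif <- function(records, config = training_config()) {
  scan <- fit_scan(records, config)
  scan <- select_model(scan, records, config$positive_rule)
  sel <- which(scan$selected)
  structure(list(results = scan, model = scan$model[[sel]],
                 map = scan$map[[sel]], config = config),
            class = "motif_fit")
}

#' @export
print.motif_fit <- function(x, ...) {
  sel <- x$results[x$results$selected, ]
  cat("<motif_fit>", nrow(x$results), "candidates; selected width",
      sel$width, "subset", sel$subset,
      sprintf("(train AUC-PR %.3f)", sel$train_aucpr), "\n")
  invisible(x)
}
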