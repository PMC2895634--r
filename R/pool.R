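#' Synthetic RNAcompete-style pool design
#'
#' Describes a reduced-scale designed RNA pool: a stem-loop group (random
#' flanks around a 10-bp Watson-Crick stem enclosing a loop, every loop
#' length in the range represented) and a weakly structured group (random
#' sequences accepted only when their mean ensemble pairing probability
#' stays below a threshold). No two pool sequences share a common
#' substring longer than `max_shared` nucleotides (enforced by hashing all
#' (max_shared + 1)-mers and regenerating on collision).
#'
#' @param n_stemloop,n_weak Group sizes (defaults 2000 + 2000).
#' @param length_range Sequence length range in nt (default 29-38).
#' @param stem_length Stem length in bp (default 10).
#' @param loop_range Loop length range for unplanted stem-loops (default
#'   3-7; planted loops may extend to 8 to host the motif).
#' @param weak_threshold Acceptance cutoff on mean per-base pairing
#'   probability for the weak group (default 0.3).
#' @param weak_composition Base sampling probabilities (A, C, G, U) for
#'   weak-group candidates. The default is purposely depleted in G/U:
#'   like the real designed pools, weakly structured sequences are drawn
#'   from a composition that avoids self-complementarity, otherwise
#'   almost no random draw passes the pairing filter.
#' @param weak_samples Ensemble sample count used by the acceptance check
#'   (default 100; the final annotation uses the full sample count).
#' @param max_shared Maximum common substring length between any two pool
#'   sequences (default 12).
#' @param plant_fraction Fraction of each group carrying the ground-truth
#'   consensus (default 0.15): at the 5' end of the loop for stem-loops,
#'   at a random position for weak sequences.
#' @param t7_prefix If TRUE, every sequence starts with the fixed 5'-AGA /
#'   AGG transcription-initiation prefix, reproducing the pool-design
#'   artifact that can confound purely sequence-driven models (default
#'   FALSE).
#' @return A `pool_design` list.
#' @export
pool_design <- function(n_stemloop = 2000L, n_weak = 2000L,
                        length_range = c(29L, 38L), stem_length = 10L,
                        loop_range = c(3L, 7L), weak_threshold = 0.3,
                        weak_composition = c(A = 0.4, C = 0.4, G = 0.1,
                                             U = 0.1),
                        weak_samples = 100L, max_shared = 12L,
                        plant_fraction = 0.15, t7_prefix = FALSE) {
  structure(list(n_stemloop = as.integer(n_stemloop),
                 n_weak = as.integer(n_weak),
                 length_range = as.integer(length_range),
                 stem_length = as.integer(stem_length),
                 loop_range = as.integer(loop_range),
                 weak_threshold = weak_threshold,
                 weak_composition = weak_composition,
                 weak_samples = as.integer(weak_samples),
                 max_shared = as.integer(max_shared),
                 plant_fraction = plant_fraction,
                 t7_prefix = t7_prefix),
            class = "pool_design")
}

#' Ground truth for synthetic affinities
#'
#' The generative twin of the motif model: a known motif model plus
#' affinity map, and a Gaussian noise level on the affinity scale. The
#' default truth is a width-6 consensus recognized sharply (a single
#' mismatch drops the sequence term from ~0.95 to ~0.05) and preferred in
#' hairpin loops (gamma maximal for L); `noise_sd = NULL` means 0.1 times
#' the noiseless affinity range, computed at generation time.
#'
#' @param model True [motif_model()].
#' @param map True [affinity_map()].
#' @param noise_sd Gaussian noise standard deviation on the affinity
#'   scale, or NULL for 0.1 x the noiseless affinity range.
#' @param consensus The consensus sequence planted by the pool generator.
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(model = NULL, map = affinity_map(1, 0),
                         noise_sd = NULL, consensus = "CACAUC") {
  if (is.null(model)) {
    w <- nchar(consensus)
    theta <- matrix(0, 4, w, dimnames = list(RNA_BASES, NULL))
    codes <- encode_rna(consensus)
    theta[cbind(codes + 1L, seq_len(w))] <- 6
    model <- motif_model(theta, gamma = c(P = -2, L = 1.5, U = 0.3, M = 0),
                         b_seq = -6 * w + 3, b_str = -6,
                         alphabet = plum_alphabet())
  }
  structure(list(model = model, map = map, noise_sd = noise_sd,
                 consensus = toupper(consensus)),
            class = "ground_truth")
}

random_rna <- function(n, prob = NULL) {
  paste(sample(RNA_BASES, n, replace = TRUE, prob = prob), collapse = "")
}

rna_complement <- function(seq) {
  chartr("ACGU", "UGCA", seq)
}

reverse_chars <- function(seq) {
  paste(rev(strsplit(seq, "")[[1]]), collapse = "")
}

# substring-uniqueness registry over (max_shared + 1)-mers
new_kmer_registry <- function(k) {
  structure(list(env = new.env(parent = emptyenv()), k = k),
            class = "kmer_registry")
}

registry_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

registry_ok <- function(reg, seq) {
  !any(vapply(registry_kmers(seq, reg$k),
              function(km) !is.null(reg$env[[km]]), logical(1)))
}

registry_add <- function(reg, seq) {
  for (km in registry_kmers(seq, reg$k)) reg$env[[km]] <- TRUE
  invisible(reg)
}

# assemble one stem-loop sequence; returns NA-like NULL on geometry misfit
build_stemloop <- function(design, loop_seq) {
  loop_len <- nchar(loop_seq)
  lr <- design$length_range
  core <- 2L * design$stem_length + loop_len
  prefix_len <- if (design$t7_prefix) 3L else 0L
  min_total <- max(lr[1], core + prefix_len)
  if (min_total > lr[2]) abort("stem-loop geometry does not fit length range.")
  total <- sample(min_total:lr[2], 1L)
  flank_total <- total - core - prefix_len
  f5 <- if (flank_total > 0) sample(0:flank_total, 1L) else 0L
  f3 <- flank_total - f5
  stem5 <- random_rna(design$stem_length)
  stem3 <- reverse_chars(rna_complement(stem5))
  prefix <- if (design$t7_prefix) paste0("AG", sample(c("A", "G"), 1L)) else ""
  paste0(prefix, random_rna(f5), stem5, loop_seq, stem3, random_rna(f3))
}

#' Generate the stem-loop group
#'
#' Each record is random flanks around a 10-bp complementary stem enclosing
#' a loop; every loop length in the design range is represented at least
#' once (loop lengths cycle). A `plant_fraction` of the records instead
#' carry the ground-truth consensus at the 5' end of the loop (loop length
#' extended as needed, at most 8). Substring uniqueness across the pool is
#' enforced via the shared registry.
#'
#' @param design A [pool_design()].
#' @param truth A [ground_truth()] (for the planted consensus).
#' @param registry Internal k-mer registry (created when NULL).
#' @return Tibble with columns `id`, `seq`, `group`, `planted`,
#'   `loop_len`.
#' @export
make_stemloop_pool <- function(design, truth = ground_truth(),
                               registry = NULL) {
  if (is.null(registry)) registry <- new_kmer_registry(design$max_shared + 1L)
  n <- design$n_stemloop
  empty <- tibble(id = character(), seq = character(), group = character(),
                  planted = logical(), loop_len = integer())
  if (n == 0L) return(empty)
  n_plant <- round(design$plant_fraction * n)
  cons <- truth$consensus
  loops <- design$loop_range[1]:design$loop_range[2]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    planted <- i <= n_plant
    for (attempt in 1:200) {
      if (planted) {
        # consensus at the loop 5' end, padded to a legal loop length
        pad <- sample(0:max(0L, 8L - nchar(cons)), 1L)
        loop_seq <- paste0(cons, random_rna(pad))
      } else {
        loop_seq <- random_rna(loops[((i - 1L) %% length(loops)) + 1L])
      }
      s <- build_stemloop(design, loop_seq)
      if (registry_ok(registry, s)) break
      s <- NULL
    }
    if (is.null(s)) {
      abort("substring-uniqueness constraint unsatisfiable; reduce n_stemloop.")
    }
    registry_add(registry, s)
    rows[[i]] <- tibble(id = sprintf("SL%05d", i), seq = s,
                        group = "stem_loop", planted = planted,
                        loop_len = nchar(loop_seq))
  }
  dplyr::bind_rows(rows)
}

#' Generate the weakly structured group
#'
#' Random sequences are accepted when their mean per-base pairing
#' probability, estimated from the built-in annotator at the design's
#' reduced sample count, stays below the design threshold. A
#' `plant_fraction` of accepted records carry the consensus at a random
#' position. The attribute `coverage` reports how many accepted sequences
#' contain each 7-mer overlapping the consensus.
#'
#' @inheritParams make_stemloop_pool
#' @param model Folding [energy_model()] used by the acceptance check.
#' @return Tibble with columns `id`, `seq`, `group`, `planted`,
#'   `mean_paired`.
#' @export
make_weak_pool <- function(design, truth = ground_truth(),
                           model = energy_model(), registry = NULL) {
  if (is.null(registry)) registry <- new_kmer_registry(design$max_shared + 1L)
  n <- design$n_weak
  if (n == 0L) {
    out <- tibble(id = character(), seq = character(), group = character(),
                  planted = logical(), mean_paired = numeric())
    attr(out, "coverage") <- consensus_kmer_coverage(character(0),
                                                     truth$consensus)
    return(out)
  }
  n_plant <- round(design$plant_fraction * n)
  cons <- truth$consensus
  lr <- design$length_range
  prefix <- function() if (design$t7_prefix)
    paste0("AG", sample(c("A", "G"), 1L)) else ""
  rows <- vector("list", n)
  attempts_total <- 0L
  for (i in seq_len(n)) {
    planted <- i <= n_plant
    accepted <- NULL
    for (attempt in 1:400) {
      attempts_total <- attempts_total + 1L
      pre <- prefix()
      len <- sample(lr[1]:lr[2], 1L) - nchar(pre)
      comp <- design$weak_composition
      if (planted) {
        rest <- len - nchar(cons)
        at <- sample(0:rest, 1L)
        s <- paste0(pre, random_rna(at, comp), cons,
                    random_rna(rest - at, comp))
      } else {
        s <- paste0(pre, random_rna(len, comp))
      }
      if (!registry_ok(registry, s)) next
      mp <- mean_paired_prob_cpp(encode_rna(s), model$pair_matrix,
                                 model$stacking, model$min_hairpin,
                                 model$beta, design$weak_samples,
                                 as.double(derive_seed(attempts_total, i)))
      if (mp < design$weak_threshold) {
        accepted <- list(seq = s, mean_paired = mp)
        break
      }
    }
    if (is.null(accepted)) {
      abort(paste0("weak-group acceptance rate too low; raise ",
                   "`weak_threshold` or shrink the pool."))
    }
    registry_add(registry, accepted$seq)
    rows[[i]] <- tibble(id = sprintf("WK%05d", i), seq = accepted$seq,
                        group = "weak", planted = planted,
                        mean_paired = accepted$mean_paired)
  }
  out <- dplyr::bind_rows(rows)
  if (n > 0L && attempts_total > 100L && n / attempts_total < 0.01) {
    abort("weak-group acceptance rate below 1%; adjust `weak_threshold`.")
  }
  attr(out, "coverage") <- consensus_kmer_coverage(out$seq, cons)
  out
}

# how many sequences contain each 7-mer that overlaps the consensus
consensus_kmer_coverage <- function(seqs, consensus, k = 7L) {
  if (nchar(consensus) >= k) {
    targets <- registry_kmers(consensus, k)
  } else {
    pad <- k - nchar(consensus)
    targets <- unique(unlist(lapply(0:pad, function(left) {
      grid <- expand.grid(rep(list(RNA_BASES), pad), stringsAsFactors = FALSE)
      apply(grid, 1L, function(bases) {
        paste0(paste(bases[seq_len(left)], collapse = ""), consensus,
               paste(bases[seq_len(pad - left) + left], collapse = ""))
      })
    })))
  }
  counts <- vapply(targets, function(t) {
    sum(vapply(seqs, function(s) grepl(t, s, fixed = TRUE), logical(1)))
  }, integer(1))
  tibble(kmer = targets, n_seqs = unname(counts))
}

#' Assign ground-truth affinities
#'
#' y = slope * N(seq, profile; true model) + intercept + Gaussian noise.
#' Records must carry annotation profiles. With `noise_sd = NULL` in the
#' truth, the noise level is set to 0.1 times the noiseless affinity
#' range and recorded in the returned attribute `noise_sd`.
#'
#' @param records Annotated records (with `profile` column).
#' @param truth A [ground_truth()].
#' @param seed Integer seed for the noise draw.
#' @return The records tibble with `affinity` (noisy) and
#'   `affinity_true` (noiseless) columns added.
#' @export
assign_affinities <- function(records, truth, seed = 1L) {
  records <- score_records(records, truth$model, truth$map)
  noiseless <- records$predicted
  noise_sd <- truth$noise_sd
  if (is.null(noise_sd)) noise_sd <- 0.1 * diff(range(noiseless))
  withr::with_seed(derive_seed(seed, 777L), {
    records$affinity <- noiseless + rnorm(length(noiseless), 0, noise_sd)
  })
  records$affinity_true <- noiseless
  records$score <- NULL
  records$predicted <- NULL
  attr(records, "noise_sd") <- noise_sd
  records
}

#' Split a pool into Set A and Set B
#'
#' Stratified halves by group tag: within each group, records are randomly
#' permuted and alternated between the two sets, so the halves are
#' disjoint, exhaustive and balanced.
#'
#' @param records Pool records with a `group` column.
#' @param seed Integer seed.
#' @return The records tibble with a `set` column ("A" or "B").
#' @export
split_sets <- function(records, seed = 1L) {
  records <- as_tibble(records)
  set <- character(nrow(records))
  withr::with_seed(derive_seed(seed, 555L), {
    for (g in unique(records$group)) {
      idx <- which(records$group == g)
      perm <- sample(idx)
      set[perm] <- rep(c("A", "B"), length.out = length(perm))
    }
  })
  records$set <- set
  records
}

#' Generate a complete annotated synthetic pool
#'
#' End-to-end generator: stem-loop group, weakly structured group,
#' full-sample annotation profiles, ground-truth affinities with noise,
#' and the Set A / Set B split. The manifest attribute records the design,
#' truth, seeds and noise level, and suffices to regenerate the pool.
#'
#' @param design A [pool_design()].
#' @param truth A [ground_truth()].
#' @param model Folding [energy_model()].
#' @param n_samples Ensemble samples per sequence for the final profiles
#'   (default 1000).
#' @param seed Integer master seed.
#' @return A `rna_pool` list: `records` tibble (id, seq, group, planted,
#'   set, affinity, affinity_true, profile) and `manifest`.
#' @export
simulate_pool <- function(design = pool_design(), truth = ground_truth(),
                          model = energy_model(), n_samples = 1000L,
                          seed = 1L) {
  registry <- new_kmer_registry(design$max_shared + 1L)
  withr::with_seed(derive_seed(seed, 111L), {
    sl <- make_stemloop_pool(design, truth, registry)
  })
  withr::with_seed(derive_seed(seed, 222L), {
    wk <- make_weak_pool(design, truth, model, registry)
  })
  records <- dplyr::bind_rows(sl[, c("id", "seq", "group", "planted")],
                              wk[, c("id", "seq", "group", "planted")])
  records <- annotate_structure(records, model = model,
                                alphabet = truth$model$alphabet,
                                n_samples = n_samples,
                                seed = derive_seed(seed, 333L))
  records <- assign_affinities(records, truth, seed = seed)
  records <- split_sets(records, seed = seed)
  manifest <- list(
    design = unclass(design),
    truth = list(consensus = truth$consensus,
                 theta = unname(truth$model$theta),
                 gamma = as.list(truth$model$gamma),
                 b_seq = truth$model$b_seq, b_str = truth$model$b_str,
                 convention = truth$model$convention,
                 slope = truth$map$slope, intercept = truth$map$intercept,
                 noise_sd = attr(records, "noise_sd")),
    n_samples = n_samples, seed = seed,
    package_version = as.character(utils::packageVersion("plumotif"))
  )
  structure(list(records = records, manifest = manifest, truth = truth),
            class = "rna_pool")
}

#' @export
print.rna_pool <- function(x, ...) {
  cat("<rna_pool>", nrow(x$records), "records (",
      sum(x$records$group == "stem_loop"), "stem-loop,",
      sum(x$records$group == "weak"), "weak );",
      "noise_sd =", format(x$manifest$truth$noise_sd), "\n")
  invisible(x)
}
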