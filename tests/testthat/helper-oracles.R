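# Independent oracles, deliberately written with different algorithms than
# the package internals they check.

oracle_pair_energy <- function(b1, b2, model) {
  key <- paste0(b1, b2)
  tab <- c(GC = model$pair_scores[["GC"]], CG = model$pair_scores[["GC"]],
           AU = model$pair_scores[["AU"]], UA = model$pair_scores[["AU"]],
           GU = model$pair_scores[["GU"]], UG = model$pair_scores[["GU"]])
  if (key %in% names(tab)) tab[[key]] else Inf
}

# recursive enumerator over pair sets; recursion keyed on the LAST base
# (the package DP recurses on the first base)
oracle_enumerate <- function(seq, model) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  rec <- function(i, j) {
    if (j - i + 1L <= model$min_hairpin) return(list(list()))
    out <- rec(i, j - 1L)                       # j unpaired
    hi <- j - model$min_hairpin - 1L
    for (k in if (hi >= i) i:hi else integer(0)) {  # j paired with k
      if (!is.finite(oracle_pair_energy(chars[k], chars[j], model))) next
      left <- if (k > i) rec(i, k - 1L) else list(list())
      inner <- rec(k + 1L, j - 1L)
      for (a in left) for (b in inner) {
        out <- c(out, list(c(a, b, list(c(k, j)))))
      }
    }
    out
  }
  structs <- if (n == 0) list(list()) else rec(1L, n)
  lapply(structs, function(pairs) {
    partner <- rep(-1L, n)
    for (p in pairs) {
      partner[p[1]] <- p[2] - 1L
      partner[p[2]] <- p[1] - 1L
    }
    partner
  })
}

oracle_structure_energy <- function(partner, seq, model) {
  chars <- strsplit(seq, "")[[1]]
  opens <- which(partner > seq_along(partner) - 1L)
  e <- 0
  for (i in opens) {
    j <- partner[i] + 1L
    e <- e + oracle_pair_energy(chars[i], chars[j], model)
    if (i + 1L < j - 1L && partner[i + 1L] == j - 2L) e <- e + model$stacking
  }
  e
}

# total Boltzmann weight by full enumeration
oracle_partition <- function(seq, model) {
  parts <- oracle_enumerate(seq, model)
  sum(vapply(parts, function(p) {
    exp(-model$beta * oracle_structure_energy(p, seq, model))
  }, numeric(1)))
}

# count of legal structures (beta -> 0 limit)
oracle_structure_count <- function(seq, model) {
  length(oracle_enumerate(seq, model))
}

# independent loop-decomposition: walks the tree of pairs built from
# explicit parent links
oracle_classify <- function(partner, alphabet = plum_alphabet()) {
  n <- length(partner)
  if (n == 0) return("")
  idx <- seq_len(n)
  is_open <- partner > idx - 1L
  # enclosing pair of every position (0 if none), by interval containment
  opens <- which(is_open)
  enclosing <- integer(n)
  for (i in idx) {
    best <- 0L
    for (o in opens) {
      c2 <- partner[o] + 1L
      if (o < i && i < c2) {
        if (best == 0L || o > best) best <- o
      }
    }
    enclosing[i] <- best
  }
  cats <- character(n)
  for (i in idx) {
    if (partner[i] >= 0L) {
      cats[i] <- "paired"
    } else if (enclosing[i] == 0L) {
      cats[i] <- "external"
    } else {
      p <- enclosing[i]
      q <- partner[p] + 1L
      kids <- opens[enclosing[opens] == p]
      unp <- idx[partner == -1L & enclosing == p]
      if (length(kids) == 0L) {
        cats[i] <- "hairpin_loop"
      } else if (length(kids) >= 2L) {
        cats[i] <- "multiloop"
      } else {
        a <- kids[1]
        b <- partner[a] + 1L
        left <- sum(unp > p & unp < a)
        right <- sum(unp > b & unp < q)
        cats[i] <- if (left > 0 && right > 0) "internal_loop" else "bulge"
      }
    }
  }
  paste(unname(alphabet$category_map[cats]), collapse = "")
}

# quadratic-time average precision (precision at every positive's rank),
# requires untied scores
oracle_average_precision <- function(scores, labels) {
  stopifnot(!anyDuplicated(scores))
  pos <- which(labels)
  mean(vapply(pos, function(i) {
    above <- scores >= scores[i]
    sum(labels[above]) / sum(above)
  }, numeric(1)))
}

# direct window-by-window noisy-OR score
oracle_score <- function(seq, profile, model) {
  n <- nchar(seq)
  w <- model$width
  p <- vapply(seq_len(n - w + 1L), function(i) {
    kmer <- substr(seq, i, i + w - 1L)
    if (grepl("[^ACGU]", kmer)) return(0)
    window_probability(kmer, profile[, i:(i + w - 1L), drop = FALSE], model)
  }, numeric(1))
  1 - prod(1 - p)
}

# straight-line objective re-implementation
oracle_objective <- function(records, model, map, lambda) {
  preds <- vapply(seq_len(nrow(records)), function(t) {
    map$slope * oracle_score(records$seq[t], records$profile[[t]], model) +
      map$intercept
  }, numeric(1))
  sum((preds - records$affinity)^2) +
    lambda * (sum(model$theta^2) + sum(model$gamma^2) +
                model$b_seq^2 + model$b_str^2)
}

random_rna_str <- function(n, bases = c("A", "C", "G", "U")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

random_profile <- function(n, alphabet = plum_alphabet()) {
  na <- length(alphabet$letters)
  m <- matrix(stats::rexp(na * n), na, n)
  m <- sweep(m, 2L, colSums(m), "/")
  rownames(m) <- alphabet$letters
  attr(m, "alphabet") <- alphabet
  m
}

random_motif_model <- function(width, sd = 1) {
  motif_model(theta = matrix(stats::rnorm(4 * width, 0, sd), 4, width),
              gamma = stats::rnorm(4, 0, sd),
              b_seq = stats::rnorm(1, 0, sd),
              b_str = stats::rnorm(1, 0, sd))
}

# all permutations of 1..n (tiny n only)
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
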