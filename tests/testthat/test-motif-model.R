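test_that("sequence term is the logistic of the PWM sum", {
  m0 <- motif_model(matrix(0, 4, 5), rep(0, 4))
  expect_equal(sequence_term("ACGUA", m0), 0.5)
  th <- matrix(0, 4, 2, dimnames = list(c("A", "C", "G", "U"), NULL))
  th["A", 1] <- 1
  th["U", 2] <- 1
  m <- motif_model(th, rep(0, 4), b_seq = -1)
  expect_equal(sequence_term("AU", m), 1 / (1 + exp(-1)))
  expect_equal(sequence_term("CC", m), 1 / (1 + exp(1)))
  withr::with_seed(21, {
    for (rep in 1:50) {
      m <- random_motif_model(6)
      kmer <- random_rna_str(6)
      codes <- match(strsplit(kmer, "")[[1]], c("A", "C", "G", "U"))
      direct <- plogis(m$b_seq + sum(m$theta[cbind(codes, 1:6)]))
      expect_equal(sequence_term(kmer, m), direct, tolerance = 1e-14)
    }
  })
})

test_that("structure term weights gamma by window profile mass", {
  # single-letter alphabet: constant term sigma(b_str + w * g)
  m1 <- motif_model(matrix(0, 4, 3), gamma = 2, b_str = 0.5,
                    alphabet = single_letter_alphabet())
  win <- matrix(1, 1, 3)
  expect_equal(structure_term(win, m1), plogis(0.5 + 3 * 2))
  # pure-L window
  alpha <- plum_alphabet()
  mL <- motif_model(matrix(0, 4, 3), gamma = c(0, 2, 0, 0))
  winL <- matrix(0, 4, 3, dimnames = list(alpha$letters, NULL))
  winL["L", ] <- 1
  expect_equal(structure_term(winL, mL), plogis(6))
  # mixed profile, hand-computed weighted sum
  mx <- motif_model(matrix(0, 4, 2), gamma = c(-1, 1, 0, 0))
  winM <- matrix(0, 4, 2, dimnames = list(alpha$letters, NULL))
  winM["P", ] <- 0.5
  winM["L", ] <- 0.5
  expect_equal(structure_term(winM, mx), 0.5)
  # mean convention divides the mass by the width
  mm <- motif_model(matrix(0, 4, 3), gamma = c(0, 2, 0, 0),
                    convention = "mean")
  winL3 <- matrix(0, 4, 3, dimnames = list(alpha$letters, NULL))
  winL3["L", ] <- 1
  expect_equal(structure_term(winL3, mm), plogis(2))
  expect_error(structure_term(matrix(1, 1, 3), mL), "alphabet")
})

test_that("window probability is the product of the two terms", {
  withr::with_seed(22, {
    m <- random_motif_model(4)
    kmer <- "ACGU"
    win <- random_profile(4)
    expect_equal(window_probability(kmer, win, m),
                 sequence_term(kmer, m) * structure_term(win, m))
    # saturated structure term: product reduces to the sequence term
    msat <- motif_model(m$theta, rep(0, 4), b_seq = m$b_seq, b_str = 50)
    expect_equal(window_probability(kmer, win, msat),
                 sequence_term(kmer, msat), tolerance = 1e-12)
    # strongly disfavored context suppresses any kmer
    moff <- motif_model(m$theta, rep(-60, 4), b_seq = 10)
    expect_lt(window_probability(kmer, win, moff), 1e-20)
  })
})

test_that("noisy-OR score matches brute force and its limits", {
  # two windows at p = 0.5 -> N = 0.75: constant theta zero, b_seq/b_str
  # chosen so every window has p 0.5 on a pure-U profile
  alpha <- plum_alphabet()
  m <- motif_model(matrix(0, 4, 5), rep(0, 4), b_seq = 0, b_str = 50)
  prof <- matrix(0, 4, 6, dimnames = list(alpha$letters, NULL))
  prof["U", ] <- 1
  expect_equal(score_sequence("ACGUAC", prof, m), 0.75)
  # all-zero window probabilities -> N = 0
  mz <- motif_model(matrix(0, 4, 5), rep(0, 4), b_seq = -100, b_str = 50)
  expect_equal(score_sequence("ACGUAC", prof, mz), 0, tolerance = 1e-12)
  # a certain window -> N = 1
  mo <- motif_model(matrix(0, 4, 5), rep(0, 4), b_seq = 100, b_str = 100)
  expect_equal(score_sequence("ACGUAC", prof, mo), 1)
  withr::with_seed(23, {
    for (rep in 1:60) {
      m <- random_motif_model(sample(4:8, 1))
      s <- random_rna_str(35)
      prof <- random_profile(35)
      expect_equal(score_sequence(s, prof, m), oracle_score(s, prof, m),
                   tolerance = 1e-12)
    }
  })
})

test_that("windows with non-ACGU characters contribute nothing", {
  withr::with_seed(24, {
    m <- random_motif_model(5)
    s <- random_rna_str(30)
    prof <- random_profile(34)
    # append 4 junk bases: all windows touching them must contribute 0
    s_ext <- paste0(s, "NNNN")
    expect_equal(score_sequence(s_ext, prof, m),
                 score_sequence(s, prof[, 1:30], m), tolerance = 1e-12)
  })
})

test_that("score is monotone in any single window probability", {
  withr::with_seed(25, {
    alpha <- plum_alphabet()
    m <- random_motif_model(4, sd = 0.5)
    s <- random_rna_str(20)
    prof <- random_profile(20)
    base <- score_sequence(s, prof, m)
    # raising b_seq raises every window probability, so N must not drop
    m_up <- motif_model(m$theta, unname(m$gamma), m$b_seq + 1, m$b_str)
    expect_gt(score_sequence(s, prof, m_up), base)
  })
})

test_that("predicted affinity is the linear map of the score", {
  withr::with_seed(26, {
    m <- random_motif_model(4)
    s <- random_rna_str(15)
    prof <- random_profile(15)
    n <- score_sequence(s, prof, m)
    expect_equal(predict_affinity(s, prof, m, affinity_map(2, -1)),
                 2 * n - 1)
    # N = 0 -> intercept
    mz <- motif_model(matrix(0, 4, 4), rep(0, 4), b_seq = -100)
    expect_equal(predict_affinity(s, prof, mz, affinity_map(3, 0.7)), 0.7,
                 tolerance = 1e-10)
    expect_error(affinity_map(0, 1), "slope")
  })
})

test_that("score errors identify short records and profile mismatches", {
  m <- random_motif_model(8)
  expect_error(score_sequence("ACGU", random_profile(4), m), "shorter")
  expect_error(score_sequence("ACGUACGUA", random_profile(5), m),
               "profile length")
})

test_that("single-letter alphabet with saturated bias reduces to a sequence PWM", {
  withr::with_seed(27, {
    theta <- matrix(rnorm(20), 4, 5)
    m_seq <- motif_model(theta, gamma = 0, b_seq = -1, b_str = 60,
                         alphabet = single_letter_alphabet())
    s <- random_rna_str(30)
    prof1 <- matrix(1, 1, 30, dimnames = list("S", NULL))
    # independent sequence-only noisy-OR
    codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "U"))
    p <- vapply(1:26, function(i) {
      plogis(-1 + sum(theta[cbind(codes[i:(i + 4)], 1:5)]))
    }, numeric(1))
    expect_equal(score_sequence(s, prof1, m_seq), 1 - prod(1 - p),
                 tolerance = 1e-12)
  })
})

test_that("the model can represent context-specific and dsRNA binders", {
  alpha <- plum_alphabet()
  # loop-specific binder: negative gamma except L
  theta <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "U"), NULL))
  theta["C", ] <- 3
  mL <- motif_model(theta, gamma = c(P = -8, L = 8, U = -8, M = -8),
                    b_seq = -6, b_str = -16)
  profL <- matrix(0, 4, 4, dimnames = list(alpha$letters, NULL))
  profL["L", ] <- 1
  profP <- matrix(0, 4, 4, dimnames = list(alpha$letters, NULL))
  profP["P", ] <- 1
  expect_gt(window_probability("CCCC", profL, mL), 0.99)
  expect_lt(window_probability("CCCC", profP, mL), 1e-10)
  # sequence-indifferent dsRNA binder: constant theta columns + large
  # positive paired gamma -> score depends only on the profile
  mP <- motif_model(matrix(1, 4, 4), gamma = c(P = 8, L = -8, U = -8, M = -8),
                    b_seq = 0, b_str = -16)
  expect_equal(window_probability("ACGU", profP, mP),
               window_probability("GGGG", profP, mP))
  expect_gt(window_probability("ACGU", profP, mP), 0.97)
  expect_lt(window_probability("ACGU", profL, mP), 1e-10)
})

test_that("model files round-trip exactly at 10 significant digits", {
  withr::with_seed(28, {
    m <- random_motif_model(5)
    map <- affinity_map(1.23456789, -0.987654321)
    path <- withr::local_tempfile(fileext = ".txt")
    write_model(m, map, path)
    back <- read_model(path)
    expect_equal(back$model$theta, m$theta, tolerance = 1e-9)
    expect_equal(back$model$gamma, m$gamma, tolerance = 1e-9)
    expect_equal(back$model$b_seq, m$b_seq, tolerance = 1e-9)
    expect_equal(back$map$slope, map$slope, tolerance = 1e-9)
    expect_identical(back$model$width, m$width)
    expect_identical(back$model$convention, m$convention)
    # writing the parsed model again gives a byte-identical file
    path2 <- withr::local_tempfile(fileext = ".txt")
    write_model(back$model, back$map, path2)
    expect_identical(readLines(path), readLines(path2))
  })
})

test_that("score_records adds score and prediction columns", {
  recs <- synthetic_records(8, len = 20, seed = 31)
  m <- withr::with_seed(32, random_motif_model(4))
  out <- score_records(recs, m, affinity_map(2, 1))
  expect_equal(out$predicted, 2 * out$score + 1)
  expect_equal(out$score[1],
               score_sequence(recs$seq[1], recs$profile[[1]], m),
               tolerance = 1e-12)
})
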