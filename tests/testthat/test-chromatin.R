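# small binarized fixture: random calls over two chromosomes
random_binary <- function(n1 = 40, n2 = 25, marks = c("m1", "m2"), seed = 1,
                          p = 0.3) {
  set.seed(seed)
  calls <- list(
    chrA = matrix(rbinom(n1 * length(marks), 1, p), n1,
                  dimnames = list(NULL, marks)),
    chrB = matrix(rbinom(n2 * length(marks), 1, p), n2,
                  dimnames = list(NULL, marks)))
  binarized_marks(calls, c(chrA = n1 * 200L, chrB = n2 * 200L), 200L)
}

test_that("Poisson presence cutoffs match the exact tail-sum oracle", {
  for (lam in c(0.5, 1, 2, 5)) {
    expect_equal(poisson_cutoff(lam, 1e-4), oracle_poisson_cutoff(lam, 1e-4),
                 info = paste("lambda", lam))
  }
  expect_equal(poisson_cutoff(1, 1e-4), 7)     # P(X>=7;1) ~ 8.3e-5
  expect_equal(poisson_cutoff(2, 1), 0)        # tail <= 1 always
  expect_identical(poisson_cutoff(0, 1e-4), Inf)
})

test_that("binarization calls presence against the genome-wide mean rate", {
  sizes <- c(chr1 = 2000L)
  zero <- signal_track(list(chr1 = numeric(10)), sizes, 200L)
  spiky <- signal_track(list(chr1 = c(rep(0, 9), 50)), sizes, 200L)
  b <- binarize(list(k4 = spiky, k27 = zero), p_threshold = 1e-4)
  expect_equal(unname(b$calls$chr1[, "k27"]), rep(0L, 10))   # lambda 0
  expect_equal(sum(b$calls$chr1[, "k4"]), 1L)
  expect_equal(which(b$calls$chr1[, "k4"] == 1L), 10L)
  # p = 1: every bin present (when lambda > 0)
  b1 <- binarize(list(k4 = spiky), p_threshold = 1)
  expect_true(all(b1$calls$chr1[, "k4"] == 1L))
  st2 <- signal_track(list(chr1 = numeric(5)), c(chr1 = 1000L), 200L)
  expect_error(binarize(list(a = zero, b = st2)), "same binning")
})

test_that("a one-state model reduces to the column means", {
  b <- random_binary(seed = 3)
  m <- learn_chromatin_model(b, n_states = 1)
  expect_equal(unname(m$emissions[1, ]),
               unname(colMeans(rbind(b$calls$chrA, b$calls$chrB))),
               tolerance = 1e-9)
  expect_equal(unname(m$transitions), matrix(1, 1, 1))
})

test_that("EM log-likelihood is nondecreasing for every restart", {
  b <- random_binary(n1 = 120, n2 = 60, seed = 5, p = 0.4)
  m <- learn_chromatin_model(b, n_states = 3, seed = 2, n_restarts = 3,
                             max_iter = 50)
  for (tr in m$trace) expect_true(all(diff(tr) >= -1e-8))
  # the kept restart is the best of the three final log-likelihoods
  finals <- vapply(m$trace, function(t) t[length(t)], numeric(1))
  expect_equal(m$loglik, max(finals))
  expect_error(learn_chromatin_model(b, n_states = 0), ">= 1")
})

test_that("forward-backward matches exhaustive path enumeration", {
  set.seed(6)
  for (i in 1:12) {
    S <- sample(2:3, 1)
    T_ <- sample(2:8, 1)
    M <- sample(1:3, 1)
    E <- matrix(runif(S * M, 0.05, 0.95), S, M,
                dimnames = list(NULL, paste0("m", 1:M)))
    A <- matrix(runif(S * S, 0.1, 1), S, S); A <- A / rowSums(A)
    pi <- runif(S, 0.1, 1); pi <- pi / sum(pi)
    model <- chromatin_model(E, A, pi, marks = colnames(E))
    x <- matrix(rbinom(T_ * M, 1, 0.5), T_, M,
                dimnames = list(NULL, colnames(E)))
    b <- binarized_marks(list(chr1 = x), c(chr1 = T_ * 200L), 200L)
    fb <- forward_backward(model, b)
    oracle <- oracle_hmm_enum(model$emissions, model$transitions,
                              model$initial, x)
    expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-10)
    expect_equal(unname(fb$posteriors$chr1), oracle$posteriors,
                 tolerance = 1e-10)
    expect_equal(unname(rowSums(fb$posteriors$chr1)), rep(1, T_),
                 tolerance = 1e-9)
  }
})

test_that("decoding recovers the true path in the noiseless limit", {
  eps <- 1e-9   # degenerate 0/1 emissions, floored for log-likelihoods
  E <- rbind(c(1 - eps, eps), c(eps, 1 - eps))
  A <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  model <- chromatin_model(E, A, c(0.5, 0.5), marks = c("m1", "m2"))
  set.seed(12)
  path <- rep(c(1L, 2L), times = c(30, 20))
  x <- cbind(m1 = as.integer(path == 1L), m2 = as.integer(path == 2L))
  b <- binarized_marks(list(chr1 = x), c(chr1 = 50L * 200L), 200L)
  seg_p <- segment_states(model, b, "posterior_max")
  seg_v <- segment_states(model, b, "viterbi")
  expect_identical(seg_p$states$chr1, path)
  expect_identical(seg_v$states$chr1, path)
})

test_that("model comparison is permutation-invariant and self-identical", {
  set.seed(15)
  E <- matrix(runif(12, 0.05, 0.95), 3, 4,
              dimnames = list(NULL, paste0("m", 1:4)))
  A <- matrix(1 / 3, 3, 3)
  m1 <- chromatin_model(E, A, marks = colnames(E))
  self <- compare_chromatin_models(m1, m1)
  expect_equal(self$per_state$max_cor, rep(1, 3), tolerance = 1e-12)
  perm <- chromatin_model(E[c(3, 1, 2), ], A, marks = colnames(E))
  expect_equal(compare_chromatin_models(perm, m1)$per_state$max_cor,
               rep(1, 3), tolerance = 1e-12)
  # constant emission vector -> NA
  flat <- chromatin_model(rbind(rep(0.4, 4), E[1:2, ]), A, marks = colnames(E))
  expect_true(is.na(compare_chromatin_models(flat, m1)$per_state$max_cor[1]))
  m2 <- chromatin_model(E[, 1:3], matrix(1 / 3, 3, 3), marks = paste0("m", 1:3))
  expect_error(compare_chromatin_models(m1, m2), "different mark sets")
})

test_that("fold enrichment follows the counting definition", {
  # 100 bins on one chromosome; state 1 occupies bins 1-10
  states <- c(rep(1L, 10), rep(2L, 90))
  seg <- omicsforge:::new_segmentation(list(chr1 = states),
                                       c(chr1 = 100L * 200L), 200L, 2L, "test")
  # feature covers bins 1-5 and 51-55 (10 bins): fold = (5/10)/(10/100) = 5
  feats <- feature_annotation(rep("chr1", 2), c(0, 50 * 200),
                              c(5 * 200, 55 * 200), "promoter")
  fe <- overlap_enrichment(seg, feats)
  expect_equal(fe["E1", "promoter"], 5.0)
  # whole-genome feature: fold 1 for every state
  whole <- feature_annotation("chr1", 0, 100 * 200, "genome")
  expect_equal(unname(overlap_enrichment(seg, whole)[, "genome"]), c(1, 1))
  # absent state yields an NA row
  seg3 <- omicsforge:::new_segmentation(list(chr1 = states),
                                        c(chr1 = 100L * 200L), 200L, 3L, "test")
  expect_true(all(is.na(overlap_enrichment(seg3, whole)["E3", ])))
  # marks as feature columns
  b <- binarized_marks(list(chr1 = matrix(c(rep(1L, 10), rep(0L, 90)),
                                          dimnames = list(NULL, "k4"))),
                       c(chr1 = 100L * 200L), 200L)
  expect_equal(overlap_enrichment(seg, marks = b)["E1", "k4"], 10.0)
  expect_error(overlap_enrichment(seg, feature_annotation("chrX", 0, 10, "f")),
               "unknown chromosome")
})

test_that("segmentation bins are covered exactly once and BED is lossless", {
  sim <- simulate_chromatin(n_bins = 600, seed = 2)
  b <- sim$truth$binary
  model <- sim$truth$model
  seg <- segment_states(model, b)
  expect_identical(lengths(seg$states),
                   vapply(b$calls, nrow, integer(1)))
  tmp <- withr::local_tempfile(fileext = ".bed")
  write_segmentation_bed(seg, tmp)
  expect_identical(read_segmentation_bed(tmp, b$chrom_sizes, 200L)$states,
                   seg$states)
})

test_that("a swept state count is chosen by emission similarity", {
  sim <- simulate_chromatin(n_bins = 4000, seed = 19)
  b <- sim$truth$binary
  ref <- learn_chromatin_model(b, n_states = 6, seed = 1, n_restarts = 2,
                               max_iter = 80)
  cands <- lapply(2:4, function(S)
    learn_chromatin_model(b, n_states = S, seed = 1, n_restarts = 2,
                          max_iter = 80))
  sweep <- compare_model_sweep(cands, ref, min_median = 0.95)
  tab <- sweep$table
  # the true 3-state structure reproduces the reference states faithfully
  expect_gte(tab$min_cor[tab$n_states == 3], 0.95)
  expect_false(is.na(sweep$recommended))
  expect_lte(sweep$recommended, 3L)
})
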