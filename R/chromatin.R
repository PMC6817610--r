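#' Construct a binarized-marks object
#'
#' Per-bin presence/absence calls for an ordered set of chromatin marks,
#' over fixed-width bins tiling each chromosome.
#'
#' @param calls named list, one binary (0/1) matrix per chromosome with
#'   bins in rows and one column per mark.
#' @param chrom_sizes named integer vector of chromosome lengths (bp).
#' @param bin_size bin width in bp (default 200).
#' @return object of class `binarized_marks`.
#' @export
binarized_marks <- function(calls, chrom_sizes, bin_size = 200L) {
  stopifnot(is.list(calls), !is.null(names(calls)))
  marks <- colnames(calls[[1L]])
  if (is.null(marks)) stop("mark names required as column names", call. = FALSE)
  for (chrom in names(calls)) {
    m <- calls[[chrom]]
    if (!identical(colnames(m), marks))
      stop("mark order differs on chromosome ", chrom, call. = FALSE)
    if (!all(m %in% c(0, 1)))
      stop("non-binary call on chromosome ", chrom, call. = FALSE)
    if (is.na(chrom_sizes[chrom]))
      stop("no size for chromosome ", chrom, call. = FALSE)
    if (nrow(m) != n_bins(chrom_sizes[[chrom]], bin_size))
      stop("bin count mismatch on chromosome ", chrom, call. = FALSE)
  }
  structure(list(calls = calls, marks = marks,
                 chrom_sizes = chrom_sizes[names(calls)],
                 bin_size = as.integer(bin_size)),
            class = "binarized_marks")
}

#' Poisson-tail presence cutoff
#'
#' Smallest integer count `c` with upper-tail probability
#' P(X >= c; lambda) <= p. `Inf` when `lambda <= 0` (no bin can be called
#' present).
#'
#' @param lambda background Poisson rate (mean signal per bin).
#' @param p tail probability threshold (default 1e-4).
#' @return integer cutoff (possibly 0 when `p = 1`, or `Inf`).
#' @export
poisson_cutoff <- function(lambda, p = 1e-4) {
  if (lambda <= 0) return(Inf)
  cut <- 0L
  while (stats::ppois(cut - 1L, lambda, lower.tail = FALSE) > p)
    cut <- cut + 1L
  cut
}

#' Binarize signal tracks by a Poisson background model
#'
#' For each mark the background rate lambda is the genome-wide mean signal
#' per bin; a bin is called present when its (rounded) count `c` satisfies
#' P(X >= c; lambda) <= `p_threshold`.
#'
#' @param tracks named list of [signal_track()] objects (one per mark),
#'   all sharing the same binning.
#' @param p_threshold Poisson upper-tail threshold (default 1e-4).
#' @return a [binarized_marks()] object; per-mark cutoffs in
#'   `attr(, "cutoffs")`.
#' @export
binarize <- function(tracks, p_threshold = 1e-4) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  ref <- tracks[[1L]]
  for (tr in tracks) {
    if (!identical(tr$chrom_sizes, ref$chrom_sizes) ||
        tr$bin_size != ref$bin_size)
      stop("tracks do not share the same binning", call. = FALSE)
  }
  marks <- names(tracks)
  cutoffs <- vapply(tracks, function(tr) {
    poisson_cutoff(mean(unlist(tr$counts, use.names = FALSE)), p_threshold)
  }, numeric(1))
  calls <- lapply(names(ref$counts), function(chrom) {
    m <- vapply(marks, function(mk) {
      as.integer(round(tracks[[mk]]$counts[[chrom]]) >= cutoffs[mk])
    }, integer(length(ref$counts[[chrom]])))
    matrix(m, ncol = length(marks), dimnames = list(NULL, marks))
  })
  names(calls) <- names(ref$counts)
  out <- binarized_marks(calls, ref$chrom_sizes, ref$bin_size)
  attr(out, "cutoffs") <- cutoffs
  out
}

# Per-bin emission log-likelihoods under independent Bernoulli marks:
# log P(x | state s) = sum_m x log E[s,m] + (1-x) log(1 - E[s,m]).
emission_loglik <- function(x, emissions) {
  x %*% t(log(emissions)) + (1 - x) %*% t(log(1 - emissions))
}

#' Fit a multivariate Bernoulli-emission hidden Markov model
#'
#' ChromHMM-style chromatin-state learning: each hidden state emits every
#' mark independently with a state-specific presence probability, and the
#' model is trained on the binarized calls by Baum-Welch EM (scaled
#' forward-backward). Chromosomes are treated as independent sequences.
#' Several random restarts are run and the fit with the best final
#' log-likelihood is kept. Parameters are clamped to `[1e-6, 1 - 1e-6]`.
#'
#' @param binary a [binarized_marks()] object.
#' @param n_states number of chromatin states (>= 1).
#' @param seed RNG seed for the restarts' initialization.
#' @param n_restarts number of EM restarts (default 3).
#' @param max_iter maximum EM iterations per restart (default 200).
#' @param tol absolute log-likelihood improvement declaring convergence
#'   (default 1e-4).
#' @return object of class `chromatin_model` with emissions (states x
#'   marks), transitions, initial distribution, the log-likelihood trace
#'   of every restart, and the index of the restart kept. States are
#'   relabelled by descending total emission mass.
#' @export
learn_chromatin_model <- function(binary, n_states, seed = 1L,
                                  n_restarts = 3L, max_iter = 200L,
                                  tol = 1e-4) {
  stopifnot(inherits(binary, "binarized_marks"))
  if (n_states < 1L) stop("n_states must be >= 1", call. = FALSE)
  X <- binary$calls
  marks <- binary$marks
  total_bins <- sum(vapply(X, nrow, integer(1)))
  if (total_bins < n_states)
    stop("fewer bins than states", call. = FALSE)
  S <- as.integer(n_states); M <- length(marks)
  clamp <- function(v) pmin(pmax(v, 1e-6), 1 - 1e-6)
  if (S == 1L) {                      # degenerate EM: closed form
    em <- matrix(clamp(colMeans(do.call(rbind, X))), 1L, M,
                 dimnames = list("E1", marks))
    ll <- sum(vapply(X, function(x) sum(emission_loglik(x, em)), numeric(1)))
    return(structure(list(n_states = 1L, marks = marks, emissions = em,
                          transitions = matrix(1, 1, 1,
                                               dimnames = list("E1", "E1")),
                          initial = stats::setNames(1, "E1"),
                          loglik = ll, trace = list(ll), best_restart = 1L,
                          converged = TRUE, seed = seed),
                     class = "chromatin_model"))
  }
  run_em <- function(E, A, pi) {
    trace <- numeric(0)
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      Esum <- matrix(0, S, M); gsum <- numeric(S)
      xisum <- matrix(0, S, S); pisum <- numeric(S)
      ll <- 0
      for (x in X) {
        fb <- .fb_cpp(emission_loglik(x, E), pi, A)
        ll <- ll + fb$loglik
        Esum <- Esum + t(fb$gamma) %*% x
        gsum <- gsum + colSums(fb$gamma)
        xisum <- xisum + fb$xisum
        pisum <- pisum + fb$gamma[1L, ]
      }
      trace <- c(trace, ll)
      if (iter > 1L && ll - trace[iter - 1L] < tol) { converged <- TRUE; break }
      E <- clamp(Esum / gsum)
      A <- pmax(xisum, 1e-6); A <- A / rowSums(A)
      pi <- pmax(pisum / length(X), 1e-6); pi <- pi / sum(pi)
    }
    list(E = E, A = A, pi = pi, trace = trace, converged = converged)
  }
  fits <- lapply(seq_len(n_restarts), function(r) {
    init <- with_seed(seed + 7919L * (r - 1L), {
      E <- matrix(stats::runif(S * M, 0.1, 0.9), S, M)
      A <- matrix(0.5 / (S - 1L), S, S); diag(A) <- 0.5
      list(E = E, A = A, pi = rep(1 / S, S))
    })
    run_em(init$E, init$A, init$pi)
  })
  finals <- vapply(fits, function(f) f$trace[length(f$trace)], numeric(1))
  best <- which.max(finals)
  fit <- fits[[best]]
  # stable state labels: descending total emission mass
  o <- order(-rowSums(fit$E), fit$E[, 1L])
  E <- fit$E[o, , drop = FALSE]
  A <- fit$A[o, o, drop = FALSE]
  pi <- fit$pi[o]
  st <- paste0("E", seq_len(S))
  dimnames(E) <- list(st, marks); dimnames(A) <- list(st, st); names(pi) <- st
  structure(list(n_states = S, marks = marks, emissions = E,
                 transitions = A, initial = pi,
                 loglik = finals[best],
                 trace = lapply(fits, `[[`, "trace"),
                 best_restart = best,
                 converged = fit$converged, seed = seed),
            class = "chromatin_model")
}

#' Construct a chromatin model from known parameters
#'
#' @param emissions states x marks matrix of mark-presence probabilities.
#' @param transitions row-stochastic states x states matrix.
#' @param initial initial state distribution (default uniform).
#' @param marks mark names (default from `colnames(emissions)`).
#' @return a `chromatin_model`.
#' @export
chromatin_model <- function(emissions, transitions,
                            initial = rep(1 / nrow(emissions), nrow(emissions)),
                            marks = colnames(emissions)) {
  emissions <- as.matrix(emissions)
  S <- nrow(emissions)
  if (is.null(marks)) marks <- paste0("mark", seq_len(ncol(emissions)))
  if (any(emissions < 0 | emissions > 1))
    stop("emissions must lie in [0, 1]", call. = FALSE)
  if (!isTRUE(all.equal(unname(rowSums(transitions)), rep(1, S), tolerance = 1e-9)))
    stop("transition rows must sum to 1", call. = FALSE)
  if (!isTRUE(all.equal(sum(initial), 1, tolerance = 1e-9)))
    stop("initial distribution must sum to 1", call. = FALSE)
  st <- paste0("E", seq_len(S))
  dimnames(emissions) <- list(st, marks)
  transitions <- as.matrix(transitions); dimnames(transitions) <- list(st, st)
  names(initial) <- st
  structure(list(n_states = S, marks = marks, emissions = emissions,
                 transitions = transitions, initial = initial,
                 loglik = NA_real_, trace = list(), best_restart = NA_integer_,
                 converged = NA, seed = NA_integer_),
            class = "chromatin_model")
}

#' @export
print.chromatin_model <- function(x, ...) {
  cat("Chromatin-state HMM:", x$n_states, "states,",
      length(x$marks), "marks (", paste(x$marks, collapse = ", "), ")\n")
  if (!is.na(x$loglik))
    cat(sprintf("  log-likelihood %.2f (restart %d of %d%s)\n", x$loglik,
                x$best_restart, length(x$trace),
                if (isTRUE(x$converged)) ", converged" else ""))
  cat("  emissions:\n")
  print(round(x$emissions, 3))
  invisible(x)
}

#' @export
summary.chromatin_model <- function(object, ...) {
  out <- list(n_states = object$n_states, marks = object$marks,
              emissions = object$emissions,
              transitions = object$transitions,
              initial = object$initial,
              loglik = object$loglik,
              n_iter = lengths(object$trace),
              converged = object$converged)
  class(out) <- "summary.chromatin_model"
  out
}

#' @export
print.summary.chromatin_model <- function(x, ...) {
  cat("Chromatin-state HMM,", x$n_states, "states\n\nEmissions:\n")
  print(round(x$emissions, 3))
  cat("\nTransitions:\n"); print(round(x$transitions, 3))
  cat("\nInitial:\n"); print(round(x$initial, 3))
  if (!is.na(x$loglik))
    cat(sprintf("\nlog-likelihood %.2f; EM iterations per restart: %s\n",
                x$loglik, paste(x$n_iter, collapse = ", ")))
  invisible(x)
}

#' @export
logLik.chromatin_model <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- with(object, n_states * length(marks) +
                            n_states * (n_states - 1) + (n_states - 1))
  class(val) <- "logLik"
  val
}

#' Forward-backward posteriors and likelihood
#'
#' Runs the scaled forward-backward algorithm for each chromosome and
#' returns the per-bin posterior state probabilities (rows sum to 1)
#' together with the total data log-likelihood under the model.
#'
#' @param model a `chromatin_model`.
#' @param binary a [binarized_marks()] with the same mark set.
#' @return list with `loglik` and `posteriors` (named list of bins x
#'   states matrices).
#' @export
forward_backward <- function(model, binary) {
  check_marks(model, binary)
  post <- lapply(binary$calls, function(x) {
    fb <- .fb_cpp(emission_loglik(x, model$emissions), model$initial,
                  model$transitions)
    colnames(fb$gamma) <- rownames(model$emissions)
    fb
  })
  list(loglik = sum(vapply(post, `[[`, numeric(1), "loglik")),
       posteriors = lapply(post, `[[`, "gamma"))
}

check_marks <- function(model, binary) {
  if (!identical(model$marks, binary$marks))
    stop("mark sets differ between model (",
         paste(model$marks, collapse = ","), ") and data (",
         paste(binary$marks, collapse = ","), ")", call. = FALSE)
  invisible(TRUE)
}

new_segmentation <- function(states, chrom_sizes, bin_size, n_states, rule) {
  structure(list(states = states, chrom_sizes = chrom_sizes[names(states)],
                 bin_size = as.integer(bin_size),
                 n_states = as.integer(n_states), rule = rule),
            class = "segmentation")
}

#' Assign a chromatin state to every bin
#'
#' `posterior_max` (default) assigns each bin its maximum-posterior state
#' from forward-backward; `viterbi` returns the jointly most probable
#' state path.
#'
#' @param model a `chromatin_model`.
#' @param binary a [binarized_marks()] with the same marks.
#' @param rule decoding rule.
#' @return object of class `segmentation` (per-chromosome integer state
#'   vectors).
#' @export
segment_states <- function(model, binary, rule = c("posterior_max", "viterbi")) {
  rule <- match.arg(rule)
  check_marks(model, binary)
  states <- if (rule == "posterior_max") {
    fb <- forward_backward(model, binary)
    lapply(fb$posteriors, function(g) max.col(g, ties.method = "first"))
  } else {
    lapply(binary$calls, function(x) {
      .viterbi_cpp(emission_loglik(x, model$emissions),
                   log(model$initial), log(model$transitions))
    })
  }
  new_segmentation(states, binary$chrom_sizes, binary$bin_size,
                   model$n_states, rule)
}

#' @export
predict.chromatin_model <- function(object, newdata,
                                    rule = c("posterior_max", "viterbi"), ...) {
  segment_states(object, newdata, match.arg(rule))
}

#' @export
print.segmentation <- function(x, ...) {
  nb <- sum(lengths(x$states))
  cat("Segmentation:", nb, "bins of", x$bin_size, "bp across",
      length(x$states), "chromosome(s);", x$n_states, "states (rule:",
      x$rule, ")\n")
  occ <- table(factor(unlist(x$states), levels = seq_len(x$n_states)))
  cat("  occupancy:", paste(sprintf("E%s=%.1f%%", names(occ),
                                    100 * occ / nb), collapse = " "), "\n")
  invisible(x)
}

#' Compare two chromatin models by emission similarity
#'
#' For each candidate state, the Pearson correlation of its emission
#' vector with every reference state; the maximum is reported per state
#' together with the median and minimum over states. States with constant
#' emission vectors get `NA`.
#'
#' @param candidate,reference `chromatin_model` objects over the same
#'   marks (in the same order).
#' @return list with `per_state` (data.frame state, best_match, max_cor),
#'   `median` and `min`.
#' @export
compare_chromatin_models <- function(candidate, reference) {
  if (!identical(candidate$marks, reference$marks))
    stop("models have different mark sets", call. = FALSE)
  cors <- t(apply(candidate$emissions, 1L, function(e) {
    apply(reference$emissions, 1L, function(r) {
      if (stats::sd(e) == 0 || stats::sd(r) == 0) NA_real_ else stats::cor(e, r)
    })
  }))
  max_cor <- apply(cors, 1L, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  best <- apply(cors, 1L, function(v) if (all(is.na(v))) NA_integer_ else which.max(v))
  per_state <- data.frame(state = rownames(candidate$emissions),
                          best_match = rownames(reference$emissions)[best],
                          max_cor = unname(max_cor),
                          stringsAsFactors = FALSE)
  list(per_state = per_state,
       median = stats::median(max_cor, na.rm = TRUE),
       min = if (all(is.na(max_cor))) NA_real_ else min(max_cor, na.rm = TRUE))
}

#' Sweep candidate state counts against a reference model
#'
#' Emits, per candidate, the emission-similarity summary against the
#' reference (conventionally the largest swept model) and recommends the
#' smallest candidate whose median max-correlation reaches
#' `min_median` — a heuristic reading of "choose the best model according
#' to similarity".
#'
#' @param models list of `chromatin_model` objects (e.g. states 10..50).
#' @param reference the model compared against.
#' @param min_median similarity required of the recommended model
#'   (default 0.95).
#' @return list with `table` (n_states, median_cor, min_cor) and
#'   `recommended` (an `n_states` value, or `NA` if none qualifies).
#' @export
compare_model_sweep <- function(models, reference, min_median = 0.95) {
  tab <- do.call(rbind, lapply(models, function(m) {
    cm <- compare_chromatin_models(m, reference)
    data.frame(n_states = m$n_states, median_cor = cm$median,
               min_cor = cm$min)
  }))
  tab <- tab[order(tab$n_states), , drop = FALSE]
  ok <- !is.na(tab$median_cor) & tab$median_cor >= min_median
  list(table = tab,
       recommended = if (any(ok)) tab$n_states[which(ok)[1L]] else NA_integer_)
}

# Rasterize intervals to per-chromosome logical bin masks (>= 1 bp
# overlap marks a bin).
rasterize_features <- function(features, chrom_sizes, bin_size) {
  df <- as.data.frame(features)
  unknown <- setdiff(unique(df$chrom), names(chrom_sizes))
  if (length(unknown))
    stop("feature(s) on unknown chromosome: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  masks <- lapply(names(chrom_sizes), function(ch) {
    logical(n_bins(chrom_sizes[[ch]], bin_size))
  })
  names(masks) <- names(chrom_sizes)
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    b0 <- floor(df$start[i] / bin_size) + 1L
    b1 <- min(floor((df$end[i] - 1) / bin_size) + 1L, length(masks[[ch]]))
    masks[[ch]][b0:b1] <- TRUE
  }
  masks
}

#' Fold enrichment of chromatin states over genomic features
#'
#' Features are rasterized to bins (any overlap counts); for state `s`
#' and feature class `f`,
#' `fold = (bins(s & f) / bins(s)) / (bins(f) / bins(genome))`.
#' With `marks` supplied, each mark's present bins are scored as an
#' additional feature column. States with zero bins yield `NA` rows.
#'
#' @param seg a `segmentation`.
#' @param features a [feature_annotation()] (one column per feature
#'   class), or `NULL` for marks only.
#' @param marks optional [binarized_marks()] on the same binning.
#' @return numeric matrix states x (feature classes + marks) of fold
#'   enrichments; overlap counts in `attr(, "counts")`.
#' @export
overlap_enrichment <- function(seg, features = NULL, marks = NULL) {
  stopifnot(inherits(seg, "segmentation"))
  state_vec <- unlist(seg$states, use.names = FALSE)
  total <- length(state_vec)
  cols <- list()
  if (!is.null(features)) {
    df <- as.data.frame(features)
    for (cl in sort(unique(df$feature_class))) {
      masks <- rasterize_features(df[df$feature_class == cl, , drop = FALSE],
                                  seg$chrom_sizes, seg$bin_size)
      cols[[cl]] <- unlist(masks[names(seg$states)], use.names = FALSE)
    }
  }
  if (!is.null(marks)) {
    if (marks$bin_size != seg$bin_size)
      stop("marks and segmentation bin sizes differ", call. = FALSE)
    for (mk in marks$marks) {
      cols[[mk]] <- unlist(lapply(names(seg$states), function(ch)
        marks$calls[[ch]][, mk] == 1), use.names = FALSE)
    }
  }
  if (!length(cols)) stop("supply features and/or marks", call. = FALSE)
  states <- seq_len(seg$n_states)
  state_bins <- vapply(states, function(s) sum(state_vec == s), numeric(1))
  fold <- matrix(NA_real_, length(states), length(cols),
                 dimnames = list(paste0("E", states), names(cols)))
  counts <- fold
  feature_bins <- vapply(cols, sum, numeric(1))
  for (j in seq_along(cols)) {
    for (s in states) {
      ov <- sum(cols[[j]] & state_vec == s)
      counts[s, j] <- ov
      if (state_bins[s] > 0 && feature_bins[j] > 0)
        fold[s, j] <- (ov / state_bins[s]) / (feature_bins[j] / total)
    }
  }
  attr(fold, "counts") <- counts
  attr(fold, "state_bins") <- stats::setNames(state_bins, rownames(fold))
  attr(fold, "feature_bins") <- feature_bins
  fold
}
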