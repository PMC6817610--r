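#' Simulate an FPKM-like expression matrix with planted co-expression
#' modules
#'
#' Each planted module is driven by a latent per-sample profile; a member
#' gene's log-expression is
#' `mu_g + sqrt(rho) * latent + sqrt(1 - rho) * noise_sd * eps`, so any
#' two members correlate at `rho` (for `noise_sd = 1`) on the log scale.
#' Background genes are independent. Log values are mapped to a
#' nonnegative FPKM-like scale as `2^g - 1` (floored at 0), so the
#' pipeline's default `log2(FPKM + 1)` transform recovers the latent
#' scale exactly.
#'
#' @param n_genes total genes (default 200).
#' @param n_samples samples (default 200).
#' @param n_modules planted modules (default 10).
#' @param module_size genes per module (default 8).
#' @param within_corr target within-module correlation rho in [0, 1]
#'   (default 0.9).
#' @param noise_sd gene-specific noise standard deviation (default 1;
#'   values other than 1 lower the realized correlation below rho).
#' @param seed RNG seed.
#' @return list with `expression` (validated matrix) and `truth` (planted
#'   module membership, all gene ids, parameters, seed).
#' @export
simulate_expression <- function(n_genes = 200L, n_samples = 200L,
                                n_modules = 10L, module_size = 8L,
                                within_corr = 0.9, noise_sd = 1, seed = 1L) {
  if (within_corr < 0 || within_corr > 1)
    stop("within_corr must lie in [0, 1]", call. = FALSE)
  if (n_modules * module_size > n_genes)
    stop("n_modules * module_size exceeds n_genes", call. = FALSE)
  genes <- sprintf("G%04d", seq_len(n_genes))
  samples <- sprintf("S%03d", seq_len(n_samples))
  modules <- lapply(seq_len(n_modules), function(m)
    genes[((m - 1L) * module_size + 1L):(m * module_size)])
  names(modules) <- sprintf("MOD%02d", seq_len(n_modules))
  g <- with_seed(seed, {
    mu <- stats::runif(n_genes, 4, 8)          # per-gene baseline, log2 scale
    latent <- matrix(stats::rnorm(n_modules * n_samples), n_modules, n_samples)
    eps <- matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                  n_genes, n_samples)
    out <- mu + sqrt(1 - within_corr) * eps
    for (m in seq_len(n_modules)) {
      rows <- ((m - 1L) * module_size + 1L):(m * module_size)
      out[rows, ] <- out[rows, ] +
        sqrt(within_corr) * matrix(latent[m, ], module_size, n_samples,
                                   byrow = TRUE)
    }
    out
  })
  fpkm <- pmax(2^g - 1, 0)
  dimnames(fpkm) <- list(genes, samples)
  validate_expression_matrix(fpkm)
  list(expression = fpkm,
       truth = list(modules = modules, genes = genes,
                    within_corr = within_corr, noise_sd = noise_sd,
                    seed = seed))
}

#' Simulate a gene-set collection around planted modules
#'
#' One term per planted module (subsampled into `size_range` when larger),
#' plus random decoy terms drawn from the full gene universe.
#'
#' @param truth `truth` element of [simulate_expression()].
#' @param extra_terms number of decoy terms (default 20).
#' @param size_range term-size interval, default `c(4, 20)` to match the
#'   prior-knowledge window used for AUROC evaluation.
#' @param seed RNG seed.
#' @return gene-set collection (named list of member vectors).
#' @export
simulate_gene_sets <- function(truth, extra_terms = 20L,
                               size_range = c(4L, 20L), seed = 1L) {
  if (is.null(truth$modules) || !length(truth$modules))
    stop("truth contains no planted modules", call. = FALSE)
  small <- lengths(truth$modules) < size_range[1L]
  if (any(small))
    stop("module(s) smaller than the minimum term size: ",
         paste(names(truth$modules)[small], collapse = ", "), call. = FALSE)
  with_seed(seed, {
    sets <- lapply(truth$modules, function(g) {
      if (length(g) > size_range[2L]) sort(sample(g, size_range[2L])) else g
    })
    names(sets) <- paste0("TERM_", names(truth$modules))
    if (extra_terms > 0L) {
      decoys <- lapply(seq_len(extra_terms), function(i) {
        sz <- sample(size_range[1L]:size_range[2L], 1L)
        sort(sample(truth$genes, sz))
      })
      names(decoys) <- sprintf("DECOY%02d", seq_len(extra_terms))
      sets <- c(sets, decoys)
    }
    attr(sets, "descriptions") <-
      stats::setNames(names(sets), names(sets))
    sets
  })
}

#' Simulate promoter sequences with a planted motif
#'
#' Background bases are i.i.d. at the given GC content; each foreground
#' promoter receives exactly `planted_per_promoter` non-overlapping copies
#' of the motif (instantiated from its IUPAC consensus) at seeded
#' positions.
#'
#' @param n_genes promoter universe size (default 500).
#' @param length promoter length in bp (default 3000).
#' @param gc GC content of the background (default 0.4).
#' @param motif planted IUPAC consensus (default the G-box "CACGTG").
#' @param foreground gene ids carrying the motif; default the first 50
#'   genes (so 50 foreground / 450 background at the defaults).
#' @param planted_per_promoter copies per foreground promoter (default 2).
#' @param seed RNG seed.
#' @return list with `promoters` (named character vector) and `truth`
#'   (motif, foreground, planted positions, seed).
#' @export
simulate_promoters <- function(n_genes = 500L, length = 3000L, gc = 0.4,
                               motif = "CACGTG", foreground = NULL,
                               planted_per_promoter = 2L, seed = 3L) {
  validate_iupac(motif)
  w <- nchar(motif)
  if (w >= length) stop("planted motif longer than the promoter", call. = FALSE)
  genes <- sprintf("G%04d", seq_len(n_genes))
  if (is.null(foreground)) foreground <- genes[seq_len(min(50L, n_genes))]
  if (!all(foreground %in% genes))
    stop("foreground ids outside the gene universe", call. = FALSE)
  if (planted_per_promoter * 2L * w > length)
    stop("cannot place ", planted_per_promoter,
         " non-overlapping copies in ", length, " bp", call. = FALSE)
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    seqs <- vapply(genes, function(g) {
      paste(sample(names(base_p), length, replace = TRUE, prob = base_p),
            collapse = "")
    }, character(1))
    positions <- list()
    for (g in foreground) {
      placed <- integer(0)
      s <- strsplit(seqs[[g]], "")[[1L]]
      while (base::length(placed) < planted_per_promoter) {
        pos <- sample.int(length - w + 1L, 1L)
        if (!any(abs(pos - placed) < w)) {
          inst <- vapply(strsplit(motif, "")[[1L]], function(ch)
            sample(strsplit(IUPAC_CODES[[ch]], "")[[1L]], 1L), character(1))
          s[pos:(pos + w - 1L)] <- inst
          placed <- c(placed, pos)
        }
      }
      seqs[g] <- paste(s, collapse = "")
      positions[[g]] <- sort(placed)
    }
    list(promoters = seqs,
         truth = list(motif = motif, foreground = foreground,
                      positions = positions, gc = gc, seed = seed))
  })
}

#' Simulate binned chromatin-mark signal from a known HMM
#'
#' A state path is sampled from the supplied (or default) HMM; mark
#' presence per bin is Bernoulli with the state's emission probability,
#' and raw per-bin counts are Poisson with mean
#' `mean_signal_per_present_bin` for present bins and
#' `mean_signal_per_absent_bin` otherwise. A feature annotation labels
#' the intervals of the first (signal-richest) state as "promoter". The
#' default model has 3 states over 4 marks, with one low-signal
#' background state occupying most of the genome so the Poisson-tail
#' binarization separates cleanly.
#'
#' @param n_bins bins on a single chromosome "chr1" (default 20000).
#' @param marks mark names (default four histone modifications).
#' @param n_states hidden states (default 3).
#' @param emissions,transitions,initial HMM parameters; defaults built in.
#' @param mean_signal_per_present_bin,mean_signal_per_absent_bin Poisson
#'   means for present/absent bins (defaults 10 and 0.2).
#' @param bin_size bin width in bp (default 200).
#' @param seed RNG seed (default 7).
#' @return list with `tracks` (named list of [signal_track()]),
#'   `features` ([feature_annotation()]) and `truth` (the generating
#'   model, the true state path, and the exact per-bin Bernoulli calls as
#'   a [binarized_marks()]).
#' @export
simulate_chromatin <- function(n_bins = 20000L,
                               marks = c("H3K4me3", "H3K27me3", "H3K9ac",
                                         "H3K36me3"),
                               n_states = 3L, emissions = NULL,
                               transitions = NULL, initial = NULL,
                               mean_signal_per_present_bin = 10,
                               mean_signal_per_absent_bin = 0.2,
                               bin_size = 200L, seed = 7L) {
  if (mean_signal_per_present_bin <= mean_signal_per_absent_bin)
    stop("present-bin mean signal must exceed absent-bin mean signal",
         call. = FALSE)
  if (is.null(emissions)) {
    if (n_states != 3L || length(marks) != 4L)
      stop("default emissions cover 3 states x 4 marks; supply 'emissions'",
           call. = FALSE)
    emissions <- rbind(c(0.95, 0.80, 0.10, 0.05),
                       c(0.10, 0.15, 0.90, 0.80),
                       c(0.02, 0.05, 0.05, 0.02))
  }
  emissions <- as.matrix(emissions)
  colnames(emissions) <- marks
  S <- nrow(emissions)
  if (is.null(transitions)) {
    if (S != 3L) stop("default transitions cover 3 states; supply 'transitions'",
                      call. = FALSE)
    transitions <- rbind(c(0.90, 0.05, 0.05),
                         c(0.05, 0.90, 0.05),
                         c(0.02, 0.02, 0.96))
  }
  transitions <- as.matrix(transitions)
  if (is.null(initial)) initial <- c(rep(0.2, S - 1L), 1 - 0.2 * (S - 1L))
  if (!isTRUE(all.equal(unname(rowSums(transitions)), rep(1, S), tolerance = 1e-9)))
    stop("transition rows must sum to 1", call. = FALSE)
  chrom_sizes <- c(chr1 = as.integer(n_bins) * as.integer(bin_size))
  out <- with_seed(seed, {
    path <- integer(n_bins)
    path[1L] <- sample.int(S, 1L, prob = initial)
    for (t in 2L:n_bins)
      path[t] <- sample.int(S, 1L, prob = transitions[path[t - 1L], ])
    present <- matrix(stats::rbinom(n_bins * length(marks), 1L,
                                    emissions[path, ]),
                      n_bins, length(marks), dimnames = list(NULL, marks))
    counts <- matrix(stats::rpois(n_bins * length(marks),
                                  ifelse(present == 1L,
                                         mean_signal_per_present_bin,
                                         mean_signal_per_absent_bin)),
                     n_bins, length(marks))
    list(path = path, present = present, counts = counts)
  })
  tracks <- lapply(seq_along(marks), function(j)
    signal_track(list(chr1 = out$counts[, j]), chrom_sizes, bin_size))
  names(tracks) <- marks
  r <- rle(out$path == 1L)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  keep <- r$values
  features <- feature_annotation(
    chrom = rep("chr1", sum(keep)),
    start = starts[keep] * bin_size,
    end = pmin(ends[keep] * bin_size, chrom_sizes[["chr1"]]),
    feature_class = "promoter")
  truth_model <- chromatin_model(emissions, transitions, initial, marks)
  list(tracks = tracks, features = features,
       truth = list(model = truth_model, path = out$path,
                    binary = binarized_marks(list(chr1 = out$present),
                                             chrom_sizes, bin_size),
                    seed = seed))
}
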