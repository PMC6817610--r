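#' Benjamini-Hochberg step-up false discovery rates
#'
#' Input p-values must lie in (0, 1]; adjusted values are returned in
#' input order and capped at 1.
#'
#' @param p numeric vector of p-values.
#' @return vector of BH-adjusted q-values.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Gene-set enrichment by the hypergeometric (Fisher) test
#'
#' For each term, the upper-tail hypergeometric probability
#' P(X >= k | N, K, n) of observing at least the overlap `k` between the
#' query (size `n`) and the term (size `K`) in a universe of `N` genes.
#' BH FDR is computed across tested terms (overlap >= 1 and at least 2
#' term genes in the universe); terms with zero overlap are reported with
#' p = 1 and are not counted in the multiple-testing burden.
#'
#' @param query character vector of genes of interest; genes outside the
#'   universe are dropped with a warning.
#' @param sets gene-set collection ([read_gene_sets()]).
#' @param universe background gene ids (deduplicated); conventionally all
#'   genes in the expression matrix.
#' @param fdr_cut rows with FDR at or below this are flagged significant
#'   (default 0.05).
#' @return data.frame with term_id, name, k_overlap, n_query, K_term,
#'   N_universe, p_value, fdr, significant; ordered by p.
#' @export
fisher_enrich <- function(query, sets, universe, fdr_cut = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("empty query after universe intersection", call. = FALSE)
  N <- length(universe); n <- length(query)
  desc <- attr(sets, "descriptions")
  rows <- lapply(names(sets), function(id) {
    term <- intersect(sets[[id]], universe)
    K <- length(term)
    k <- length(intersect(term, query))
    tested <- k >= 1L && K >= 2L
    p <- if (k == 0L) 1 else stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id,
               name = if (!is.null(desc) && !is.na(desc[id])) desc[[id]] else id,
               k_overlap = k, n_query = n, K_term = K, N_universe = N,
               p_value = p, tested = tested, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  if (any(out$tested)) out$fdr[out$tested] <- bh_fdr(out$p_value[out$tested])
  out$significant <- !is.na(out$fdr) & out$fdr <= fdr_cut
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment table as TSV
#'
#' @param enrichment data.frame from [fisher_enrich()].
#' @param path output path.
#' @export
write_enrichment <- function(enrichment, path) {
  utils::write.table(enrichment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
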