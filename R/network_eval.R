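#' Label gene pairs from gene-set prior knowledge
#'
#' Terms are restricted to genes present in the expression matrix; terms
#' whose restricted size lies in `[size_min, size_max]` (default [4, 20])
#' form the prior. Positive pairs are all unordered pairs co-annotated to
#' at least one kept term; negative pairs are a seeded uniform sample of
#' pairs sharing no kept term.
#'
#' @param sets gene-set collection from [read_gene_sets()].
#' @param genes_in_matrix character vector of measured gene ids.
#' @param size_min,size_max term-size interval defining prior-knowledge
#'   terms.
#' @param n_negative number of negative pairs (default: one per positive).
#' @param seed RNG seed for negative sampling.
#' @return data.frame of class `labeled_pairs` with columns gene_a,
#'   gene_b, label; provenance in attributes.
#' @export
label_pairs_from_go <- function(sets, genes_in_matrix, size_min = 4L,
                                size_max = 20L, n_negative = NULL, seed = 1L) {
  if (!length(sets)) stop("empty gene-set collection", call. = FALSE)
  restricted <- lapply(sets, intersect, y = genes_in_matrix)
  sizes <- lengths(restricted)
  keep <- sizes >= size_min & sizes <= size_max
  if (!any(keep))
    stop(sprintf("no prior-knowledge terms: no term has between %d and %d measured genes",
                 size_min, size_max), call. = FALSE)
  kept <- restricted[keep]
  pos_keys <- unique(unlist(lapply(kept, function(g) {
    g <- sort(g)
    if (length(g) < 2L) return(character(0))
    p <- utils::combn(g, 2L)
    pair_key(p[1L, ], p[2L, ])
  })))
  if (!length(pos_keys))
    stop("prior-knowledge terms yield no gene pairs", call. = FALSE)
  n_pos <- length(pos_keys)
  if (is.null(n_negative)) n_negative <- n_pos
  genes <- sort(unique(genes_in_matrix))
  n_all <- choose(length(genes), 2)
  if (n_all - n_pos < n_negative)
    stop(sprintf("only %d candidate negative pairs available, %d requested",
                 n_all - n_pos, n_negative), call. = FALSE)
  neg_keys <- with_seed(seed, {
    found <- character(0)
    while (length(found) < n_negative) {
      a <- sample(genes, 2L * (n_negative - length(found)) + 10L, replace = TRUE)
      b <- sample(genes, length(a), replace = TRUE)
      k <- pair_key(a, b)[a != b]
      k <- setdiff(unique(k), c(pos_keys, found))
      found <- c(found, k)
    }
    found[seq_len(n_negative)]
  })
  split_key <- function(k) do.call(rbind, strsplit(k, "\r", fixed = TRUE))
  pos <- split_key(pos_keys); neg <- split_key(neg_keys)
  out <- data.frame(gene_a = c(pos[, 1L], neg[, 1L]),
                    gene_b = c(pos[, 2L], neg[, 2L]),
                    label = rep(c("positive", "negative"),
                                c(n_pos, n_negative)),
                    stringsAsFactors = FALSE)
  attr(out, "size_interval") <- c(size_min, size_max)
  attr(out, "seed") <- seed
  attr(out, "n_terms") <- sum(keep)
  class(out) <- c("labeled_pairs", "data.frame")
  out
}

#' Area under the ROC curve by the rank (Mann-Whitney) formulation
#'
#' Equals P(score_pos > score_neg) + 0.5 P(tie) over all positive x
#' negative pairs.
#'
#' @param scores numeric scores, one per observation.
#' @param labels `"positive"`/`"negative"` character vector or logical
#'   (TRUE = positive), aligned with `scores`; a `labeled_pairs`
#'   data.frame is also accepted (its `label` column is used).
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  if (is.data.frame(labels)) labels <- labels$label
  if (is.character(labels)) labels <- labels == "positive"
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  if (anyNA(scores) || anyNA(labels))
    stop("scores/labels contain NA", call. = FALSE)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUROC needs both a positive and a negative class", call. = FALSE)
  r <- rank(scores)                  # midranks handle ties as 1/2 credit
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Tune (PCC, MR) thresholds by AUROC against labeled prior pairs
#'
#' Each grid cell (pcc_cut, mr_cut) defines a thresholded network; labeled
#' pairs passing the cell's filter are scored 1, the rest 0, and the AUROC
#' of this binary classifier against the labels is recorded together with
#' the number of edges the cell would induce over the full matrix. Cells
#' under which no labeled pair passes get AUROC `NA` and are excluded from
#' the argmax; argmax ties are broken toward sparser networks.
#'
#' @param corr PCC matrix.
#' @param mr positive-tail mutual-rank matrix on the same genes.
#' @param labeled `labeled_pairs` from [label_pairs_from_go()]; pairs with
#'   genes missing from the matrix are dropped with a warning.
#' @param pcc_grid,mr_grid candidate thresholds.
#' @return list with `table` (pcc_cut, mr_cut, auroc, n_edges) and `best`
#'   (the argmax row).
#' @export
select_thresholds <- function(corr, mr, labeled,
                              pcc_grid = seq(0.5, 0.95, by = 0.05),
                              mr_grid = seq(10, 100, by = 10)) {
  if (!length(pcc_grid) || !length(mr_grid))
    stop("empty threshold grid", call. = FALSE)
  ids <- rownames(corr)
  ok <- labeled$gene_a %in% ids & labeled$gene_b %in% ids
  if (!all(ok)) {
    warning(sum(!ok), " labeled pair(s) with genes absent from the matrix dropped")
    labeled <- labeled[ok, , drop = FALSE]
  }
  if (!nrow(labeled)) stop("no labeled pairs overlap the matrix", call. = FALSE)
  ia <- match(labeled$gene_a, ids); ib <- match(labeled$gene_b, ids)
  pair_pcc <- corr[cbind(ia, ib)]
  pair_mr <- mr[cbind(ia, ib)]
  ut <- upper.tri(corr)
  all_pcc <- corr[ut]; all_mr <- mr[ut]
  grid <- expand.grid(pcc_cut = pcc_grid, mr_cut = mr_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- grid$pcc_cut[i]; m <- grid$mr_cut[i]
    passed <- as.numeric(pair_pcc >= p & pair_mr <= m)
    n_edges <- sum(all_pcc >= p & all_mr <= m)
    a <- if (sum(passed) == 0) NA_real_ else auroc(passed, labeled)
    c(auroc = a, n_edges = n_edges)
  })
  tab <- cbind(grid, do.call(rbind, res))
  cand <- tab[!is.na(tab$auroc), , drop = FALSE]
  if (!nrow(cand))
    stop("argmax undefined: every grid cell empties the network over the labeled pairs",
         call. = FALSE)
  o <- order(-cand$auroc, cand$n_edges, -cand$pcc_cut, cand$mr_cut)
  list(table = tab, best = cand[o[1L], , drop = FALSE])
}
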