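#' Flag outlier samples by correlation-based cluster analysis
#'
#' Computes the sample-sample Pearson correlation matrix (on transformed
#' expression) and flags samples whose mean correlation with all other
#' samples falls below `min_mean_corr`. The hierarchical-clustering leaf
#' order is returned for visual inspection of the outliers.
#'
#' @param x expression matrix (genes x samples).
#' @param min_mean_corr samples with mean inter-sample correlation below
#'   this are flagged (default 0.5).
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @param transform `"log2p1"` (default, log2(FPKM+1)) or `"none"`.
#' @return list with `kept`, `flagged`, `sample_cor` and `cluster_order`.
#' @export
qc_filter_samples <- function(x, min_mean_corr = 0.5, linkage = "average",
                              transform = c("log2p1", "none")) {
  validate_expression_matrix(x)
  transform <- match.arg(transform)
  if (ncol(x) < 3L)
    stop("sample QC needs at least 3 samples", call. = FALSE)
  y <- if (transform == "log2p1") log2(x + 1) else x
  if (any(apply(y, 2L, stats::sd) == 0))
    stop("sample(s) with constant expression; sample correlation undefined",
         call. = FALSE)
  sc <- stats::cor(y)
  mean_corr <- (rowSums(sc) - 1) / (ncol(sc) - 1)
  flagged <- colnames(x)[mean_corr < min_mean_corr]
  hc <- stats::hclust(stats::as.dist(1 - sc), method = linkage)
  list(kept = setdiff(colnames(x), flagged),
       flagged = flagged,
       sample_cor = sc,
       mean_corr = mean_corr,
       cluster_order = colnames(x)[hc$order])
}

#' Pairwise Pearson correlation between genes
#'
#' Computes the gene-gene PCC matrix across samples. Genes with zero
#' variance under the chosen transform have undefined PCC; they are
#' excluded from the matrix and listed in `attr(, "dropped_genes")`.
#'
#' @param x expression matrix (genes x samples), at least 3 samples.
#' @param transform `"log2p1"` (default) or `"none"` for raw FPKM.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
compute_pcc <- function(x, transform = c("log2p1", "none")) {
  validate_expression_matrix(x)
  transform <- match.arg(transform)
  if (ncol(x) < 3L)
    stop("PCC needs at least 3 samples", call. = FALSE)
  y <- if (transform == "log2p1") log2(x + 1) else x
  v <- apply(y, 1L, stats::sd)
  dropped <- rownames(y)[v == 0]
  y <- y[v > 0, , drop = FALSE]
  if (nrow(y) == 0L)
    stop("all genes have zero variance under transform '", transform, "'",
         call. = FALSE)
  cc <- stats::cor(t(y))
  cc <- (cc + t(cc)) / 2          # enforce exact symmetry
  cc[cc > 1] <- 1; cc[cc < -1] <- -1
  diag(cc) <- 1
  attr(cc, "dropped_genes") <- dropped
  attr(cc, "transform") <- transform
  cc
}

# Rank(A->B): position of B when A's partners (self excluded) are sorted by
# descending PCC for the positive tail / ascending for the negative tail,
# ties broken lexicographically by gene id for cross-platform determinism.
rank_matrix <- function(corr, tail = c("positive", "negative")) {
  tail <- match.arg(tail)
  n <- nrow(corr)
  ids <- rownames(corr)
  rk <- matrix(NA_real_, n, n, dimnames = dimnames(corr))
  for (a in seq_len(n)) {
    cand <- setdiff(seq_len(n), a)
    key <- if (tail == "positive") -corr[a, cand] else corr[a, cand]
    o <- order(key, ids[cand])
    rk[a, cand[o]] <- seq_along(cand)
  }
  rk
}

#' Mutual rank of gene pairs from a correlation matrix
#'
#' `Rank(A->B)` is the position of B in A's partner list sorted by
#' descending PCC (`tail = "positive"`) or ascending PCC
#' (`tail = "negative"`, for anti-correlated partners). The mutual rank
#' combines the two directed ranks, by default as their geometric mean
#' `sqrt(Rank(A->B) * Rank(B->A))`; `mode = "product"` uses the raw
#' product.
#'
#' @param corr symmetric PCC matrix from [compute_pcc()].
#' @param tail rank on the positive (descending-PCC) or negative
#'   (ascending-PCC) tail.
#' @param mode `"geometric_mean"` (default) or `"product"`.
#' @return symmetric matrix of mutual ranks (diagonal `NA`); every scored
#'   pair has MR >= 1.
#' @export
compute_mutual_rank <- function(corr, tail = c("positive", "negative"),
                                mode = c("geometric_mean", "product")) {
  tail <- match.arg(tail); mode <- match.arg(mode)
  if (nrow(corr) < 3L)
    stop("mutual rank needs at least 3 genes", call. = FALSE)
  if (is.null(rownames(corr)))
    stop("correlation matrix must carry gene ids as dimnames", call. = FALSE)
  rk <- rank_matrix(corr, tail)
  pr <- rk * t(rk)
  mr <- if (mode == "geometric_mean") sqrt(pr) else pr
  attr(mr, "mode") <- mode
  attr(mr, "tail") <- tail
  mr
}

#' Threshold presets for network construction
#'
#' The global network uses PCC >= 0.8 with MR <= 55; the conditional
#' (tissue-preferential) network uses PCC >= 0.8 with MR <= 50. Both use
#' PCC <= -0.3 for negative edges.
#'
#' @param preset `"global"` or `"conditional"`.
#' @return list with `pcc_min_pos`, `pcc_max_neg` and `mr_max`.
#' @export
network_thresholds <- function(preset = c("global", "conditional")) {
  preset <- match.arg(preset)
  list(pcc_min_pos = 0.8, pcc_max_neg = -0.3,
       mr_max = if (preset == "global") 55 else 50)
}

#' Build a signed co-expression network from PCC and mutual-rank matrices
#'
#' A positive edge requires `pcc >= pcc_min_pos` and positive-tail
#' `MR <= mr_max`; a negative edge requires `pcc <= pcc_max_neg` and
#' negative-tail `MR <= mr_max`. The thresholds used are recorded in the
#' returned object.
#'
#' @param corr PCC matrix.
#' @param mr_pos positive-tail mutual-rank matrix.
#' @param mr_neg negative-tail mutual-rank matrix, or `NULL` to skip
#'   negative edges.
#' @param pcc_min_pos,pcc_max_neg,mr_max filtering thresholds
#'   (defaults: the global-network preset 0.8 / -0.3 / 55).
#' @return object of class `coexpression_network` with elements `nodes`,
#'   `edges` (data.frame gene_a, gene_b, pcc, mr, sign) and `thresholds`.
#' @export
build_network <- function(corr, mr_pos, mr_neg = NULL,
                          pcc_min_pos = 0.8, pcc_max_neg = -0.3, mr_max = 55) {
  ids <- rownames(corr)
  if (!identical(ids, rownames(mr_pos)))
    stop("corr and mr_pos gene ids differ", call. = FALSE)
  if (!is.null(mr_neg) && !identical(ids, rownames(mr_neg)))
    stop("corr and mr_neg gene ids differ", call. = FALSE)
  ut <- upper.tri(corr)
  take_edges <- function(mask, mr, sign) {
    idx <- which(mask & ut, arr.ind = TRUE)
    if (!nrow(idx))
      return(data.frame(gene_a = character(0), gene_b = character(0),
                        pcc = numeric(0), mr = numeric(0),
                        sign = character(0), stringsAsFactors = FALSE))
    a <- ids[idx[, 1L]]; b <- ids[idx[, 2L]]
    swap <- a > b
    data.frame(gene_a = ifelse(swap, b, a), gene_b = ifelse(swap, a, b),
               pcc = corr[idx], mr = mr[idx], sign = sign,
               stringsAsFactors = FALSE)
  }
  pos <- take_edges(corr >= pcc_min_pos & mr_pos <= mr_max, mr_pos, "positive")
  neg <- if (is.null(mr_neg)) NULL else
    take_edges(corr <= pcc_max_neg & mr_neg <= mr_max, mr_neg, "negative")
  edges <- rbind(pos, neg)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = ids, edges = edges,
                 thresholds = list(pcc_min_pos = pcc_min_pos,
                                   pcc_max_neg = pcc_max_neg,
                                   mr_max = mr_max,
                                   mr_mode = attr(mr_pos, "mode"))),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("Co-expression network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  tb <- table(x$edges$sign)
  cat("  positive:", if ("positive" %in% names(tb)) tb[["positive"]] else 0L,
      " negative:", if ("negative" %in% names(tb)) tb[["negative"]] else 0L, "\n")
  cat(sprintf("  thresholds: PCC >= %.2f (pos), PCC <= %.2f (neg), MR <= %g [%s]\n",
              x$thresholds$pcc_min_pos, x$thresholds$pcc_max_neg,
              x$thresholds$mr_max,
              if (is.null(x$thresholds$mr_mode)) "?" else x$thresholds$mr_mode))
  invisible(x)
}

#' @export
summary.coexpression_network <- function(object, ...) {
  deg <- table(factor(c(object$edges$gene_a, object$edges$gene_b),
                      levels = object$nodes))
  out <- list(n_nodes = length(object$nodes),
              n_edges = nrow(object$edges),
              n_connected = sum(deg > 0),
              degree_summary = summary(as.integer(deg)),
              thresholds = object$thresholds)
  class(out) <- "summary.coexpression_network"
  out
}

#' @export
print.summary.coexpression_network <- function(x, ...) {
  cat("Co-expression network\n")
  cat("  nodes:", x$n_nodes, " edges:", x$n_edges, "\n")
  cat(sprintf("  connected nodes: %d (%.1f%%)\n", x$n_connected,
              100 * x$n_connected / x$n_nodes))
  cat("  degree: "); print(x$degree_summary)
  invisible(x)
}

#' Compare two co-expression networks
#'
#' Edges are identified by their unordered gene pair; the comparison
#' reports the edge Jaccard index, the shared edge count, and a per-gene
#' table of neighbour overlap.
#'
#' @param a,b `coexpression_network` objects (node sets may differ).
#' @return list with `jaccard`, `n_shared`, `n_a`, `n_b` and `per_gene`
#'   (data.frame gene, deg_a, deg_b, shared, jaccard).
#' @export
compare_networks <- function(a, b) {
  ka <- pair_key(a$edges$gene_a, a$edges$gene_b)
  kb <- pair_key(b$edges$gene_a, b$edges$gene_b)
  shared <- intersect(ka, kb)
  uni <- union(ka, kb)
  genes <- sort(union(a$nodes, b$nodes))
  nb <- function(net, g) {
    e <- net$edges
    c(e$gene_b[e$gene_a == g], e$gene_a[e$gene_b == g])
  }
  per_gene <- do.call(rbind, lapply(genes, function(g) {
    na_ <- nb(a, g); nb_ <- nb(b, g)
    s <- length(intersect(na_, nb_)); u <- length(union(na_, nb_))
    data.frame(gene = g, deg_a = length(na_), deg_b = length(nb_),
               shared = s, jaccard = if (u) s / u else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(jaccard = if (length(uni)) length(shared) / length(uni) else NA_real_,
       n_shared = length(shared), n_a = length(ka), n_b = length(kb),
       per_gene = per_gene)
}

#' Write a network edge list as TSV
#'
#' Columns gene_a, gene_b, pcc (6 decimals), mr (2 decimals), sign.
#'
#' @param network a `coexpression_network`.
#' @param path output path.
#' @export
write_edge_list <- function(network, path) {
  e <- network$edges
  lines <- c("gene_a\tgene_b\tpcc\tmr\tsign",
             sprintf("%s\t%s\t%.6f\t%.2f\t%s",
                     e$gene_a, e$gene_b, e$pcc, e$mr, e$sign))
  writeLines(lines, path)
  invisible(path)
}

#' Read a network edge list written by [write_edge_list()]
#'
#' @param path TSV edge list.
#' @return a `coexpression_network` (nodes = genes present in edges;
#'   thresholds unknown).
#' @export
read_edge_list <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "pcc", "mr", "sign")
  if (!all(need %in% colnames(e)))
    stop("edge list must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  structure(list(nodes = sort(unique(c(e$gene_a, e$gene_b))),
                 edges = e[, need],
                 thresholds = list(pcc_min_pos = NA_real_,
                                   pcc_max_neg = NA_real_,
                                   mr_max = NA_real_, mr_mode = NA_character_)),
            class = "coexpression_network")
}
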