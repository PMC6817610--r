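#' Extract strand-resolved promoter sequences
#'
#' For a forward-strand gene the promoter is the `length` bp immediately
#' upstream of the TSS, `[TSS - length, TSS)`; for a reverse-strand gene
#' it is `[gene_end, gene_end + length)` reverse-complemented, so every
#' returned sequence reads 5' to 3' toward the TSS. Promoters truncated at
#' a chromosome edge are flagged in `attr(, "truncated")`.
#'
#' @param genome named character vector of chromosome sequences, a
#'   `DNAStringSet`, or a path to a FASTA file.
#' @param annotation [feature_annotation()] of gene intervals; every row
#'   needs a gene_id and a `+`/`-` strand.
#' @param length promoter length in bp (default 3000).
#' @return named uppercase character vector, one promoter per gene.
#' @export
extract_promoters <- function(genome, annotation, length = 3000L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  ann <- as.data.frame(annotation)
  if (any(is.na(ann$gene_id) | !nzchar(ann$gene_id)))
    stop("every promoter interval needs a gene_id", call. = FALSE)
  if (any(!ann$strand %in% c("+", "-")))
    stop("gene(s) without strand: ",
         paste(ann$gene_id[!ann$strand %in% c("+", "-")], collapse = ", "),
         call. = FALSE)
  missing_chr <- setdiff(unique(ann$chrom), names(genome))
  if (length(missing_chr))
    stop("chromosome(s) missing from FASTA: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  out <- character(nrow(ann))
  truncated <- character(0)
  for (i in seq_len(nrow(ann))) {
    chr_len <- Biostrings::width(genome[ann$chrom[i]])
    if (ann$strand[i] == "+") {
      to <- ann$start[i]                       # TSS (0-based) = interval start
      from <- max(0, to - length)
      s <- as.character(Biostrings::subseq(genome[[ann$chrom[i]]],
                                           start = from + 1L, end = to))
    } else {
      from <- ann$end[i]                       # TSS (0-based) = interval end
      to <- min(chr_len, from + length)
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::subseq(genome[[ann$chrom[i]]], start = from + 1L, end = to)))
    }
    if (nchar(s) < length) truncated <- c(truncated, ann$gene_id[i])
    out[i] <- toupper(s)
  }
  names(out) <- ann$gene_id
  if (anyDuplicated(names(out)))
    stop("duplicate gene_id in annotation: ",
         names(out)[duplicated(names(out))][1L], call. = FALSE)
  attr(out, "truncated") <- truncated
  out
}

# IUPAC consensus -> regex of ACGT character classes. An N in the subject
# sequence belongs to no class, so an ambiguous promoter base never
# satisfies a motif position.
iupac_to_regex <- function(consensus) {
  letters <- strsplit(toupper(consensus), "")[[1L]]
  paste0(vapply(letters, function(ch) {
    b <- IUPAC_CODES[[ch]]
    if (nchar(b) == 1L) b else paste0("[", b, "]")
  }, character(1)), collapse = "")
}

#' Count occurrences of an IUPAC motif in promoter sequences
#'
#' Overlapping matches are counted, on the promoter strand only (set
#' `both_strands = TRUE` to also count matches of the reverse complement).
#'
#' @param promoters named character vector of promoter sequences.
#' @param motif IUPAC consensus string.
#' @param both_strands also count reverse-complement matches
#'   (default FALSE; promoters are already strand-resolved).
#' @return total count, with per-gene counts in `attr(, "per_gene")`.
#' @export
count_motif <- function(promoters, motif, both_strands = FALSE) {
  validate_iupac(motif)
  pats <- paste0("(?=", iupac_to_regex(motif), ")")
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    pats <- c(pats, paste0("(?=", iupac_to_regex(rc), ")"))
  }
  per_gene <- vapply(promoters, function(s) {
    sum(vapply(pats, function(p) {
      m <- gregexpr(p, s, perl = TRUE)[[1L]]
      if (m[1L] == -1L) 0L else length(m)
    }, integer(1)))
  }, integer(1))
  total <- sum(per_gene)
  attr(total, "per_gene") <- per_gene
  total
}

#' Motif enrichment Z-score and normal-tail P-value
#'
#' `Z = (n - mean) / stdev` and `P = 1 - pnorm(n, mean, stdev)`, the
#' statistics summarizing an observed motif count against its randomized
#' background distribution. A zero stdev yields `NA` for both.
#'
#' @param n observed motif count in the query promoters.
#' @param mean,stdev background mean and (population) standard deviation.
#' @return list with `z` and `p`.
#' @export
motif_z_score <- function(n, mean, stdev) {
  if (any(stdev < 0)) stop("stdev must be nonnegative", call. = FALSE)
  z <- ifelse(stdev > 0, (n - mean) / stdev, NA_real_)
  p <- ifelse(stdev > 0, stats::pnorm(n, mean, stdev, lower.tail = FALSE),
              NA_real_)
  list(z = z, p = p)
}

#' Promoter motif enrichment against a randomized gene background
#'
#' For each motif, `N_motif` is its occurrence count in the query genes'
#' promoters; the background distribution is obtained by drawing `m`
#' (= query size) genes from the promoter universe without replacement,
#' `n_draws` times, and counting in each draw. The enrichment statistics
#' are `Z = (N_motif - mean_motif) / stdev_motif` (population standard
#' deviation over draws) and the normal upper-tail
#' `P = 1 - pnorm(N_motif, mean_motif, stdev_motif)`. Motifs absent from
#' every background draw (stdev 0) are reported with `NA` statistics.
#'
#' @param query_genes genes of interest (must have promoters).
#' @param promoters named character vector covering the promoter universe.
#' @param library named character vector of IUPAC consensus motifs.
#' @param n_draws number of background draws (default 1000).
#' @param seed RNG seed for the background draws.
#' @param both_strands passed to [count_motif()].
#' @return data.frame with motif_id, n_motif, mean_motif, stdev_motif,
#'   z_score, p_value, n_draws; ordered by descending Z.
#' @export
motif_enrichment <- function(query_genes, promoters, library,
                             n_draws = 1000L, seed = 1L,
                             both_strands = FALSE) {
  query_genes <- unique(query_genes)
  m <- length(query_genes)
  if (m < 2L) stop("need at least 2 query genes", call. = FALSE)
  if (!all(query_genes %in% names(promoters)))
    stop("query gene(s) without a promoter: ",
         paste(utils::head(setdiff(query_genes, names(promoters)), 5L),
               collapse = ", "), call. = FALSE)
  G <- length(promoters)
  if (m > G) stop("query larger than the promoter universe", call. = FALSE)
  if (n_draws < 1L) stop("n_draws must be >= 1", call. = FALSE)
  # count each motif once per gene; draw totals are then subset sums
  counts <- vapply(library, function(mo)
    attr(count_motif(promoters, mo, both_strands), "per_gene"),
    numeric(G))
  counts <- matrix(counts, nrow = G,
                   dimnames = list(names(promoters), names(library)))
  qsum <- colSums(counts[query_genes, , drop = FALSE])
  draw_idx <- with_seed(seed, {
    replicate(n_draws, sample.int(G, m, replace = FALSE), simplify = FALSE)
  })
  bg <- t(vapply(draw_idx, function(ix) colSums(counts[ix, , drop = FALSE]),
                 numeric(ncol(counts))))
  bg <- matrix(bg, nrow = n_draws)
  mu <- colMeans(bg)
  sd0 <- sqrt(colMeans(bg^2) - mu^2)         # population stdev (ddof = 0)
  sd0[sd0 < 0] <- 0
  zp <- motif_z_score(qsum, mu, sd0)
  out <- data.frame(motif_id = names(library),
                    n_motif = unname(qsum), mean_motif = unname(mu),
                    stdev_motif = unname(sd0), z_score = unname(zp$z),
                    p_value = unname(zp$p), n_draws = n_draws,
                    stringsAsFactors = FALSE)
  zkey <- ifelse(is.na(out$z_score), -Inf, out$z_score)
  out <- out[order(-zkey, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
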