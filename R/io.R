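#' Validate a genes-by-samples expression matrix
#'
#' An expression matrix is a plain numeric matrix of nonnegative FPKM-like
#' values with unique gene identifiers as row names and unique sample
#' identifiers as column names.
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have gene row names and sample column names",
         call. = FALSE)
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g))
    stop("duplicate gene identifier(s): ", paste(dup_g, collapse = ", "),
         call. = FALSE)
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s))
    stop("duplicate sample identifier(s): ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  if (anyNA(x))
    stop("expression matrix contains missing values; imputation is not supported",
         call. = FALSE)
  if (any(x < 0))
    stop("expression values must be nonnegative", call. = FALSE)
  invisible(x)
}

#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; the body must be numeric and nonnegative. Malformed input
#' (ragged rows, non-numeric cells, duplicate identifiers) is reported with
#' row/column context.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix (genes x samples) with dimnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) < 2L)
    stop("expression table needs a header row and at least one gene row",
         call. = FALSE)
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged table: row %d has %d fields, expected %d",
                 bad, nf[bad], nf[1L]), call. = FALSE)
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character")
  gene_ids <- tab[[1L]]
  sample_ids <- colnames(tab)[-1L]
  body <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) & !(body %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                 body[bad[1L, 1L], bad[1L, 2L]],
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]),
         call. = FALSE)
  dimnames(num) <- list(gene_ids, sample_ids)
  validate_expression_matrix(num)
  num
}

#' Write an expression matrix as tab-separated text
#'
#' Values are written with full double precision so a write/read round trip
#' reproduces the matrix exactly.
#'
#' @param x validated expression matrix.
#' @param path output path.
#' @param id_column header for the gene-identifier column.
#' @export
write_expression_matrix <- function(x, path, id_column = "gene_id") {
  validate_expression_matrix(x)
  header <- paste(c(id_column, colnames(x)), collapse = "\t")
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `term<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a line are collapsed (set semantics).
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (one per term), with term
#'   descriptions in `attr(, "descriptions")`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need term, description and >= 1 member",
                   i, length(f)), call. = FALSE)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop(sprintf("GMT line %d ('%s') has an empty member list", i, f[1L]),
           call. = FALSE)
    if (f[1L] %in% names(sets))
      stop("duplicate term id: ", f[1L], call. = FALSE)
    sets[[f[1L]]] <- members
    desc[f[1L]] <- f[2L]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors; descriptions taken from
#'   `attr(sets, "descriptions")` when present.
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(id) {
    d <- if (!is.null(desc) && !is.na(desc[id])) desc[[id]] else id
    paste(c(id, d, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a binned signal track
#'
#' Fixed-width bins (default 200 bp) tile each chromosome without gaps or
#' overlap; the last bin may be short.
#'
#' @param counts named list, one nonnegative numeric vector of per-bin
#'   values per chromosome.
#' @param chrom_sizes named integer vector of chromosome lengths (bp).
#' @param bin_size bin width in bp.
#' @return object of class `signal_track`.
#' @export
signal_track <- function(counts, chrom_sizes, bin_size = 200L) {
  stopifnot(is.list(counts), !is.null(names(counts)))
  for (chrom in names(counts)) {
    if (is.na(chrom_sizes[chrom]))
      stop("no size for chromosome ", chrom, call. = FALSE)
    nb <- n_bins(chrom_sizes[[chrom]], bin_size)
    if (length(counts[[chrom]]) != nb)
      stop(sprintf("chromosome %s: %d bins supplied, %d expected",
                   chrom, length(counts[[chrom]]), nb), call. = FALSE)
    if (any(counts[[chrom]] < 0))
      stop("negative signal on chromosome ", chrom, call. = FALSE)
  }
  structure(list(counts = counts,
                 chrom_sizes = chrom_sizes[names(counts)],
                 bin_size = as.integer(bin_size)),
            class = "signal_track")
}

n_bins <- function(chrom_size, bin_size) as.integer(ceiling(chrom_size / bin_size))

#' Read a bedGraph signal file into fixed bins
#'
#' Intervals are 0-based half-open. Two aggregation semantics are offered:
#' `"coverage"` (default) sets each bin to
#' sum(value x overlap-bp) / bin_size, i.e. mean coverage; `"counts"`
#' attributes each interval's value to the bin containing its midpoint.
#' Uncovered bins are 0.
#'
#' @param path path to a bedGraph file (track/browser/comment lines are
#'   skipped).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param bin_size bin width in bp (default 200).
#' @param mode `"coverage"` or `"counts"`.
#' @return a [signal_track()].
#' @export
read_signal_bedgraph <- function(path, chrom_sizes, bin_size = 200L,
                                 mode = c("coverage", "counts")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  counts <- lapply(chrom_sizes, function(sz) numeric(n_bins(sz, bin_size)))
  names(counts) <- names(chrom_sizes)
  if (length(lines)) {
    f <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(f)
    if (any(nf < 4L))
      stop(sprintf("bedGraph line %d has %d field(s); need chrom, start, end, value",
                   which(nf < 4L)[1L], nf[nf < 4L][1L]), call. = FALSE)
    chrom <- vapply(f, `[[`, character(1), 1L)
    start <- as.numeric(vapply(f, `[[`, character(1), 2L))
    end   <- as.numeric(vapply(f, `[[`, character(1), 3L))
    value <- as.numeric(vapply(f, `[[`, character(1), 4L))
    if (anyNA(start) || anyNA(end) || anyNA(value))
      stop("non-numeric start/end/value in bedGraph", call. = FALSE)
    unknown <- setdiff(unique(chrom), names(chrom_sizes))
    if (length(unknown))
      stop("chromosome(s) not in chrom_sizes: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    if (any(value < 0)) {
      i <- which(value < 0)[1L]
      stop(sprintf("negative value %g at %s:%d-%d", value[i], chrom[i],
                   start[i], end[i]), call. = FALSE)
    }
    if (any(start >= end))
      stop("interval with start >= end in bedGraph", call. = FALSE)
    over <- end > chrom_sizes[chrom]
    if (any(over)) {
      i <- which(over)[1L]
      stop(sprintf("interval %s:%d-%d extends beyond chromosome end (%d)",
                   chrom[i], start[i], end[i], chrom_sizes[[chrom[i]]]),
           call. = FALSE)
    }
    bs <- bin_size
    if (mode == "counts") {
      mid_bin <- floor((start + end) / 2 / bs) + 1L
      for (ch in unique(chrom)) {
        sel <- chrom == ch
        agg <- rowsum(value[sel], mid_bin[sel])
        counts[[ch]][as.integer(rownames(agg))] <-
          counts[[ch]][as.integer(rownames(agg))] + agg[, 1L]
      }
    } else {
      b0 <- floor(start / bs)
      b1 <- floor((end - 1) / bs)
      single <- b0 == b1
      for (ch in unique(chrom)) {
        sel <- chrom == ch & single
        if (any(sel)) {
          w <- value[sel] * (end[sel] - start[sel]) / bs
          agg <- rowsum(w, b0[sel] + 1L)
          ix <- as.integer(rownames(agg))
          counts[[ch]][ix] <- counts[[ch]][ix] + agg[, 1L]
        }
      }
      for (i in which(!single)) {
        ch <- chrom[i]
        bins <- b0[i]:b1[i]
        ov <- pmin(end[i], (bins + 1) * bs) - pmax(start[i], bins * bs)
        counts[[ch]][bins + 1L] <- counts[[ch]][bins + 1L] + value[i] * ov / bs
      }
    }
  }
  signal_track(counts, chrom_sizes, bin_size)
}

#' Write a chromatin-state segmentation as BED4
#'
#' Adjacent bins in the same state are merged; coordinates are 0-based
#' half-open and the final interval is truncated at the chromosome end.
#' States are written as `E<state>`.
#'
#' @param seg a `segmentation` object (see [segment_states()]).
#' @param path output path.
#' @export
write_segmentation_bed <- function(seg, path) {
  stopifnot(inherits(seg, "segmentation"))
  bs <- seg$bin_size
  out <- character(0)
  for (chrom in names(seg$states)) {
    s <- seg$states[[chrom]]
    r <- rle(s)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    start <- starts_bin * bs
    end <- pmin(ends_bin * bs, seg$chrom_sizes[[chrom]])
    out <- c(out, sprintf("%s\t%d\t%d\tE%d", chrom, start, end, r$values))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a BED4 segmentation back into per-bin states
#'
#' Inverse of [write_segmentation_bed()]: intervals must tile each
#' chromosome and carry `E<state>` labels.
#'
#' @param path BED4 file.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param bin_size bin width used when the segmentation was produced.
#' @return a `segmentation` object.
#' @export
read_segmentation_bed <- function(path, chrom_sizes, bin_size = 200L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- vapply(f, `[[`, character(1), 1L)
  start <- as.numeric(vapply(f, `[[`, character(1), 2L))
  end   <- as.numeric(vapply(f, `[[`, character(1), 3L))
  state <- as.integer(sub("^E", "", vapply(f, `[[`, character(1), 4L)))
  if (anyNA(state)) stop("malformed state label in BED4", call. = FALSE)
  states <- lapply(names(chrom_sizes), function(ch) {
    nb <- n_bins(chrom_sizes[[ch]], bin_size)
    v <- integer(nb)
    sel <- which(chrom == ch)
    for (i in sel) {
      b0 <- floor(start[i] / bin_size) + 1L
      b1 <- floor((end[i] - 1) / bin_size) + 1L
      v[b0:b1] <- state[i]
    }
    if (any(v == 0L)) stop("BED4 does not tile chromosome ", ch, call. = FALSE)
    v
  })
  names(states) <- names(chrom_sizes)
  new_segmentation(states, chrom_sizes, bin_size,
                   n_states = max(unlist(states)), rule = "file")
}

#' Construct a genomic feature annotation
#'
#' Intervals use the BED convention (0-based half-open). `feature_class`
#' is free text; the conventional vocabulary is promoter, 5UTR, exon,
#' intron, 3UTR, intergenic and TE, with anything else treated as a custom
#' class.
#'
#' @param chrom,start,end interval coordinates.
#' @param feature_class character vector of feature classes.
#' @param strand `"+"`, `"-"` or `"*"` (default).
#' @param gene_id optional gene identifier per interval.
#' @return data.frame of class `feature_annotation`.
#' @export
feature_annotation <- function(chrom, start, end, feature_class,
                               strand = "*", gene_id = NA_character_) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   feature_class = as.character(feature_class),
                   strand = as.character(strand),
                   gene_id = as.character(gene_id),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end))
    stop("feature interval with start >= end (row ",
         which(df$start >= df$end)[1L], ")", call. = FALSE)
  if (any(df$start < 0))
    stop("negative feature start", call. = FALSE)
  if (!all(df$strand %in% c("+", "-", "*")))
    stop("strand must be '+', '-' or '*'", call. = FALSE)
  class(df) <- c("feature_annotation", "data.frame")
  df
}

#' Read genomic features from a BED file
#'
#' Columns: chrom, start, end, then optionally name (used as the feature
#' class), score (ignored) and strand. GFF-style 1-based input can be
#' converted with `one_based = TRUE`.
#'
#' @param path BED file.
#' @param default_class class assigned when the name column is absent.
#' @param one_based set TRUE for 1-based inclusive coordinates.
#' @return a [feature_annotation()].
#' @export
read_feature_bed <- function(path, default_class = "custom", one_based = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (!length(lines))
    return(feature_annotation(character(0), numeric(0), numeric(0), character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 3L))
    stop("BED line ", which(nf < 3L)[1L], " has fewer than 3 fields", call. = FALSE)
  start <- as.numeric(vapply(f, `[[`, character(1), 2L))
  end <- as.numeric(vapply(f, `[[`, character(1), 3L))
  if (one_based) start <- start - 1
  feature_annotation(
    chrom = vapply(f, `[[`, character(1), 1L),
    start = start, end = end,
    feature_class = ifelse(nf >= 4L,
                           vapply(f, function(x) if (length(x) >= 4L) x[[4L]] else "",
                                  character(1)),
                           default_class),
    strand = ifelse(nf >= 6L,
                    vapply(f, function(x) if (length(x) >= 6L) x[[6L]] else "*",
                           character(1)),
                    "*"))
}

IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                 B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Read a motif library (identifier + IUPAC consensus, tab-separated)
#'
#' @param path TSV with columns motif_id, consensus and optionally source.
#' @return named character vector of consensus strings.
#' @export
read_motif_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 2L))
    stop("motif library line ", which(nf < 2L)[1L],
         " needs motif_id and consensus", call. = FALSE)
  ids <- vapply(f, `[[`, character(1), 1L)
  cons <- toupper(vapply(f, `[[`, character(1), 2L))
  if (anyDuplicated(ids))
    stop("duplicate motif id: ", ids[duplicated(ids)][1L], call. = FALSE)
  lib <- stats::setNames(cons, ids)
  for (id in ids) validate_iupac(lib[[id]], id)
  lib
}

validate_iupac <- function(consensus, id = consensus) {
  bad <- setdiff(strsplit(toupper(consensus), "")[[1L]], names(IUPAC_CODES))
  if (length(bad))
    stop(sprintf("motif '%s': invalid IUPAC symbol(s) %s", id,
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  if (nchar(consensus) < 4L)
    stop(sprintf("motif '%s': consensus shorter than 4 nt", id), call. = FALSE)
  invisible(consensus)
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA file, one sequence per gene.
#' @return named uppercase character vector (gene id -> sequence).
#' @export
read_promoters <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(out)))
    stop("duplicate promoter id: ", names(out)[duplicated(names(out))][1L],
         call. = FALSE)
  out
}

#' Write promoter sequences as FASTA
#'
#' @param promoters named character vector of sequences.
#' @param path output path.
#' @export
write_promoters <- function(promoters, path) {
  ss <- Biostrings::DNAStringSet(promoters)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
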