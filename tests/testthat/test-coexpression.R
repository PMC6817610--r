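# helper: expression matrix straight from a numeric matrix of FPKM values
as_expr <- function(m) {
  dimnames(m) <- list(sprintf("g%02d", seq_len(nrow(m))),
                      sprintf("s%02d", seq_len(ncol(m))))
  m
}

test_that("PCC matches the textbook formula on hand-checked profiles", {
  m <- as_expr(rbind(c(1, 2, 3, 4),
                     c(2, 4, 6, 8),
                     c(4, 3, 2, 1),
                     c(1, 3, 2, 4)))
  cc <- compute_pcc(m, transform = "none")
  expect_equal(cc["g01", "g02"], 1.0)
  expect_equal(cc["g01", "g03"], -1.0)
  expect_equal(cc["g01", "g04"], 0.8)
  expect_true(isSymmetric(unclass(cc)))
  expect_true(all(abs(cc) <= 1))
  expect_equal(unname(diag(cc)), rep(1, 4))
})

test_that("zero-variance genes are excluded and reported", {
  m <- as_expr(rbind(c(1, 2, 3, 4), c(5, 5, 5, 5), c(2, 1, 4, 3)))
  cc <- compute_pcc(m, transform = "none")
  expect_identical(attr(cc, "dropped_genes"), "g02")
  expect_identical(rownames(cc), c("g01", "g03"))
  expect_error(compute_pcc(as_expr(matrix(1, 2, 4)), transform = "none"),
               "zero variance")
  expect_error(compute_pcc(as_expr(matrix(1:4, 2, 2))), "3 samples")
})

test_that("sample QC flags the uncorrelated sample and only that one", {
  set.seed(11)
  base <- rnorm(40, mean = 6)
  m <- pmax(cbind(base + rnorm(40, sd = 0.1),
                  base + rnorm(40, sd = 0.1),
                  base + rnorm(40, sd = 0.1),
                  rnorm(40, mean = 6)), 0)
  rownames(m) <- sprintf("g%02d", 1:40)
  colnames(m) <- paste0("s", 1:4)
  qc <- qc_filter_samples(m, min_mean_corr = 0.5, transform = "none")
  expect_identical(qc$flagged, "s4")
  expect_setequal(qc$kept, c("s1", "s2", "s3"))
  # flagging agrees with a direct mean-correlation computation
  direct <- (rowSums(cor(m)) - 1) / 3
  expect_identical(qc$flagged, colnames(m)[direct < 0.5])

  ident <- as_expr(matrix(rep(rexp(20, 1 / 50), 3), ncol = 3))
  expect_identical(qc_filter_samples(ident, 0.5, transform = "none")$flagged,
                   character(0))
  expect_identical(qc_filter_samples(m, min_mean_corr = -1,
                                     transform = "none")$flagged,
                   character(0))
  expect_error(qc_filter_samples(as_expr(matrix(1:4, 2, 2))), "3 samples")
})

test_that("mutual ranks agree with the sort-based oracle on random matrices", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:20, 1)
    y <- matrix(rnorm(n * 10), n, 10)
    rownames(y) <- sprintf("g%02d", seq_len(n))
    cc <- cor(t(y))
    for (tail in c("positive", "negative")) {
      mr <- compute_mutual_rank(cc, tail = tail)
      expect_equal(mr, oracle_mutual_rank(cc, tail),
                   ignore_attr = TRUE, tolerance = 1e-12)
      expect_true(isSymmetric(unname(unclass(mr))))
      expect_true(all(mr[upper.tri(mr)] >= 1))
    }
    mr_p <- compute_mutual_rank(cc, mode = "product")
    mr_g <- compute_mutual_rank(cc, mode = "geometric_mean")
    expect_equal(unclass(mr_p), unclass(mr_g)^2, ignore_attr = TRUE)
  }
})

test_that("mutual rank combines directed ranks 4 and 9 into 6 (or 36)", {
  # crafted 12-gene correlation matrix: B is A's 4th-closest partner
  # while A is only B's 9th-closest (see helper-oracles.R)
  cc <- crafted_rank_matrix()
  rk_ab <- which(names(sort(cc["g01", -1], decreasing = TRUE)) == "g02")
  rk_ba <- which(names(sort(cc["g02", -2], decreasing = TRUE)) == "g01")
  expect_identical(c(rk_ab, rk_ba), c(4L, 9L))       # construction holds
  mr_g <- compute_mutual_rank(cc, mode = "geometric_mean")
  mr_p <- compute_mutual_rank(cc, mode = "product")
  expect_equal(mr_g["g01", "g02"], 6.0)
  expect_equal(mr_p["g01", "g02"], 36)
  # two mutual top partners always score MR = 1
  set.seed(3)
  y <- matrix(rnorm(50), 5, 10)
  y[2, ] <- y[1, ] + rnorm(10, sd = 1e-3)
  rownames(y) <- paste0("g", 1:5)
  cc2 <- cor(t(y))
  expect_equal(compute_mutual_rank(cc2)["g1", "g2"], 1)
  expect_equal(compute_mutual_rank(cc2, mode = "product")["g1", "g2"], 1)
})

test_that("network construction equals the pairwise filter oracle", {
  set.seed(7)
  lat <- rnorm(30)
  y <- rbind(lat + rnorm(30, sd = 0.05),
             lat + rnorm(30, sd = 0.05),
             lat + rnorm(30, sd = 0.05),
             matrix(rnorm(60), 2, 30))
  rownames(y) <- paste0("g", 1:5)
  cc <- cor(t(y))
  mr <- compute_mutual_rank(cc)
  net <- build_network(cc, mr, pcc_min_pos = 0.8, mr_max = 55)
  # brute force: test every unordered pair against the thresholds
  want <- list()
  for (a in 1:4) for (b in (a + 1):5) {
    if (cc[a, b] >= 0.8 && mr[a, b] <= 55)
      want[[length(want) + 1L]] <- sort(rownames(cc)[c(a, b)])
  }
  got <- Map(c, net$edges$gene_a, net$edges$gene_b)
  expect_setequal(vapply(got, paste, "", collapse = "-"),
                  vapply(want, paste, "", collapse = "-"))
  expect_setequal(unlist(lapply(want, identity)), c("g1", "g2", "g3"))
  expect_true(all(net$edges$sign == "positive"))
})

test_that("thresholds are monotone and gene order does not matter", {
  set.seed(21)
  y <- matrix(rnorm(200), 20, 10)
  rownames(y) <- sprintf("g%02d", 1:20)
  cc <- cor(t(y))
  mr <- compute_mutual_rank(cc)
  edge_keys <- function(net) paste(net$edges$gene_a, net$edges$gene_b)
  base <- build_network(cc, mr, pcc_min_pos = 0.3, mr_max = 10)
  stricter_p <- build_network(cc, mr, pcc_min_pos = 0.5, mr_max = 10)
  stricter_m <- build_network(cc, mr, pcc_min_pos = 0.3, mr_max = 5)
  expect_true(all(edge_keys(stricter_p) %in% edge_keys(base)))
  expect_true(all(edge_keys(stricter_m) %in% edge_keys(base)))

  perm <- sample(20)
  cc2 <- cc[perm, perm]
  net2 <- build_network(cc2, compute_mutual_rank(cc2),
                        pcc_min_pos = 0.3, mr_max = 10)
  expect_setequal(edge_keys(net2), edge_keys(base))
})

test_that("negative edges use the ascending tail and the sign matches PCC", {
  set.seed(5)
  lat <- rnorm(40)
  y <- rbind(lat, -lat + rnorm(40, sd = 0.05), matrix(rnorm(120), 3, 40))
  rownames(y) <- paste0("g", 1:5)
  cc <- cor(t(y))
  net <- build_network(cc, compute_mutual_rank(cc, "positive"),
                       compute_mutual_rank(cc, "negative"),
                       pcc_min_pos = 0.8, pcc_max_neg = -0.3, mr_max = 55)
  neg <- net$edges[net$edges$sign == "negative", ]
  expect_true(all(neg$pcc < 0))
  expect_true(any(neg$gene_a == "g1" & neg$gene_b == "g2"))
  pos <- net$edges[net$edges$sign == "positive", ]
  expect_true(all(pos$pcc > 0))
})

test_that("network comparison reports edge Jaccard and per-gene overlap", {
  mk <- function(pairs) {
    e <- do.call(rbind, lapply(pairs, function(p)
      data.frame(gene_a = p[1], gene_b = p[2], pcc = 0.9, mr = 1,
                 sign = "positive", stringsAsFactors = FALSE)))
    structure(list(nodes = sort(unique(unlist(pairs))), edges = e,
                   thresholds = list()), class = "coexpression_network")
  }
  a <- mk(list(c("a", "b"), c("b", "c")))
  expect_equal(compare_networks(a, a)$jaccard, 1.0)
  b <- mk(list(c("a", "b"), c("c", "d")))
  cmp <- compare_networks(a, b)
  expect_equal(cmp$jaccard, 1 / 3)
  expect_equal(cmp$n_shared, 1L)
  d <- mk(list(c("x", "y")))
  expect_equal(compare_networks(a, d)$jaccard, 0)
  pg <- cmp$per_gene
  expect_equal(pg$shared[pg$gene == "b"], 1L)
  expect_equal(pg$deg_a[pg$gene == "b"], 2L)
})

test_that("edge lists round trip through TSV", {
  set.seed(2)
  y <- matrix(rnorm(100), 10, 10)
  rownames(y) <- sprintf("g%02d", 1:10)
  cc <- cor(t(y))
  net <- build_network(cc, compute_mutual_rank(cc), pcc_min_pos = 0.2,
                       mr_max = 20)
  expect_gt(nrow(net$edges), 0)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, tmp)
  back <- read_edge_list(tmp)
  expect_identical(back$edges$gene_a, net$edges$gene_a)
  expect_equal(back$edges$pcc, net$edges$pcc, tolerance = 1e-6)
  expect_identical(back$edges$sign, net$edges$sign)
})
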