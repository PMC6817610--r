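# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (enumeration, double loops, direct sums) and never
# share code with the implementation paths they check.

# --- graphs ---------------------------------------------------------------

# Erdos-Renyi G(n, p) as an edge data.frame with letter-ish node names.
random_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(nodes, 2L))
  keep <- runif(nrow(pairs)) < p
  data.frame(gene_a = pairs[keep, 1L], gene_b = pairs[keep, 2L],
             stringsAsFactors = FALSE)
}

adjacency_from_edges <- function(edges, nodes) {
  A <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    A[edges$gene_a[i], edges$gene_b[i]] <- TRUE
    A[edges$gene_b[i], edges$gene_a[i]] <- TRUE
  }
  A
}

# All k-cliques by recursive extension in vertex order.
enumerate_k_cliques <- function(A, k) {
  nodes <- rownames(A)
  out <- list()
  extend <- function(clique, cand) {
    if (length(clique) == k) {
      out[[length(out) + 1L]] <<- clique
      return(invisible())
    }
    for (i in seq_along(cand)) {
      v <- cand[i]
      if (all(A[v, clique])) {
        rest <- cand[-seq_len(i)]
        extend(c(clique, v), rest)
      }
    }
  }
  extend(character(0), nodes)
  out
}

# Raw k-clique percolation: BFS over the clique graph where two k-cliques
# are adjacent iff they share k-1 nodes. Returns a set of sorted member
# vectors (one per community), itself sorted for comparability.
oracle_kclique_communities <- function(edges, k) {
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  if (!length(nodes)) return(list())
  A <- adjacency_from_edges(edges, nodes)
  cl <- enumerate_k_cliques(A, k)
  m <- length(cl)
  if (!m) return(list())
  assigned <- rep(NA_integer_, m)
  comp <- 0L
  for (s in seq_len(m)) {
    if (!is.na(assigned[s])) next
    comp <- comp + 1L
    queue <- s; assigned[s] <- comp
    while (length(queue)) {
      i <- queue[1L]; queue <- queue[-1L]
      for (j in seq_len(m)) {
        if (is.na(assigned[j]) &&
            length(intersect(cl[[i]], cl[[j]])) >= k - 1L) {
          assigned[j] <- comp
          queue <- c(queue, j)
        }
      }
    }
  }
  comms <- lapply(seq_len(comp), function(cid)
    sort(unique(unlist(cl[assigned == cid]))))
  comms[order(vapply(comms, paste, character(1), collapse = ","))]
}

canonical_modules <- function(module_set) {
  mods <- lapply(module_set$modules, sort)
  unname(mods[order(vapply(mods, paste, character(1), collapse = ","))])
}

# --- statistics -----------------------------------------------------------

# AUROC by explicit pair counting over all positive x negative pairs.
oracle_auroc <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Upper-tail hypergeometric P(X >= k) by direct summation of the density.
oracle_hyper_p <- function(N, K, n, k) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Smallest c with P(X >= c; lambda) <= p, from scratch via the Poisson pmf.
oracle_poisson_cutoff <- function(lambda, p) {
  pmf <- function(x) exp(-lambda) * lambda^x / factorial(x)
  cdf <- 0
  for (cut in 0:500) {
    if (1 - cdf <= p) return(cut)       # tail P(X >= cut)
    cdf <- cdf + pmf(cut)
  }
  Inf
}

# Overlapping IUPAC motif count by an explicit sliding window.
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))
oracle_count_motif <- function(seq, motif) {
  s <- strsplit(seq, "")[[1L]]
  m <- strsplit(motif, "")[[1L]]
  w <- length(m)
  if (length(s) < w) return(0L)
  hits <- 0L
  for (i in seq_len(length(s) - w + 1L)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      if (!(s[i + j - 1L] %in% IUPAC_SETS[[m[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- hits + 1L
  }
  hits
}

# Mutual ranks by independent per-row sorting (ties by gene id).
oracle_mutual_rank <- function(corr, tail = "positive", mode = "geometric_mean") {
  ids <- rownames(corr)
  n <- length(ids)
  rk <- matrix(NA_real_, n, n, dimnames = dimnames(corr))
  for (a in seq_len(n)) {
    others <- ids[-a]
    vals <- corr[a, others]
    o <- if (tail == "positive") order(-vals, others) else order(vals, others)
    for (pos in seq_along(o)) rk[a, others[o[pos]]] <- pos
  }
  mr <- matrix(NA_real_, n, n, dimnames = dimnames(corr))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    pr <- rk[a, b] * rk[b, a]
    mr[a, b] <- if (mode == "geometric_mean") sqrt(pr) else pr
  }
  mr
}

# 12-gene correlation matrix crafted so that gene g02 is g01's 4th-closest
# partner while g01 is only g02's 9th-closest: directed ranks (4, 9).
crafted_rank_matrix <- function() {
  ids <- sprintf("g%02d", 1:12)
  cc <- matrix(0, 12, 12, dimnames = list(ids, ids))
  cc[lower.tri(cc)] <- seq(-0.400, -0.075, by = 0.005)
  cc <- cc + t(cc); diag(cc) <- 1
  set_pair <- function(a, b, v) { cc[a, b] <<- v; cc[b, a] <<- v }
  set_pair("g01", "g02", 0.50)
  set_pair("g01", "g03", 0.90); set_pair("g01", "g04", 0.80)
  set_pair("g01", "g05", 0.70)
  for (i in 5:12) set_pair("g02", ids[i], 0.95 - 0.01 * i)
  cc
}

# --- HMM ------------------------------------------------------------------

# Exhaustive path enumeration: likelihood and per-bin posteriors for a
# Bernoulli-emission HMM on one short sequence.
oracle_hmm_enum <- function(emissions, transitions, initial, x) {
  S <- nrow(emissions); T_ <- nrow(x)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T_)))
  lik <- apply(paths, 1L, function(path) {
    p <- initial[path[1L]]
    for (t in seq_len(T_)) {
      e <- emissions[path[t], ]
      p <- p * prod(e^x[t, ] * (1 - e)^(1 - x[t, ]))
      if (t > 1L) p <- p * transitions[path[t - 1L], path[t]]
    }
    p
  })
  total <- sum(lik)
  post <- matrix(0, T_, S)
  for (t in seq_len(T_)) for (s in seq_len(S))
    post[t, s] <- sum(lik[paths[, t] == s]) / total
  list(loglik = log(total), posteriors = post)
}
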