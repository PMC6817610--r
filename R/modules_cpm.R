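#' Overlapping modules by k-clique percolation
#'
#' A k-clique community is a connected component of the relation joining
#' k-cliques that share k-1 nodes; each community is reported as the union
#' of its cliques' nodes, so modules may overlap. The computation
#' percolates over maximal cliques (of size >= k, connected when their
#' intersection has >= k-1 nodes), which yields communities identical to
#' raw k-clique percolation.
#'
#' @param network a `coexpression_network`, or a data.frame/matrix whose
#'   first two columns are an undirected edge list.
#' @param k clique size (>= 3); the community analyses behind this package
#'   use k = 6.
#' @param edge_sign `"positive"` (default; only positively correlated
#'   edges carry clique semantics) or `"all"`.
#' @return object of class `module_set`: list with `modules` (named list
#'   of member gene vectors), `k` and `min_size`.
#' @export
find_k_clique_communities <- function(network, k = 6L,
                                      edge_sign = c("positive", "all")) {
  edge_sign <- match.arg(edge_sign)
  if (k < 3L) stop("k must be at least 3", call. = FALSE)
  if (inherits(network, "coexpression_network")) {
    e <- network$edges
    if (edge_sign == "positive") e <- e[e$sign == "positive", , drop = FALSE]
    el <- cbind(e$gene_a, e$gene_b)
  } else {
    el <- as.matrix(network[, 1:2, drop = FALSE])
  }
  if (!nrow(el)) return(new_module_set(list(), k))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g)
  cl <- igraph::max_cliques(g, min = k)
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  comps <- percolate_cliques(cl, k)
  modules <- lapply(comps, function(ix) sort(unique(unlist(cl[ix]))))
  new_module_set(modules, k)
}

# Connected components of the clique-overlap relation (>= k-1 shared
# nodes) via union-find. `cliques` is a list of sorted character vectors.
percolate_cliques <- function(cliques, k) {
  m <- length(cliques)
  if (!m) return(list())
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  # bucket cliques by member to avoid the full m^2 scan on sparse overlap
  memb <- data.frame(node = unlist(cliques),
                     clique = rep.int(seq_len(m), lengths(cliques)),
                     stringsAsFactors = FALSE)
  by_node <- split(memb$clique, memb$node)
  cand <- unique(do.call(rbind, lapply(by_node, function(cs) {
    if (length(cs) < 2L) return(NULL)
    t(utils::combn(sort(cs), 2L))
  })))
  if (!is.null(cand)) {
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1L]; j <- cand[r, 2L]
      if (find(i) != find(j) &&
          length(intersect(cliques[[i]], cliques[[j]])) >= k - 1L) {
        parent[find(i)] <- find(j)
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  unname(split(seq_len(m), roots))
}

new_module_set <- function(modules, k, min_size = k) {
  modules <- modules[order(-lengths(modules),
                           vapply(modules, function(m) m[1L], character(1)))]
  names(modules) <- if (length(modules)) paste0("M", seq_along(modules)) else character(0)
  structure(list(modules = modules, k = as.integer(k),
                 min_size = as.integer(min_size)),
            class = "module_set")
}

#' Drop modules below a minimum size
#'
#' Module ids are re-assigned deterministically (descending size, then
#' lexicographically smallest member).
#'
#' @param modules a `module_set`.
#' @param min_size smallest member count retained (modules with exactly
#'   `min_size` genes are kept).
#' @return filtered `module_set`.
#' @export
filter_modules <- function(modules, min_size = 6L) {
  stopifnot(inherits(modules, "module_set"))
  keep <- lengths(modules$modules) >= min_size
  new_module_set(modules$modules[keep], modules$k, min_size)
}

#' @export
print.module_set <- function(x, ...) {
  cat("Module set:", length(x$modules), "module(s), k =", x$k, "\n")
  if (length(x$modules)) {
    sz <- lengths(x$modules)
    cat("  sizes:", paste(utils::head(sz, 10L), collapse = ", "),
        if (length(sz) > 10L) "..." else "", "\n")
    cat("  genes covered:", length(unique(unlist(x$modules))), "\n")
  }
  invisible(x)
}

#' Write modules as TSV (module_id, size, comma-joined members)
#'
#' @param modules a `module_set`.
#' @param path output path.
#' @export
write_modules <- function(modules, path) {
  lines <- c("module_id\tsize\tmembers",
             vapply(names(modules$modules), function(id) {
               m <- modules$modules[[id]]
               sprintf("%s\t%d\t%s", id, length(m), paste(m, collapse = ","))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
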