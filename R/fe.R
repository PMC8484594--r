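#' Absorb fixed effects by alternating weighted demeaning
#'
#' Removes one or two high-dimensional fixed-effect groups from a set of
#' columns by alternating weighted group-demeaning (the method of
#' alternating projections), iterated until the largest absolute change in
#' any value falls below `tol`. With a single grouping factor one pass is
#' exact weighted group-centering; with two nested factors convergence
#' takes at most two sweeps.
#'
#' @param values Numeric vector or matrix (columns demeaned jointly).
#' @param fe_groups List of one or two factors (or vectors coercible to
#'   factor), each of length `nrow(values)`.
#' @param weights Nonnegative observation weights (default all 1).
#' @param tol Convergence tolerance on the max absolute update
#'   (default 1e-10).
#' @param max_iter Maximum number of full sweeps (default 1000).
#' @return Matrix of demeaned values with attribute `iterations`.
#' @export
within_transform <- function(values, fe_groups, weights = NULL,
                             tol = 1e-10, max_iter = 1000L) {
  if (tol <= 0) stop("tol must be > 0")
  V <- as.matrix(values)
  n <- nrow(V)
  if (!length(fe_groups)) return(V)
  fe_groups <- lapply(fe_groups, function(g) {
    if (!length(g)) stop("empty fixed-effect group")
    f <- as.factor(g)
    if (length(f) != n) stop("fixed-effect group length mismatch")
    f
  })
  if (is.null(weights)) weights <- rep(1, n)
  wsums <- lapply(fe_groups, function(f) {
    as.vector(rowsum(weights, f, reorder = TRUE))
  })
  iter <- 0L
  repeat {
    iter <- iter + 1L
    delta <- 0
    for (j in seq_along(fe_groups)) {
      f <- fe_groups[[j]]
      gm <- rowsum(V * weights, f, reorder = TRUE) / wsums[[j]]
      adj <- gm[as.integer(f), , drop = FALSE]
      V <- V - adj
      delta <- max(delta, max(abs(adj)))
    }
    if (length(fe_groups) == 1L) break
    if (delta < tol) break
    if (iter >= max_iter) {
      stop("within_transform did not converge in ", max_iter,
           " sweeps (last delta ", signif(delta, 3), ")")
    }
  }
  dimnames(V) <- list(NULL, colnames(as.matrix(values)))
  attr(V, "iterations") <- iter
  V
}

# Rank of the fixed-effect dummy space: levels of each factor minus the
# number of connected components of the bipartite respondent/cell graph
# (union-find). Needed for exact CR1 degrees of freedom.
#
# When `cluster` is supplied, factors nested within clusters (every level
# inside a single cluster, e.g. respondent effects under respondent
# clustering) are excluded from the count: their absorption consumes no
# between-cluster information, and counting them makes the finite-cluster
# correction -- and hence the standard errors -- conservative.
fe_dof <- function(fe_groups, cluster = NULL) {
  if (!length(fe_groups)) return(0L)
  fs <- lapply(fe_groups, as.factor)
  if (!is.null(cluster)) {
    cl <- as.factor(cluster)
    nested <- vapply(fs, function(f) {
      pairs <- paste0(as.integer(f), "\r", as.integer(cl))
      length(unique(pairs)) == nlevels(f)
    }, logical(1))
    fs <- fs[!nested]
    if (!length(fs)) return(0L)
    if (length(fs) == 1L) return(nlevels(fs[[1]]))
  }
  if (length(fs) == 1L) return(nlevels(fs[[1]]))
  n1 <- nlevels(fs[[1]]); n2 <- nlevels(fs[[2]])
  parent <- seq_len(n1 + n2)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  a <- as.integer(fs[[1]]); b <- as.integer(fs[[2]]) + n1
  for (i in seq_along(a)) {
    ra <- find(a[i]); rb <- find(b[i])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- unique(vapply(unique(c(a, b)), find, integer(1)))
  n1 + n2 - length(roots)
}
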