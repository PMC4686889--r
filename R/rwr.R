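#' Column-normalized transition matrix of a network
#'
#' Builds the sparse column-stochastic matrix `W` with
#' `W[i, j] = A[i, j] / degree(j)`: column `j` spreads one unit of
#' probability evenly over the neighbours of node `j`. Node order is the
#' (sorted) node set of the network and is carried along for all walk
#' results.
#'
#' @param network A connected `gene_network` with at least 2 nodes,
#'   typically the output of [biggest_connected_component()].
#' @return An object of class `transition_matrix`: list with `W` (sparse
#'   dgCMatrix) and `nodes`.
#' @export
column_normalize <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  n <- length(network$nodes)
  if (n < 2L) abort("the walk needs at least 2 nodes.")
  ig <- as_igraph(network)
  deg <- igraph::degree(ig)
  if (any(deg == 0)) {
    abort("network has isolated node(s); extract the biggest connected component first.")
  }
  if (!igraph::is_connected(ig)) {
    abort("network is not connected; extract the biggest connected component first.")
  }
  idx_from <- match(network$edges$from, network$nodes)
  idx_to <- match(network$edges$to, network$nodes)
  deg <- unname(deg[network$nodes])
  W <- Matrix::sparseMatrix(
    i = c(idx_from, idx_to),
    j = c(idx_to, idx_from),
    x = 1 / c(deg[idx_to], deg[idx_from]),
    dims = c(n, n), dimnames = list(network$nodes, network$nodes)
  )
  structure(list(W = W, nodes = network$nodes), class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d nodes (column-stochastic)\n",
              length(x$nodes)))
  invisible(x)
}

#' Build the weighted seed (restart) vector from candidate groups
#'
#' Network genes carrying a promoter-methylation aberration or a somatic
#' mutation (groups B and C) become source nodes: members of exactly one
#' group score 1, members of both score 2, everything else 0. The initial
#' probability vector is the score vector normalized to sum 1. Group
#' members absent from the network are excluded (count reported).
#'
#' @param nodes Character vector: the walk's node order (e.g.
#'   `transition_matrix$nodes`).
#' @param group_b,group_c Character vectors of gene ids.
#' @return An object of class `seed_vector`: list with `p0` (named numeric,
#'   sums to 1), `raw_scores` (named integer 0/1/2) and `seeds` (source
#'   node ids).
#' @examples
#' make_seed_vector(c("g1", "g2", "g3"), c("g1", "g3"), c("g3"))
#' @export
make_seed_vector <- function(nodes, group_b, group_c = character(0)) {
  group_b <- unique(as.character(group_b))
  group_c <- unique(as.character(group_c))
  outside <- setdiff(union(group_b, group_c), nodes)
  if (length(outside)) {
    inform(sprintf("make_seed_vector: %d group gene(s) not in the network were excluded.",
                   length(outside)))
  }
  scores <- setNames(integer(length(nodes)), nodes)
  one <- intersect(nodes, setdiff(union(group_b, group_c),
                                  intersect(group_b, group_c)))
  two <- intersect(nodes, intersect(group_b, group_c))
  scores[one] <- 1L
  scores[two] <- 2L
  if (sum(scores) == 0) abort("no group gene is present in the network; no seeds.")
  structure(
    list(p0 = scores / sum(scores), raw_scores = scores,
         seeds = nodes[scores > 0]),
    class = "seed_vector"
  )
}

#' Random walk with restart to the steady state
#'
#' Iterates `p_{t+1} = (1 - r) W p_t + r p0` from `p0` until the L1
#' difference between successive iterates falls below `tol`. With a
#' column-stochastic `W`, total probability is conserved at every step, and
#' the fixed point solves `(I - (1 - r) W) p = r p0`.
#'
#' @param W A `transition_matrix` (or a plain column-stochastic matrix).
#' @param p0 Seed vector summing to 1 (a `seed_vector` or numeric).
#' @param r Restart probability in `(0, 1]` (default 0.7).
#' @param tol L1 convergence threshold (default 1e-10).
#' @param max_iter Iteration cap (default 10000); hitting it returns the
#'   last iterate flagged as non-converged, with a warning.
#' @return List: `p_inf` (named steady-state probabilities), `iterations`,
#'   `converged`, `max_mass_dev` (largest observed `|sum(p_t) - 1|`).
#' @examples
#' net <- gene_network(data.frame(from = "a", to = "b"))
#' tm <- column_normalize(net)
#' random_walk_restart(tm, c(a = 1, b = 0))$p_inf # (0.769..., 0.230...)
#' @export
random_walk_restart <- function(W, p0, r = 0.7, tol = 1e-10,
                                max_iter = 10000) {
  check_scalar_number(r, "r", 0, 1, strict_lower = TRUE)
  check_scalar_number(tol, "tol", 0, strict_lower = TRUE)
  nodes <- NULL
  if (inherits(W, "transition_matrix")) {
    nodes <- W$nodes
    W <- W$W
  }
  if (inherits(p0, "seed_vector")) p0 <- p0$p0
  p0 <- as.numeric(p0)
  if (length(p0) != nrow(W)) abort("`p0` length must match the node count.")
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-9) abort("`p0` must be a probability vector.")

  p <- p0
  it <- 0L
  converged <- FALSE
  max_dev <- abs(sum(p) - 1)
  while (it < max_iter) {
    it <- it + 1L
    p_new <- as.numeric((1 - r) * (W %*% p)) + r * p0
    max_dev <- max(max_dev, abs(sum(p_new) - 1))
    if (sum(abs(p_new - p)) < tol) {
      p <- p_new
      converged <- TRUE
      break
    }
    p <- p_new
  }
  if (!converged) warn(sprintf("walk did not converge within %d iterations.", max_iter))
  if (!is.null(nodes)) names(p) <- nodes
  list(p_inf = p, iterations = it, converged = converged,
       max_mass_dev = max_dev)
}

# steady states for many restart vectors at once via one sparse
# factorization of (I - (1-r)W); numerically equal to the iteration
rwr_solve <- function(W, P0, r) {
  M <- Matrix::Diagonal(nrow(W)) - (1 - r) * W
  as.matrix(Matrix::solve(M, r * P0))
}

#' Permutation p-values for steady-state probabilities
#'
#' Null model: the observed multiset of raw seed scores is re-placed at
#' uniformly random node positions (equivalent to permuting node labels
#' with the topology fixed), the walk is re-run, and each node's observed
#' steady-state probability is compared with its own null distribution.
#' Two estimators are available: `"plugin"` is the plain plug-in ratio,
#' counting strictly greater null values over `B`; `"pseudocount"` (default) uses `(1 + #{null >= obs}) /
#' (1 + B)`, which never returns 0.
#'
#' @param W A `transition_matrix`.
#' @param seed_vec A `seed_vector` from [make_seed_vector()].
#' @param B Number of permutations (default 10000).
#' @param r,tol As in [random_walk_restart()].
#' @param p_mode `"pseudocount"` or `"plugin"`.
#' @param seed RNG seed for the permutation stream.
#' @param chunk_size Permutations solved per factorized linear solve, to
#'   bound memory (default 2000).
#' @return A tibble `gene_id`, `raw_score`, `steady_prob`, `perm_p`, plus
#'   attributes `p_mode` and `B`.
#' @export
permutation_pvalues <- function(W, seed_vec, B = 10000, r = 0.7, tol = 1e-10,
                                p_mode = c("pseudocount", "plugin"),
                                seed = NULL, chunk_size = 2000) {
  stopifnot(inherits(W, "transition_matrix"), inherits(seed_vec, "seed_vector"))
  p_mode <- match.arg(p_mode)
  if (B < 1) abort("`B` must be at least 1.")
  use_seed(seed)
  n <- length(W$nodes)
  obs <- random_walk_restart(W, seed_vec, r = r, tol = tol)
  scores <- seed_vec$raw_scores[seed_vec$raw_scores > 0]
  k <- length(scores)
  vals <- as.numeric(scores) / sum(scores)

  n_ge <- integer(n)
  n_gt <- integer(n)
  done <- 0L
  while (done < B) {
    b <- min(chunk_size, B - done)
    pos <- unlist(lapply(seq_len(b), function(i) sample.int(n, k)),
                  use.names = FALSE)
    P0 <- Matrix::sparseMatrix(i = pos, j = rep(seq_len(b), each = k),
                               x = rep(vals, b), dims = c(n, b))
    null_p <- rwr_solve(W$W, P0, r)
    n_ge <- n_ge + rowSums(null_p >= obs$p_inf)
    n_gt <- n_gt + rowSums(null_p > obs$p_inf)
    done <- done + b
  }
  perm_p <- if (p_mode == "plugin") unname(n_gt) / B else (1 + unname(n_ge)) / (1 + B)
  res <- tibble(
    gene_id = W$nodes,
    raw_score = as.integer(seed_vec$raw_scores),
    steady_prob = unname(obs$p_inf),
    perm_p = perm_p
  )
  attr(res, "p_mode") <- p_mode
  attr(res, "B") <- B
  attr(res, "walk") <- obs[c("iterations", "converged", "max_mass_dev")]
  res
}

#' Score and test network genes by random walk with restart
#'
#' End-to-end propagation stage: column-normalize the network, build the
#' weighted seed vector from candidate groups B and C, run the walk to
#' steady state, and attach node-label-permutation p-values.
#'
#' @param network A connected `gene_network` (use
#'   [biggest_connected_component()] first).
#' @param group_b,group_c Gene id vectors defining the seeds (see
#'   [make_seed_vector()]).
#' @param r Restart probability (default 0.7).
#' @param tol L1 convergence threshold (default 1e-10).
#' @param B Permutations (default 10000).
#' @param alpha Significance cut on the permutation p (default 0.01,
#'   strict `<`).
#' @param p_mode,seed As in [permutation_pvalues()].
#' @return An object of class `rwr_result`: tibble `gene_id`, `raw_score`,
#'   `steady_prob`, `perm_p`, `significant`, `rank` (by decreasing
#'   steady-state probability, ties by gene id).
#' @export
rwr_significance <- function(network, group_b, group_c = character(0),
                             r = 0.7, tol = 1e-10, B = 10000, alpha = 0.01,
                             p_mode = c("pseudocount", "plugin"),
                             seed = NULL) {
  tm <- column_normalize(network)
  sv <- make_seed_vector(tm$nodes, group_b, group_c)
  res <- permutation_pvalues(tm, sv, B = B, r = r, tol = tol,
                             p_mode = p_mode, seed = seed)
  res <- res |>
    mutate(significant = .data$perm_p < alpha) |>
    arrange(desc(.data$steady_prob), .data$gene_id) |>
    mutate(rank = row_number())
  attr(res, "alpha") <- alpha
  class(res) <- c("rwr_result", class(res))
  res
}

#' Select the significant genes from a walk result
#'
#' @param result An `rwr_result` (or the tibble from
#'   [permutation_pvalues()]).
#' @param alpha Strict upper bound on the permutation p (default 0.01): a
#'   gene at exactly `alpha` is excluded.
#' @return A tibble of significant genes ranked by decreasing steady-state
#'   probability, ties broken by gene id.
#' @export
select_significant <- function(result, alpha = 0.01) {
  check_scalar_number(alpha, "alpha", 0, 1)
  result |>
    filter(.data$perm_p < alpha) |>
    arrange(desc(.data$steady_prob), .data$gene_id) |>
    mutate(rank = row_number()) |>
    as_tibble()
}

#' Glance at a walk result
#'
#' @param x An `rwr_result`.
#' @param ... Unused.
#' @return One-row tibble: node and seed counts, iterations, convergence,
#'   permutation count and number of significant genes.
#' @method glance rwr_result
#' @export
glance.rwr_result <- function(x, ...) {
  walk <- attr(x, "walk")
  tibble(
    n_nodes = nrow(x),
    n_seeds = sum(x$raw_score > 0),
    iterations = walk$iterations,
    converged = walk$converged,
    B = attr(x, "B"),
    p_mode = attr(x, "p_mode"),
    n_significant = sum(x$significant)
  )
}

#' Rank plot of steady-state probabilities
#'
#' @param object An `rwr_result`.
#' @param ... Unused.
#' @return A ggplot of steady-state probability against rank, significant
#'   genes highlighted.
#' @method autoplot rwr_result
#' @export
autoplot.rwr_result <- function(object, ...) {
  ggplot(object, aes(x = .data$rank, y = .data$steady_prob,
                     colour = .data$significant)) +
    geom_point(size = 0.8) +
    scale_y_log10() +
    labs(x = "rank", y = "steady-state probability",
         colour = sprintf("perm p < %g", attr(object, "alpha") %||% 0.01)) +
    theme_minimal()
}
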