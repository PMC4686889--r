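#' Upper-tail hypergeometric overlap probability
#'
#' For two gene groups of sizes `K` and `M` drawn from a background of `N`
#' genes, the probability of sharing at least `x` genes:
#' `P(X >= x)` with `X ~ Hypergeometric(N, K, M)`. The tail is accumulated
#' from log-space hypergeometric densities, so probabilities far below
#' double-precision underflow of individual terms remain accurate.
#'
#' @param N Background size (here: all differentially expressed genes).
#' @param K,M Sizes of the two groups.
#' @param x Observed overlap.
#' @return The upper-tail probability, in `(0, 1]`; `x = 0` returns exactly 1.
#' @examples
#' hypergeometric_tail(4041, 568, 397, 107) # ~6.31e-13
#' hypergeometric_tail(10, 4, 5, 3)         # 66/252
#' @export
hypergeometric_tail <- function(N, K, M, x) {
  for (nm in c("N", "K", "M", "x")) {
    v <- get(nm)
    check_scalar_number(v, nm, 0)
    if (v != round(v)) abort(sprintf("`%s` must be an integer count.", nm))
  }
  if (K > N || M > N) abort("group sizes K and M cannot exceed the background N.")
  if (x > min(K, M)) abort("overlap x cannot exceed min(K, M).")
  if (x == 0) return(1)
  support <- x:min(K, M)
  exp(logsumexp(dhyper(support, m = K, n = N - K, k = M, log = TRUE)))
}

#' Form candidate gene groups from multi-layer aberration calls
#'
#' Builds the three sign-consistent candidate sets used for downstream
#' network propagation:
#' * Group A: up-regulated and amplified, or down-regulated and deleted;
#' * Group B: up-regulated with promoter hypomethylation, or down-regulated
#'   with promoter hypermethylation;
#' * Group C: differentially expressed (either direction) and recurrently
#'   mutated.
#' Groups may overlap. The background for overlap testing is the full set
#' of differentially expressed genes.
#'
#' @param deg Expression calls from [call_deg()].
#' @param cnv Copy-number calls from [call_cnv()] (optional).
#' @param methylation Methylation calls from [call_methylation()] (optional).
#' @param mutated Mutation table from [call_mutated()], or a character
#'   vector of mutated gene ids (optional).
#' @return An object of class `gene_groups`: list with character vectors
#'   `A`, `B`, `C`, a `membership` tibble (`gene_id`, `group`,
#'   `expr_direction`), and `background_n`.
#' @export
form_groups <- function(deg, cnv = NULL, methylation = NULL, mutated = NULL) {
  passed_set <- function(calls, dirs) {
    if (is.null(calls)) return(character(0))
    calls$gene_id[calls$passed & calls$direction %in% dirs]
  }
  up <- passed_set(deg, "up")
  down <- passed_set(deg, "down")
  degs <- union(up, down)
  if (!length(degs)) warn("no differentially expressed genes; all groups empty.")

  mut_genes <- if (is.data.frame(mutated)) {
    mutated$gene_id[mutated$passed]
  } else {
    as.character(mutated %||% character(0))
  }

  A <- sort(union(intersect(up, passed_set(cnv, "amp")),
                  intersect(down, passed_set(cnv, "del"))))
  B <- sort(union(intersect(up, passed_set(methylation, "hypo")),
                  intersect(down, passed_set(methylation, "hyper"))))
  C <- sort(intersect(degs, mut_genes))

  expr_dir <- setNames(rep("down", length(degs)), degs)
  expr_dir[up] <- "up"
  membership <- bind_rows(
    tibble(gene_id = A, group = "A"),
    tibble(gene_id = B, group = "B"),
    tibble(gene_id = C, group = "C")
  )
  if (nrow(membership)) {
    membership <- mutate(membership,
                         expr_direction = unname(expr_dir[.data$gene_id]))
  } else {
    membership$expr_direction <- character(0)
  }
  structure(
    list(A = A, B = B, C = C, membership = membership,
         background = sort(degs), background_n = length(degs)),
    class = "gene_groups"
  )
}

#' @export
print.gene_groups <- function(x, ...) {
  cat(sprintf(
    "<gene_groups> A: %d, B: %d, C: %d (background: %d DEGs)\n",
    length(x$A), length(x$B), length(x$C), x$background_n
  ))
  invisible(x)
}

#' Tidy gene-group membership
#'
#' @param x A `gene_groups` object from [form_groups()].
#' @param ... Unused.
#' @return The membership tibble (`gene_id`, `group`, `expr_direction`).
#' @method tidy gene_groups
#' @export
tidy.gene_groups <- function(x, ...) x$membership

#' Pairwise hypergeometric overlap tests between candidate groups
#'
#' Tests each unordered pair of groups (A-B, A-C, B-C) for overlap beyond
#' chance with [hypergeometric_tail()], using the number of differentially
#' expressed genes as the background `N`.
#'
#' @param groups A `gene_groups` object from [form_groups()].
#' @param background_n Background size; defaults to the group object's DEG
#'   count.
#' @return A tibble with one row per pair: `group1`, `group2`, `N`, `K`,
#'   `M`, `overlap`, `p_value`.
#' @export
overlap_tests <- function(groups, background_n = NULL) {
  stopifnot(inherits(groups, "gene_groups"))
  N <- background_n %||% groups$background_n
  if (N <= 0) abort("background size must be positive.")
  pairs <- list(c("A", "B"), c("A", "C"), c("B", "C"))
  purrr::map_dfr(pairs, function(pr) {
    g1 <- groups[[pr[1]]]
    g2 <- groups[[pr[2]]]
    x <- length(intersect(g1, g2))
    tibble(group1 = pr[1], group2 = pr[2], N = N,
           K = length(g1), M = length(g2), overlap = x,
           p_value = hypergeometric_tail(N, length(g1), length(g2), x))
  })
}
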