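#' Simulate a scale-free network with a planted propagation-proximal module
#'
#' Grows a connected preferential-attachment graph, designates `n_seeds`
#' seed nodes, and plants a module emulating the genes a propagation
#' analysis is meant to recover: genes carrying both classes of upstream
#' aberration (so they enter both candidate groups and receive raw score 2)
#' that additionally sit in a dense, seed-adjacent neighbourhood. Module
#' members are wired into a clique and each to `seeds_per_module_gene`
#' distinct seed nodes (at least 3); every other node sees seeds only
#' through the random scale-free topology. `truth` reports the module, the
#' score-1 seeds, and ready-made `group_b` / `group_c` vectors whose
#' intersection is the module, for direct use with [make_seed_vector()] or
#' [rwr_significance()].
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param attachment_param Edges added per new node in the
#'   preferential-attachment growth (default 2).
#' @param planted_module_size Size of the planted module (0 disables
#'   planting; must satisfy `planted_module_size + n_seeds <= n_nodes`).
#' @param n_seeds Number of seed-designated nodes; the default `NULL`
#'   takes 40 or whatever still fits beside the module in small graphs.
#' @param seeds_per_module_gene Seed neighbours wired to each module gene
#'   (default 6, minimum 3).
#' @param seed RNG seed; identical seeds give identical edge lists.
#' @return List: `network` (a `gene_network`), `truth` (list with
#'   `planted_module`, `seeds`, `group_b`, `group_c`).
#' @export
simulate_network <- function(n_nodes, attachment_param = 2,
                             planted_module_size = 10, n_seeds = NULL,
                             seeds_per_module_gene = 6, seed = NULL) {
  check_scalar_number(n_nodes, "n_nodes", 2)
  check_scalar_number(attachment_param, "attachment_param", 1)
  check_scalar_number(planted_module_size, "planted_module_size", 0, n_nodes)
  n_seeds <- n_seeds %||% min(40, n_nodes - planted_module_size)
  check_scalar_number(n_seeds, "n_seeds", 0, n_nodes)
  if (planted_module_size > 0 && seeds_per_module_gene < 3) {
    abort("`seeds_per_module_gene` must be at least 3.")
  }
  if (planted_module_size > 0 && n_seeds < seeds_per_module_gene) {
    abort("`n_seeds` must be at least `seeds_per_module_gene` to wire the module.")
  }
  if (planted_module_size + n_seeds > n_nodes) {
    abort("`planted_module_size` + `n_seeds` cannot exceed `n_nodes`.")
  }
  use_seed(seed)
  ids <- sprintf("v%04d", seq_len(n_nodes))
  g <- igraph::sample_pa(n_nodes, power = 1, m = attachment_param,
                         directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- tibble(from = ids[el[, 1]], to = ids[el[, 2]])

  module <- sort(sample(ids, planted_module_size))
  seeds <- sort(sample(setdiff(ids, module), n_seeds))
  if (planted_module_size > 0) {
    spokes <- purrr::map_dfr(module, function(m) {
      tibble(from = m, to = sample(seeds, seeds_per_module_gene))
    })
    clique <- if (planted_module_size > 1) {
      pairs <- utils::combn(module, 2)
      tibble(from = pairs[1, ], to = pairs[2, ])
    } else {
      tibble(from = character(0), to = character(0))
    }
    edges <- bind_rows(edges, spokes, clique)
  }
  list(
    network = gene_network(edges),
    truth = list(planted_module = module, seeds = seeds,
                 group_b = sort(c(seeds, module)), group_c = module)
  )
}
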