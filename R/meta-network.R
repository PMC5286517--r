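#' Coupling weight between two regulatory links sharing a regulator
#'
#' Two links r -> g and r -> g' are coupled in proportion to the
#' co-functionality of their targets and the similarity of their
#' confidence weights:
#'
#'   upsilon_delta = w_ff * (1 - |upsilon_a - upsilon_b|)
#'
#' The weight is strictly decreasing in the absolute weight distance when
#' `w_ff > 0`, increasing in `w_ff`, symmetric in its first two arguments,
#' and stays in `[0, 1]`. An alternative combination rule
#' `w_ff / (1 + |distance|)` with the same monotonicities is available via
#' `rule = "ratio"`.
#'
#' @param upsilon_a,upsilon_b Link confidence weights in `[0, 1]`.
#' @param w_ff Co-functionality weight of the two target genes in `[0, 1]`
#'   (0 when the pair is absent from the co-function network).
#' @param rule `"product"` (default) or `"ratio"`.
#' @return Coupling weight in `[0, 1]`.
#' @export
meta_edge_weight <- function(upsilon_a, upsilon_b, w_ff,
                             rule = c("product", "ratio")) {
  rule <- match.arg(rule)
  stopifnot(all(upsilon_a >= 0 & upsilon_a <= 1),
            all(upsilon_b >= 0 & upsilon_b <= 1),
            all(w_ff >= 0 & w_ff <= 1))
  d <- abs(upsilon_a - upsilon_b)
  switch(rule,
         product = w_ff * (1 - d),
         ratio   = w_ff / (1 + d))
}

#' Build the meta gene regulatory network
#'
#' Lifts the network one level: regulatory links become nodes, and every
#' unordered pair of links controlled by the same regulator becomes a meta
#' edge weighted by [meta_edge_weight()]. Gene pairs absent from the
#' co-function network contribute coupling weight 0 (absent evidence is
#' treated as no evidence of co-functionality, reflecting the partial
#' coverage of such datasets); the zero-weight edges are still emitted so
#' that the spanning-tree step decides their fate.
#'
#' @param network Network `data.frame` (`regulator`, `target`, `weight`).
#' @param cofn Co-function network: `data.frame` with columns `gene_a`,
#'   `gene_b`, `weight` (undirected, weights in `[0, 1]`).
#' @param rule Combination rule passed to [meta_edge_weight()].
#' @return `data.frame` with columns `regulator`, `target_a`, `target_b`,
#'   `weight`; one row per unordered pair of same-regulator links, with
#'   `target_a < target_b`.
#' @export
build_meta_network <- function(network, cofn = NULL, rule = "product") {
  wff_lookup <- character(0)
  if (!is.null(cofn) && nrow(cofn)) {
    wff_lookup <- stats::setNames(as.numeric(cofn$weight),
                                  pair_id(cofn$gene_a, cofn$gene_b))
    if (any(wff_lookup < 0) || any(wff_lookup > 1)) {
      stop("co-function weights must lie in [0, 1]")
    }
  }
  parts <- split(seq_len(nrow(network)), network$regulator)
  out <- lapply(parts, function(idx) {
    k <- length(idx)
    if (k < 2) return(NULL)
    cmb <- utils::combn(idx, 2)
    i <- cmb[1, ]; j <- cmb[2, ]
    ta <- network$target[i]; tb <- network$target[j]
    swap <- ta > tb
    tmp <- ta[swap]; ta[swap] <- tb[swap]; tb[swap] <- tmp
    wff <- unname(wff_lookup[pair_id(ta, tb)])
    wff[is.na(wff)] <- 0
    data.frame(regulator = network$regulator[i],
               target_a = ta, target_b = tb,
               weight = meta_edge_weight(network$weight[i],
                                         network$weight[j], wff, rule),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(NULL)))
  if (is.null(out)) {
    out <- data.frame(regulator = character(), target_a = character(),
                      target_b = character(), weight = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[order(out$regulator, out$target_a, out$target_b), , drop = FALSE]
}

#' Decompose the meta network into spanning-tree modules
#'
#' Partitions regulatory links into modules: each connected component of
#' the meta graph is reduced to its maximum spanning tree (maximizing the
#' total coupling weight), and every link participating in no meta edge
#' becomes a singleton module. The maximum spanning forest is computed by
#' Kruskal's algorithm with a deterministic tie rule — among equal-weight
#' edges the lexicographically smaller (regulator, target_a, target_b)
#' triple wins — so module structure is identical across runs and
#' platforms. Every input link appears in exactly one module.
#'
#' @param meta_edges `data.frame` from [build_meta_network()].
#' @param network Network `data.frame` whose links are the module nodes.
#' @return List of modules. Each module is a list with elements
#'   `id` (integer), `regulator`, `links` (`data.frame` with `regulator`,
#'   `target`, `weight`) and `edges` (`data.frame` with `a`, `b` — row
#'   indices into `links` — and `weight`; zero rows for singletons).
#' @export
extract_modules <- function(meta_edges, network) {
  ids <- link_id(network$regulator, network$target)
  n <- length(ids)
  node_of <- stats::setNames(seq_len(n), ids)

  # union-find
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }

  tree_a <- integer(0); tree_b <- integer(0); tree_w <- numeric(0)
  if (nrow(meta_edges)) {
    ord <- order(-meta_edges$weight, meta_edges$regulator,
                 meta_edges$target_a, meta_edges$target_b)
    ea <- node_of[link_id(meta_edges$regulator, meta_edges$target_a)][ord]
    eb <- node_of[link_id(meta_edges$regulator, meta_edges$target_b)][ord]
    ew <- meta_edges$weight[ord]
    for (k in seq_along(ea)) {
      ra <- find(ea[k]); rb <- find(eb[k])
      if (ra != rb) {
        parent[ra] <- rb
        tree_a <- c(tree_a, ea[k]); tree_b <- c(tree_b, eb[k])
        tree_w <- c(tree_w, ew[k])
      }
    }
  }

  comp <- vapply(seq_len(n), find, 0L)
  comp_ids <- unique(comp)
  modules <- vector("list", length(comp_ids))
  for (m in seq_along(comp_ids)) {
    nodes <- which(comp == comp_ids[m])
    local <- stats::setNames(seq_along(nodes), nodes)
    in_comp <- tree_a %in% nodes
    modules[[m]] <- list(
      id = m,
      regulator = network$regulator[nodes[1]],
      links = data.frame(regulator = network$regulator[nodes],
                         target = network$target[nodes],
                         weight = network$weight[nodes],
                         stringsAsFactors = FALSE),
      edges = data.frame(a = unname(local[as.character(tree_a[in_comp])]),
                         b = unname(local[as.character(tree_b[in_comp])]),
                         weight = tree_w[in_comp])
    )
  }
  modules
}

#' Flatten a module list to one link table
#'
#' @param modules Module list from [extract_modules()].
#' @return `data.frame` with columns `module_id`, `regulator`, `target`,
#'   `weight`, one row per link.
#' @export
module_links <- function(modules) {
  out <- do.call(rbind, lapply(modules, function(m) {
    cbind(module_id = m$id, m$links)
  }))
  rownames(out) <- NULL
  out
}
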