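#' Energy of a joint link-state assignment in a module
#'
#' Each regulatory link l in a module carries a binary state `x_l`
#' (1 = keep, 0 = remove). With spins `s_l = 2 x_l - 1`, the module energy
#' is the Ising form
#'
#'   E(x) = - sum_l (upsilon_l - gamma) * s_l
#'          - lambda * sum_(l,l') upsilon_delta(l,l') * s_l * s_l'
#'
#' where the pairwise sum runs over the module's spanning-tree edges and is
#' empty for singleton modules. Low energy (hence high probability under
#' `p(x) = exp(-E)/Z`) favors keeping links whose weight exceeds the
#' threshold `gamma` and assigning strongly coupled link pairs the same
#' state; `lambda` globally scales the coupling. This sign and offset
#' convention is THE core modeling assumption: it reduces, for a singleton
#' module, to removal exactly when `upsilon <= gamma`.
#'
#' @param module Module from [extract_modules()].
#' @param x Integer vector of 0/1 states, one per module link.
#' @param gamma Link-weight threshold.
#' @param lambda Coupling penalty, `>= 0`.
#' @return Scalar energy.
#' @export
module_energy <- function(module, x, gamma, lambda) {
  n <- nrow(module$links)
  if (length(x) != n || anyNA(x)) stop("x must assign 0/1 to every link")
  stopifnot(all(x %in% c(0, 1)))
  s <- 2 * x - 1
  e <- -sum((module$links$weight - gamma) * s)
  if (nrow(module$edges)) {
    e <- e - lambda * sum(module$edges$weight *
                            s[module$edges$a] * s[module$edges$b])
  }
  e
}

# Indices of links clamped to x = 1: strictly above the threshold.
clamped_links <- function(module, gamma) {
  which(module$links$weight > gamma)
}

#' Joint probability of a link-state assignment
#'
#' `p(x) = exp(-E(x)) / Z` where the partition function `Z` sums over all
#' configurations consistent with the clamped evidence: links with
#' `upsilon > gamma` are fixed at `x = 1` (conditioning; the model class is
#' closed under conditioning). Configurations violating the evidence have
#' probability 0. Computed by exhaustive enumeration over the free links,
#' so intended for small modules (at most 20 free links).
#'
#' @inheritParams module_energy
#' @return Probability of `x` given the clamped evidence.
#' @export
joint_probability <- function(module, x, gamma, lambda) {
  n <- nrow(module$links)
  clamped <- clamped_links(module, gamma)
  if (any(x[clamped] != 1)) return(0)
  free <- setdiff(seq_len(n), clamped)
  if (length(free) > 20) stop("module too large for exhaustive enumeration")
  states <- as.matrix(expand.grid(rep(list(0:1), length(free))))
  loge <- apply(states, 1, function(sf) {
    xx <- x
    xx[free] <- sf
    -module_energy(module, xx, gamma, lambda)
  })
  exp(-module_energy(module, x, gamma, lambda) - logsumexp(loge))
}

#' Exact marginal retention probabilities by belief propagation
#'
#' Runs two-pass sum-product message passing (leaves to root, then root to
#' leaves) on the module's spanning tree, in log domain with per-message
#' max-normalization for numerical stability. Links with
#' `upsilon > gamma` are clamped to `x = 1` via evidence messages (a delta
#' at state 1), leaving the topology intact; their marginal is exactly 1
#' and they act as fixed evidence on their neighbors. On trees the result
#' is exact: it equals brute-force enumeration of the conditioned
#' distribution.
#'
#' For a free singleton the marginal has the closed form
#' `p = sigma(2 (upsilon - gamma))` with `sigma` the logistic function.
#'
#' @inheritParams module_energy
#' @param clamp If `TRUE` (default), links with `upsilon > gamma` are
#'   fixed to `x = 1`; `FALSE` computes the unconditioned sum-product
#'   marginals (e.g. the singleton closed form for all weights).
#' @return List with `p` (numeric vector of marginal probabilities of
#'   `x_l = 1`, one per module link) and `clamped` (logical vector).
#' @export
bp_marginals <- function(module, gamma, lambda, clamp = TRUE) {
  n <- nrow(module$links)
  edges <- module$edges
  if (nrow(edges) != n - 1 && !(n == 1 && nrow(edges) == 0)) {
    stop("module edge set is not a tree")
  }
  clamped <- if (clamp) seq_len(n) %in% clamped_links(module, gamma)
             else rep(FALSE, n)

  # log unary potentials: column j is state x = j-1 (spin -1, +1)
  h <- module$links$weight - gamma
  logphi <- unname(cbind(-h, h))
  logphi[clamped, 1] <- -Inf
  logphi[clamped, 2] <- 0

  if (n == 1) {
    m0 <- unname(logphi[1, ]) - max(logphi[1, ])
    p <- exp(m0) / sum(exp(m0))
    return(list(p = p[2], clamped = clamped))
  }

  # adjacency with per-edge coupling J = lambda * upsilon_delta
  nbr <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges$a[k]; b <- edges$b[k]; J <- lambda * edges$weight[k]
    nbr[[a]] <- rbind(nbr[[a]], c(b, J))
    nbr[[b]] <- rbind(nbr[[b]], c(a, J))
  }

  # BFS order from root 1
  order_bfs <- integer(n); parent <- integer(n)
  visited <- logical(n)
  order_bfs[1] <- 1L; visited[1] <- TRUE; head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- order_bfs[head]
    for (r in seq_len(NROW(nbr[[v]]))) {
      u <- nbr[[v]][r, 1]
      if (!visited[u]) {
        visited[u] <- TRUE
        tail <- tail + 1L
        order_bfs[tail] <- u
        parent[u] <- v
      }
    }
    head <- head + 1L
  }
  if (!all(visited)) stop("module edge set is not connected")

  coupling <- function(v, u) {  # J on edge (v, u)
    rows <- nbr[[v]]
    rows[match(u, rows[, 1]), 2]
  }
  # pairwise log potential matrix for states (x_v, x_u) given J:
  # J * s_v * s_u with spins +-1
  pair_mat <- function(J) matrix(c(J, -J, -J, J), 2, 2)

  msg_up <- vector("list", n)    # message v -> parent(v)
  msg_down <- vector("list", n)  # message parent(v) -> v
  send <- function(v, to, incoming) {
    # incoming: list of messages into v (2-vectors), excluding the one from `to`
    belief <- logphi[v, ]
    for (m in incoming) belief <- belief + m
    M <- pair_mat(coupling(v, to))
    out <- c(logsumexp(belief + M[, 1]), logsumexp(belief + M[, 2]))
    out - max(out[is.finite(out)], -Inf)
  }

  # upward pass (reverse BFS order)
  for (v in rev(order_bfs[-1])) {
    inc <- list()
    for (r in seq_len(NROW(nbr[[v]]))) {
      u <- nbr[[v]][r, 1]
      if (u != parent[v]) inc <- c(inc, list(msg_up[[u]]))
    }
    msg_up[[v]] <- send(v, parent[v], inc)
  }
  # downward pass (BFS order)
  for (v in order_bfs[-1]) {
    p_v <- parent[v]
    inc <- list()
    for (r in seq_len(NROW(nbr[[p_v]]))) {
      u <- nbr[[p_v]][r, 1]
      if (u == v) next
      if (u == parent[p_v]) inc <- c(inc, list(msg_down[[p_v]]))
      else inc <- c(inc, list(msg_up[[u]]))
    }
    msg_down[[v]] <- send(p_v, v, inc)
  }

  p <- numeric(n)
  for (v in seq_len(n)) {
    belief <- logphi[v, ]
    for (r in seq_len(NROW(nbr[[v]]))) {
      u <- nbr[[v]][r, 1]
      belief <- belief +
        (if (u == parent[v]) msg_down[[v]] else msg_up[[u]])
    }
    belief <- belief - max(belief)
    p[v] <- exp(belief[2]) / sum(exp(belief))
  }
  p[clamped] <- 1
  list(p = p, clamped = clamped)
}

#' Prune a module at given hyperparameters
#'
#' Keeps a link exactly when its marginal retention probability strictly
#' exceeds 0.5; a marginal of exactly 0.5 removes the link. Clamped links
#' (`upsilon > gamma`) are always retained.
#'
#' @inheritParams module_energy
#' @return Logical vector: `TRUE` for retained links, in module link order.
#' @export
prune_module <- function(module, gamma, lambda) {
  bp_marginals(module, gamma, lambda)$p > 0.5
}

#' Prune every module and return the candidate network
#'
#' Applies [prune_module()] at one hyperparameter pair to all modules and
#' unions the retained links.
#'
#' @param modules Module list from [extract_modules()].
#' @inheritParams module_energy
#' @return Network `data.frame` of retained links.
#' @export
prune_network <- function(modules, gamma, lambda) {
  keep <- lapply(modules, function(m) m$links[prune_module(m, gamma, lambda), ,
                                              drop = FALSE])
  out <- do.call(rbind, keep)
  grn(out$regulator, out$target, out$weight)
}

#' Per-link marginals for a whole module list
#'
#' @param modules Module list.
#' @inheritParams module_energy
#' @return `data.frame` with `module_id`, `regulator`, `target`, `weight`,
#'   `p`, `clamped`, `retained`.
#' @export
network_marginals <- function(modules, gamma, lambda) {
  out <- do.call(rbind, lapply(modules, function(m) {
    bp <- bp_marginals(m, gamma, lambda)
    data.frame(module_id = m$id, m$links, p = bp$p, clamped = bp$clamped,
               retained = bp$p > 0.5, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
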