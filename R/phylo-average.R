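# Gaussian message algebra for Brownian-motion conditioning.
# A message is c(mean, var); var = Inf encodes "uninformative" and var = 0 a
# point constraint. combine_messages() multiplies Gaussian densities
# (precision-weighted mean); zero-variance messages pin the result.
combine_messages <- function(msgs) {
  vars <- vapply(msgs, `[`, numeric(1), 2)
  means <- vapply(msgs, `[`, numeric(1), 1)
  if (any(vars == 0)) {
    return(c(means[which(vars == 0)[1]], 0))
  }
  inf <- is.infinite(vars)
  if (all(inf)) return(c(NA_real_, Inf))
  prec <- 1 / vars[!inf]
  c(sum(means[!inf] * prec) / sum(prec), 1 / sum(prec))
}

# tree accessors ------------------------------------------------------------

tree_children <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    ch[[p]] <- c(ch[[p]], e)
  }
  ch
}

check_leaf_values <- function(tree, values) {
  if (is.null(names(values)) || !all(names(values) %in% tree$tip.label)) {
    stop("every value must be named after a leaf of the tree")
  }
  if (anyDuplicated(names(values))) stop("duplicate leaf names in values")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("leaf values must be finite")
  }
  invisible(values)
}

#' Simple (unweighted) multi-species average
#'
#' Arithmetic mean of the observed orthologous window scores; species without
#' an ortholog are simply omitted.
#'
#' @param values Named numeric vector of per-species scores.
#' @return The mean score.
#' @export
simple_average <- function(values) {
  if (length(values) == 0) stop("no observed species")
  if (anyNA(values)) values <- values[!is.na(values)]
  if (length(values) == 0) stop("no observed species")
  mean(values)
}

#' Brownian-motion temporal tree average
#'
#' Treats the per-species window scores as leaf observations of a trait
#' evolving by Brownian motion along the phylogeny and returns the expected
#' time-average of the trait over all branches, conditioned on the leaves:
#' `E[(1/T) * integral of X(t) dt | leaves]` with `T` the total branch
#' length. Writing `m_v` for the conditional mean of the trait at node `v`
#' (diffuse prior at the root), the expected average over a branch of length
#' `tau` from parent `p` to child `c` is `(m_p + m_c)/2` (a Brownian bridge
#' between the endpoints), so the result is
#' `sum_b tau_b (m_parent(b) + m_child(b)) / 2 / sum_b tau_b`.
#'
#' Conditional means are computed in two linear-time passes: an upward
#' (pruning) pass collecting each subtree's Gaussian message and a downward
#' pass distributing the information from the rest of the tree. The answer
#' does not depend on the Brownian rate, which cancels from all conditional
#' means. Leaves absent from `values` are marginalized over.
#'
#' @param tree A rooted `"phylo"` tree with branch lengths (see
#'   [read_newick()]).
#' @param values Named numeric vector of scores for at least two leaves.
#' @return The temporal average (single number); attribute `node_means`
#'   carries the conditional mean at every node (tips first, then internal
#'   nodes, in `ape` node order).
#' @export
bm_tree_average <- function(tree, values) {
  validate_tree(tree)
  check_leaf_values(tree, values)
  if (length(values) < 2) stop("Brownian-motion averaging needs >= 2 leaves")
  if (sum(tree$edge.length) <= 0) stop("tree has zero total branch length")

  ntip <- ape::Ntip(tree)
  n_node <- ntip + tree$Nnode
  root <- ntip + 1L
  children <- tree_children(tree)
  obs <- rep(NA_real_, ntip)
  obs[match(names(values), tree$tip.label)] <- values

  # upward pass: up_msg[v, ] = Gaussian message about X_v from v's subtree
  up_msg <- matrix(NA_real_, n_node, 2)
  po <- ape::reorder.phylo(tree, "postorder")
  for (v in seq_len(ntip)) {
    up_msg[v, ] <- if (is.na(obs[v])) c(NA_real_, Inf) else c(obs[v], 0)
  }
  internal_po <- unique(po$edge[, 1])  # parents in postorder: children done first
  for (v in internal_po) {
    msgs <- lapply(children[[v]], function(e) {
      child <- tree$edge[e, 2]
      m <- up_msg[child, ]
      c(m[1], m[2] + tree$edge.length[e])
    })
    up_msg[v, ] <- combine_messages(msgs)
  }

  # downward pass: down[v] = message about X_v from everything outside v's
  # subtree (diffuse at the root)
  down_msg <- matrix(NA_real_, n_node, 2)
  down_msg[root, ] <- c(NA_real_, Inf)
  edge_pre <- rev(seq_len(nrow(po$edge)))  # edges parent-before-child
  for (idx in edge_pre) {
    p <- po$edge[idx, 1]
    v <- po$edge[idx, 2]
    # which edge of the original tree is this?
    elen <- po$edge.length[idx]
    sib_edges <- children[[p]]
    msgs <- list(down_msg[p, ])
    for (se in sib_edges) {
      child <- tree$edge[se, 2]
      if (child == v) next
      m <- up_msg[child, ]
      msgs <- c(msgs, list(c(m[1], m[2] + tree$edge.length[se])))
    }
    at_p <- combine_messages(msgs)
    down_msg[v, ] <- c(at_p[1], at_p[2] + elen)
  }

  node_mean <- vapply(seq_len(n_node), function(v) {
    combine_messages(list(up_msg[v, ], down_msg[v, ]))[1]
  }, numeric(1))
  if (anyNA(node_mean)) stop("tree is disconnected from the observations")

  num <- 0
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    v <- tree$edge[e, 2]
    num <- num + tree$edge.length[e] * (node_mean[p] + node_mean[v]) / 2
  }
  structure(num / sum(tree$edge.length), node_means = node_mean)
}

#' Quadratic-time oracle for the Brownian-motion temporal average
#'
#' Reference implementation used for testing [bm_tree_average()]: builds the
#' full joint Gaussian of all node values under Brownian motion with a flat
#' (diffuse) root, conditions on the observed leaves by a direct linear
#' solve, and forms the same branch-wise temporal average. Covariance of two
#' nodes equals the length of their shared path from the root.
#'
#' @inheritParams bm_tree_average
#' @return The temporal average (single number).
#' @export
bm_tree_average_oracle <- function(tree, values) {
  validate_tree(tree)
  check_leaf_values(tree, values)
  if (length(values) < 2) stop("Brownian-motion averaging needs >= 2 leaves")
  if (sum(tree$edge.length) <= 0) stop("tree has zero total branch length")

  ntip <- ape::Ntip(tree)
  n_node <- ntip + tree$Nnode
  root <- ntip + 1L
  parent <- integer(n_node); parent[root] <- 0L
  plen <- numeric(n_node)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    plen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  depth <- numeric(n_node)
  # parent precedes child in a preorder walk
  po <- ape::reorder.phylo(tree, "postorder")
  for (idx in rev(seq_len(nrow(po$edge)))) {
    v <- po$edge[idx, 2]
    depth[v] <- depth[po$edge[idx, 1]] + po$edge.length[idx]
  }
  # ancestor sets for shared-path covariance
  anc <- vector("list", n_node)
  anc[[root]] <- root
  for (idx in rev(seq_len(nrow(po$edge)))) {
    v <- po$edge[idx, 2]
    anc[[v]] <- c(anc[[po$edge[idx, 1]]], v)
  }
  cov_nodes <- function(a, b) {
    common <- intersect(anc[[a]], anc[[b]])
    max(depth[common])
  }
  obs_idx <- match(names(values), tree$tip.label)
  y <- as.numeric(values)
  k <- length(y)
  S_LL <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    S_LL[i, j] <- cov_nodes(obs_idx[i], obs_idx[j])
  }
  Si <- tryCatch(solve(S_LL), error = function(e)
    stop("singular conditioning system (coincident zero-depth leaves?)"))
  one <- rep(1, k)
  mu_hat <- as.numeric(one %*% Si %*% y) / as.numeric(one %*% Si %*% one)
  resid <- Si %*% (y - mu_hat)
  node_mean <- vapply(seq_len(n_node), function(v) {
    cv <- vapply(seq_len(k), function(i) cov_nodes(v, obs_idx[i]), numeric(1))
    mu_hat + as.numeric(cv %*% resid)
  }, numeric(1))
  num <- sum(tree$edge.length *
               (node_mean[tree$edge[, 1]] + node_mean[tree$edge[, 2]]) / 2)
  num / sum(tree$edge.length)
}

#' Combine per-species motif profiles into a multi-species profile
#'
#' For each window of the reference profile, gathers the orthologous window
#' scores named by `orthology` and replaces the reference score with their
#' simple mean or Brownian-motion tree average. Windows with no ortholog in
#' any other species keep the reference score.
#'
#' @param tree Phylogeny whose tip labels are the species names (required
#'   for `method = "bm"`).
#' @param profiles Named list of `motif_profile` objects, one per species;
#'   the first (or `reference`) is the reference species.
#' @param orthology Data frame with columns `window` (row index in the
#'   reference profile), `species`, and `ortholog` (row index in that
#'   species' profile). The reference species' own score is always included.
#' @param method `"simple"` or `"bm"`.
#' @param reference Name of the reference species (default first profile).
#' @return A `motif_profile` with `species = "combined"`.
#' @export
combine_profiles <- function(tree = NULL, profiles, orthology,
                             method = c("simple", "bm"),
                             reference = names(profiles)[1]) {
  method <- match.arg(method)
  if (is.null(names(profiles)) || !reference %in% names(profiles)) {
    stop("profiles must be a named list containing the reference species")
  }
  if (method == "bm" && is.null(tree)) stop("bm averaging needs a tree")
  ref <- profiles[[reference]]
  scores <- ref$score
  for (w in seq_along(scores)) {
    hits <- orthology[orthology$window == w, , drop = FALSE]
    vals <- c(scores[w])
    names(vals) <- reference
    for (r in seq_len(nrow(hits))) {
      sp <- hits$species[r]
      if (sp == reference) next
      if (!sp %in% names(profiles)) stop("unknown species in orthology: ", sp)
      vals[sp] <- profiles[[sp]]$score[hits$ortholog[r]]
    }
    if (length(vals) >= 2) {
      scores[w] <- if (method == "simple") simple_average(vals)
                   else as.numeric(bm_tree_average(tree, vals))
    }
  }
  out <- ref
  out$score <- scores
  attr(out, "species") <- "combined"
  out
}
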