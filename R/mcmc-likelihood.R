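#' Construct a genealogy object
#'
#' A tip-labelled binary genealogy: tips are nodes `1..n_tip` at time 0,
#' internal nodes follow, and `parent[root]` is `NA`. Node times are in
#' generations and increase root-ward.
#'
#' @param parent Integer vector of parent node ids (`NA` for the root).
#' @param time Numeric node times (tips 0).
#' @param tip_pop Character population label per tip.
#' @return A `genealogy` list (parent, time, tip_pop, n_tip, root, tmrca).
#' @export
genealogy <- function(parent, time, tip_pop) {
  n_tip <- length(tip_pop)
  root <- which(is.na(parent))
  if (length(root) != 1L) stop("genealogy must have exactly one root")
  for (v in seq_along(parent)) {
    p <- parent[v]
    if (!is.na(p) && time[p] <= time[v] - 1e-12) {
      stop("node times must increase root-ward")
    }
  }
  list(parent = as.integer(parent), time = as.numeric(time),
       tip_pop = as.character(tip_pop), n_tip = n_tip,
       root = as.integer(root), tmrca = time[root])
}

# edges sorted by parent time ascending (children complete before use)
genealogy_edges <- function(tree) {
  child <- which(!is.na(tree$parent))
  par <- tree$parent[child]
  ord <- order(tree$time[par], par)
  cbind(parent = par[ord], child = child[ord])
}

#' Single-step mutation model log-likelihood of haplotypes on a genealogy
#'
#' Felsenstein pruning per locus over a truncated integer repeat window
#' around the observed range (half-width at least `6 * sqrt(theta_max)`,
#' widened automatically and capped), with a uniform root prior over the
#' window and loci treated as independent.
#'
#' @param tree A [genealogy()] whose tips match the table rows in order.
#' @param table A [haplotype_table()] (or integer repeat matrix).
#' @param mu Mutation rate per locus per generation.
#' @param window_pad Optional fixed half-width padding (integer); when
#'   `NULL` it is chosen from `theta_max = 2 * mu * tmrca`.
#' @return Log-likelihood (may be `-Inf`, e.g. `mu = 0` with unequal
#'   haplotypes).
#' @export
tree_log_likelihood <- function(tree, table, mu, window_pad = NULL) {
  tips <- if (inherits(table, "haplotype_table")) loci_matrix(table)
          else as.matrix(table)
  if (nrow(tips) != tree$n_tip) stop("tips must match table rows")
  if (ncol(tips) == 0L) return(0)
  theta_max <- 2 * mu * max(tree$time)
  pad <- if (is.null(window_pad)) window_pad_for(theta_max) else
    as.integer(window_pad)
  win <- locus_windows(tips, pad)
  edges <- genealogy_edges(tree)
  theta <- mu * (tree$time[edges[, "parent"]] - tree$time[edges[, "child"]])
  smm_tree_loglik_cpp(edges[, "parent"], edges[, "child"], theta,
                      tips, length(tree$parent), win$lo, win$hi)
}

window_pad_for <- function(theta_max, cap = 200L) {
  pad <- max(4L, as.integer(ceiling(6 * sqrt(max(theta_max, 0)))))
  if (pad > cap) stop("pruning window overflow: theta too large")
  pad
}

locus_windows <- function(tips, pad) {
  lo <- integer(ncol(tips)); hi <- integer(ncol(tips))
  for (l in seq_len(ncol(tips))) {
    x <- tips[, l]
    x <- x[!is.na(x)]
    if (!length(x)) x <- 14L
    lo[l] <- min(x) - pad
    hi[l] <- max(x) + pad
  }
  list(lo = lo, hi = hi)
}

#' Structured-coalescent log prior density of a genealogy
#'
#' Density of the genealogy under the splitting, constant-then-growing
#' demography: within each active population unit, each lineage pair
#' coalesces at rate `1/(w * N(t))`; units merge root-ward at the model's
#' split times. Genealogies with coalescences between populations below
#' their split time (or invalid split ordering) have density zero
#' (`-Inf` returned).
#'
#' @param tree A [genealogy()]; `tip_pop` labels must be model
#'   populations.
#' @param model A [demography_model()] (mutation fields unused here).
#' @param units Optional precomputed merge schedule from an earlier call
#'   with the same demography (internal cache).
#' @return Log-density.
#' @export
coalescent_log_prior <- function(tree, model, units = NULL) {
  n <- tree$n_tip
  if (n == 1L) return(0)
  pops <- model$populations
  pop_idx <- match(tree$tip_pop, pops)
  if (anyNA(pop_idx)) stop("tip population not in model")
  st <- model$split_times
  if (length(st) > 1L) {
    # root-ward ordering: every internal child must be younger than parent
    phy <- model$phy
    n_pt <- length(pops)
    for (e in seq_len(nrow(phy$edge))) {
      chi <- phy$edge[e, 2L]
      if (chi > n_pt) {
        t_par <- st[model$node_labels[phy$edge[e, 1L] - n_pt]]
        t_chi <- st[model$node_labels[chi - n_pt]]
        if (t_par <= t_chi) return(-Inf)
      }
    }
  }
  if (length(st) && any(st < 0)) return(-Inf)

  if (is.null(units)) units <- demography_units(model)
  weights <- if (length(pops) == 1L) 1 else as.numeric(units$weights)
  if (is.null(units$mt)) {
    merges <- units$merges
    units$mt <- vapply(merges, function(m) m$time, numeric(1))
    units$mn <- vapply(merges, function(m) as.integer(m$node), integer(1))
    units$ma <- vapply(merges, function(m) as.integer(m$children[1L]),
                       integer(1))
    units$mb <- vapply(merges, function(m) as.integer(m$children[2L]),
                       integer(1))
  }
  coal_log_prior_cpp(tree$parent, tree$time, as.integer(pop_idx), n,
                     weights, units$mt, units$mn, units$ma, units$mb,
                     model$N0, model$N_a, model$beta, model$growth_rate)
}
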