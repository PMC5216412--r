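#' Construct a refugium-expansion demography model
#'
#' The demography is a rooted population tree with a constant-then-
#' exponential total effective size: backward in time the total size is
#' `N(t) = N0 * exp(-r * t)` for `t < beta` (growth phase, rate `r` implied
#' by `N0`, `N_a` and `beta`) and `N(t) = N_a` at and before the growth
#' onset `beta`. At each population split (backward: merge) the parent's
#' size is divided among the two children, a fraction `p` to the first
#' child, so child sizes always sum to the parent size.
#'
#' @param topology Newick string over population labels, e.g.
#'   `"((A,B),(C,D));"`. Internal nodes may carry labels; unlabelled nodes
#'   are named `split1`, `split2`, ... in `ape` node order (root first).
#' @param N0 Present-day total effective size (number of males for Y data).
#' @param N_a Ancestral total size at and before growth onset.
#' @param beta Growth onset time, generations before present (0 disables
#'   growth; then `N_a` must equal `N0`).
#' @param split_times Named numeric vector of split times (generations) for
#'   each internal node; names must match node labels. A single unnamed
#'   value is accepted when there is one split.
#' @param split_props Split proportions in (0,1), fraction of the parent
#'   size assigned to the first child; recycled; default 0.5.
#' @param mu STR mutation rate per locus per generation.
#' @param ancestral_repeat Root repeat count for simulated STR loci.
#' @return An object of class `demography_model`.
#' @export
demography_model <- function(topology, N0, N_a = N0, beta = 0,
                             split_times = numeric(0), split_props = 0.5,
                             mu = 6.9e-4, ancestral_repeat = 14L) {
  if (!grepl("\\(", topology)) {
    # single population: plain label, no tree
    pop <- sub(";\\s*$", "", trimws(topology))
    if (!nzchar(pop)) stop("empty topology")
    phy <- NULL
    n_pop <- 1L
    n_int <- 0L
    node_labels <- character(0)
  } else {
    phy <- ape::read.tree(text = topology)
    if (is.null(phy)) stop("could not parse topology")
    n_pop <- length(phy$tip.label)
    n_int <- phy$Nnode
    node_labels <- phy$node.label
  }
  if (is.null(node_labels) || !any(nzchar(node_labels))) {
    node_labels <- paste0("split", seq_len(n_int))
  }
  node_labels[!nzchar(node_labels)] <-
    paste0("split", which(!nzchar(node_labels)))
  if (N0 < 1 || N_a < 1) stop("N0 and N_a must be >= 1")
  if (beta < 0) stop("beta must be >= 0")
  if (beta == 0 && abs(N_a - N0) > 1e-9) {
    stop("beta = 0 requires N_a = N0")
  }
  r <- if (beta > 0) log(N0 / N_a) / beta else 0
  if (n_int > 0 && n_pop > 1) {
    if (length(split_times) != n_int) {
      stop("need one split time per internal node (", n_int, ")")
    }
    if (is.null(names(split_times)) && n_int == 1L) {
      names(split_times) <- node_labels
    }
    if (!setequal(names(split_times), node_labels)) {
      stop("split_times names must match internal node labels: ",
           paste(node_labels, collapse = ", "))
    }
    split_times <- split_times[node_labels]
  }
  split_props <- rep_len(split_props, max(n_int, 1L))
  if (any(split_props <= 0 | split_props >= 1)) {
    stop("split proportions must lie strictly in (0, 1)")
  }
  model <- structure(list(
    phy = phy, populations = if (is.null(phy)) pop else phy$tip.label,
    node_labels = node_labels,
    N0 = N0, N_a = N_a, beta = beta, growth_rate = r,
    split_times = split_times, split_props = split_props,
    mu = mu, ancestral_repeat = as.integer(ancestral_repeat)
  ), class = "demography_model")
  validate_demography(model)
}

validate_demography <- function(model) {
  phy <- model$phy
  n_tip <- length(phy$tip.label)
  if (n_tip > 1) {
    # split times must increase strictly root-ward
    st <- model$split_times
    for (e in seq_len(nrow(phy$edge))) {
      par <- phy$edge[e, 1L]
      chi <- phy$edge[e, 2L]
      if (chi > n_tip) {
        t_par <- st[model$node_labels[par - n_tip]]
        t_chi <- st[model$node_labels[chi - n_tip]]
        if (t_par <= t_chi) {
          stop("split times must increase root-ward (",
               model$node_labels[chi - n_tip], " >= its parent)")
        }
      }
    }
    if (any(st < 0)) stop("split times must be non-negative")
  }
  model
}

#' Total effective size at time t (generations before present)
#' @param model A `demography_model`.
#' @param t Time, generations before present.
#' @return Numeric vector of sizes.
#' @export
total_size_at <- function(model, t) {
  ifelse(t < model$beta,
         model$N0 * exp(-model$growth_rate * t),
         model$N_a)
}

# Integral of 1/N(z) over [t0, t1] for the total size trajectory.
# Piecewise: exponential growth below beta, constant N_a above.
inv_size_integral <- function(model, t0, t1) {
  if (t1 <= t0) return(0)
  r <- model$growth_rate
  beta <- model$beta
  acc <- 0
  lo <- t0
  hi <- min(t1, beta)
  if (hi > lo) {
    acc <- acc + if (r == 0) (hi - lo) / model$N0 else
      (exp(r * hi) - exp(r * lo)) / (model$N0 * r)
    lo <- hi
  }
  if (t1 > beta) {
    lo2 <- max(t0, beta)
    acc <- acc + (t1 - lo2) / model$N_a
  }
  acc
}

# Inverse cumulative hazard: smallest s in (t0, t1] with
# C * w^-1 * integral_{t0}^{s} dz/N(z) = E, or +Inf if the hazard over
# (t0, t1] is below E. C is the pair-coalescence factor k(k-1)/2, w the
# unit's share of the total size.
invert_hazard <- function(model, t0, t1, C, w, E) {
  if (C <= 0) return(Inf)
  target <- E * w / C
  r <- model$growth_rate
  beta <- model$beta
  lo <- t0
  # growth segment
  if (lo < beta) {
    hi <- min(t1, beta)
    seg <- if (r == 0) (hi - lo) / model$N0 else
      (exp(r * hi) - exp(r * lo)) / (model$N0 * r)
    if (target <= seg) {
      s <- if (r == 0) lo + target * model$N0 else
        log(exp(r * lo) + target * model$N0 * r) / r
      return(s)
    }
    target <- target - seg
    lo <- hi
    if (lo >= t1) return(Inf)
  }
  # constant segment
  lo <- max(lo, beta)
  s <- lo + target * model$N_a
  if (s <= t1) s else Inf
}

# Population-unit bookkeeping: active units between splits, each a set of
# terminal populations with a size weight. Returns, in merge order
# (increasing split time), the split events and the terminal weights.
demography_units <- function(model) {
  phy <- model$phy
  if (is.null(phy) || length(phy$tip.label) == 1L) {
    return(list(weights = stats::setNames(1, model$populations[1L]),
                merges = list(), n_tip = 1L))
  }
  n_tip <- length(phy$tip.label)
  # weight of each node = product of split proportions along root path
  n_node <- n_tip + phy$Nnode
  weight <- rep(NA_real_, n_node)
  root <- n_tip + 1L
  weight[root] <- 1
  # preorder
  ord <- order(match(phy$edge[, 1L], c(root, seq_len(n_node))))
  edges <- phy$edge[order(phy$edge[, 1L]), , drop = FALSE]
  # walk edges in preorder via repeated passes (small trees)
  repeat {
    done <- TRUE
    for (e in seq_len(nrow(phy$edge))) {
      par <- phy$edge[e, 1L]; chi <- phy$edge[e, 2L]
      if (!is.na(weight[par]) && is.na(weight[chi])) {
        kids <- phy$edge[phy$edge[, 1L] == par, 2L]
        p <- model$split_props[par - n_tip]
        w_first <- weight[par] * p
        w_second <- weight[par] * (1 - p)
        weight[kids[1L]] <- w_first
        if (length(kids) > 1L) weight[kids[2L]] <- w_second
        done <- FALSE
      }
    }
    if (done) break
  }
  merges <- lapply(order(model$split_times), function(i) {
    node <- n_tip + i
    kids <- phy$edge[phy$edge[, 1L] == node, 2L]
    list(node = node, label = model$node_labels[i],
         time = unname(model$split_times[i]), children = kids)
  })
  list(weights = weight, merges = merges, n_tip = n_tip)
}

#' Earliest legal coalescence time for each population pair
#'
#' Two lineages sampled from different populations may only coalesce above
#' the split time of the populations' most recent common ancestral
#' population.
#'
#' @param model A `demography_model`.
#' @return Symmetric matrix of minimum coalescence times (0 on diagonal).
#' @export
pairwise_split_floor <- function(model) {
  pops <- model$populations
  n <- length(pops)
  out <- matrix(0, n, n, dimnames = list(pops, pops))
  if (n == 1L) return(out)
  phy <- model$phy
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      mrca <- ape::getMRCA(phy, c(pops[i], pops[j]))
      tm <- model$split_times[model$node_labels[mrca - n]]
      out[i, j] <- out[j, i] <- unname(tm)
    }
  }
  out
}
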