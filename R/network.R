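#' Median-joining haplotype network for STR data
#'
#' Distances are summed absolute repeat differences. The network starts
#' from the minimum-spanning network of feasible links at tolerance
#' `epsilon` (an edge is feasible when its length is within `epsilon` of
#' the threshold at which its endpoints become connected); component-wise
#' medians of linked triplets are then added greedily whenever they
#' shorten the spanning weight, the network is recomputed, and obsolete
#' median vectors (degree below 3) are pruned. Rows with missing loci are
#' excluded (count reported). Input row order does not matter: haplotypes
#' are canonically ordered before tie-breaking.
#'
#' @param table A [haplotype_table()].
#' @param epsilon Integer tolerance `>= 0` (default 0).
#' @return An object of class `haplotype_network`: `nodes` (data frame:
#'   id, haplotype key, multiplicity, is_median, population counts),
#'   `edges` (data frame: from, to, weight, and the per-locus signed
#'   steps as a label), `haplotypes` (matrix of node haplotypes), and
#'   `n_excluded`.
#' @export
build_mj_network <- function(table, epsilon = 0L) {
  if (nrow(table) == 0L) stop("need at least one haplotype")
  reps <- loci_matrix(table)
  complete <- stats::complete.cases(reps)
  n_excluded <- sum(!complete)
  reps <- reps[complete, , drop = FALSE]
  pops <- table$population[complete]
  if (nrow(reps) == 0L) stop("no complete haplotypes")

  key <- apply(reps, 1L, paste, collapse = ",")
  ord <- order(key)
  ukey <- unique(key[ord])
  hap <- reps[match(ukey, key), , drop = FALSE]
  rownames(hap) <- NULL
  multiplicity <- as.integer(table(key)[ukey])
  pop_counts <- t(vapply(ukey, function(k) {
    table(factor(pops[key == k], levels = unique(pops)))
  }, integer(length(unique(pops)))))
  if (length(unique(pops)) == 1L) {
    pop_counts <- matrix(multiplicity, ncol = 1L,
                         dimnames = list(NULL, unique(pops)))
  }
  is_median <- rep(FALSE, nrow(hap))

  repeat {
    net <- feasible_network(hap, epsilon)
    med <- best_median(hap, net, is_median)
    if (is.null(med)) break
    hap <- rbind(hap, med)
    is_median <- c(is_median, TRUE)
  }
  # prune obsolete medians (degree < 3), iterating because removals can
  # lower other medians' degrees
  repeat {
    net <- feasible_network(hap, epsilon)
    deg <- tabulate(c(net$edges$from, net$edges$to), nbins = nrow(hap))
    drop <- which(is_median & deg < 3L)
    if (!length(drop)) break
    keep <- setdiff(seq_len(nrow(hap)), drop)
    hap <- hap[keep, , drop = FALSE]
    is_median <- is_median[keep]
  }
  net <- feasible_network(hap, epsilon)
  n_obs <- sum(!is_median)
  nodes <- data.frame(id = seq_len(nrow(hap)),
                      key = apply(hap, 1L, paste, collapse = ","),
                      multiplicity = c(multiplicity,
                                       rep(0L, nrow(hap) - n_obs)),
                      is_median = is_median)
  pc <- rbind(pop_counts,
              matrix(0L, nrow(hap) - n_obs, ncol(pop_counts),
                     dimnames = list(NULL, colnames(pop_counts))))
  edges <- net$edges
  edges$label <- vapply(seq_len(nrow(edges)), function(i) {
    d <- hap[edges$to[i], ] - hap[edges$from[i], ]
    loc <- which(d != 0)
    paste(sprintf("%s%+d", colnames(hap)[loc], d[loc]), collapse = ";")
  }, character(1))
  structure(list(nodes = nodes, pop_counts = pc, edges = edges,
                 haplotypes = hap, n_excluded = n_excluded,
                 epsilon = epsilon),
            class = "haplotype_network")
}

# minimum-spanning network: edges within epsilon of the connection
# threshold (minimax path distance); epsilon = 0 gives the union of all
# minimum spanning trees
feasible_network <- function(hap, epsilon) {
  n <- nrow(hap)
  if (n == 1L) {
    return(list(edges = data.frame(from = integer(0), to = integer(0),
                                   weight = numeric(0)),
                mst_weight = 0))
  }
  d <- as.matrix(stats::dist(hap, method = "manhattan"))
  # minimax connection distances via an MST
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g, algorithm = "prim")
  mw <- sum(igraph::E(mst)$weight)
  minimax <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    paths <- igraph::shortest_paths(mst, from = i, to = (i + 1L):n,
                                    output = "epath")$epath
    for (j in seq_along(paths)) {
      minimax[i, i + j] <- minimax[i + j, i] <-
        max(igraph::E(mst)$weight[as.integer(paths[[j]])])
    }
  }
  idx <- which(upper.tri(d) & d <= minimax + epsilon, arr.ind = TRUE)
  list(edges = data.frame(from = idx[, 1L], to = idx[, 2L],
                          weight = d[idx]),
       mst_weight = mw)
}

# best median vector of any linked triplet, or NULL when none shortens
# the spanning weight; ties broken on the lexicographically smallest
# haplotype
best_median <- function(hap, net, is_median) {
  edges <- net$edges
  if (nrow(edges) < 2L) return(NULL)
  n <- nrow(hap)
  adj <- matrix(FALSE, n, n)
  adj[cbind(edges$from, edges$to)] <- TRUE
  adj <- adj | t(adj)
  existing <- apply(hap, 1L, paste, collapse = ",")
  cand <- list()
  for (u in seq_len(n - 1L)) {
    for (v in seq(u + 1L, n)) {
      if (!adj[u, v]) next
      linked <- which(adj[u, ] | adj[v, ])
      for (w in setdiff(linked, c(u, v))) {
        if (w < v && adj[u, w]) next  # triple seen before
        m <- apply(hap[c(u, v, w), , drop = FALSE], 2L, stats::median)
        m <- as.integer(round(m))
        k <- paste(m, collapse = ",")
        if (k %in% existing || k %in% names(cand)) next
        cand[[k]] <- m
      }
    }
  }
  if (!length(cand)) return(NULL)
  base_w <- net$mst_weight
  best <- NULL
  best_gain <- 0
  for (k in sort(names(cand))) {
    m <- cand[[k]]
    new_hap <- rbind(hap, m)
    new_w <- feasible_network(new_hap, 0)$mst_weight
    gain <- base_w - new_w
    if (gain > best_gain + 1e-9) {
      best_gain <- gain
      best <- m
    }
  }
  best
}

#' Population composition and assortativity of a haplotype network
#'
#' Summarises how geographically organised a network is: for each edge
#' between observed haplotypes, the probability that two individuals
#' drawn from its endpoints share a population; significance against a
#' permutation null that shuffles individuals' population labels
#' (`(count >= observed + 1) / (n_perm + 1)` convention).
#'
#' @param net A `haplotype_network`.
#' @param n_perm Number of label permutations.
#' @param seed RNG seed.
#' @return A list: `node_composition` (population counts per node),
#'   `assortativity` (mean same-population edge probability),
#'   `p` (permutation p-value), and a `degenerate` flag (single
#'   population or no usable edges).
#' @export
network_geography_summary <- function(net, n_perm = 999L, seed = 1L) {
  pc <- net$pop_counts
  if (ncol(pc) < 2L || nrow(net$edges) == 0L || nrow(net$nodes) < 2L) {
    return(list(node_composition = pc, assortativity = NA_real_,
                p = NA_real_, degenerate = TRUE))
  }
  same_frac <- function(pc) {
    vals <- vapply(seq_len(nrow(net$edges)), function(i) {
      a <- pc[net$edges$from[i], ]
      b <- pc[net$edges$to[i], ]
      na <- sum(a); nb <- sum(b)
      if (na == 0 || nb == 0) return(NA_real_)
      sum(a * b) / (na * nb)
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  obs <- same_frac(pc)
  if (is.nan(obs)) {
    return(list(node_composition = pc, assortativity = NA_real_,
                p = NA_real_, degenerate = TRUE))
  }
  # expand to individual labels, shuffle, recount
  node_of_ind <- rep(seq_len(nrow(pc)), rowSums(pc))
  pop_of_ind <- unlist(lapply(seq_len(nrow(pc)), function(i) {
    rep(colnames(pc), pc[i, ])
  }))
  set.seed(as.integer(seed))
  perm_stats <- vapply(seq_len(n_perm), function(i) {
    shuffled <- sample(pop_of_ind)
    pcp <- t(vapply(seq_len(nrow(pc)), function(v) {
      table(factor(shuffled[node_of_ind == v], levels = colnames(pc)))
    }, integer(ncol(pc))))
    same_frac(pcp)
  }, numeric(1))
  p <- (sum(perm_stats >= obs - 1e-12) + 1) / (n_perm + 1)
  list(node_composition = pc, assortativity = obs, p = p,
       degenerate = FALSE)
}

#' Write a haplotype network as edge-list and node tables
#'
#' @param net A `haplotype_network`.
#' @param edge_path,node_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_network <- function(net, edge_path, node_path) {
  write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  nodes <- cbind(net$nodes, as.data.frame(net$pop_counts))
  write.table(nodes, node_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(edge_path, node_path))
}
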