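#' Simulate Y-STR haplotypes under a refugium-expansion demography
#'
#' Backward-in-time haploid structured coalescent: within each active
#' population unit, every lineage pair coalesces at rate `1/(w * N(t))`
#' where `w` is the unit's share of the total size `N(t)`; lineages from
#' different populations merge only root-ward of their populations' split
#' time. STR loci mutate by the single-step model: mutation counts on each
#' branch are Poisson with mean `mu * length`, each step +1 or -1 with
#' probability 1/2. Unique-event polymorphisms (UEPs) are placed on
#' branches and define haplogroup labels.
#'
#' @param model A [demography_model()].
#' @param n_per_pop Named integer vector of sample sizes per population
#'   (a single unnamed value is accepted for a one-population model).
#' @param n_loci Number of STR loci; the 11-locus default panel names are
#'   used when `n_loci` is 11, else `L1..Ln`.
#' @param seed Integer RNG seed (reruns are bitwise identical).
#' @param uep Optional named numeric vector of clade fractions; for each
#'   entry a UEP is placed on the oldest branch whose clade is closest in
#'   size to `fraction * n`, and its carriers take the marker name as
#'   haplogroup label.
#' @return A list with elements `table` (a [haplotype_table()]) and
#'   `truth` (realized sample TMRCA, the model split times, per-UEP clade
#'   TMRCAs, the seed, and the realized genealogy).
#' @export
simulate_str_sample <- function(model, n_per_pop, n_loci = 11L, seed = 1L,
                                uep = NULL) {
  pops <- model$populations
  if (length(pops) == 0L) stop("model has no populations")
  if (is.null(names(n_per_pop))) {
    if (length(pops) == 1L && length(n_per_pop) == 1L) {
      names(n_per_pop) <- pops
    } else {
      stop("n_per_pop must be named by population")
    }
  }
  if (!setequal(names(n_per_pop), pops)) {
    stop("n_per_pop names must match model populations")
  }
  n_per_pop <- n_per_pop[pops]
  if (any(n_per_pop < 1L)) stop("all per-population sample sizes must be >= 1")

  set.seed(as.integer(seed))
  gen <- simulate_genealogy(model, n_per_pop)
  n <- gen$n_tip
  loci <- if (n_loci == 11L) default_loci() else paste0("L", seq_len(n_loci))
  rep_mat <- mutate_str(gen, model$mu, n_loci, model$ancestral_repeat)
  colnames(rep_mat) <- loci

  haplogroup <- rep("ROOT", n)
  uep_tmrca <- numeric(0)
  if (!is.null(uep) && length(uep)) {
    if (is.null(names(uep))) stop("uep fractions must be named")
    for (m in names(uep)) {
      pl <- place_uep(gen, uep[[m]])
      haplogroup[pl$carriers] <- m
      uep_tmrca[m] <- pl$clade_tmrca
    }
  }

  pop_labels <- gen$tip_pop
  table <- haplotype_table(
    sample_id = sprintf("%s_%03d", pop_labels, stats::ave(
      seq_len(n), pop_labels, FUN = seq_along)),
    population = pop_labels,
    haplogroup = haplogroup,
    repeats = rep_mat,
    check_range = FALSE  # the SMM is unbounded; deep genealogies can drift
  )
  truth <- list(
    tmrca = gen$tmrca,
    split_times = model$split_times,
    uep_tmrca = uep_tmrca,
    seed = as.integer(seed),
    genealogy = gen
  )
  if (length(uep_tmrca) && any(uep_tmrca > gen$tmrca + 1e-9)) {
    stop("internal error: subclade TMRCA exceeds sample TMRCA")
  }
  list(table = table, truth = truth)
}

# Structured-coalescent genealogy. Tips are 1..n, internal nodes created
# in coalescence order n+1..2n-1; parent[root] = NA.
simulate_genealogy <- function(model, n_per_pop) {
  units <- demography_units(model)
  pops <- model$populations
  n <- sum(n_per_pop)
  n_node <- 2L * n - 1L
  parent <- rep(NA_integer_, n_node)
  node_time <- numeric(n_node)
  tip_pop <- rep(names(n_per_pop), n_per_pop)

  # active lineage sets keyed by population-tree node id
  n_tip_pt <- if (length(pops) > 1L) length(pops) else 1L
  lineages <- list()
  for (i in seq_along(pops)) {
    lineages[[as.character(i)]] <- which(tip_pop == pops[i])
  }
  weights <- units$weights
  if (length(pops) == 1L) weights <- c(1)
  merges <- units$merges
  merge_idx <- 1L
  t <- 0
  next_internal <- n + 1L

  repeat {
    total_lin <- sum(lengths(lineages))
    if (total_lin == 1L) break
    t_next_split <- if (merge_idx <= length(merges))
      merges[[merge_idx]]$time else Inf
    # candidate coalescence per active unit
    best_s <- Inf; best_unit <- NULL
    for (key in names(lineages)) {
      k <- length(lineages[[key]])
      if (k < 2L) next
      w <- weights[as.integer(key)]
      E <- stats::rexp(1)
      s <- invert_hazard(model, t, t_next_split, k * (k - 1) / 2, w, E)
      if (s < best_s) { best_s <- s; best_unit <- key }
    }
    if (is.finite(best_s)) {
      lin <- lineages[[best_unit]]
      pair <- sample(seq_along(lin), 2L)
      node <- next_internal; next_internal <- next_internal + 1L
      parent[lin[pair]] <- node
      node_time[node] <- best_s
      lineages[[best_unit]] <- c(lin[-pair], node)
      t <- best_s
    } else if (is.finite(t_next_split)) {
      mg <- merges[[merge_idx]]
      kids <- as.character(mg$children)
      merged <- unlist(lineages[kids], use.names = FALSE)
      lineages[kids] <- NULL
      lineages[[as.character(mg$node)]] <- merged
      t <- max(t, mg$time)
      merge_idx <- merge_idx + 1L
    } else {
      stop("internal error: no coalescence possible and no split left")
    }
  }
  root <- if (n == 1L) 1L else next_internal - 1L
  list(parent = parent, time = node_time, tip_pop = tip_pop, n_tip = n,
       root = root, tmrca = node_time[root])
}

# Single-step mutations along the genealogy; returns tips x loci matrix.
mutate_str <- function(gen, mu, n_loci, ancestral_repeat) {
  n <- gen$n_tip
  n_node <- if (n == 1L) 1L else 2L * n - 1L
  state <- matrix(NA_integer_, n_node, n_loci)
  state[gen$root, ] <- ancestral_repeat
  if (n > 1L) {
    # process children after parents: decreasing node time works because
    # parents are strictly older than children
    ord <- order(gen$time, decreasing = TRUE)
    ord <- ord[ord != gen$root]
    for (v in ord) {
      p <- gen$parent[v]
      if (is.na(p)) next
      len <- gen$time[p] - gen$time[v]
      steps <- stats::rpois(n_loci, mu * len)
      net <- 2L * stats::rbinom(n_loci, steps, 0.5) - steps
      state[v, ] <- state[p, ] + net
    }
  }
  state[seq_len(n), , drop = FALSE]
}

# Deterministic UEP placement: among branches whose clade size is >=
# fraction*n (and < n), the smallest such clade; ties broken by older
# branch midpoint, then node id.
place_uep <- function(gen, fraction) {
  n <- gen$n_tip
  if (n == 1L) return(list(carriers = 1L, clade_tmrca = 0))
  target <- max(1L, ceiling(fraction * n))
  clade <- clade_tips(gen)
  sizes <- lengths(clade)
  cand <- which(!is.na(gen$parent) & sizes >= target & sizes < n)
  if (!length(cand)) cand <- which(!is.na(gen$parent) & sizes < n)
  midpt <- (gen$time[gen$parent[cand]] + gen$time[cand]) / 2
  ord <- order(sizes[cand], -midpt, cand)
  best <- cand[ord[1L]]
  list(carriers = clade[[best]],
       clade_tmrca = gen$time[best])
}

# tips below each node
clade_tips <- function(gen) {
  n <- gen$n_tip
  n_node <- 2L * n - 1L
  clade <- vector("list", n_node)
  for (v in seq_len(n)) clade[[v]] <- v
  ord <- order(gen$time)  # children before parents
  for (v in ord) {
    p <- gen$parent[v]
    if (!is.na(p)) clade[[p]] <- c(clade[[p]], clade[[v]])
  }
  clade
}
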