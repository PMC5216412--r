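#' Bayesian MCMC for STR TMRCAs and population split times
#'
#' Metropolis-Hastings sampler over genealogies and demographic
#' parameters under the single-step mutation model and the splitting,
#' constant-then-exponential-growth coalescent. Genealogy moves are a
#' uniform node-time slide (multiplicative for the root) and a restricted
#' subtree reattachment at fixed node height; parameter moves are
#' log-scale (or reflected) random walks plus independence proposals from
#' the prior. Population-tree topology is fixed per run.
#'
#' @param table A [haplotype_table()]; populations must match the
#'   topology's tip labels.
#' @param priors A [prior_spec()].
#' @param topology Newick string over population labels (`NULL` for a
#'   single-population run).
#' @param n_iter Total sweeps; each sweep makes several genealogy updates
#'   and one pass over the parameters.
#' @param burn_in Sweeps discarded before recording (`< n_iter`).
#' @param thin Record every `thin`-th sweep.
#' @param seed Integer seed; identical seeds give identical traces.
#' @param fixed Named list pinning parameters (e.g.
#'   `list(mu = 6.9e-4, growth = 0, beta = 0)`); fixed parameters get no
#'   moves and no prior term.
#' @param window_pad Optional pruning-window padding (see
#'   [tree_log_likelihood()]); fixed for the whole run so the posterior
#'   target is consistent across iterations.
#' @param rw_scale Base scale of the log/reflected random walks.
#' @return A list of class `mcmc_fit`: `summary` (a data frame of
#'   medians, 2.5%/97.5% quantiles and effective sample sizes per
#'   quantity), `trace` (data frame), `acceptance` (per move type), and
#'   the run settings.
#' @export
run_mcmc <- function(table, priors = prior_spec(), topology = NULL,
                     n_iter = 2000L, burn_in = 500L, thin = 2L, seed = 1L,
                     fixed = list(), window_pad = NULL, rw_scale = 0.5) {
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  set.seed(as.integer(seed))
  tmpl <- mcmc_template(table, topology, priors, fixed, window_pad)
  st <- init_state(tmpl)
  loglik <- state_loglik(tmpl, st)
  lp_coal <- state_coal_prior(tmpl, st)
  lp_par <- state_param_prior(tmpl, st)
  if (!is.finite(loglik + lp_coal + lp_par)) {
    # retry initialisation from the prior; if the data are too spread
    # for a prior-typical genealogy (truncated kernels give such states
    # zero likelihood), deepen the initial tree progressively so sibling
    # haplotypes become reachable, and let the chain adapt from there
    for (i in 1:24) {
      st <- init_state(tmpl)
      if (i > 4 && st$tree$n_tip > 1L) {
        f <- 2^min(i - 4, 8)
        internal <- seq.int(st$tree$n_tip + 1L, length(st$tree$parent))
        st$tree$time[internal] <- st$tree$time[internal] * f
        st$tree$tmrca <- st$tree$time[st$tree$root]
        if (is.null(tmpl$fixed$mu)) {
          st$params$mu <- st$params$mu * sqrt(f)
        }
      }
      loglik <- state_loglik(tmpl, st)
      lp_coal <- state_coal_prior(tmpl, st)
      lp_par <- state_param_prior(tmpl, st)
      if (is.finite(loglik + lp_coal + lp_par)) break
    }
    if (!is.finite(loglik + lp_coal + lp_par)) {
      stop("could not initialise a finite-posterior state")
    }
  }
  cur <- list(st = st, loglik = loglik, lp_coal = lp_coal, lp_par = lp_par)

  n_tip <- st$tree$n_tip
  n_slide <- max(3L, ceiling(n_tip / 8))
  n_spr <- if (n_tip >= 3L) 2L else 0L
  acc <- counters()
  keep <- seq.int(burn_in + 1L, n_iter)
  keep <- keep[(keep - burn_in - 1L) %% thin == 0L]
  trace <- vector("list", length(keep))
  ki <- 1L

  for (it in seq_len(n_iter)) {
    if (n_tip > 1L) {
      for (s in seq_len(n_slide)) cur <- move_slide(tmpl, cur, acc)
      for (s in seq_len(n_spr)) cur <- move_spr(tmpl, cur, acc)
      cur <- move_scale(tmpl, cur, acc)
      cur <- move_ridge(tmpl, cur, acc)
      cur <- move_split_gibbs(tmpl, cur, acc)
      cur <- move_split_translate(tmpl, cur, acc)
      cur <- move_split_gibbs(tmpl, cur, acc)
      cur <- move_split_translate(tmpl, cur, acc)
    }
    cur <- move_params(tmpl, cur, acc, rw_scale)
    if (it > burn_in && ki <= length(trace) && it == keep[ki]) {
      trace[[ki]] <- state_row(tmpl, cur, it)
      ki <- ki + 1L
    }
  }
  trace <- do.call(rbind, trace)
  acc_rates <- rates(acc)
  low <- acc_rates[!is.na(acc_rates) & acc_rates < 0.005]
  if (length(low)) {
    warning("possible non-mixing: acceptance rate below 0.5% for ",
            paste(names(low), collapse = ", "))
  }
  qty <- setdiff(names(trace), c("iter", "logpost", "loglik"))
  summary <- do.call(rbind, lapply(qty, function(q) {
    x <- trace[[q]]
    data.frame(quantity = q, median = stats::median(x),
               q025 = unname(stats::quantile(x, 0.025)),
               q975 = unname(stats::quantile(x, 0.975)),
               ess = ess(x))
  }))
  structure(list(summary = summary, trace = trace, acceptance = acc_rates,
                 n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed), topology = topology),
            class = "mcmc_fit")
}

#' @export
print.mcmc_fit <- function(x, ...) {
  cat(sprintf("STR coalescent MCMC: %d sweeps (burn-in %d, thin %d)\n",
              x$n_iter, x$burn_in, x$thin))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# ---- internal machinery ----------------------------------------------------

mcmc_template <- function(table, topology, priors, fixed, window_pad) {
  pops <- unique(table$population)
  if (is.null(topology)) {
    if (length(pops) > 1L) stop("multi-population data needs a topology")
    phy <- NULL; node_labels <- character(0)
  } else {
    phy <- ape::read.tree(text = topology)
    if (!setequal(phy$tip.label, pops)) {
      stop("topology tips must match table populations")
    }
    pops <- phy$tip.label
    node_labels <- phy$node.label
    if (is.null(node_labels) || !any(nzchar(node_labels))) {
      node_labels <- paste0("split", seq_len(phy$Nnode))
    }
    node_labels[!nzchar(node_labels)] <-
      paste0("split", which(!nzchar(node_labels)))
  }
  tips <- loci_matrix(table)
  has_data <- ncol(tips) > 0L
  mu_ref <- if (!is.null(fixed$mu)) fixed$mu else q_prior(priors$mu, 0.5)
  N_ref <- if (!is.null(fixed$N0)) fixed$N0 else q_prior(priors$N0, 0.5)
  # reference theta for the window: a root-to-tip path of ~2 * 2N
  # generations at the central mutation rate, capped to keep the state
  # space compact (tail mass beyond is negligible for SMM data)
  pad <- if (!is.null(window_pad)) as.integer(window_pad) else
    window_pad_for(min(2 * mu_ref * 4 * N_ref, 25))
  win <- if (has_data) locus_windows(tips, pad) else NULL
  n_split <- if (is.null(phy)) 0L else phy$Nnode
  # population bitmask per population-tree node, for fast clade queries
  pt_masks <- NULL
  if (!is.null(phy)) {
    P <- length(pops)
    pt_masks <- integer(P + phy$Nnode)
    pt_masks[seq_len(P)] <- bitwShiftL(1L, seq_len(P) - 1L)
    repeat {
      done <- TRUE
      for (e in seq_len(nrow(phy$edge))) {
        par <- phy$edge[e, 1L]; chi <- phy$edge[e, 2L]
        if (pt_masks[chi] != 0L &&
            bitwAnd(pt_masks[par], pt_masks[chi]) != pt_masks[chi]) {
          pt_masks[par] <- bitwOr(pt_masks[par], pt_masks[chi])
          done <- FALSE
        }
      }
      if (done) break
    }
  }
  # merge skeleton: children of each internal population-tree node and a
  # preorder, so per-iteration weight/merge updates avoid tree traversal
  skel <- NULL
  if (!is.null(phy)) {
    P <- length(pops)
    kids <- lapply(seq_len(n_split), function(i) {
      phy$edge[phy$edge[, 1L] == P + i, 2L]
    })
    preorder <- integer(0)
    frontier <- P + 1L
    while (length(frontier)) {
      preorder <- c(preorder, frontier)
      frontier <- setdiff(phy$edge[phy$edge[, 1L] %in% frontier, 2L],
                          seq_len(P))
    }
    skel <- list(kids = kids, preorder = preorder)
  }
  list(pops = pops, phy = phy, node_labels = node_labels,
       n_split = n_split, tips = tips, win = win, has_data = has_data,
       tip_pop = as.character(table$population),
       pt_masks = pt_masks, skel = skel,
       priors = priors, fixed = fixed)
}

template_model <- function(tmpl, params) {
  st <- params$split_times
  structure(list(
    phy = tmpl$phy, populations = tmpl$pops, node_labels = tmpl$node_labels,
    N0 = params$N0, N_a = params$N0 * exp(-params$growth * params$beta),
    beta = params$beta, growth_rate = params$growth,
    split_times = st, split_props = params$p_split,
    mu = params$mu, ancestral_repeat = 14L), class = "demography_model")
}

draw_params <- function(tmpl) {
  pr <- tmpl$priors
  fx <- tmpl$fixed
  take <- function(name, sp) if (!is.null(fx[[name]])) fx[[name]] else r_prior(sp)
  params <- list(mu = take("mu", pr$mu), N0 = take("N0", pr$N0),
                 growth = take("growth", pr$growth),
                 beta = take("beta", pr$beta))
  # respect the N_a >= 1 invariant at initialisation
  for (i in 1:200) {
    if (params$N0 * exp(-params$growth * params$beta) >= 1) break
    params$N0 <- take("N0", pr$N0)
    params$growth <- take("growth", pr$growth)
    params$beta <- take("beta", pr$beta)
  }
  if (tmpl$n_split > 0L) {
    if (!is.null(fx$split_times)) {
      params$split_times <- fx$split_times[tmpl$node_labels]
    } else {
      # data-driven starting point: a method-of-moments split estimate
      # from the excess of between-group over within-group repeat
      # diversity, jittered across retries; this chooses where the chain
      # starts, not what it targets
      base <- moment_split_init(tmpl)
      for (i in 1:50) {
        st <- stats::setNames(
          pmin(pmax(base * exp(stats::rnorm(tmpl$n_split, 0, 0.3)),
                    q_prior(pr$split_time, 0.02)),
               q_prior(pr$split_time, 0.98)),
          tmpl$node_labels)
        if (split_order_ok(tmpl, st)) break
      }
      if (!split_order_ok(tmpl, st)) st <- repair_split_order(tmpl, st)
      params$split_times <- st
    }
    params$p_split <- if (!is.null(fx$p_split))
      rep_len(fx$p_split, tmpl$n_split) else r_prior(pr$p_split, tmpl$n_split)
  } else {
    params$split_times <- stats::setNames(numeric(0), character(0))
    params$p_split <- numeric(0)
  }
  params
}

# method-of-moments split-time initialisation: for each internal node
# of the population tree, the between-clade mean pairwise squared repeat
# difference exceeds the within-clade mean by roughly 4 mu s, s the
# split time; fall back to a low prior quantile without data
moment_split_init <- function(tmpl) {
  pr <- tmpl$priors
  fallback <- rep(q_prior(pr$split_time, 0.1), max(tmpl$n_split, 1L))
  if (!tmpl$has_data || tmpl$n_split == 0L) return(fallback)
  mu_ref <- if (!is.null(tmpl$fixed$mu)) tmpl$fixed$mu else
    q_prior(pr$mu, 0.5)
  reps <- tmpl$tips
  P <- length(tmpl$pops)
  pop_idx <- match(tmpl$tip_pop, tmpl$pops)
  msd_between <- function(i1, i2) {
    vals <- vapply(seq_len(ncol(reps)), function(l) {
      x <- reps[i1, l]; y <- reps[i2, l]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (!length(x) || !length(y)) return(NA_real_)
      # mean over cross pairs of (x - y)^2
      mean(x^2) + mean(y^2) - 2 * mean(x) * mean(y)
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  msd_within <- function(i1) {
    vals <- vapply(seq_len(ncol(reps)), function(l) {
      x <- reps[i1, l]; x <- x[!is.na(x)]
      n <- length(x)
      if (n < 2) return(NA_real_)
      (n * sum(x^2) - sum(x)^2) / (n * (n - 1) / 2)
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  out <- numeric(tmpl$n_split)
  for (i in seq_len(tmpl$n_split)) {
    kids <- tmpl$skel$kids[[i]]
    m1 <- tmpl$pt_masks[kids[1L]]
    m2 <- tmpl$pt_masks[kids[2L]]
    in1 <- which(bitwAnd(bitwShiftL(1L, pop_idx - 1L), m1) != 0L)
    in2 <- which(bitwAnd(bitwShiftL(1L, pop_idx - 1L), m2) != 0L)
    if (length(in1) < 2L || length(in2) < 2L) { out[i] <- fallback[i]; next }
    d_b <- msd_between(in1, in2)
    d_w <- (msd_within(in1) + msd_within(in2)) / 2
    s_hat <- (d_b - d_w) / (4 * mu_ref)
    out[i] <- if (is.finite(s_hat)) max(s_hat, 1) else fallback[i]
  }
  out
}

# lift each parent split above its children (postorder), then rescale
# into the prior support if needed; order is preserved by the rescale
repair_split_order <- function(tmpl, st) {
  P <- length(tmpl$pops)
  for (node in rev(tmpl$skel$preorder)) {
    i <- node - P
    for (k in tmpl$skel$kids[[i]]) {
      if (k > P) st[i] <- max(st[i], st[k - P] * 1.05 + 1)
    }
  }
  hi <- q_prior(tmpl$priors$split_time, 0.99)
  if (max(st) > hi) st <- st * hi / max(st)
  st
}

split_order_ok <- function(tmpl, st) {
  if (tmpl$n_split <= 1L) return(TRUE)
  phy <- tmpl$phy
  n_pt <- length(tmpl$pops)
  for (e in seq_len(nrow(phy$edge))) {
    chi <- phy$edge[e, 2L]
    if (chi > n_pt) {
      if (st[tmpl$node_labels[phy$edge[e, 1L] - n_pt]] <=
          st[tmpl$node_labels[chi - n_pt]]) return(FALSE)
    }
  }
  TRUE
}

init_state <- function(tmpl) {
  params <- draw_params(tmpl)
  model <- template_model(tmpl, params)
  n_per_pop <- table(factor(tmpl$tip_pop, levels = tmpl$pops))
  gen <- simulate_genealogy(model, stats::setNames(as.integer(n_per_pop),
                                                   tmpl$pops))
  # simulate_genealogy orders tips by population blocks; rebuild so tip i
  # corresponds to table row i: sim tip j is table row ord[j]
  ord <- order(match(tmpl$tip_pop, tmpl$pops))
  n <- gen$n_tip
  map <- c(ord, if (length(gen$parent) > n) seq.int(n + 1L, length(gen$parent)))
  parent <- gen$parent
  new_parent <- rep(NA_integer_, length(parent))
  for (v in seq_along(parent)) {
    if (!is.na(parent[v])) new_parent[map[v]] <- map[parent[v]]
  }
  new_time <- numeric(length(parent))
  new_time[map] <- gen$time
  tree <- list(parent = new_parent, time = new_time,
               tip_pop = tmpl$tip_pop, n_tip = n,
               root = map[gen$root], tmrca = gen$tmrca)
  refresh_units(tmpl, list(tree = tree, params = params))
}

state_loglik <- function(tmpl, st) {
  if (!tmpl$has_data) return(0)
  tree <- st$tree
  edges <- genealogy_edges(tree)
  theta <- st$params$mu *
    (tree$time[edges[, "parent"]] - tree$time[edges[, "child"]])
  smm_tree_loglik_cpp(edges[, "parent"], edges[, "child"], theta,
                      tmpl$tips, length(tree$parent),
                      tmpl$win$lo, tmpl$win$hi)
}

state_coal_prior <- function(tmpl, st) {
  model <- template_model(tmpl, st$params)
  units <- st$units
  if (is.null(units)) units <- demography_units(model)
  coalescent_log_prior(st$tree, model, units)
}

# merge schedule depends only on split times / proportions; refresh the
# cache when those change (fast path over the precomputed skeleton)
refresh_units <- function(tmpl, st) {
  if (is.null(tmpl$skel)) {
    st$units <- demography_units(template_model(tmpl, st$params))
    return(st)
  }
  P <- length(tmpl$pops)
  n_split <- tmpl$n_split
  weight <- numeric(P + n_split)
  weight[P + 1L] <- 1
  for (node in tmpl$skel$preorder) {
    i <- node - P
    k <- tmpl$skel$kids[[i]]
    p <- st$params$p_split[i]
    weight[k[1L]] <- weight[node] * p
    weight[k[2L]] <- weight[node] * (1 - p)
  }
  ord <- order(st$params$split_times)
  merges <- lapply(ord, function(i) {
    list(node = P + i, label = tmpl$node_labels[i],
         time = unname(st$params$split_times[i]),
         children = tmpl$skel$kids[[i]])
  })
  st$units <- list(
    weights = weight, merges = merges, n_tip = P,
    mt = unname(st$params$split_times[ord]),
    mn = P + ord,
    ma = vapply(ord, function(i) tmpl$skel$kids[[i]][1L], integer(1)),
    mb = vapply(ord, function(i) tmpl$skel$kids[[i]][2L], integer(1)))
  st
}

state_param_prior <- function(tmpl, st) {
  pr <- tmpl$priors
  fx <- tmpl$fixed
  p <- st$params
  # model invariant: the ancestral size N_a = N0 exp(-r beta) must be at
  # least one individual
  if (p$N0 * exp(-p$growth * p$beta) < 1) return(-Inf)
  lp <- 0
  if (is.null(fx$mu)) lp <- lp + d_prior(pr$mu, p$mu)
  if (is.null(fx$N0)) lp <- lp + d_prior(pr$N0, p$N0)
  if (is.null(fx$growth)) lp <- lp + d_prior(pr$growth, p$growth)
  if (is.null(fx$beta)) lp <- lp + d_prior(pr$beta, p$beta)
  if (tmpl$n_split > 0L) {
    if (!split_order_ok(tmpl, p$split_times)) return(-Inf)
    if (is.null(fx$split_times)) {
      lp <- lp + sum(d_prior(pr$split_time, p$split_times))
    }
    if (is.null(fx$p_split)) {
      lp <- lp + sum(d_prior(pr$p_split, p$p_split))
    }
  }
  lp
}

counters <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- integer(0); e$a <- integer(0)
  e
}

bump <- function(acc, move, accepted) {
  if (is.na(match(move, names(acc$n)))) {
    acc$n[move] <- 0L; acc$a[move] <- 0L
  }
  acc$n[move] <- acc$n[move] + 1L
  if (accepted) acc$a[move] <- acc$a[move] + 1L
}

rates <- function(acc) {
  if (!length(acc$n)) return(numeric(0))
  acc$a / acc$n
}

accept_state <- function(tmpl, cur, prop_st, move, acc,
                         log_hastings = 0, need_lik = TRUE,
                         params_changed = TRUE) {
  lp_par <- if (params_changed) state_param_prior(tmpl, prop_st) else
    cur$lp_par
  if (!is.finite(lp_par)) { bump(acc, move, FALSE); return(cur) }
  lp_coal <- state_coal_prior(tmpl, prop_st)
  if (!is.finite(lp_coal)) { bump(acc, move, FALSE); return(cur) }
  loglik <- if (need_lik) state_loglik(tmpl, prop_st) else cur$loglik
  ratio <- (loglik + lp_coal + lp_par) -
    (cur$loglik + cur$lp_coal + cur$lp_par) + log_hastings
  if (is.finite(ratio) && log(stats::runif(1)) < ratio) {
    bump(acc, move, TRUE)
    list(st = prop_st, loglik = loglik, lp_coal = lp_coal, lp_par = lp_par)
  } else {
    bump(acc, move, FALSE)
    cur
  }
}

move_slide <- function(tmpl, cur, acc) {
  tree <- cur$st$tree
  n <- tree$n_tip
  if (n < 2L) return(cur)
  internal <- seq.int(n + 1L, length(tree$parent))
  v <- if (length(internal) == 1L) internal else sample(internal, 1L)
  kids <- which(!is.na(tree$parent) & tree$parent == v)
  lo <- max(tree$time[kids])
  p <- tree$parent[v]
  if (is.na(p)) {
    x <- tree$time[v] - lo
    z <- stats::rnorm(1, 0, 0.7)
    x_new <- x * exp(z)
    t_new <- lo + x_new
    log_h <- log(x_new / x)
  } else {
    hi <- tree$time[p]
    if (hi <= lo) return(cur)
    t_new <- stats::runif(1, lo, hi)
    log_h <- 0
  }
  prop <- cur$st
  prop$tree$time[v] <- t_new
  prop$tree$tmrca <- prop$tree$time[prop$tree$root]
  accept_state(tmpl, cur, prop, "slide", acc, log_h,
               params_changed = FALSE)
}

move_spr <- function(tmpl, cur, acc) {
  tree <- cur$st$tree
  n <- tree$n_tip
  if (n < 3L) return(cur)
  nn <- length(tree$parent)
  cand_v <- which(!is.na(tree$parent))
  v <- cand_v[sample.int(length(cand_v), 1L)]
  u <- tree$parent[v]
  kids_u <- which(!is.na(tree$parent) & tree$parent == u)
  w <- setdiff(kids_u, v)
  if (length(w) != 1L) return(cur)
  g <- tree$parent[u]
  t_u <- tree$time[u]
  # remaining tree: drop u, connect g -> w
  rem_parent <- tree$parent
  rem_parent[w] <- g
  rem_parent[u] <- NA_integer_  # u removed
  rem_root <- if (is.na(g)) w else tree$root
  # candidate attachment points: edges (a -> b) of remaining tree with
  # time[b] < t_u < time[a]; plus the branch above the remaining root
  sub <- c(v, descendants(tree, v))
  in_rem <- setdiff(seq_len(nn), c(sub, u))
  cand <- in_rem[!is.na(rem_parent[in_rem]) &
                 rem_parent[in_rem] != u &
                 tree$time[in_rem] < t_u &
                 tree$time[rem_parent[in_rem]] > t_u]
  root_branch <- t_u > tree$time[rem_root]
  m <- length(cand) + as.integer(root_branch)
  if (m == 0L) { bump(acc, "spr", FALSE); return(cur) }
  pick <- sample.int(m, 1L)
  prop <- cur$st
  pt <- prop$tree
  # detach
  pt$parent[w] <- g
  if (pick <= length(cand)) {
    b <- cand[pick]
    a <- rem_parent[b]
    pt$parent[b] <- u
    pt$parent[u] <- a
  } else {
    # attach above the remaining root: u becomes root
    pt$parent[rem_root] <- u
    pt$parent[u] <- NA_integer_
  }
  pt$root <- which(is.na(pt$parent))
  pt$tmrca <- pt$time[pt$root]
  prop$tree <- pt
  accept_state(tmpl, cur, prop, "spr", acc, 0, params_changed = FALSE)
}

# Exact Gibbs draw of a single split time from its full conditional.
# For a two-population model with constant N over the feasible range
# (growth 0, or onset below the range), the conditional density of the
# split s given the genealogy is piecewise exponential in s: the slope
# is -(R_split - R_merged)/N from the waiting-time exponent (R the
# pair-coalescence rate sums with counts frozen between events), and
# each within-population coalescence at t_e contributes a -log(w) jump
# when s rises past it (the event's unit share switches from w to 1).
# Sampling the piecewise form by inverse CDF gives acceptance 1 and
# decorrelates the split from the genealogy in one step.
move_split_gibbs_exact <- function(tmpl, cur, acc) {
  st <- cur$st
  tree <- st$tree
  n <- tree$n_tip
  P <- length(tmpl$pops)
  supp <- prior_support(tmpl$priors$split_time)
  params <- st$params
  # constant-N requirement over [supp1, hi]
  if (params$growth > 0 && params$beta > supp[1L]) return(NULL)
  N_const <- if (params$growth == 0) params$N0 else
    params$N0 * exp(-params$growth * params$beta)
  w1 <- st$units$weights[1L]
  w2 <- st$units$weights[2L]
  # classify internal events by population content
  gm <- integer(length(tree$parent))
  gm[seq_len(n)] <- bitwShiftL(1L, match(tree$tip_pop, tmpl$pops) - 1L)
  ord <- order(tree$time)
  for (v in ord) {
    q <- tree$parent[v]
    if (!is.na(q)) gm[q] <- bitwOr(gm[q], gm[v])
  }
  internal <- seq.int(n + 1L, length(tree$parent))
  internal <- internal[order(tree$time[internal])]
  ev_t <- tree$time[internal]
  ev_mask <- gm[internal]
  cross <- ev_mask == 3L
  hi <- min(c(ev_t[cross], supp[2L]))
  lo <- supp[1L]
  if (hi <= lo) return(NULL)
  w_of <- c(w1, w2)
  # breakpoints: within-pop events inside (lo, hi)
  inside <- !cross & ev_t > lo & ev_t < hi
  bp <- c(lo, ev_t[inside], hi)
  jump <- c(0, -log(w_of[ev_mask[inside]]), 0)
  # lineage counts per population at the start of each piece
  nA <- sum(tree$tip_pop == tmpl$pops[1L])
  nB <- n - nA
  k1 <- nA - cumsum(c(0, ev_mask[inside] == 1L))
  k2 <- nB - cumsum(c(0, ev_mask[inside] == 2L))
  # include events at or below lo
  below <- !cross & ev_t <= lo
  k1 <- k1 - sum(ev_mask[below] == 1L)
  k2 <- k2 - sum(ev_mask[below] == 2L)
  n_piece <- length(bp) - 1L
  slope <- numeric(n_piece)
  g0 <- numeric(n_piece)  # log-density value at the left end of piece
  g <- 0
  for (i in seq_len(n_piece)) {
    g <- g + jump[i]
    g0[i] <- g
    K <- k1[i] + k2[i]
    r_split <- k1[i] * (k1[i] - 1) / (2 * w1) +
      k2[i] * (k2[i] - 1) / (2 * w2)
    r_merged <- K * (K - 1) / 2
    slope[i] <- -(r_split - r_merged) / N_const
    g <- g + slope[i] * (bp[i + 1L] - bp[i])
  }
  # log integral of exp(g0 + slope * x) over each piece length
  len <- diff(bp)
  log_int <- vapply(seq_len(n_piece), function(i) {
    a <- slope[i] * len[i]
    lr <- if (abs(a) < 1e-10) a / 2 else if (a > 0)
      a + log1p(-exp(-a)) - log(a) else log1p(-exp(a)) - log(-a)
    g0[i] + log(len[i]) + lr
  }, numeric(1))
  # categorical over pieces via Gumbel trick, then inverse CDF inside
  pick <- which.max(log_int + -log(-log(stats::runif(n_piece))))
  a <- slope[pick]
  u <- stats::runif(1)
  x <- if (abs(a * len[pick]) < 1e-10) u * len[pick] else
    log1p(u * (exp(a * len[pick]) - 1)) / a
  s_new <- bp[pick] + x
  prop <- st
  prop$params$split_times[1L] <- s_new
  prop <- refresh_units(tmpl, prop)
  lp_par <- state_param_prior(tmpl, prop)
  lp_coal <- state_coal_prior(tmpl, prop)
  if (!is.finite(lp_par + lp_coal)) return(NULL)  # numeric guard
  bump(acc, "split_gibbs", TRUE)
  list(st = prop, loglik = cur$loglik, lp_coal = lp_coal, lp_par = lp_par)
}

# Gibbs-style split-time update: given the genealogy, each split time is
# free exactly on an interval (its children's split times up to the
# youngest genealogy node that joins lineages across that split); propose
# uniformly there and Metropolis-correct with the coalescent density.
move_split_gibbs <- function(tmpl, cur, acc) {
  if (tmpl$n_split == 0L || !is.null(tmpl$fixed$split_times)) return(cur)
  if (tmpl$n_split == 1L) {
    ex <- move_split_gibbs_exact(tmpl, cur, acc)
    if (!is.null(ex)) return(ex)
  }
  tree <- cur$st$tree
  n <- tree$n_tip
  P <- length(tmpl$pops)
  # population mask of every genealogy node
  gm <- integer(length(tree$parent))
  gm[seq_len(n)] <- bitwShiftL(1L, match(tree$tip_pop, tmpl$pops) - 1L)
  ord <- order(tree$time)
  for (v in ord) {
    p <- tree$parent[v]
    if (!is.na(p)) gm[p] <- bitwOr(gm[p], gm[v])
  }
  # minimal covering population-tree node per genealogy internal node
  internal <- seq.int(n + 1L, length(tree$parent))
  pt_internal <- seq.int(P + 1L, P + tmpl$n_split)
  sizes <- vapply(tmpl$pt_masks[pt_internal], function(m)
    sum(bitwAnd(m, bitwShiftL(1L, 0:(P - 1L))) != 0L), integer(1))
  pt_by_size <- pt_internal[order(sizes)]
  ceiling_of <- rep(Inf, tmpl$n_split)
  for (v in internal) {
    m <- gm[v]
    if (sum(bitwAnd(m, bitwShiftL(1L, 0:(P - 1L))) != 0L) < 2L) next
    for (x in pt_by_size) {
      if (bitwAnd(tmpl$pt_masks[x], m) == m) {
        i <- x - P
        ceiling_of[i] <- min(ceiling_of[i], tree$time[v])
        break
      }
    }
  }
  supp <- prior_support(tmpl$priors$split_time)
  phy <- tmpl$phy
  for (i in seq_len(tmpl$n_split)) {
    st <- cur$st$params$split_times
    node <- P + i
    kids <- phy$edge[phy$edge[, 1L] == node, 2L]
    lo <- supp[1L]
    for (k in kids) if (k > P) lo <- max(lo, st[k - P])
    hi <- min(ceiling_of[i], supp[2L])
    par_edge <- phy$edge[phy$edge[, 2L] == node, 1L]
    if (length(par_edge)) hi <- min(hi, st[par_edge - P])
    if (!is.finite(hi) || hi <= lo) next
    prop <- cur$st
    prop$params$split_times[i] <- stats::runif(1, lo, hi)
    prop <- refresh_units(tmpl, prop)
    cur <- accept_state(tmpl, cur, prop, "split_gibbs", acc,
                        need_lik = FALSE)
  }
  cur
}

# Translate a split time together with every genealogy node above it.
# The split and the post-merge coalescences form a tight ridge (merging
# earlier means coalescing earlier); sliding the whole block traverses
# it in one step. Rejected unless the moved/unmoved node sets are the
# same in both directions, which also guarantees time-order validity.
move_split_translate <- function(tmpl, cur, acc) {
  if (tmpl$n_split == 0L || !is.null(tmpl$fixed$split_times)) return(cur)
  tree <- cur$st$tree
  i <- if (tmpl$n_split == 1L) 1L else sample.int(tmpl$n_split, 1L)
  s <- cur$st$params$split_times[i]
  # mixture of proposal scales: small steps track the ridge, large ones
  # jump between shallow- and deep-split configurations
  delta <- stats::rnorm(1, 0, sample(c(150, 600, 1500), 1L))
  s2 <- s + delta
  supp <- prior_support(tmpl$priors$split_time)
  if (s2 <= supp[1L] || s2 >= supp[2L]) {
    bump(acc, "split_shift", FALSE)
    return(cur)
  }
  times <- tree$time
  n <- tree$n_tip
  internal <- seq.int(n + 1L, length(times))
  moved <- internal[times[internal] > s]
  if (delta < 0) {
    # an unmoved internal node inside (s2, s] would change the moved set
    # on the reverse move
    unmoved_in_gap <- any(times[internal] <= s & times[internal] > s2)
    if (unmoved_in_gap) {
      bump(acc, "split_shift", FALSE)
      return(cur)
    }
  }
  prop <- cur$st
  prop$params$split_times[i] <- s2
  prop$tree$time[moved] <- times[moved] + delta
  prop$tree$tmrca <- prop$tree$time[prop$tree$root]
  prop <- refresh_units(tmpl, prop)
  accept_state(tmpl, cur, prop, "split_shift", acc)
}

# rescale all internal node times by a common factor (tree-height move)
move_scale <- function(tmpl, cur, acc) {
  tree <- cur$st$tree
  n <- tree$n_tip
  if (length(tree$parent) <= n) return(cur)
  f <- exp(stats::rnorm(1, 0, 0.15))
  internal <- seq.int(n + 1L, length(tree$parent))
  prop <- cur$st
  prop$tree$time[internal] <- tree$time[internal] * f
  prop$tree$tmrca <- prop$tree$time[prop$tree$root]
  accept_state(tmpl, cur, prop, "scale", acc, length(internal) * log(f),
               params_changed = FALSE)
}

# joint rescaling along the model's time/size scaling symmetry:
# t -> f t, N0 -> f N0, beta -> f beta, splits -> f s, growth -> r/f,
# mu -> mu/f leaves likelihood and coalescent density invariant, so the
# chain can traverse the mu*t ridge; fixed parameters are left alone
move_ridge <- function(tmpl, cur, acc) {
  tree <- cur$st$tree
  n <- tree$n_tip
  if (length(tree$parent) <= n) return(cur)
  fx <- tmpl$fixed
  f <- exp(stats::rnorm(1, 0, 0.3))
  internal <- seq.int(n + 1L, length(tree$parent))
  prop <- cur$st
  prop$tree$time[internal] <- tree$time[internal] * f
  prop$tree$tmrca <- prop$tree$time[prop$tree$root]
  jac <- length(internal)
  if (is.null(fx$N0)) { prop$params$N0 <- prop$params$N0 * f; jac <- jac + 1L }
  if (is.null(fx$beta)) { prop$params$beta <- prop$params$beta * f; jac <- jac + 1L }
  if (is.null(fx$growth)) { prop$params$growth <- prop$params$growth / f; jac <- jac - 1L }
  if (is.null(fx$mu)) { prop$params$mu <- prop$params$mu / f; jac <- jac - 1L }
  if (tmpl$n_split > 0L && is.null(fx$split_times)) {
    prop$params$split_times <- prop$params$split_times * f
    jac <- jac + tmpl$n_split
    prop <- refresh_units(tmpl, prop)
  }
  # when mu is rescaled too, every edge theta is unchanged and the
  # likelihood is exactly invariant
  accept_state(tmpl, cur, prop, "ridge", acc, jac * log(f),
               need_lik = !is.null(fx$mu))
}

descendants <- function(tree, v) {
  out <- integer(0)
  frontier <- v
  while (length(frontier)) {
    ch <- which(!is.na(tree$parent) & tree$parent %in% frontier)
    out <- c(out, ch)
    frontier <- ch
  }
  setdiff(out, v)
}

move_params <- function(tmpl, cur, acc, rw_scale) {
  fx <- tmpl$fixed
  pr <- tmpl$priors
  # mu: likelihood + prior
  if (is.null(fx$mu)) {
    prop <- cur$st
    prop$params$mu <- cur$st$params$mu * exp(stats::rnorm(1, 0, rw_scale))
    cur <- accept_state(tmpl, cur, prop, "mu_rw", acc,
                        log(prop$params$mu / cur$st$params$mu))
    if (stats::runif(1) < 0.25) {
      prop <- cur$st
      prop$params$mu <- r_prior(pr$mu)
      # prior proposal: prior term cancels with proposal density
      cur <- accept_prior_proposal(tmpl, cur, prop, "mu_prior", acc,
                                   need_lik = TRUE)
    }
  }
  for (nm in c("N0", "growth")) {
    if (!is.null(fx[[nm]])) next
    prop <- cur$st
    prop$params[[nm]] <- cur$st$params[[nm]] * exp(stats::rnorm(1, 0, rw_scale))
    cur <- accept_state(tmpl, cur, prop, paste0(nm, "_rw"), acc,
                        log(prop$params[[nm]] / cur$st$params[[nm]]),
                        need_lik = FALSE)
    prop <- cur$st
    prop$params[[nm]] <- r_prior(pr[[nm]])
    cur <- accept_prior_proposal(tmpl, cur, prop, paste0(nm, "_prior"), acc,
                                 need_lik = FALSE)
  }
  if (is.null(fx$beta)) {
    supp <- prior_support(pr$beta)
    prop <- cur$st
    prop$params$beta <- reflect(cur$st$params$beta +
                                  stats::rnorm(1, 0, rw_scale * diff(supp) / 5),
                                supp[1L], supp[2L])
    cur <- accept_state(tmpl, cur, prop, "beta_rw", acc, need_lik = FALSE)
    prop <- cur$st
    prop$params$beta <- r_prior(pr$beta)
    cur <- accept_prior_proposal(tmpl, cur, prop, "beta_prior", acc,
                                 need_lik = FALSE)
  }
  if (tmpl$n_split > 0L && is.null(fx$split_times)) {
    supp <- prior_support(pr$split_time)
    for (i in seq_len(tmpl$n_split)) {
      prop <- cur$st
      prop$params$split_times[i] <-
        reflect(cur$st$params$split_times[i] +
                  stats::rnorm(1, 0, rw_scale * diff(supp) / 5),
                supp[1L], supp[2L])
      prop <- refresh_units(tmpl, prop)
      cur <- accept_state(tmpl, cur, prop, "split_rw", acc, need_lik = FALSE)
    }
  }
  if (tmpl$n_split > 0L && is.null(fx$p_split)) {
    for (i in seq_len(tmpl$n_split)) {
      prop <- cur$st
      prop$params$p_split[i] <- reflect(cur$st$params$p_split[i] +
                                          stats::rnorm(1, 0, 0.1), 0, 1)
      prop <- refresh_units(tmpl, prop)
      cur <- accept_state(tmpl, cur, prop, "p_split_rw", acc, need_lik = FALSE)
    }
  }
  cur
}

# independence proposal from the prior: the parameter-prior density
# cancels with the proposal, leaving the coalescent-prior (and, for mu,
# likelihood) ratio
accept_prior_proposal <- function(tmpl, cur, prop_st, move, acc, need_lik) {
  lp_par <- state_param_prior(tmpl, prop_st)
  if (!is.finite(lp_par)) { bump(acc, move, FALSE); return(cur) }
  lp_coal <- state_coal_prior(tmpl, prop_st)
  if (!is.finite(lp_coal)) { bump(acc, move, FALSE); return(cur) }
  loglik <- if (need_lik) state_loglik(tmpl, prop_st) else cur$loglik
  ratio <- (loglik + lp_coal) - (cur$loglik + cur$lp_coal)
  if (is.finite(ratio) && log(stats::runif(1)) < ratio) {
    bump(acc, move, TRUE)
    list(st = prop_st, loglik = loglik, lp_coal = lp_coal, lp_par = lp_par)
  } else {
    bump(acc, move, FALSE)
    cur
  }
}

reflect <- function(x, lo, hi) {
  if (hi <= lo) return(lo)
  width <- hi - lo
  y <- (x - lo) %% (2 * width)
  lo + ifelse(y > width, 2 * width - y, y)
}

state_row <- function(tmpl, cur, it) {
  p <- cur$st$params
  row <- data.frame(iter = it,
                    logpost = cur$loglik + cur$lp_coal + cur$lp_par,
                    loglik = cur$loglik,
                    mu = p$mu, N0 = p$N0, growth = p$growth, beta = p$beta,
                    N_a = p$N0 * exp(-p$growth * p$beta),
                    tmrca = cur$st$tree$tmrca)
  if (tmpl$n_split > 0L) {
    for (i in seq_len(tmpl$n_split)) {
      row[[paste0("split_", tmpl$node_labels[i])]] <- p$split_times[i]
      row[[paste0("p_", tmpl$node_labels[i])]] <- p$p_split[i]
    }
  }
  row
}

# effective sample size by Geyer's initial positive sequence
ess <- function(x) {
  n <- length(x)
  if (n < 10L || stats::sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 2L, 1000L), plot = FALSE)$acf[-1L]
  s <- 0
  k <- 1L
  while (k + 1L <= length(rho)) {
    g <- rho[k] + rho[k + 1L]
    if (g <= 0) break
    s <- s + g
    k <- k + 2L
  }
  max(1, n / (1 + 2 * s))
}

#' TMRCA of the carriers of a unique-event polymorphism
#'
#' Runs the coalescent MCMC on the UEP-carrier subset, collapsed to a
#' single population, and reports the root TMRCA posterior. Carrier
#' monophyly holds by construction of the subset analysis (an
#' approximation to full UEP conditioning on the whole genealogy).
#'
#' @param table A [haplotype_table()].
#' @param uep_carriers Logical or integer row index of carriers, or a
#'   character vector of sample ids.
#' @param ... Passed to [run_mcmc()] (priors, chain settings, seed).
#' @return An `mcmc_fit` (TMRCA row of `summary` is the clade age); for
#'   a single carrier, a degenerate fit with TMRCA 0 and a warning.
#' @export
uep_tmrca <- function(table, uep_carriers, ...) {
  idx <- if (is.character(uep_carriers)) {
    match(uep_carriers, table$sample_id)
  } else if (is.logical(uep_carriers)) which(uep_carriers) else uep_carriers
  if (anyNA(idx) || length(idx) == 0L) stop("carrier set empty or unknown")
  sub <- ht_subset(table, idx)
  sub$population <- rep("carriers", nrow(sub))
  if (nrow(sub) == 1L) {
    warning("single carrier: TMRCA is 0 by definition")
    out <- list(summary = data.frame(quantity = "tmrca", median = 0,
                                     q025 = 0, q975 = 0, ess = NA),
                trace = NULL, acceptance = numeric(0))
    class(out) <- "mcmc_fit"
    return(out)
  }
  run_mcmc(sub, topology = NULL, ...)
}
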