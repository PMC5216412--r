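#' Harmonic mean of effective population sizes
#'
#' Effective sizes combine harmonically over epochs or sources:
#' `n / sum(1/v)`. Full precision is returned; reporting conventionally
#' rounds to 3 significant figures (e.g. 7,000 and 9,500 combine to
#' 8,060).
#'
#' @param values Positive effective sizes.
#' @return Harmonic mean (full precision; apply `signif(x, 3)` to report).
#' @export
harmonic_mean_ne <- function(values) {
  if (length(values) == 0L) stop("empty size list")
  if (any(values <= 0)) stop("sizes must be positive")
  length(values) / sum(1 / values)
}

#' Dating configuration for F_ST-based divergence times
#'
#' @param ne_values Effective sizes to combine (harmonic mean), or a
#'   single combined Ne.
#' @param generation_time Years per generation (default 28.96, must lie in
#'   `[20, 35]`).
#' @return A list with `ne` (combined) and `generation_time`.
#' @export
dating_config <- function(ne_values = c(7000, 9500), generation_time = 28.96) {
  if (generation_time < 20 || generation_time > 35) {
    stop("generation time must lie in [20, 35] years")
  }
  list(ne = harmonic_mean_ne(ne_values), ne_values = ne_values,
       generation_time = generation_time)
}

#' Convert an F_ST value to a divergence time
#'
#' Under pure drift, differentiation accumulates as
#' `F_ST = 1 - exp(-t / (2 Ne))`, so `t = -2 Ne log(1 - F_ST)`
#' generations; years follow from the generation time. The linear
#' small-F_ST approximation `t = 2 Ne F_ST` is also returned for
#' comparison (it understates the time at appreciable F_ST).
#'
#' @param fst F_ST in `[0, 1)`; negative values are clamped to 0 with a
#'   warning.
#' @param config A [dating_config()].
#' @return A list with `generations`, `years`, `ka`, and the linear
#'   approximation `generations_linear`.
#' @export
fst_to_time <- function(fst, config = dating_config()) {
  if (any(fst >= 1)) stop("fst must be < 1")
  if (any(fst < 0)) {
    warning("negative fst clamped to 0")
    fst <- pmax(fst, 0)
  }
  gens <- -2 * config$ne * log(1 - fst)
  list(generations = gens,
       years = gens * config$generation_time,
       ka = gens * config$generation_time / 1000,
       generations_linear = 2 * config$ne * fst)
}

#' Double-conformation pooled split-time runs
#'
#' A balanced four-group split `((A,B),(C,D))` induces a spurious
#' interaction between the `(A,B)` and `(C,D)` split times when both are
#' estimated in one run. The double-conformation device runs the sampler
#' twice, pooling one sister pair at a time -- designs `(AB,(C,D))` and
#' `((A,B),CD)` -- so each root split is estimated without the
#' interaction, and the two root-split posteriors provide a consistency
#' check: overlapping 95% intervals and a median ratio within
#' `[1/1.75, 1.75]`.
#'
#' @param table A [haplotype_table()].
#' @param plan Named list of four character vectors `A`, `B`, `C`, `D`
#'   giving the population membership of each group.
#' @param priors A [prior_spec()].
#' @param seed Integer seed (the two runs use `seed` and `seed + 1`).
#' @param ... Chain settings passed to [run_mcmc()].
#' @return A list of class `double_conformation`: `fit_ab_cd` (design
#'   `(AB,(C,D))`), `fit_a_b_cd` (design `((A,B),CD)`), `root_ab_cd` and
#'   `root_a_b_cd` (root-split summary rows), and `consistency`.
#' @export
run_double_conformation <- function(table, plan, priors = prior_spec(),
                                    seed = 1L, ...) {
  for (g in c("A", "B", "C", "D")) {
    if (is.null(plan[[g]]) || !length(plan[[g]])) {
      stop("plan must name non-empty groups A, B, C, D")
    }
    missing <- setdiff(plan[[g]], table$population)
    if (length(missing)) {
      stop("group ", g, " population absent from table: ",
           paste(missing, collapse = ", "))
    }
  }
  all_pops <- unlist(plan)
  if (anyDuplicated(all_pops)) stop("plan groups must be disjoint")

  pool_to <- function(groups) {
    sub <- ht_subset(table, table$population %in% all_pops)
    pop <- sub$population
    for (g in names(groups)) pop[pop %in% groups[[g]]] <- g
    sub$population <- pop
    sub
  }
  # design 1: (AB,(C,D)) -- root split is AB vs CD, with C/D resolved
  t1 <- pool_to(list(AB = c(plan$A, plan$B), C = plan$C, D = plan$D))
  fit1 <- run_mcmc(t1, priors = priors,
                   topology = "(AB,(C,D)inner)root;", seed = seed, ...)
  # design 2: ((A,B),CD)
  t2 <- pool_to(list(A = plan$A, B = plan$B, CD = c(plan$C, plan$D)))
  fit2 <- run_mcmc(t2, priors = priors,
                   topology = "((A,B)inner,CD)root;", seed = seed + 1L, ...)
  root1 <- fit1$summary[fit1$summary$quantity == "split_root", ]
  root2 <- fit2$summary[fit2$summary$quantity == "split_root", ]
  overlap <- root1$q025 <= root2$q975 && root2$q025 <= root1$q975
  ratio <- root1$median / root2$median
  structure(list(fit_ab_cd = fit1, fit_a_b_cd = fit2,
                 root_ab_cd = root1, root_a_b_cd = root2,
                 consistency = list(overlap = overlap,
                                    median_ratio = ratio,
                                    consistent = overlap &&
                                      ratio >= 1 / 1.75 && ratio <= 1.75)),
            class = "double_conformation")
}

#' Assemble a dated population split tree from run reports
#'
#' Combines per-node posterior reports into a single dated topology (the
#' figure-style chronology): each internal node of the skeleton must be
#' matched by exactly one report; ages are converted to thousands of
#' years (ka) via the generation time. Child-older-than-parent
#' inversions are flagged, never silently fixed.
#'
#' @param reports Named list: for each internal node label, a list/row
#'   with `median`, `q025`, `q975` in generations.
#' @param topology Newick skeleton over population labels with internal
#'   node labels naming the reports.
#' @param config A [dating_config()].
#' @return A list of class `split_tree`: `nodes` (data frame with ages in
#'   ka), `newick` (ages and intervals as bracketed node comments), and
#'   `inversions`.
#' @export
assemble_split_tree <- function(reports, topology, config = dating_config()) {
  phy <- ape::read.tree(text = topology)
  n_tip <- length(phy$tip.label)
  labels <- phy$node.label
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("topology must label every internal node")
  }
  missing <- setdiff(labels, names(reports))
  if (length(missing)) {
    stop("no report for internal node: ", paste(missing, collapse = ", "))
  }
  g <- config$generation_time / 1000
  nodes <- do.call(rbind, lapply(labels, function(l) {
    r <- reports[[l]]
    data.frame(node = l, age_ka = r$median * g,
               q025_ka = r$q025 * g, q975_ka = r$q975 * g)
  }))
  # parent/child ordering check
  inversions <- character(0)
  for (e in seq_len(nrow(phy$edge))) {
    chi <- phy$edge[e, 2L]
    if (chi > n_tip) {
      par_l <- labels[phy$edge[e, 1L] - n_tip]
      chi_l <- labels[chi - n_tip]
      if (nodes$age_ka[nodes$node == chi_l] >
          nodes$age_ka[nodes$node == par_l] + 1e-12) {
        inversions <- c(inversions, paste0(chi_l, ">", par_l))
      }
    }
  }
  ann <- vapply(labels, function(l) {
    r <- nodes[nodes$node == l, ]
    sprintf("%s[&age=%.4g,interval={%.4g,%.4g}]",
            l, r$age_ka, r$q025_ka, r$q975_ka)
  }, character(1))
  phy$node.label <- unname(ann)
  newick <- ape::write.tree(phy)
  structure(list(nodes = nodes, newick = newick, inversions = inversions,
                 config = config),
            class = "split_tree")
}
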