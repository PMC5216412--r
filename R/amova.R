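#' Hierarchical AMOVA with Phi statistics on STR haplotypes
#'
#' Excoffier-style analysis of molecular variance on squared repeat-count
#' differences, partitioning variance among regions (sigma_a), among
#' populations within regions (sigma_b), and within populations (sigma_c),
#' with the fixation indices `Phi_CT = sigma_a / total`,
#' `Phi_SC = sigma_b / (sigma_b + sigma_c)` and
#' `Phi_ST = (sigma_a + sigma_b) / total`. Significance of `Phi_CT` is
#' assessed by permuting whole populations among regions (region sizes in
#' populations preserved); the p-value uses the `(count >= observed + 1) /
#' (n_perm + 1)` convention.
#'
#' @param table A [haplotype_table()].
#' @param pooling A [population_pooling()] mapping populations to regions.
#' @param n_perm Number of permutations, or `"exhaustive"` to enumerate
#'   every distinct assignment of populations to regions.
#' @param seed RNG seed for the permutations.
#' @param distance `"repeat"` (squared repeat-count differences, default)
#'   or `"haplotype"` (0/1 haplotype identity).
#' @return An object of class `amova_result`: variance components, Phi
#'   statistics, permutation p-value and count.
#' @export
amova <- function(table, pooling, n_perm = 999L, seed = 1L,
                  distance = c("repeat", "haplotype")) {
  distance <- match.arg(distance)
  pop <- as.character(table$population)
  pops <- unique(pop)
  reg_of_pop <- region_of(pooling, pops)
  regions <- unique(reg_of_pop)
  if (length(regions) < 2L) stop("need at least two regions")
  if (all(tabulate(factor(reg_of_pop, levels = regions)) == 1L)) {
    stop("every region holds a single population; ",
         "permutation of populations among regions is undefined")
  }
  d2 <- squared_distance_matrix(table, distance)
  obs <- amova_components(d2, pop, pops, reg_of_pop)

  reg_sizes <- table(factor(reg_of_pop, levels = regions))
  phi_perm <- if (identical(n_perm, "exhaustive")) {
    assignments <- enumerate_assignments(length(pops), as.integer(reg_sizes))
    vapply(assignments, function(a) {
      amova_components(d2, pop, pops, regions[a])$phi_ct
    }, numeric(1))
  } else {
    set.seed(as.integer(seed))
    vapply(seq_len(n_perm), function(i) {
      amova_components(d2, pop, pops, sample(reg_of_pop))$phi_ct
    }, numeric(1))
  }
  n_eff <- length(phi_perm)
  p <- (sum(phi_perm >= obs$phi_ct - 1e-12) + 1) / (n_eff + 1)
  structure(c(obs, list(p_phi_ct = p, n_perm = n_eff,
                        perm_phi_ct = phi_perm)),
            class = "amova_result")
}

# squared pairwise distances between haplotypes
squared_distance_matrix <- function(table, distance = "repeat") {
  reps <- loci_matrix(table)
  n <- nrow(reps)
  if (distance == "repeat") {
    d2 <- matrix(0, n, n)
    for (l in seq_len(ncol(reps))) {
      x <- reps[, l]
      dif <- outer(x, x, "-")^2
      dif[is.na(dif)] <- 0  # pairwise-complete per locus
      d2 <- d2 + dif
    }
    d2
  } else {
    key <- apply(reps, 1L, paste, collapse = ",")
    1 - outer(key, key, "==") * 1
  }
}

# variance components for a given assignment of populations to regions
amova_components <- function(d2, pop, pops, reg_of_pop) {
  region <- reg_of_pop[match(pop, pops)]
  N <- length(pop)
  ssd_pair <- function(idx) {
    if (length(idx) < 2L) return(0)
    sum(d2[idx, idx]) / 2 / length(idx)
  }
  ssd_total <- ssd_pair(seq_len(N))
  pop_idx <- split(seq_len(N), pop)
  reg_idx <- split(seq_len(N), region)
  ssd_wp <- sum(vapply(pop_idx, ssd_pair, numeric(1)))
  ssd_wr <- sum(vapply(reg_idx, ssd_pair, numeric(1)))
  ssd_ap <- ssd_wr - ssd_wp         # among populations within regions
  ssd_ag <- ssd_total - ssd_wr      # among regions

  G <- length(reg_idx)
  P <- length(pop_idx)
  df_ag <- G - 1L
  df_ap <- P - G
  df_wp <- N - P
  n_p <- lengths(pop_idx)
  n_g <- lengths(reg_idx)
  pop_region <- vapply(names(pop_idx), function(p)
    region[pop == p][1L], character(1))
  sum_np2_over_ng <- sum(vapply(names(reg_idx), function(g) {
    sum(n_p[pop_region == g]^2) / length(reg_idx[[g]])
  }, numeric(1)))
  n1 <- (N - sum_np2_over_ng) / df_ap
  n2 <- (sum_np2_over_ng - sum(n_p^2) / N) / df_ag
  n3 <- (N - sum(n_g^2) / N) / df_ag

  ms_wp <- if (df_wp > 0) ssd_wp / df_wp else 0
  ms_ap <- if (df_ap > 0) ssd_ap / df_ap else 0
  ms_ag <- if (df_ag > 0) ssd_ag / df_ag else 0
  sigma_c <- ms_wp
  sigma_b <- if (df_ap > 0) (ms_ap - sigma_c) / n1 else 0
  sigma_a <- (ms_ag - sigma_c - n2 * sigma_b) / n3
  total <- sigma_a + sigma_b + sigma_c
  phi_ct <- if (total == 0) 0 else sigma_a / total
  phi_sc <- if (sigma_b + sigma_c == 0) 0 else sigma_b / (sigma_b + sigma_c)
  phi_st <- if (total == 0) 0 else (sigma_a + sigma_b) / total
  list(sigma_a = sigma_a, sigma_b = sigma_b, sigma_c = sigma_c,
       total = total, phi_ct = phi_ct, phi_sc = phi_sc, phi_st = phi_st,
       ssd = c(among_regions = ssd_ag, among_pops = ssd_ap,
               within_pops = ssd_wp, total = ssd_total),
       df = c(df_ag, df_ap, df_wp))
}

# all distinct assignments of P populations into region slots of given
# sizes (multiset permutations, regions distinguishable)
enumerate_assignments <- function(P, sizes) {
  labels <- rep(seq_along(sizes), sizes)
  perms <- unique_perms(labels)
  lapply(seq_len(nrow(perms)), function(i) perms[i, ])
}

unique_perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L))
  out <- NULL
  for (u in unique(v)) {
    rest <- v[-match(u, v)]
    sub <- unique_perms(rest)
    out <- rbind(out, cbind(u, sub))
  }
  unname(out)
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (squared repeat differences)\n")
  cat(sprintf("  sigma_a (among regions)           %10.4f\n", x$sigma_a))
  cat(sprintf("  sigma_b (among pops within)       %10.4f\n", x$sigma_b))
  cat(sprintf("  sigma_c (within pops)             %10.4f\n", x$sigma_c))
  cat(sprintf("  Phi_CT %.4f  Phi_SC %.4f  Phi_ST %.4f\n",
              x$phi_ct, x$phi_sc, x$phi_st))
  cat(sprintf("  p(Phi_CT) = %.4g  (%d permutations)\n", x$p_phi_ct, x$n_perm))
  invisible(x)
}
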