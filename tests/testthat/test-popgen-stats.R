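test_that("pairwise R_ST matches hand-worked and brute-force values", {
  # monomorphic identical groups: 0/0 convention -> 0
  t0 <- make_table(matrix(10L, 4, 1), c("a", "a", "b", "b"))
  expect_equal(unname(pairwise_rst(t0)["a", "b"]), 0)
  # fixed difference, S_w = 0 -> R_ST = 1
  t1 <- make_table(matrix(c(10L, 10L, 12L, 12L), 4, 1), c("a", "a", "b", "b"))
  expect_equal(unname(pairwise_rst(t1)["a", "b"]), 1)
  # pop1 = {10, 12}, pop2 = {11, 13}: raw -0.2, clamped 0
  t2 <- make_table(matrix(c(10L, 12L, 11L, 13L), 4, 1), c("a", "a", "b", "b"))
  D <- pairwise_rst(t2)
  expect_equal(unname(attr(D, "raw")["a", "b"]), -0.2)
  expect_equal(unname(D["a", "b"]), 0)
  expect_error(pairwise_rst(make_table(matrix(10L, 2, 1), c("a", "a"))),
               "two groups")
  # random fixtures vs the naive O(n^2 L) oracle
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(4:20, 1)
    L <- sample(1:4, 1)
    reps <- matrix(sample(10:16, n * L, replace = TRUE), n, L)
    if (rep %% 2 == 0) reps[sample(length(reps), 2)] <- NA
    pop <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(pop)) < 2) pop[1:2] <- c("a", "b")
    tab <- make_table(reps, pop)
    got <- attr(pairwise_rst(tab), "raw")["a", "b"]
    want <- rst_brute(reps[pop == "a", , drop = FALSE],
                      reps[pop == "b", , drop = FALSE])
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("Hudson F_ST per-site values follow the stated formula", {
  # p1 = 0.2, p2 = 0.8, n1 = n2 = 50 alleles -> 0.5198
  g <- rbind(site1 = c(rep(2L, 5), rep(0L, 20), rep(2L, 20), rep(0L, 5)))
  gm <- genotype_matrix(g, c(rep("A", 25), rep("B", 25)))
  f <- hudson_fst(gm, "A", "B")
  p1 <- 0.2; p2 <- 0.8
  want <- ((p1 - p2)^2 - p1 * (1 - p1) / 49 - p2 * (1 - p2) / 49) /
    (p1 * (1 - p2) + p2 * (1 - p1))
  expect_equal(f$per_site$fst, want)
  expect_equal(round(want, 4), 0.5198)
  # fixed difference -> 1
  g2 <- rbind(s = c(rep(0L, 10), rep(2L, 10)))
  f2 <- hudson_fst(genotype_matrix(g2, rep(c("A", "B"), each = 10)), "A", "B")
  expect_equal(f2$per_site$fst, 1)
  # equal frequencies -> ~0, monomorphic sites excluded with a count
  g3 <- rbind(a = rep(1L, 20), b = rep(0L, 20))
  f3 <- hudson_fst(genotype_matrix(g3, rep(c("A", "B"), each = 10)), "A", "B")
  expect_equal(f3$n_excluded, 1L)
  expect_lt(abs(f3$estimate), 0.1)
})

test_that("individual-pair F_ST treats each sample as a two-allele pool", {
  g <- cbind(i1 = c(0L, 2L, 2L), i2 = c(0L, 2L, 2L), i3 = c(2L, 0L, 0L))
  gm <- genotype_matrix(g, c("p", "p", "q"))
  D <- pairwise_individual_fst(gm, min_sites = 1)
  expect_equal(unname(D["i1", "i2"]), 0)
  expect_equal(unname(D["i1", "i3"]), 1)
  # 3-site hand-worked heterozygous pair
  g2 <- cbind(a = c(1L, 2L, 0L), b = c(0L, 1L, 1L))
  gm2 <- genotype_matrix(g2, c("p", "q"))
  per_site <- function(p1, p2) {
    c((p1 - p2)^2 - p1 * (1 - p1) - p2 * (1 - p2),
      p1 * (1 - p2) + p2 * (1 - p1))
  }
  parts <- rbind(per_site(.5, 0), per_site(1, .5), per_site(0, .5))
  expect_equal(unname(attr(pairwise_individual_fst(gm2, 1), "raw")["a", "b"]),
               sum(parts[, 1]) / sum(parts[, 2]))
  # short pairs flagged unreliable
  expect_true(attr(pairwise_individual_fst(gm2, min_sites = 50),
                   "unreliable")["a", "b"])
})

test_that("AMOVA partitions variance exactly and permutes populations", {
  pool4 <- population_pooling(c("p1", "p2", "p3", "p4"),
                              c("R1", "R1", "R2", "R2"))
  # all haplotypes identical: all components zero, Phi_CT reported 0
  t0 <- make_table(matrix(12L, 8, 2), rep(c("p1", "p2", "p3", "p4"), each = 2))
  a0 <- amova(t0, pool4, n_perm = 9, seed = 1)
  expect_equal(a0$sigma_a, 0)
  expect_equal(a0$sigma_b, 0)
  expect_equal(a0$sigma_c, 0)
  expect_equal(a0$phi_ct, 0)
  # degenerate design: every region one population
  pool2 <- population_pooling(c("p1", "p2"), c("R1", "R2"))
  t2 <- make_table(matrix(sample(10:14, 12, TRUE), 6, 2),
                   rep(c("p1", "p2"), each = 3))
  expect_error(amova(t2, pool2, 99), "single population")
  # two distinguishable region clusters, exhaustive permutation oracle
  set.seed(7)
  reps <- rbind(matrix(sample(10:11, 8, TRUE), 4, 2),
                matrix(sample(14:15, 8, TRUE), 4, 2))
  t4 <- make_table(reps, rep(c("p1", "p2", "p3", "p4"), each = 2))
  a4 <- amova(t4, pool4, n_perm = "exhaustive")
  # 4 populations in two regions of 2: 6 ordered assignments
  expect_equal(a4$n_perm, 6L)
  # p equals the exact rank fraction of the observed Phi_CT
  expect_equal(a4$p_phi_ct,
               (sum(a4$perm_phi_ct >= a4$phi_ct - 1e-12) + 1) / 7)
  expect_gt(a4$phi_ct, 0.5)
  # sums-of-squares additivity on random fixtures
  for (i in 1:5) {
    n <- 16
    tab <- make_table(matrix(sample(9:16, 2 * n, TRUE), n, 2),
                      sample(c("p1", "p2", "p3", "p4"), n, TRUE))
    if (length(unique(tab$population)) < 4) next
    a <- amova(tab, pool4, n_perm = 19, seed = i)
    expect_equal(unname(a$ssd["among_regions"] + a$ssd["among_pops"] +
                          a$ssd["within_pops"]),
                 unname(a$ssd["total"]), tolerance = 1e-9)
    expect_equal(a$sigma_a + a$sigma_b + a$sigma_c, a$total)
  }
})

test_that("classical MDS reconstructs Euclidean configurations", {
  # 3 collinear points, distances 1, 1, 2: exact 1-D embedding
  m <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  ord <- classical_mds(dist_matrix(m), k = 1)
  d <- as.matrix(stats::dist(ord$coordinates))
  expect_equal(unname(d[1, 2]), 1, tolerance = 1e-9)
  expect_equal(unname(d[1, 3]), 2, tolerance = 1e-9)
  # distances from planar points are reproduced to 1e-9
  set.seed(3)
  pts <- matrix(rnorm(8), 4, 2)
  D <- as.matrix(stats::dist(pts))
  dimnames(D) <- list(paste0("x", 1:4), paste0("x", 1:4))
  emb <- classical_mds(dist_matrix(D), k = 2)
  expect_lt(max(abs(as.matrix(stats::dist(emb$coordinates)) - D)), 1e-9)
  expect_error(classical_mds(dist_matrix(D), k = 4), "smaller")
  # higher-dimensional cloud: embedding distances match to 1e-9 at full k
  pts5 <- matrix(rnorm(30), 6, 5)
  D5 <- as.matrix(stats::dist(pts5))
  dimnames(D5) <- list(paste0("p", 1:6), paste0("p", 1:6))
  e5 <- classical_mds(dist_matrix(D5), k = 5)
  expect_lt(max(abs(as.matrix(stats::dist(e5$coordinates)) - D5)), 1e-9)
})

test_that("Mantel correlation and exact permutation p behave correctly", {
  set.seed(5)
  pts <- matrix(rnorm(10), 5, 2)
  D1 <- as.matrix(stats::dist(pts))
  expect_equal(mantel(D1, D1, n_perm = 99)$r, 1)
  # location/scale shifts leave r = 1
  expect_equal(mantel(D1, 2 * D1 + 0 * D1, n_perm = 9)$r, 1)
  # exhaustive mode equals a hand enumeration over all 4! label orders
  D2 <- as.matrix(stats::dist(matrix(rnorm(8), 4, 2)))
  D1b <- as.matrix(stats::dist(matrix(rnorm(8), 4, 2)))
  got <- mantel(D1b, D2, n_perm = "exhaustive")
  ut <- function(m) m[upper.tri(m)]
  perms <- refugium:::all_perms(4)
  rs <- vapply(perms, function(p) stats::cor(ut(D1b), ut(D2[p, p])),
               numeric(1))
  expect_equal(got$p, mean(rs >= got$r - 1e-12))
  # independent cross-check of the statistic against vegan
  vg <- vegan::mantel(stats::as.dist(D1b), stats::as.dist(D2),
                      permutations = 0)
  expect_equal(got$r, unname(vg$statistic), tolerance = 1e-12)
  expect_error(mantel(D1, matrix(1, 5, 5), 9), "zero variance")
  expect_error(mantel(D1[1:3, 1:3], D1[1:3, 1:3], 9), "at least 4")
})

test_that("Fisher geographic test equals hypergeometric enumeration", {
  expect_equal(fisher_geo_test(4, 0, 0, 7), 1 / 330, tolerance = 1e-12)
  expect_equal(fisher_geo_test(1, 0, 0, 1), 1)
  expect_equal(fisher_geo_test(3, 1, 1, 4), fisher_brute(3, 1, 1, 4),
               tolerance = 1e-9)
  # all margins <= 12: agreement with exhaustive table enumeration
  set.seed(9)
  for (i in 1:10) {
    cell <- sample(0:6, 4, replace = TRUE)
    if (sum(cell) == 0) cell[1] <- 1
    expect_equal(fisher_geo_test(cell[1], cell[2], cell[3], cell[4]),
                 fisher_brute(cell[1], cell[2], cell[3], cell[4]),
                 tolerance = 1e-9)
  }
  expect_error(fisher_geo_test(0, 0, 0, 0), "all-zero")
})

test_that("neighbor joining recovers additive trees exactly", {
  # n = 2: a single edge carrying the full distance
  m <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- neighbor_joining(dist_matrix(m))
  expect_equal(sum(t2$edge.length), 3)
  # n = 3: closed-form three-point branch lengths
  m3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m3["a", "b"] <- m3["b", "a"] <- 5
  m3["a", "c"] <- m3["c", "a"] <- 7
  m3["b", "c"] <- m3["c", "b"] <- 8
  t3 <- neighbor_joining(dist_matrix(m3))
  cd <- ape::cophenetic.phylo(t3)
  expect_equal(unname(cd["a", "b"]), 5, tolerance = 1e-9)
  expect_equal(unname(cd["a", "c"]), 7, tolerance = 1e-9)
  expect_equal(unname(cd["b", "c"]), 8, tolerance = 1e-9)
  # additive 4-taxon metric: topology and branch lengths recovered
  true <- ape::read.tree(text = "((A:2,B:3):1,(C:4,D:5):2);")
  D4 <- ape::cophenetic.phylo(true)
  D4 <- D4[c("A", "B", "C", "D"), c("A", "B", "C", "D")]
  t4 <- neighbor_joining(dist_matrix(D4))
  expect_equal(ape::cophenetic.phylo(t4)[rownames(D4), colnames(D4)], D4,
               tolerance = 1e-9)
  expect_true(all(t4$edge.length >= 0))
  m[1, 2] <- m[2, 1] <- NA
  expect_error(neighbor_joining(m), "NaN")
})

test_that("Ward clustering follows the Lance-Williams recurrence", {
  # two tight clusters separate at the top split
  pts <- rbind(matrix(rnorm(10, 0, .05), 5, 2),
               matrix(rnorm(10, 8, .05), 5, 2))
  D <- as.matrix(stats::dist(pts))
  dimnames(D) <- list(paste0("x", 1:10), paste0("x", 1:10))
  hc <- ward_cluster(dist_matrix(D))
  top <- stats::cutree(hc, 2)
  expect_equal(length(unique(top[1:5])), 1L)
  expect_equal(length(unique(top[6:10])), 1L)
  expect_true(all(diff(hc$height) > -1e-9))
  # duplicated point merges at height 0
  dd <- as.matrix(stats::dist(rbind(pts[1, ], pts[1, ], pts[7, ])))
  dimnames(dd) <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_lt(min(ward_cluster(dist_matrix(dd))$height), 1e-6)
  # 5-point fixture: merge heights equal a hand-rolled Ward (ward.D2) run
  set.seed(8)
  p5 <- matrix(rnorm(10), 5, 2)
  D5 <- as.matrix(stats::dist(p5))
  dimnames(D5) <- list(paste0("p", 1:5), paste0("p", 1:5))
  hc5 <- ward_cluster(dist_matrix(D5), k_mds = 4)
  lw <- function(d) {
    # Lance-Williams update for Ward (on squared distances)
    d2 <- d^2
    n <- nrow(d2)
    sizes <- rep(1, n)
    active <- seq_len(n)
    heights <- numeric(0)
    while (length(active) > 1) {
      sub <- d2[active, active]
      diag(sub) <- Inf
      ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      i <- active[ij[1]]; j <- active[ij[2]]
      heights <- c(heights, sqrt(d2[i, j]))
      ni <- sizes[i]; nj <- sizes[j]
      for (k in setdiff(active, c(i, j))) {
        nk <- sizes[k]
        d2[i, k] <- d2[k, i] <-
          ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
          (ni + nj + nk)
      }
      sizes[i] <- ni + nj
      active <- setdiff(active, j)
    }
    heights
  }
  expect_equal(hc5$height, lw(D5), tolerance = 1e-9)
})

test_that("per-group STR variance handles singletons and missing data", {
  tab <- make_table(matrix(c(10L, 12L, 10L, 10L, 11L, NA), 3, 2),
                    c("g1", "g1", "g2"))
  v <- str_variance(tab)
  expect_equal(v$mean_variance[v$group == "g1"], mean(c(2, 0.5)))
  expect_true(v$undefined[v$group == "g2"])
  # monomorphic group has zero variance
  t0 <- make_table(matrix(13L, 4, 3), rep("g", 4))
  expect_equal(str_variance(t0)$mean_variance, 0)
})

test_that("haplogroup frequency PCA matches a direct eigen oracle", {
  tr <- haplogroup_tree(c("Y", "J", "E", "J1", "J2"),
                        c(NA, "Y", "Y", "J", "J"))
  hg <- c("J1", "J1", "J2", "E", "J2", "E", "J1", "J2", "E")
  pop <- c("a", "a", "a", "b", "b", "b", "c", "c", "c")
  tab <- make_table(matrix(12L, 9, 1), pop, haplogroup = hg)
  ord <- haplogroup_frequency_pca(tab, tr, depth = 1, k = 2)
  freq <- attr(ord, "frequencies")
  expect_equal(unname(rowSums(freq)), rep(1, 3))
  ctr <- scale(freq, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(freq), symmetric = TRUE)
  want <- ctr %*% ev$vectors[, 1:2]
  # scores agree up to per-axis sign
  for (k in 1:2) {
    expect_true(max(abs(ord$coordinates[, k] - want[, k])) < 1e-9 ||
                  max(abs(ord$coordinates[, k] + want[, k])) < 1e-9)
  }
  # identical frequency rows: all coordinates 0
  tab2 <- make_table(matrix(12L, 4, 1), c("a", "a", "b", "b"),
                     haplogroup = c("J1", "J2", "J1", "J2"))
  ord2 <- haplogroup_frequency_pca(tab2, tr, depth = 2, k = 1)
  expect_lt(max(abs(ord2$coordinates)), 1e-12)
})
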