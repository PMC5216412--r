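#' Construct a biallelic genotype matrix
#'
#' @param geno Integer matrix, sites x samples, alternate-allele dosages in
#'   {0, 1, 2} with `NA` for missing; rownames are site ids.
#' @param population Character vector of population labels, one per sample.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, population) {
  geno <- as.matrix(geno)
  if (length(population) != ncol(geno)) {
    stop("one population label per sample required")
  }
  ok <- is.na(geno) | geno %in% c(0L, 1L, 2L)
  if (!all(ok)) stop("genotypes must be dosages 0/1/2 or NA")
  if (is.null(rownames(geno))) rownames(geno) <- paste0("site", seq_len(nrow(geno)))
  if (anyDuplicated(rownames(geno))) stop("site ids must be unique")
  if (is.null(colnames(geno))) colnames(geno) <- paste0("ind", seq_len(ncol(geno)))
  structure(geno, population = as.character(population),
            class = c("genotype_matrix", class(matrix())))
}

#' Simulate divergent SNP genotypes by pure drift
#'
#' Two populations split `t_split` generations ago from a common ancestor;
#' ancestral allele frequencies are uniform on `p_range`, and each
#' population then drifts by Wright-Fisher binomial resampling of `2N`
#' allele copies per generation (no mutation, migration or selection).
#' Diploid genotypes are drawn from the final frequencies under
#' Hardy-Weinberg.
#'
#' @param n_sites Number of independent biallelic sites.
#' @param n_per_pop Sample sizes (diploid individuals), length 1 or 2.
#' @param N Diploid effective population size during drift.
#' @param t_split Split time in generations (integer >= 0).
#' @param seed Integer RNG seed.
#' @param p_range Range of the ancestral allele-frequency distribution.
#' @return A [genotype_matrix()] with populations `"pop1"` and `"pop2"`.
#' @export
simulate_divergent_genotypes <- function(n_sites, n_per_pop, N, t_split,
                                         seed = 1L,
                                         p_range = c(0.05, 0.95)) {
  if (t_split < 0) stop("t_split must be non-negative")
  t_split <- as.integer(round(t_split))
  n_per_pop <- rep_len(as.integer(n_per_pop), 2L)
  set.seed(as.integer(seed))
  p0 <- stats::runif(n_sites, p_range[1L], p_range[2L])
  drift <- function(p) {
    for (g in seq_len(t_split)) {
      p <- stats::rbinom(n_sites, 2L * N, p) / (2 * N)
    }
    p
  }
  p1 <- drift(p0)
  p2 <- drift(p0)
  g1 <- matrix(stats::rbinom(n_sites * n_per_pop[1L], 2L, rep(p1, n_per_pop[1L])),
               nrow = n_sites)
  g2 <- matrix(stats::rbinom(n_sites * n_per_pop[2L], 2L, rep(p2, n_per_pop[2L])),
               nrow = n_sites)
  geno <- cbind(g1, g2)
  rownames(geno) <- paste0("site", seq_len(n_sites))
  colnames(geno) <- c(paste0("pop1_", seq_len(n_per_pop[1L])),
                      paste0("pop2_", seq_len(n_per_pop[2L])))
  genotype_matrix(geno, c(rep("pop1", n_per_pop[1L]),
                          rep("pop2", n_per_pop[2L])))
}

#' Read / write a SNP genotype table
#'
#' Tab-delimited text: a `site_id` column then one column per sample;
#' a `#population` comment line above the header carries population labels.
#'
#' @param path File path.
#' @return A [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path) {
  lines <- readLines(path, n = 1L, encoding = "UTF-8")
  if (!startsWith(lines[1L], "#population\t")) {
    stop("genotype file must start with a '#population' line")
  }
  pops <- strsplit(sub("^#population\t", "", lines[1L]), "\t")[[1L]]
  raw <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  geno <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(geno) <- "integer"
  rownames(geno) <- raw[[1L]]
  genotype_matrix(geno, pops)
}

#' @rdname read_genotype_matrix
#' @param x A `genotype_matrix`.
#' @export
write_genotype_matrix <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("#population", attr(x, "population")), collapse = "\t"),
             con)
  df <- data.frame(site_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
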