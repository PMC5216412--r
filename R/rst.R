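#' Pairwise R_ST distances between groups of STR haplotypes
#'
#' Slatkin-style R_ST from squared repeat-count differences. For a pair of
#' groups and one locus, `S_w` is the mean within-group pairwise squared
#' difference (the two groups weighted equally by default) and `S_bar` the
#' mean squared difference over all pooled pairs; `R_ST = (S_bar - S_w) /
#' S_bar`. Loci are combined by summing numerators and denominators.
#' `0/0` is defined as 0. Matrix entries are clamped at 0 for use as
#' dissimilarities; raw signed estimates are kept in the `raw` attribute.
#'
#' @param table A [haplotype_table()].
#' @param grouping `"population"` or `"region"`, or a vector of group
#'   labels (one per row).
#' @param weight_groups_equally If `FALSE`, `S_w` weights groups by their
#'   pair counts instead of equally.
#' @return A [dist_matrix()] over group labels, with attribute `raw`.
#' @export
pairwise_rst <- function(table, grouping = "population",
                         weight_groups_equally = TRUE) {
  groups <- resolve_grouping(table, grouping)
  labs <- unique(groups)
  if (length(labs) < 2L) stop("need at least two groups")
  reps <- loci_matrix(table)
  all_missing <- colSums(!is.na(reps)) == 0L
  if (any(all_missing)) {
    warning("dropping all-missing loci: ",
            paste(colnames(reps)[all_missing], collapse = ", "))
    reps <- reps[, !all_missing, drop = FALSE]
  }
  n <- length(labs)
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  raw <- m
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      r <- rst_pair(reps[groups == labs[i], , drop = FALSE],
                    reps[groups == labs[j], , drop = FALSE],
                    weight_groups_equally)
      raw[i, j] <- raw[j, i] <- r
      m[i, j] <- m[j, i] <- max(r, 0)
    }
  }
  dist_matrix(m, raw = raw)
}

# R_ST for one group pair, loci combined by summing numerator/denominator.
rst_pair <- function(a, b, weight_groups_equally = TRUE) {
  num <- 0
  den <- 0
  for (l in seq_len(ncol(a))) {
    x <- a[, l][!is.na(a[, l])]
    y <- b[, l][!is.na(b[, l])]
    sw_parts <- c(mean_sq_diff_within(x), mean_sq_diff_within(y))
    if (weight_groups_equally) {
      sw <- mean(sw_parts, na.rm = TRUE)
      if (is.nan(sw)) sw <- NA_real_
    } else {
      w <- c(choose(length(x), 2), choose(length(y), 2))
      sw <- if (sum(w) > 0) sum(sw_parts * w, na.rm = TRUE) / sum(w[!is.na(sw_parts)]) else NA_real_
    }
    pooled <- c(x, y)
    sbar <- mean_sq_diff_within(pooled)
    if (is.na(sbar)) next
    if (is.na(sw)) sw <- 0
    num <- num + (sbar - sw)
    den <- den + sbar
  }
  if (den == 0) 0 else num / den
}

# mean pairwise squared difference within a vector; NA when < 2 values
mean_sq_diff_within <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  # sum over unordered pairs of (xi - xj)^2 = n*sum(x^2) - (sum x)^2
  ss <- n * sum(as.numeric(x)^2) - sum(as.numeric(x))^2
  ss / (n * (n - 1) / 2)
}

resolve_grouping <- function(table, grouping) {
  if (length(grouping) == 1L && is.character(grouping)) {
    if (!grouping %in% names(table)) {
      stop("grouping column not present: ", grouping)
    }
    as.character(table[[grouping]])
  } else {
    if (length(grouping) != nrow(table)) {
      stop("grouping vector must have one label per row")
    }
    as.character(grouping)
  }
}
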