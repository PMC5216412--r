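#' Per-group STR repeat-count variance
#'
#' For each group, the sample variance (n-1 denominator) of repeat counts
#' is computed per locus with missing values excluded, then averaged
#' across loci. This is the per-population diversity statistic behind
#' variance contour maps.
#'
#' @param table A [haplotype_table()].
#' @param grouping `"population"`, `"region"`, or a label vector.
#' @return A data frame with columns `group`, `mean_variance`,
#'   `n_loci_used`, and a logical `undefined` flag for groups where no
#'   locus has two or more observations.
#' @export
str_variance <- function(table, grouping = "population") {
  groups <- resolve_grouping(table, grouping)
  reps <- loci_matrix(table)
  labs <- unique(groups)
  rows <- lapply(labs, function(g) {
    m <- reps[groups == g, , drop = FALSE]
    v <- apply(m, 2L, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2L) NA_real_ else stats::var(x)
    })
    used <- sum(!is.na(v))
    data.frame(group = g,
               mean_variance = if (used > 0) mean(v, na.rm = TRUE) else NA_real_,
               n_loci_used = used,
               undefined = used == 0L)
  })
  do.call(rbind, rows)
}
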