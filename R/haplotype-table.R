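#' The 11 Y-STR loci used throughout the package
#'
#' Default locus panel, in fixed column order: DYS388, DYS389I, DYS390,
#' DYS391, DYS393, DYS19, DYS437, DYS439, DYS389II, DYS392, DYS438.
#'
#' @return Character vector of locus names.
#' @export
default_loci <- function() {
  c("DYS388", "DYS389I", "DYS390", "DYS391", "DYS393", "DYS19",
    "DYS437", "DYS439", "DYS389II", "DYS392", "DYS438")
}

.MISSING_CODE <- "?"
.REPEAT_MIN <- 3L
.REPEAT_MAX <- 60L

#' Construct a haplotype table
#'
#' A haplotype table holds one Y chromosome per row: a sample identifier, a
#' population label, a haplogroup label, and integer repeat counts at a fixed
#' ordered panel of STR loci. Missing repeat counts are stored as `NA`.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param population Character vector of population labels.
#' @param haplogroup Character vector of haplogroup labels.
#' @param repeats Integer matrix (samples x loci) of repeat counts; `NA`
#'   marks missing calls. Column names give the locus panel.
#' @param region Optional character vector of region labels.
#' @param check_range Enforce the observed-data repeat range [3, 60]
#'   (default). Simulated tables may exceed it: the single-step mutation
#'   model is unbounded by design.
#'
#' @return An object of class `haplotype_table`: a data frame with columns
#'   `sample_id`, `population`, `haplogroup`, optionally `region`, and one
#'   integer column per locus; the locus panel is kept in
#'   `attr(x, "loci")`.
#' @export
haplotype_table <- function(sample_id, population, haplogroup, repeats,
                            region = NULL, check_range = TRUE) {
  repeats <- as.matrix(repeats)
  storage.mode(repeats) <- "integer"
  if (ncol(repeats) > 0L && is.null(colnames(repeats))) {
    stop("`repeats` must have locus names as column names")
  }
  if (ncol(repeats) == 0L) colnames(repeats) <- character(0)
  n <- length(sample_id)
  if (nrow(repeats) != n || length(population) != n || length(haplogroup) != n) {
    stop("sample_id, population, haplogroup and repeats must agree in length")
  }
  df <- data.frame(sample_id = as.character(sample_id),
                   population = as.character(population),
                   haplogroup = as.character(haplogroup),
                   stringsAsFactors = FALSE)
  if (!is.null(region)) df$region <- as.character(region)
  df <- cbind(df, as.data.frame(repeats))
  rownames(df) <- NULL
  attr(df, "loci") <- colnames(repeats)
  class(df) <- c("haplotype_table", "data.frame")
  validate_haplotype_table(df, check_range = check_range)
}

#' @rdname haplotype_table
#' @param x Object to validate.
#' @export
validate_haplotype_table <- function(x, check_range = TRUE) {
  loci <- attr(x, "loci")
  if (is.null(loci)) {
    meta <- intersect(c("sample_id", "population", "haplogroup", "region"),
                      names(x))
    if (length(meta) == ncol(x)) loci <- character(0)  # locus-free table
    else stop("missing locus attribute")
  }
  if (!all(loci %in% names(x))) stop("locus columns absent from table")
  if (anyDuplicated(x$sample_id)) {
    dup <- x$sample_id[duplicated(x$sample_id)][1L]
    stop("duplicate sample_id: ", dup)
  }
  rep_mat <- loci_matrix(x)
  bad <- if (check_range)
    !is.na(rep_mat) & (rep_mat < .REPEAT_MIN | rep_mat > .REPEAT_MAX)
  else matrix(FALSE, nrow(rep_mat), ncol(rep_mat))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("repeat count out of range [%d, %d] at sample %s, locus %s",
                 .REPEAT_MIN, .REPEAT_MAX,
                 x$sample_id[idx[1L]], loci[idx[2L]]))
  }
  x
}

#' Extract the repeat-count matrix from a haplotype table
#'
#' @param x A `haplotype_table`.
#' @return Integer matrix (samples x loci), rownames = sample ids.
#' @export
loci_matrix <- function(x) {
  loci <- attr(x, "loci")
  m <- as.matrix(x[, loci, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- x$sample_id
  m
}

#' Read a haplotype table from a tab-delimited file
#'
#' Expects a UTF-8, tab-delimited file with a header line naming columns
#' `sample_id`, `population`, `haplogroup`, optionally `region`, followed by
#' one column per STR locus. Lines starting with `#` are ignored. Missing
#' repeat counts are coded `?`.
#'
#' @param path File path.
#' @param locus_spec Ordered locus names expected in the file; defaults to
#'   the header's own ordering of non-metadata columns. If given, the file's
#'   loci must match this set and the returned table uses this order.
#' @return A [haplotype_table()].
#' @export
read_haplotype_table <- function(path, locus_spec = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", fileEncoding = "UTF-8")
  meta_cols <- intersect(c("sample_id", "population", "haplogroup", "region"),
                         names(raw))
  if (!all(c("sample_id", "population", "haplogroup") %in% meta_cols)) {
    stop("header must name sample_id, population and haplogroup columns")
  }
  file_loci <- setdiff(names(raw), meta_cols)
  if (is.null(locus_spec)) {
    locus_spec <- file_loci
  } else {
    unknown <- setdiff(file_loci, locus_spec)
    missing <- setdiff(locus_spec, file_loci)
    if (length(unknown) || length(missing)) {
      stop("locus columns do not match locus_spec; unknown: [",
           paste(unknown, collapse = ", "), "], absent: [",
           paste(missing, collapse = ", "), "]")
    }
  }
  if (length(locus_spec) == 0L) stop("no locus columns found")
  n <- nrow(raw)
  rep_mat <- matrix(NA_integer_, n, length(locus_spec),
                    dimnames = list(NULL, locus_spec))
  for (loc in locus_spec) {
    v <- raw[[loc]]
    miss <- v == .MISSING_CODE | v == "" | is.na(v)
    num <- suppressWarnings(as.integer(v))
    bad <- !miss & (is.na(num) | num != suppressWarnings(as.numeric(v)))
    if (any(bad)) {
      stop(sprintf("malformed repeat count '%s' at data line %d, locus %s",
                   v[which(bad)[1L]], which(bad)[1L], loc))
    }
    num[miss] <- NA_integer_
    rep_mat[, loc] <- num
  }
  haplotype_table(raw$sample_id, raw$population, raw$haplogroup, rep_mat,
                  region = if ("region" %in% names(raw)) raw$region else NULL)
}

#' Write a haplotype table to a tab-delimited file
#'
#' Inverse of [read_haplotype_table()]; missing repeats are written as `?`.
#'
#' @param x A `haplotype_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(x, path) {
  loci <- attr(x, "loci")
  out <- x
  class(out) <- "data.frame"
  for (loc in loci) {
    v <- as.character(out[[loc]])
    v[is.na(v)] <- .MISSING_CODE
    out[[loc]] <- v
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Subset a haplotype table by row
#'
#' Keeps the locus attribute and class; used to select haplogroup carriers
#' or population subsets.
#'
#' @param x A `haplotype_table`.
#' @param i Row index (logical or integer).
#' @return A `haplotype_table`.
#' @export
ht_subset <- function(x, i) {
  loci <- attr(x, "loci")
  out <- as.data.frame(x)[i, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "loci") <- loci
  class(out) <- c("haplotype_table", "data.frame")
  out
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype_table: %d chromosomes, %d loci, %d populations\n",
              nrow(x), length(attr(x, "loci")),
              length(unique(x$population))))
  print(head(as.data.frame(x), 6L))
  invisible(x)
}
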