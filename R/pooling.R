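#' Construct a population-to-region pooling
#'
#' Regional pooling assigns each sampled population to exactly one
#' geographic region (e.g. Arabia, Mesopotamia, Northern Levant) so that
#' variance can be partitioned among regions, among populations within
#' regions, and within populations.
#'
#' @param population Character vector of population names (unique).
#' @param region Character vector of region names, same length.
#' @return An object of class `population_pooling`: a data frame with
#'   columns `population` and `region`.
#' @export
population_pooling <- function(population, region) {
  population <- as.character(population)
  region <- as.character(region)
  if (length(population) != length(region)) {
    stop("population and region must have the same length")
  }
  if (length(population) == 0L) stop("pooling is empty")
  if (anyDuplicated(population)) {
    dup <- population[duplicated(population)][1L]
    stop("population mapped to more than one region: ", dup)
  }
  df <- data.frame(population = population, region = region,
                   stringsAsFactors = FALSE)
  class(df) <- c("population_pooling", "data.frame")
  df
}

#' Read a population-to-region pooling file
#'
#' Two-column tab-delimited file `population<TAB>region`, `#` comments
#' ignored.
#'
#' @param path File path.
#' @return A [population_pooling()].
#' @export
read_pooling <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    colClasses = "character", stringsAsFactors = FALSE,
                    quote = "", fileEncoding = "UTF-8")
  if (!all(c("population", "region") %in% names(raw))) {
    stop("pooling file must have columns 'population' and 'region'")
  }
  population_pooling(raw$population, raw$region)
}

#' Write a pooling to a tab-delimited file
#' @param x A `population_pooling`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pooling <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Map population labels to regions
#'
#' @param pooling A `population_pooling`.
#' @param population Character vector of population labels.
#' @return Character vector of region labels.
#' @export
region_of <- function(pooling, population) {
  idx <- match(population, pooling$population)
  if (anyNA(idx)) {
    stop("population not in pooling: ",
         paste(unique(population[is.na(idx)]), collapse = ", "))
  }
  pooling$region[idx]
}
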