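#' Construct a haplogroup tree
#'
#' Rooted tree of Y haplogroup labels (e.g. J > J1 > J1e), optionally with
#' the unique-event polymorphism (UEP) marker that defines each edge.
#'
#' @param label Character vector of haplogroup labels (unique).
#' @param parent Character vector of parent labels; `NA` for the root.
#' @param uep Optional character vector naming the UEP marker on the edge
#'   above each node.
#' @return An object of class `haplogroup_tree`.
#' @export
haplogroup_tree <- function(label, parent, uep = NULL) {
  label <- as.character(label)
  parent <- as.character(parent)
  if (anyDuplicated(label)) stop("haplogroup labels must be unique")
  roots <- which(is.na(parent))
  if (length(roots) != 1L) stop("tree must have exactly one root")
  known <- parent %in% label | is.na(parent)
  if (!all(known)) {
    stop("unknown parent label: ", parent[!known][1L])
  }
  # acyclicity: walking up from every node must reach the root
  for (i in seq_along(label)) {
    seen <- character(0)
    cur <- label[i]
    while (!is.na(cur)) {
      if (cur %in% seen) stop("cycle detected at haplogroup ", cur)
      seen <- c(seen, cur)
      cur <- parent[match(cur, label)]
    }
  }
  structure(list(label = label, parent = parent, uep = uep),
            class = "haplogroup_tree")
}

#' Read a haplogroup tree from a Newick file
#'
#' Node and tip labels carry haplogroup names; topology gives the nesting.
#'
#' @param path Newick file path.
#' @return A [haplogroup_tree()].
#' @export
read_haplogroup_tree <- function(path) {
  phy <- ape::read.tree(path)
  labels <- c(phy$tip.label, phy$node.label)
  n_tip <- length(phy$tip.label)
  parent <- rep(NA_character_, length(labels))
  for (e in seq_len(nrow(phy$edge))) {
    child <- phy$edge[e, 2L]
    par <- phy$edge[e, 1L]
    parent[child] <- labels[par]
  }
  haplogroup_tree(labels, parent)
}

#' Resolve haplogroup labels to ancestors at a fixed depth
#'
#' Depth 0 is the root; depth 1 its children, and so on. Labels already at
#' or above the requested depth map to themselves.
#'
#' @param tree A `haplogroup_tree`.
#' @param labels Character vector of haplogroup labels to resolve.
#' @param depth Non-negative integer tree depth.
#' @return Character vector of ancestor labels.
#' @export
haplogroup_at_depth <- function(tree, labels, depth) {
  idx <- match(labels, tree$label)
  if (anyNA(idx)) {
    stop("haplogroup not in tree: ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  node_depth <- function(lab) {
    d <- 0L
    cur <- lab
    repeat {
      p <- tree$parent[match(cur, tree$label)]
      if (is.na(p)) return(d)
      d <- d + 1L
      cur <- p
    }
  }
  vapply(labels, function(lab) {
    d <- node_depth(lab)
    cur <- lab
    while (d > depth) {
      cur <- tree$parent[match(cur, tree$label)]
      d <- d - 1L
    }
    cur
  }, character(1), USE.NAMES = FALSE)
}
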