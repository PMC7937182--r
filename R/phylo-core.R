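#' @import ape
#' @importFrom stats median runif setNames
#' @importFrom utils read.delim write.csv
NULL

#' Parse a Newick string into a validated rooted tree
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' rest of the pipeline relies on: unique, non-empty leaf labels and a single
#' root. Internal-node labels (typically bootstrap values in gene trees) are
#' retained as opaque annotations in `node.label` and never interpreted as
#' taxa. Polytomies are preserved. A single-leaf tree (`"A;"`) is handled
#' explicitly because it is a degenerate case of the underlying parser.
#'
#' @param text A Newick string, terminated by `;`.
#' @return An object of class `phylo`.
#' @export
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' ape::Ntip(tr)
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text) || !endsWith(text, ";")) {
    stop("Newick parse error: string must be non-empty and end with ';'")
  }
  if (grepl("^[^();,]+;$", text)) {
    # degenerate single-leaf tree
    lab <- sub(";$", "", text)
    len <- NA_real_
    if (grepl(":", lab)) {
      len <- suppressWarnings(as.numeric(sub("^.*:", "", lab)))
      lab <- sub(":.*$", "", lab)
    }
    tr <- structure(list(
      edge = matrix(c(2L, 1L), 1L, 2L),
      tip.label = lab, Nnode = 1L
    ), class = "phylo", order = "cladewise")
    if (!is.na(len)) tr$edge.length <- len
    return(validate_tree(tr))
  }
  tr <- tryCatch(ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
      " [input: ", substr(text, 1, 60), "]", call. = FALSE),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w),
      " [input: ", substr(text, 1, 60), "]", call. = FALSE))
  if (is.null(tr)) stop("Newick parse error: unparseable string")
  validate_tree(tr)
}

#' Validate the rooted-tree invariants of a phylo object
#'
#' @param tree A `phylo` object.
#' @return `tree`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  labs <- tree$tip.label
  if (any(is.na(labs)) || any(!nzchar(labs))) {
    stop("tree validation error: empty leaf label")
  }
  if (anyDuplicated(labs)) {
    stop("tree validation error: duplicate leaf labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  n <- ape::Ntip(tree)
  kids <- tabulate(tree$edge[, 1], nbins = n + tree$Nnode)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(root) != 1L) stop("tree validation error: not exactly one root")
  if (n > 1L) {
    internal <- (n + 1L):(n + tree$Nnode)
    if (any(kids[internal] < 2L)) {
      stop("tree validation error: internal node with fewer than 2 children")
    }
  }
  tree
}

#' Serialize a rooted tree to Newick
#'
#' Inverse of [parse_newick()]: the round trip preserves topology, labels and
#' branch lengths (written to 10 significant digits).
#'
#' @param tree A `phylo` object.
#' @return A Newick string.
#' @export
write_newick <- function(tree) {
  validate_tree(tree)
  if (ape::Ntip(tree) == 1L) {
    len <- if (!is.null(tree$edge.length)) paste0(":", format(tree$edge.length[1], digits = 10)) else ""
    return(paste0(tree$tip.label, len, ";"))
  }
  ape::write.tree(tree, digits = 10)
}

#' Read one or more Newick trees from a file
#'
#' Accepts either a file containing one tree per line or a directory of
#' `.nwk`/`.tre`/`.newick` files (one tree each).
#'
#' @param path File or directory path.
#' @return A list of validated `phylo` objects, named by file or line index.
#' @export
read_trees <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(nwk|tre|tree|newick)$", full.names = TRUE)
    if (length(files) == 0L) stop("no Newick files found in ", path)
    trees <- lapply(files, function(f) parse_newick(paste(readLines(f, warn = FALSE), collapse = "")))
    names(trees) <- sub("\\.[^.]+$", "", basename(files))
    return(trees)
  }
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  trees <- lapply(lines, parse_newick)
  names(trees) <- sprintf("tree%04d", seq_along(trees))
  trees
}

#' Write a list of trees, one Newick string per line
#'
#' @param trees A list of `phylo` objects.
#' @param path Output file path.
#' @export
write_trees <- function(trees, path) {
  writeLines(vapply(trees, write_newick, character(1)), path)
}

# parent lookup: parent[i] is the parent node of node i, 0 for the root
node_parents <- function(tree) {
  p <- integer(ape::Ntip(tree) + tree$Nnode)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

root_node <- function(tree) ape::Ntip(tree) + 1L

# tip labels subtended by a node
tips_under <- function(tree, node) {
  n <- ape::Ntip(tree)
  if (node <= n) return(tree$tip.label[node])
  tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1]]]
}

# number of edges on the path root -> node
node_depth_edges <- function(tree, node) {
  p <- node_parents(tree)
  d <- 0L
  while (p[node] != 0L) {
    node <- p[node]
    d <- d + 1L
  }
  d
}

#' Most recent common ancestor of a set of leaves
#'
#' The deepest node whose descendant leaf set contains all of `labels`.
#' For a single label the MRCA is the leaf itself.
#'
#' @param tree A rooted `phylo` object.
#' @param labels Character vector of leaf labels (non-empty).
#' @return The node id (ape numbering: tips `1..Ntip`, internals above).
#' @export
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' mrca_node(tr, c("A", "B"))
mrca_node <- function(tree, labels) {
  if (length(labels) == 0L) stop("mrca of an empty label set is undefined")
  miss <- setdiff(labels, tree$tip.label)
  if (length(miss) > 0L) stop("unknown leaf label(s): ", paste(miss, collapse = ", "))
  if (length(unique(labels)) == 1L) return(match(labels[1], tree$tip.label))
  ape::getMRCA(tree, unique(labels))
}

#' Is node `a` a strict ancestor of node `b`?
#'
#' `TRUE` iff `a` lies on the root-to-`b` path and `a != b`. The root is an
#' ancestor of every other node.
#'
#' @param tree A rooted `phylo` object.
#' @param a,b Node ids.
#' @return Logical scalar.
#' @export
is_ancestor <- function(tree, a, b) {
  nmax <- ape::Ntip(tree) + tree$Nnode
  if (a < 1L || a > nmax || b < 1L || b > nmax) stop("unknown node id")
  if (a == b) return(FALSE)
  p <- node_parents(tree)
  while (p[b] != 0L) {
    b <- p[b]
    if (b == a) return(TRUE)
  }
  FALSE
}

#' Does the outgroup form a single partition of the unrooted topology?
#'
#' `TRUE` iff removing some edge of the unrooted topology splits the leaves
#' into exactly (`outgroup`, rest). This is the admission filter for
#' outgroup rooting: trees where the outgroup is interleaved with the
#' ingroup cannot be rooted unambiguously and are discarded upstream.
#'
#' @param tree A `phylo` object (its stored rooting is ignored).
#' @param outgroup Character vector of outgroup leaf labels; must be a
#'   non-empty proper subset of the leaf set.
#' @return Logical scalar.
#' @export
outgroup_partition_ok <- function(tree, outgroup) {
  outgroup <- unique(outgroup)
  if (length(outgroup) == 0L) stop("outgroup set is empty")
  miss <- setdiff(outgroup, tree$tip.label)
  if (length(miss) > 0L) stop("outgroup labels not in tree: ", paste(miss, collapse = ", "))
  ingroup <- setdiff(tree$tip.label, outgroup)
  if (length(ingroup) == 0L) stop("outgroup equals the full leaf set")
  # a single leaf, outgroup or ingroup side, is always separated by its own edge
  if (length(outgroup) == 1L || length(ingroup) == 1L) return(TRUE)
  # re-root at an ingroup leaf: the outgroup is a partition of the unrooted
  # topology iff it is a clade in this rooting
  u <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  r <- ape::root(u, outgroup = ingroup[1], resolve.root = TRUE)
  m <- ape::getMRCA(r, outgroup)
  setequal(tips_under(r, m), outgroup)
}

#' Root a tree on the branch separating outgroup from ingroup
#'
#' Recomputes the rooting from the unrooted topology (so already-rooted
#' input is re-rooted from scratch) and returns a tree whose root has
#' exactly two children: one subtending exactly the outgroup leaves, the
#' other exactly the ingroup. When branch lengths are present the root edge
#' is split into two equal halves; branch lengths are not used by any
#' downstream computation, so this is purely a serialization convention.
#'
#' @inheritParams outgroup_partition_ok
#' @return A rooted `phylo` object.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  outgroup <- unique(outgroup)
  if (!outgroup_partition_ok(tree, outgroup)) {
    stop("outgroup not a single partition")
  }
  ingroup <- setdiff(tree$tip.label, outgroup)
  if (ape::Ntip(tree) == 2L) {
    r <- tree
  } else {
    u <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
    if (length(ingroup) == 1L) {
      # rooting at the lone ingroup leaf isolates the outgroup on the other side
      r <- ape::root(u, outgroup = ingroup, resolve.root = TRUE)
    } else if (length(outgroup) == 1L) {
      r <- ape::root(u, outgroup = outgroup, resolve.root = TRUE)
    } else {
      # make the outgroup a clade first (guaranteed possible by the check above)
      u <- ape::unroot(ape::root(u, outgroup = ingroup[1], resolve.root = TRUE))
      r <- ape::root(u, outgroup = outgroup, resolve.root = TRUE)
    }
  }
  rn <- root_node(r)
  kids <- r$edge[r$edge[, 1] == rn, 2]
  stopifnot(length(kids) == 2L)
  if (!is.null(r$edge.length)) {
    ke <- which(r$edge[, 1] == rn)
    tot <- sum(r$edge.length[ke])
    r$edge.length[ke] <- tot / 2
  }
  sides <- lapply(kids, function(k) tips_under(r, k))
  if (!setequal(sides[[1]], outgroup) && !setequal(sides[[2]], outgroup)) {
    stop("internal error: rooting did not isolate the outgroup") # nocov
  }
  validate_tree(r)
}

#' Extract the rooted ingroup subtree of an outgroup-rooted tree
#'
#' @param tree A tree rooted by [root_on_outgroup()].
#' @param outgroup The outgroup labels used for rooting.
#' @return The ingroup subtree as a rooted `phylo` object.
#' @export
drop_outgroup <- function(tree, outgroup) {
  rn <- root_node(tree)
  kids <- tree$edge[tree$edge[, 1] == rn, 2]
  if (length(kids) != 2L) stop("tree is not rooted with two root children")
  sides <- lapply(kids, function(k) tips_under(tree, k))
  og_side <- which(vapply(sides, function(s) setequal(s, intersect(s, outgroup)), logical(1)))
  if (length(og_side) == 0L) stop("no root child subtends only outgroup leaves")
  ing <- kids[setdiff(1:2, og_side[1])]
  n <- ape::Ntip(tree)
  if (ing <= n) {
    # single-leaf ingroup
    return(parse_newick(paste0(tree$tip.label[ing], ";")))
  }
  ape::extract.clade(tree, ing)
}
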