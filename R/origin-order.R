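#' Assign a trait its origin node on a rooted tree
#'
#' Under the single-origin (Dollo-style) assumption a trait is gained once
#' and may be lost any number of times, so the most tipward node that can
#' explain all observed presences is the MRCA of the trait-bearing leaves.
#' That node is returned as the trait's origin. (Read literally, "the most
#' recent node where the trait is present in any descendant" would admit
#' every ancestor of any bearer; the MRCA of all bearers is the only reading
#' compatible with a single gain followed by losses, and is what this
#' function implements.)
#'
#' Species missing from the tree (e.g., when mapping onto a gene tree that
#' spans a taxon subset) are ignored; missing states never count as
#' presences, so they cannot pull an origin rootward.
#'
#' @param tree A rooted `phylo` object.
#' @param tm A [trait_matrix()].
#' @param trait Trait name.
#' @return The origin node id.
#' @export
assign_origin <- function(tree, tm, trait) {
  bearers <- intersect(presence_set(tm, trait), tree$tip.label)
  if (length(bearers) == 0L) {
    stop("trait '", trait, "' absent everywhere on this tree")
  }
  mrca_node(tree, bearers)
}

#' Order relation between two origin nodes
#'
#' Two traits whose origins coincide are `"simultaneous"` at the resolution
#' of the sampled taxa; when one origin is an ancestor of the other, the
#' ancestral trait emerged earlier; origins in disjoint subtrees are
#' `"non_nested"` and carry no order information.
#'
#' @param tree A rooted `phylo` object.
#' @param origin_a,origin_b Node ids.
#' @return One of `"simultaneous"`, `"first_earlier"`, `"second_earlier"`,
#'   `"non_nested"`.
#' @export
compare_pair <- function(tree, origin_a, origin_b) {
  nmax <- ape::Ntip(tree) + tree$Nnode
  if (origin_a < 1L || origin_a > nmax || origin_b < 1L || origin_b > nmax) {
    stop("unknown node id")
  }
  if (origin_a == origin_b) return("simultaneous")
  if (is_ancestor(tree, origin_a, origin_b)) return("first_earlier")
  if (is_ancestor(tree, origin_b, origin_a)) return("second_earlier")
  "non_nested"
}

# relation of every unordered pair of origins, given precomputed ancestor
# paths (list: node -> integer vector of ancestors, root first)
pair_relations <- function(origins, ancestors) {
  k <- length(origins)
  rel <- matrix(NA_character_, k, k, dimnames = list(names(origins), names(origins)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      a <- origins[[i]]; b <- origins[[j]]
      rel[i, j] <-
        if (a == b) "simultaneous"
        else if (a %in% ancestors[[as.character(b)]]) "first_earlier"
        else if (b %in% ancestors[[as.character(a)]]) "second_earlier"
        else "non_nested"
    }
  }
  rel
}

ancestor_paths <- function(tree, nodes) {
  p <- node_parents(tree)
  paths <- lapply(unique(nodes), function(nd) {
    anc <- integer(0)
    while (p[nd] != 0L) {
      nd <- p[nd]
      anc <- c(anc, nd)
    }
    anc
  })
  names(paths) <- as.character(unique(nodes))
  paths
}

#' Infer the order of trait emergence on a rooted species tree
#'
#' Maps every trait to its origin node ([assign_origin()]), groups traits
#' with a common origin into blocks, orders the blocks from the root toward
#' the tips, and records the order relation for every unordered trait pair.
#' Non-nested pairs (origins in disjoint subtrees) do not abort the
#' analysis; they are returned as a first-class result list, and when that
#' list is empty the blocks form a total order of emergence.
#'
#' @param tree A rooted `phylo` object.
#' @param tm A [trait_matrix()]; species sets must already agree (see
#'   [reconcile()]).
#' @param skip_absent Skip (with a warning) traits with no presence instead
#'   of raising an error.
#' @return A `trait_order` object: list with `origins` (named node ids),
#'   `origin_tips` (leaf set of each origin clade), `blocks` (root-most
#'   first; each with `traits`, `node`, `depth`), `relations` (k x k
#'   matrix), `non_nested` (data frame of pairs), `n_pairs`, and `tree`.
#' @export
build_order <- function(tree, tm, skip_absent = FALSE) {
  validate_tree(tree)
  traits <- colnames(tm)
  if (skip_absent) {
    absent <- traits[vapply(traits, function(tr)
      length(intersect(presence_set(tm, tr), tree$tip.label)) == 0L, logical(1))]
    if (length(absent) > 0L) {
      warning("skipping trait(s) with no presence on the tree: ",
              paste(absent, collapse = ", "))
      traits <- setdiff(traits, absent)
    }
  }
  if (length(traits) == 0L) stop("no traits to order")
  origins <- vapply(traits, function(tr) assign_origin(tree, tm, tr), integer(1))
  anc <- ancestor_paths(tree, origins)
  rel <- pair_relations(as.list(origins), anc)
  k <- length(traits)
  nn <- which(upper.tri(rel) & rel == "non_nested", arr.ind = TRUE)
  non_nested <- data.frame(trait_a = traits[nn[, 1]], trait_b = traits[nn[, 2]],
                           stringsAsFactors = FALSE)
  # blocks: traits sharing an origin node; ordered root-most first by node
  # depth (a linear extension of the ancestry partial order), ties broken by
  # first appearance in column order
  uniq <- unique(origins)
  depth <- vapply(uniq, function(nd) length(anc[[as.character(nd)]]), integer(1))
  ord <- order(depth, match(uniq, origins))
  blocks <- lapply(ord, function(i) {
    nd <- uniq[i]
    list(node = nd, depth = depth[i],
         tips = sort(tips_under(tree, nd)),
         traits = traits[origins == nd])
  })
  structure(list(
    origins = origins,
    origin_tips = lapply(setNames(as.list(origins), traits),
                         function(nd) sort(tips_under(tree, nd))),
    blocks = blocks,
    relations = rel,
    non_nested = non_nested,
    n_pairs = k * (k - 1L) / 2L,
    tree = tree
  ), class = "trait_order")
}

#' @export
print.trait_order <- function(x, ...) {
  cat("Trait emergence order: ", length(x$origins), " traits, ",
      length(x$blocks), " origin blocks, ", x$n_pairs, " pairs, ",
      nrow(x$non_nested), " non-nested\n", sep = "")
  for (i in seq_along(x$blocks)) {
    b <- x$blocks[[i]]
    cat(sprintf("  block %d (depth %d, clade of %d): %s\n", i, b$depth,
                length(b$tips), paste(b$traits, collapse = ", ")))
  }
  invisible(x)
}

#' Export a trait order report to JSON and CSV
#'
#' Writes `order.json` (blocks, pairwise relations, non-nested list) and
#' `pair_relations.csv` (k x k relation matrix) under `out_dir`.
#'
#' @param x A `trait_order` object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_order_report <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(out_dir, "order.json")
  csv_path <- file.path(out_dir, "pair_relations.csv")
  payload <- list(
    n_traits = length(x$origins),
    n_pairs = x$n_pairs,
    blocks = lapply(x$blocks, function(b)
      list(traits = b$traits, depth = b$depth, clade_size = length(b$tips),
           clade = b$tips)),
    non_nested = x$non_nested,
    relations = as.data.frame(x$relations)
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  utils::write.csv(x$relations, csv_path)
  invisible(c(json_path, csv_path))
}
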