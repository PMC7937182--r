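#' Read a species-to-group map from TSV
#'
#' Two columns: species label, group name. Every ingroup species of the
#' census must appear exactly once.
#'
#' @param path Path to the TSV (header optional; detected by the header
#'   `species` in the first field).
#' @return Named character vector: species -> group.
#' @export
read_group_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (tolower(trimws(df[1, 1])) == "species") df <- df[-1, , drop = FALSE]
  if (ncol(df) < 2L) stop("group map needs two columns: species, group")
  sp <- trimws(df[[1]]); gr <- trimws(df[[2]])
  if (anyDuplicated(sp)) {
    stop("duplicate species in group map: ",
         paste(unique(sp[duplicated(sp)]), collapse = ", "))
  }
  setNames(gr, sp)
}

#' Classify a rooted ingroup tree by its basal/ancestral group
#'
#' Given a tree whose root has exactly two children and a species-to-group
#' map, determines which groups occur on each side of the root:
#' * if no group occurs on both sides and exactly one side is occupied by a
#'   single group, that group is **basal** — it forms an entire lineage
#'   stemming from the root, supporting a root position on the branch
#'   separating it from the rest;
#' * if exactly one group occurs on both sides, that group is
#'   **ancestral** — the root falls within it;
#' * if more than one group spans the root, or both root children are
#'   single-group (so "basal" is not well defined), the verdict is
#'   **ambiguous**.
#'
#' @param tree A rooted `phylo` object with a two-child root.
#' @param group_map Named character vector: species -> group.
#' @return A list with `verdict` (`"basal"`, `"ancestral"` or
#'   `"ambiguous"`), `group` (the basal/ancestral group or `NA`),
#'   `side_groups` (groups on each root side) and `note`.
#' @export
classify_root <- function(tree, group_map) {
  rn <- root_node(tree)
  kids <- tree$edge[tree$edge[, 1] == rn, 2]
  if (length(kids) != 2L) {
    stop("classify_root requires a root with exactly two children")
  }
  sides <- lapply(kids, function(k) tips_under(tree, k))
  unmapped <- setdiff(unlist(sides), names(group_map))
  if (length(unmapped) > 0L) {
    stop("leaves without a group: ", paste(unmapped, collapse = ", "))
  }
  g1 <- unique(unname(group_map[sides[[1]]]))
  g2 <- unique(unname(group_map[sides[[2]]]))
  spanning <- intersect(g1, g2)
  side_groups <- list(side1 = g1, side2 = g2)
  if (length(spanning) == 0L) {
    single1 <- length(g1) == 1L
    single2 <- length(g2) == 1L
    if (single1 && single2) {
      return(list(verdict = "ambiguous", group = NA_character_,
                  side_groups = side_groups,
                  note = "both root children are single-group; basal not well defined"))
    }
    if (single1 || single2) {
      return(list(verdict = "basal",
                  group = if (single1) g1 else g2,
                  side_groups = side_groups, note = ""))
    }
    return(list(verdict = "ambiguous", group = NA_character_,
                side_groups = side_groups,
                note = "no group spans the root but neither side is single-group"))
  }
  if (length(spanning) == 1L) {
    return(list(verdict = "ancestral", group = spanning,
                side_groups = side_groups, note = ""))
  }
  list(verdict = "ambiguous", group = NA_character_,
       side_groups = side_groups,
       note = paste("groups spanning the root:", paste(spanning, collapse = ", ")))
}

#' Root-support census over a set of gene trees
#'
#' Runs the rooting and classification pipeline on every gene tree:
#' 1. trees whose outgroup leaves do not form a single partition of the
#'    unrooted topology (including trees with no outgroup leaf at all,
#'    which cannot be rooted) are discarded with reason `outgroup_split`;
#' 2. survivors are rooted on the outgroup and the outgroup leaves dropped;
#' 3. trees in which any named group has fewer than `min_per_group` leaves
#'    are discarded with reason `min_group_count`;
#' 4. the remainder are classified by [classify_root()].
#'
#' The outgroup filter is applied before the group-count filter. Optional
#' per-tree metadata (e.g., alignment lengths) are carried through and
#' summarized as per-category medians.
#'
#' @param gene_trees Named list of `phylo` objects (rooting ignored).
#' @param group_map Named character vector: species -> group.
#' @param outgroup Character vector of outgroup leaf labels.
#' @param min_per_group Minimum leaves required of every named group
#'   (default 2).
#' @param metadata Optional named numeric vector (tree id -> value, e.g.
#'   alignment length) for per-category medians.
#' @return A `root_census` object: list with `per_tree` (data frame:
#'   tree, verdict, group, reason), `tally` (named counts), optional
#'   `metadata_medians`, and the parameters used.
#' @export
census <- function(gene_trees, group_map, outgroup, min_per_group = 2L,
                   metadata = NULL) {
  if (is.null(names(gene_trees))) {
    names(gene_trees) <- sprintf("tree%04d", seq_along(gene_trees))
  }
  groups <- unique(unname(group_map))
  rows <- lapply(names(gene_trees), function(id) {
    gt <- gene_trees[[id]]
    og <- intersect(outgroup, gt$tip.label)
    ing <- setdiff(gt$tip.label, outgroup)
    ok <- length(og) > 0L && length(ing) > 0L &&
      tryCatch(outgroup_partition_ok(gt, og), error = function(e) FALSE)
    if (!ok) {
      return(data.frame(tree = id, verdict = "discarded", group = NA_character_,
                        reason = "outgroup_split", stringsAsFactors = FALSE))
    }
    rooted <- root_on_outgroup(gt, og)
    ingroup_tree <- drop_outgroup(rooted, og)
    counts <- table(factor(unname(group_map[ingroup_tree$tip.label]), levels = groups))
    if (any(counts < min_per_group)) {
      return(data.frame(tree = id, verdict = "discarded", group = NA_character_,
                        reason = "min_group_count", stringsAsFactors = FALSE))
    }
    rn <- root_node(ingroup_tree)
    kids <- ingroup_tree$edge[ingroup_tree$edge[, 1] == rn, 2]
    if (ape::Ntip(ingroup_tree) < 2L || length(kids) != 2L) {
      return(data.frame(tree = id, verdict = "ambiguous", group = NA_character_,
                        reason = "polytomy_at_root", stringsAsFactors = FALSE))
    }
    cl <- classify_root(ingroup_tree, group_map)
    data.frame(tree = id, verdict = cl$verdict, group = cl$group,
               reason = "", stringsAsFactors = FALSE)
  })
  per_tree <- do.call(rbind, rows)
  tally <- c(
    n_trees = nrow(per_tree),
    discarded_outgroup = sum(per_tree$reason == "outgroup_split"),
    discarded_min_group = sum(per_tree$reason == "min_group_count"),
    classified = sum(per_tree$verdict %in% c("basal", "ancestral", "ambiguous"))
  )
  verdict_counts <- table(paste0(per_tree$verdict,
                                 ifelse(is.na(per_tree$group), "",
                                        paste0(":", per_tree$group))))
  res <- list(per_tree = per_tree, tally = tally,
              verdict_counts = as.list(verdict_counts),
              min_per_group = min_per_group, groups = groups)
  if (!is.null(metadata)) {
    key <- paste0(per_tree$verdict,
                  ifelse(is.na(per_tree$group), "", paste0(":", per_tree$group)))
    vals <- metadata[per_tree$tree]
    res$metadata_medians <- tapply(vals, key, stats::median, na.rm = TRUE)
  }
  structure(res, class = "root_census")
}

#' @export
print.root_census <- function(x, ...) {
  cat("Root-support census: ", x$tally["n_trees"], " gene trees\n",
      "  discarded (outgroup split): ", x$tally["discarded_outgroup"], "\n",
      "  discarded (group < ", x$min_per_group, "): ",
      x$tally["discarded_min_group"], "\n",
      "  classified: ", x$tally["classified"], "\n", sep = "")
  for (v in names(x$verdict_counts)) {
    if (!startsWith(v, "discarded")) {
      cat("    ", v, ": ", x$verdict_counts[[v]], "\n", sep = "")
    }
  }
  invisible(x)
}

#' Export a root census to JSON and CSV
#'
#' Writes `census.json` (tally, verdict counts, optional metadata medians)
#' and `census_per_tree.csv` under `out_dir`.
#'
#' @param x A `root_census` object.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_census <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(out_dir, "census.json")
  csv_path <- file.path(out_dir, "census_per_tree.csv")
  payload <- list(tally = as.list(x$tally), verdict_counts = x$verdict_counts,
                  min_per_group = x$min_per_group)
  if (!is.null(x$metadata_medians)) {
    payload$metadata_medians <- as.list(x$metadata_medians)
  }
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  utils::write.csv(x$per_tree, csv_path, row.names = FALSE)
  invisible(c(json_path, csv_path))
}
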