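#' Minimum state changes of a binary character on a fixed tree
#'
#' Small (fixed-tree) parsimony for a single binary character, computed by
#' dynamic programming over a postorder traversal with unit change cost —
#' the Sankoff recursion, which generalizes Fitch counting to multifurcating
#' nodes. Missing states carry the full state set `{0, 1}` and so never add
#' steps. The count is invariant to the position of the root because the
#' cost function is symmetric.
#'
#' @param tree A rooted `phylo` object (polytomies allowed).
#' @param states Named vector over the tree's leaves with values 0, 1 or
#'   `NA` (missing). Every leaf must be named; at least one state must be
#'   non-missing.
#' @return Integer: the minimum number of 0<->1 changes.
#' @export
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' parsimony_steps(tr, c(A = 1, B = 0, C = 1, D = 0))
parsimony_steps <- function(tree, states) {
  validate_tree(tree)
  labs <- tree$tip.label
  miss <- setdiff(labs, names(states))
  if (length(miss) > 0L) stop("leaf without a state: ", paste(miss, collapse = ", "))
  s <- states[labs]
  if (all(is.na(s))) stop("all states missing")
  if (!all(s %in% c(0, 1, NA))) stop("states must be 0, 1 or NA")
  n <- ape::Ntip(tree)
  if (n == 1L) return(0L)
  ntot <- n + tree$Nnode
  cost0 <- numeric(ntot)
  cost1 <- numeric(ntot)
  cost0[seq_len(n)] <- ifelse(is.na(s), 0, ifelse(s == 0, 0, Inf))
  cost1[seq_len(n)] <- ifelse(is.na(s), 0, ifelse(s == 1, 0, Inf))
  eg <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(eg))) {
    par <- eg[i, 1]; child <- eg[i, 2]
    cost0[par] <- cost0[par] + min(cost0[child], cost1[child] + 1)
    cost1[par] <- cost1[par] + min(cost1[child], cost0[child] + 1)
  }
  rt <- root_node(tree)
  as.integer(min(cost0[rt], cost1[rt]))
}

#' Minimum conceivable steps of a binary character
#'
#' 0 if the character is invariant over its non-missing observations,
#' otherwise 1 (a single gain suffices on some tree). This is the `m` of
#' the consistency index.
#'
#' @param states Vector of 0, 1 and `NA`.
#' @return Integer 0 or 1.
#' @export
min_steps <- function(states) {
  obs <- states[!is.na(states)]
  if (length(obs) == 0L) stop("all states missing")
  if (length(unique(obs)) <= 1L) 0L else 1L
}

#' Maximum conceivable steps of a binary character
#'
#' The parsimony length on a maximally uninformative (star) topology:
#' the smaller of the two non-missing state counts. This is the `g` of the
#' retention index.
#'
#' @inheritParams min_steps
#' @return Integer.
#' @export
max_steps <- function(states) {
  obs <- states[!is.na(states)]
  if (length(obs) == 0L) stop("all states missing")
  min(sum(obs == 0), sum(obs == 1))
}

#' Per-trait parsimony steps and homoplasy indices
#'
#' For every trait computes `m` ([min_steps()]), the observed tree length
#' `s` ([parsimony_steps()]), `g` ([max_steps()]), the consistency index
#' `CI = m/s` (1 means a single gain explains the data; low values signal
#' repeated loss or gain) and the retention index `RI = (g-s)/(g-m)` (1
#' means the trait is a clean synapomorphy; 0 means no grouping signal is
#' retained). `CI` is undefined for invariant traits (`s = 0`) and `RI`
#' whenever `g = m` (e.g., a trait present in a single species); undefined
#' values are `NA` and excluded from the medians, with the exclusions
#' reported.
#'
#' @param tree A rooted `phylo` object.
#' @param tm A [trait_matrix()] over the same species set.
#' @return A `parsimony_indices` object: list with `table` (data frame:
#'   trait, m, s, g, ci, ri), `median_ci`, `median_ri`, `ci_excluded`,
#'   `ri_excluded`.
#' @export
trait_indices <- function(tree, tm) {
  validate_tree(tree)
  if (!setequal(rownames(tm), tree$tip.label)) {
    stop("tree and trait matrix species sets differ; reconcile() them first")
  }
  traits <- colnames(tm)
  rows <- lapply(traits, function(tr) {
    st <- setNames(tm[, tr], rownames(tm))
    m <- min_steps(st)
    s <- parsimony_steps(tree, st)
    g <- max_steps(st)
    data.frame(trait = tr, m = m, s = s, g = g,
               ci = if (s == 0L) NA_real_ else m / s,
               ri = if (g == m) NA_real_ else (g - s) / (g - m),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(
    table = tab,
    median_ci = stats::median(tab$ci, na.rm = TRUE),
    median_ri = stats::median(tab$ri, na.rm = TRUE),
    ci_excluded = tab$trait[is.na(tab$ci)],
    ri_excluded = tab$trait[is.na(tab$ri)]
  ), class = "parsimony_indices")
}

#' @export
print.parsimony_indices <- function(x, ...) {
  cat("Parsimony homoplasy indices over ", nrow(x$table), " traits\n",
      "  median CI = ", format(x$median_ci, digits = 4),
      " (", length(x$ci_excluded), " undefined)\n",
      "  median RI = ", format(x$median_ri, digits = 4),
      " (", length(x$ri_excluded), " undefined)\n", sep = "")
  invisible(x)
}

#' Export parsimony indices to CSV and JSON
#'
#' Writes `indices.csv` (per-trait table) and `indices_summary.json`
#' (medians and undefined-value exclusions) under `out_dir`.
#'
#' @param x A `parsimony_indices` object.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_indices <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(out_dir, "indices.csv")
  json_path <- file.path(out_dir, "indices_summary.json")
  utils::write.csv(x$table, csv_path, row.names = FALSE)
  jsonlite::write_json(list(
    median_ci = x$median_ci, median_ri = x$median_ri,
    n_traits = nrow(x$table),
    ci_excluded = x$ci_excluded, ri_excluded = x$ri_excluded
  ), json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
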