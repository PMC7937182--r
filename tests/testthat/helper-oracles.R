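# Independent oracles and fixture builders used across the suite.

# Brute-force small parsimony: enumerate every assignment of internal nodes
# (and of missing leaves) and count edge changes. Only feasible for tiny
# trees; that is the point.
bf_parsimony <- function(tree, states) {
  labs <- tree$tip.label
  n <- length(labs)
  ntot <- n + tree$Nnode
  s <- states[labs]
  vars <- c((n + 1L):ntot, which(is.na(s)))
  k <- length(vars)
  stopifnot(k <= 16)
  best <- Inf
  for (code in 0:(2^k - 1)) {
    a <- integer(ntot)
    a[seq_len(n)] <- ifelse(is.na(s), 0L, s)
    a[vars] <- as.integer(intToBits(code))[seq_len(k)]
    ch <- sum(a[tree$edge[, 1]] != a[tree$edge[, 2]])
    if (ch < best) best <- ch
  }
  best
}

# Brute-force MRCA: intersect the root-to-leaf node paths and take the
# last (deepest) shared node.
bf_mrca <- function(tree, labels) {
  par <- integer(ape::Ntip(tree) + tree$Nnode)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  path_of <- function(lab) {
    nd <- match(lab, tree$tip.label)
    path <- nd
    while (par[nd] != 0L) {
      nd <- par[nd]
      path <- c(nd, path) # root first
    }
    path
  }
  paths <- lapply(labels, path_of)
  common <- Reduce(intersect, paths)
  common[length(common)]
}

# Random rooted binary tree with deterministic labels.
rand_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$tip.label <- sprintf("L%02d", seq_len(n))
  tr
}

# Build a trait_matrix from a named list trait -> presence labels,
# over an explicit species universe.
tm_from_sets <- function(species, sets) {
  m <- matrix(0L, length(species), length(sets),
              dimnames = list(species, names(sets)))
  for (tr in names(sets)) m[sets[[tr]], tr] <- 1L
  trait_matrix(m)
}

# Pairwise order relations implied by the simulator's true origin nodes,
# in trait-column order (comparable elementwise with build_order()$relations).
truth_relations <- function(tree, truth) {
  origins <- truth$origins
  k <- length(origins)
  rel <- matrix(NA_character_, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) rel[i, j] <- compare_pair(tree, origins[i], origins[j])
    }
  }
  rel
}

# Fixed 10-tree census fixture over groups X = {x1,x2}, Y = {y1,y2},
# Z = {z1,z2} and outgroup {og1,og2}: 2 trees with an interleaved outgroup,
# 3 trees missing group Z members, 5 classifiable (3 basal X, 1 basal Z,
# 1 ancestral Y).
census_fixture <- function() {
  nwk <- c(
    interleaved1 = "(og1,(x1,(og2,(x2,(y1,(y2,(z1,z2)))))));",
    interleaved2 = "((og1,y1),((x1,x2),(og2,(y2,(z1,z2)))));",
    missing_z1   = "((og1,og2),(x1,(x2,(y1,(y2,z1)))));",
    missing_z2   = "((og1,og2),((x1,x2),(y1,(y2,z2))));",
    missing_z3   = "((og1,og2),(y1,(y2,(x1,x2))));",
    basal_x1     = "((og1,og2),((x1,x2),(y1,(y2,(z1,z2)))));",
    basal_x2     = "((og1,og2),((x1,x2),((y1,y2),(z1,z2))));",
    basal_x3     = "((og1,og2),((x2,x1),(z1,(z2,(y1,y2)))));",
    basal_z      = "((og1,og2),((z1,z2),(x1,(x2,(y1,y2)))));",
    ancestral_y  = "((og1,og2),((y1,(x1,x2)),(y2,(z1,z2))));"
  )
  trees <- lapply(nwk, parse_newick)
  group_map <- c(x1 = "X", x2 = "X", y1 = "Y", y2 = "Y", z1 = "Z", z2 = "Z")
  list(trees = trees, group_map = group_map, outgroup = c("og1", "og2"))
}
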