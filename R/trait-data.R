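#' Construct and validate a binary trait matrix
#'
#' The central character table: species in rows, traits in columns, cells
#' coded `1` (present), `0` (absent) or `NA` (unobserved, written `?` on
#' disk). Every trait must have at least one non-missing observation.
#'
#' @param x An integer/numeric matrix of 0, 1 and `NA` with unique row names
#'   (species) and unique column names (traits).
#' @return `x` with class `trait_matrix`.
#' @export
trait_matrix <- function(x) {
  if (!is.matrix(x)) stop("trait matrix must be a matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("trait matrix needs species row names and trait column names")
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate species labels: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate trait names: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  }
  storage.mode(x) <- "integer"
  bad <- which(!(x %in% c(0L, 1L, NA_integer_)))
  if (length(bad) > 0L) {
    i <- ((bad[1] - 1L) %% nrow(x)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(x)) + 1L
    stop("invalid trait state at species '", rownames(x)[i], "', trait '",
         colnames(x)[j], "': must be 0, 1 or ?")
  }
  all_missing <- colnames(x)[colSums(!is.na(x)) == 0L]
  if (length(all_missing) > 0L) {
    stop("trait(s) with no non-missing observation: ",
         paste(all_missing, collapse = ", "))
  }
  class(x) <- c("trait_matrix", class(x))
  x
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("Binary trait matrix: ", nrow(x), " species x ", ncol(x), " traits; ",
      sum(is.na(x)), " missing cells\n", sep = "")
  invisible(x)
}

#' Read a species-by-trait table from TSV/CSV
#'
#' Expects a header row of trait names; the first column holds species
#' labels. Cells must be `0`, `1` or `?`.
#'
#' @param path Path to the table.
#' @param sep Field separator; `"\t"` (default) or `","`.
#' @return A [trait_matrix()].
#' @export
read_trait_matrix <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("trait table needs a species column plus >=1 trait column")
  species <- trimws(df[[1]])
  cells <- as.matrix(df[, -1, drop = FALSE])
  cells <- trimws(cells)
  bad <- which(!(cells %in% c("0", "1", "?")))
  if (length(bad) > 0L) {
    i <- ((bad[1] - 1L) %% nrow(cells)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(cells)) + 1L
    stop("invalid trait state '", cells[bad[1]], "' at row ", i + 1L,
         " (species '", species[i], "'), column '", colnames(cells)[j], "'")
  }
  m <- matrix(NA_integer_, nrow(cells), ncol(cells),
              dimnames = list(species, colnames(cells)))
  m[cells == "0"] <- 0L
  m[cells == "1"] <- 1L
  trait_matrix(m)
}

#' Write a trait matrix to TSV (missing cells as `?`)
#'
#' @param tm A [trait_matrix()].
#' @param path Output file path.
#' @export
write_trait_matrix <- function(tm, path) {
  out <- matrix(as.character(tm), nrow(tm), ncol(tm))
  out[is.na(out)] <- "?"
  df <- data.frame(species = rownames(tm), out, check.names = FALSE)
  colnames(df) <- c("species", colnames(tm))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

check_trait <- function(tm, trait) {
  if (!trait %in% colnames(tm)) stop("unknown trait: ", trait)
  trait
}

#' Species sets by trait state
#'
#' `presence_set()` returns the species scored `1` for a trait;
#' `absence_set()` those scored `0`; `missing_set()` those unobserved.
#' The three sets partition the species set.
#'
#' @param tm A [trait_matrix()].
#' @param trait A trait (column) name.
#' @return Character vector of species labels.
#' @export
presence_set <- function(tm, trait) {
  check_trait(tm, trait)
  rownames(tm)[which(tm[, trait] == 1L)]
}

#' @rdname presence_set
#' @export
absence_set <- function(tm, trait) {
  check_trait(tm, trait)
  rownames(tm)[which(tm[, trait] == 0L)]
}

#' @rdname presence_set
#' @export
missing_set <- function(tm, trait) {
  check_trait(tm, trait)
  rownames(tm)[is.na(tm[, trait])]
}

#' Reconcile a trait matrix with a tree's leaf set
#'
#' By default an error is raised when the species sets differ. With
#' `prune = TRUE` both objects are restricted to the intersection and the
#' dropped labels are reported; traits left with no non-missing observation
#' after pruning are dropped and reported as well.
#'
#' @param tm A [trait_matrix()].
#' @param tree A rooted `phylo` object.
#' @param prune Restrict both inputs to the common species set?
#' @return A list with elements `matrix`, `tree`, `dropped_species_tree`,
#'   `dropped_species_matrix`, `dropped_traits`.
#' @export
reconcile <- function(tm, tree, prune = FALSE) {
  sp_m <- rownames(tm)
  sp_t <- tree$tip.label
  common <- intersect(sp_m, sp_t)
  if (length(common) == 0L) stop("tree and trait matrix share no species")
  if (setequal(sp_m, sp_t)) {
    return(list(matrix = tm, tree = tree,
                dropped_species_tree = character(0),
                dropped_species_matrix = character(0),
                dropped_traits = character(0)))
  }
  if (!prune) {
    stop("species sets differ between tree and trait matrix ",
         "(", length(setdiff(sp_t, sp_m)), " tree-only, ",
         length(setdiff(sp_m, sp_t)), " matrix-only); use prune = TRUE")
  }
  drop_t <- setdiff(sp_t, common)
  drop_m <- setdiff(sp_m, common)
  tree2 <- if (length(drop_t) > 0L) ape::drop.tip(tree, drop_t) else tree
  m2 <- tm[common, , drop = FALSE]
  dead <- colnames(m2)[colSums(!is.na(m2)) == 0L]
  if (length(dead) > 0L) m2 <- m2[, setdiff(colnames(m2), dead), drop = FALSE]
  if (ncol(m2) == 0L) stop("no traits with observations remain after pruning")
  list(matrix = trait_matrix(unclass(m2)), tree = validate_tree(tree2),
       dropped_species_tree = drop_t, dropped_species_matrix = drop_m,
       dropped_traits = dead)
}
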