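#' Binary metabolite-to-pathway incidence matrix
#'
#' A `pathway_matrix` is a P x Q binary matrix whose entry (i, j) is 1 when
#' metabolite i is a member of pathway j. It masks the first layer of a
#' pathway-informed network so connections exist only between metabolites
#' and the pathways they belong to.
#'
#' @param mat numeric matrix with entries in \{0, 1\}.
#' @param metabolite_names character vector naming the P rows (unique).
#' @param pathway_names character vector naming the Q columns (unique).
#' @return An object of class `pathway_matrix`: a list with elements
#'   `matrix`, `metabolite_names`, `pathway_names`.
#' @examples
#' pm <- pathway_matrix(rbind(c(1, 1), c(0, 1)), c("m1", "m2"), c("p1", "p2"))
#' edge_count(pm)
#' @export
pathway_matrix <- function(mat,
                           metabolite_names = rownames(mat),
                           pathway_names = colnames(mat)) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  if (is.null(metabolite_names) || is.null(pathway_names)) {
    stop("metabolite_names and pathway_names are required")
  }
  if (length(metabolite_names) != nrow(mat)) {
    stop("metabolite_names length does not match matrix rows")
  }
  if (length(pathway_names) != ncol(mat)) {
    stop("pathway_names length does not match matrix columns")
  }
  if (anyDuplicated(metabolite_names)) stop("metabolite names must be unique")
  if (anyDuplicated(pathway_names)) stop("pathway names must be unique")
  if (!all(mat %in% c(0, 1))) stop("pathway matrix entries must be 0 or 1")
  dimnames(mat) <- list(metabolite_names, pathway_names)
  structure(
    list(matrix = mat,
         metabolite_names = as.character(metabolite_names),
         pathway_names = as.character(pathway_names)),
    class = "pathway_matrix"
  )
}

#' Number of metabolite-pathway memberships (ones) in the incidence matrix
#' @param pm a [pathway_matrix()].
#' @return integer count of ones.
#' @export
edge_count <- function(pm) {
  stopifnot(inherits(pm, "pathway_matrix"))
  as.integer(sum(pm$matrix))
}

#' @export
print.pathway_matrix <- function(x, ...) {
  cat(sprintf("<pathway_matrix> %d metabolites x %d pathways, %d edges\n",
              nrow(x$matrix), ncol(x$matrix), edge_count(x)))
  invisible(x)
}

#' Read a metabolite-to-pathway mapping file into an incidence matrix
#'
#' Accepts either a two-column file (`metabolite<sep>pathway`, one edge per
#' line) or a GMT-style file (`pathway<TAB>description<TAB>member...`). The
#' delimiter of the two-column dialect is auto-detected between tab and comma.
#' Rows are ordered by `metabolite_order` (the model's input features);
#' pathways are sorted lexicographically so the result is deterministic.
#' Metabolites listed in `metabolite_order` but absent from the mapping get
#' all-zero rows with a warning; mapping entries for unknown metabolites are
#' dropped with a warning.
#'
#' @param path path to the mapping file.
#' @param metabolite_order character vector of feature names defining row order.
#' @return a [pathway_matrix()].
#' @export
read_pathway_mapping <- function(path, metabolite_order) {
  if (!file.exists(path)) stop("mapping file not found: ", path)
  metabolite_order <- as.character(metabolite_order)
  if (anyDuplicated(metabolite_order)) stop("metabolite_order must be unique")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty mapping file: ", path)

  tab_fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(tab_fields)
  if (all(nf >= 3L)) {
    # GMT dialect: pathway, description, members...
    edges <- do.call(rbind, lapply(tab_fields, function(f) {
      cbind(metabolite = f[-(1:2)], pathway = f[[1L]])
    }))
  } else {
    sep <- if (all(nf == 2L)) "\t" else ","
    fields <- if (sep == "\t") tab_fields else strsplit(lines, ",", fixed = TRUE)
    if (!all(lengths(fields) == 2L)) {
      stop("mapping file is neither two-column nor GMT: ", path)
    }
    edges <- do.call(rbind, fields)
    colnames(edges) <- c("metabolite", "pathway")
  }
  edges <- unique(data.frame(metabolite = trimws(edges[, 1L]),
                             pathway = trimws(edges[, 2L]),
                             stringsAsFactors = FALSE))

  unknown <- setdiff(unique(edges$metabolite), metabolite_order)
  if (length(unknown) > 0L) {
    warning("mapping metabolites not in metabolite_order, ignored: ",
            paste(unknown, collapse = ", "))
    edges <- edges[edges$metabolite %in% metabolite_order, , drop = FALSE]
  }
  if (nrow(edges) == 0L) stop("mapping has no edges for the given metabolites")

  # radix sort = byte order, independent of the session locale
  pathways <- sort(unique(edges$pathway), method = "radix")
  mat <- matrix(0, length(metabolite_order), length(pathways),
                dimnames = list(metabolite_order, pathways))
  mat[cbind(match(edges$metabolite, metabolite_order),
            match(edges$pathway, pathways))] <- 1

  unmapped <- metabolite_order[rowSums(mat) == 0]
  if (length(unmapped) > 0L) {
    warning("metabolites without any pathway (all-zero rows): ",
            paste(unmapped, collapse = ", "))
  }
  pathway_matrix(mat, metabolite_order, pathways)
}

#' Write an incidence matrix as tab-separated text with row/column headers
#' @param pm a [pathway_matrix()].
#' @param path output path.
#' @export
write_pathway_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "pathway_matrix"))
  df <- data.frame(metabolite = pm$metabolite_names,
                   pm$matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Edge-count-matched random rewiring of the incidence matrix
#'
#' Places exactly `edge_count(pm)` ones uniformly at random (without
#' replacement) among the P x Q cells, keeping shape and names. This is the
#' "randomly connected" mask ablation: it preserves only the total number of
#' connections, not the degree structure; all-zero rows or columns may occur.
#'
#' @param pm a [pathway_matrix()].
#' @param seed integer seed; the result is deterministic given the seed.
#' @return a [pathway_matrix()] with the same shape, names and edge count.
#' @export
randomize_pathway_matrix <- function(pm, seed) {
  stopifnot(inherits(pm, "pathway_matrix"))
  k <- edge_count(pm)
  cells <- length(pm$matrix)
  new <- matrix(0, nrow(pm$matrix), ncol(pm$matrix))
  idx <- with_seed(seed, sample.int(cells, k))
  new[idx] <- 1
  pathway_matrix(new, pm$metabolite_names, pm$pathway_names)
}

#' Row-shuffled incidence matrix
#'
#' Permutes the rows (metabolite-to-pathway membership profiles) while
#' keeping the metabolite names fixed, so each metabolite receives some
#' metabolite's full pathway profile. Preserves the multiset of row profiles
#' and therefore every pathway's in-degree (column sums).
#'
#' @inheritParams randomize_pathway_matrix
#' @return a [pathway_matrix()] with permuted rows.
#' @export
shuffle_pathway_rows <- function(pm, seed) {
  stopifnot(inherits(pm, "pathway_matrix"))
  p <- nrow(pm$matrix)
  perm <- with_seed(seed, sample.int(p))
  pathway_matrix(pm$matrix[perm, , drop = FALSE],
                 pm$metabolite_names, pm$pathway_names)
}

#' The synthetic example mapping shipped with the package
#'
#' Loads `inst/extdata/pathway_mapping_synthetic.tsv`, a synthetic
#' stand-in mapping at the scale of a 37-metabolite NMR panel against 138
#' metabolic/signaling pathways with 468 memberships. Pathway membership in
#' this file is generated, not curated: it emulates the shape and degree
#' structure of a KEGG-derived mapping for examples and simulations, and
#' must not be used for biological interpretation.
#'
#' @param metabolite_order optional explicit row order; defaults to the
#'   metabolite panel order stored in the file.
#' @return a [pathway_matrix()] (37 x 138 with the default order).
#' @export
example_pathway_matrix <- function(metabolite_order = NULL) {
  path <- system.file("extdata", "pathway_mapping_synthetic.tsv",
                      package = "pathsurv", mustWork = TRUE)
  if (is.null(metabolite_order)) {
    edges <- utils::read.delim(path, header = FALSE,
                               col.names = c("metabolite", "pathway"))
    metabolite_order <- unique(edges$metabolite)
  }
  read_pathway_mapping(path, metabolite_order)
}
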