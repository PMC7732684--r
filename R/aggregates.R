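# Correlation distance between the columns of a cohorts x features matrix,
# tolerant of missing entries (pairwise-complete). Column pairs with no
# overlapping cohorts get the maximal distance 2 with a warning.
correlation_distance <- function(mat) {
  cors <- suppressWarnings(
    stats::cor(mat, use = "pairwise.complete.obs", method = "pearson")
  )
  if (any(is.na(cors))) {
    warning("Some profile pairs share no complete observations or have ",
            "zero variance; their distance is set to the maximum (2)")
    cors[is.na(cors)] <- -1
  }
  stats::as.dist(1 - cors)
}

resolve_distance <- function(mat, distance) {
  switch(distance,
    correlation = correlation_distance(mat),
    euclidean = stats::dist(t(mat), method = "euclidean"),
    stop("Unknown distance: ", distance)
  )
}

#' Form module aggregates by clustering response profiles
#'
#' Groups modules whose percent-response profiles across a reference panel
#' of cohorts are similar, mirroring how fixed repertoires collapse
#' hundreds of modules into a few dozen grid rows. Module columns are
#' clustered by hierarchical agglomeration (default: distance = 1 - Pearson
#' correlation of response profiles, complete linkage) and the tree is cut
#' into `k` aggregates. Aggregates are labelled "A1", "A2", ... in order of
#' first appearance along the dendrogram leaf ordering, so the labelling is
#' deterministic; the labels are positional and carry no identity claim
#' about any published aggregate numbering.
#'
#' @param fm A `fingerprint_matrix` over reference cohorts (rows) and
#'   modules (columns); at least 2 cohorts.
#' @param k Number of aggregates, between 1 and the number of usable module
#'   columns.
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage Agglomeration method for [stats::hclust()]; default
#'   `"complete"`.
#' @param max_missing_frac Maximum tolerated fraction of missing responses
#'   per module column; columns above it (including all-missing columns)
#'   are excluded with a warning. Default 0.5.
#' @return An `aggregate_assignment`: data.frame with columns `module_id`
#'   and `aggregate`, attributes `k` and `tree` (the column hclust).
#' @export
build_aggregates <- function(fm, k, distance = "correlation",
                             linkage = "complete", max_missing_frac = 0.5) {
  mat <- unclass(fm)
  if (nrow(mat) < 2L) {
    stop("build_aggregates needs at least 2 reference cohorts")
  }
  miss_frac <- colMeans(is.na(mat))
  drop <- miss_frac > max_missing_frac
  if (any(drop)) {
    warning("Excluding ", sum(drop), " module column(s) with > ",
            max_missing_frac * 100, "% missing responses: ",
            paste(colnames(mat)[drop], collapse = ", "))
    mat <- mat[, !drop, drop = FALSE]
  }
  if (ncol(mat) < 1L) stop("No usable module columns remain")
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > ncol(mat)) {
    stop("k must be between 1 and the number of usable modules (",
         ncol(mat), ")")
  }
  k <- as.integer(k)
  if (ncol(mat) == 1L) {
    tree <- NULL
    cut <- stats::setNames(1L, colnames(mat))
    leaf_order <- colnames(mat)
  } else {
    tree <- stats::hclust(resolve_distance(mat, distance), method = linkage)
    cut <- stats::cutree(tree, k = k)
    leaf_order <- tree$labels[tree$order]
  }
  # relabel clusters positionally along the leaf ordering
  first_seen <- unique(cut[leaf_order])
  relabel <- stats::setNames(seq_along(first_seen), first_seen)
  assignment <- data.frame(
    module_id = names(cut),
    aggregate = paste0("A", relabel[as.character(cut)]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(assignment, "k") <- k
  attr(assignment, "tree") <- tree
  class(assignment) <- c("aggregate_assignment", "data.frame")
  assignment
}

#' Co-cluster a fingerprint matrix for heatmap ordering
#'
#' Independently clusters the cohort rows and module columns of a
#' fingerprint matrix (default: correlation distance, complete linkage) and
#' returns both leaf orderings with their trees — the ordering used to draw
#' clustered fingerprint heatmaps. A degenerate axis (a single row or
#' column) keeps its identity ordering with a warning.
#'
#' @param fm A `fingerprint_matrix`.
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage Agglomeration method; default `"complete"`.
#' @return A `cluster_ordering`: list with `row_order` and `col_order`
#'   (character vectors, permutations of the dimnames), `row_tree` and
#'   `col_tree` (hclust objects or NULL for degenerate axes).
#' @export
cocluster_matrix <- function(fm, distance = "correlation",
                             linkage = "complete") {
  mat <- unclass(fm)
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("fingerprint matrix must carry cohort and module dimnames")
  }
  cluster_axis <- function(m, axis) {
    if (nrow(m) < 2L) {
      warning("Degenerate ", axis, " axis (fewer than 2 entries); ",
              "keeping input order")
      return(list(order = rownames(m), tree = NULL))
    }
    tree <- stats::hclust(resolve_distance(t(m), distance), method = linkage)
    list(order = tree$labels[tree$order], tree = tree)
  }
  rows <- cluster_axis(mat, "row")
  cols <- cluster_axis(t(mat), "column")
  structure(
    list(row_order = rows$order, col_order = cols$order,
         row_tree = rows$tree, col_tree = cols$tree),
    class = "cluster_ordering"
  )
}

#' Serialise a cluster ordering to JSON (trees as Newick)
#'
#' @param ordering A `cluster_ordering` from [cocluster_matrix()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cluster_ordering <- function(ordering, path) {
  tree_newick <- function(tree) {
    if (is.null(tree)) return(NULL)
    ape::write.tree(ape::as.phylo(tree))
  }
  payload <- list(
    row_order = ordering$row_order,
    col_order = ordering$col_order,
    row_tree_newick = tree_newick(ordering$row_tree),
    col_tree_newick = tree_newick(ordering$col_tree)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Summarise a fingerprint at aggregate level
#'
#' Collapses module responses into per-aggregate statistics: the mean
#' signed response over member modules (missing, i.e. low-coverage,
#' entries excluded) and the counts of members responding at or beyond a
#' threshold, split by sign. An aggregate whose members are all missing is
#' marked missing rather than summarised.
#'
#' @param fp A `fingerprint`.
#' @param assignment An `aggregate_assignment` (or any data.frame with
#'   columns `module_id`, `aggregate`) covering the fingerprint's modules.
#' @param response_threshold Absolute response at or above which a member
#'   counts as responding; default 15.
#' @return data.frame with columns `aggregate`, `n_modules`, `mean_response`,
#'   `n_up`, `n_down`, `missing`.
#' @export
summarize_by_aggregate <- function(fp, assignment, response_threshold = 15) {
  stopifnot(response_threshold >= 0)
  uncovered <- setdiff(fp$module_id, assignment$module_id)
  if (length(uncovered) > 0L) {
    stop("Assignment does not cover module(s): ",
         paste(uncovered, collapse = ", "))
  }
  agg <- assignment$aggregate[match(fp$module_id, assignment$module_id)]
  res <- lapply(split(fp$response, agg), function(r) {
    obs <- r[!is.na(r)]
    if (length(obs) == 0L) {
      return(data.frame(n_modules = length(r), mean_response = NA_real_,
                        n_up = NA_integer_, n_down = NA_integer_,
                        missing = TRUE))
    }
    data.frame(
      n_modules = length(r),
      mean_response = mean(obs),
      n_up = sum(obs >= response_threshold),
      n_down = sum(obs <= -response_threshold),
      missing = FALSE
    )
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(aggregate = names(res), stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  out
}

#' Write an aggregate assignment as TSV
#'
#' @param assignment An `aggregate_assignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aggregate_assignment <- function(assignment, path) {
  utils::write.table(as.data.frame(assignment), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
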