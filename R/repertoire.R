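#' Read gene-set memberships from a GMT file
#'
#' GMT is the de-facto tab-separated gene-set exchange format: one set per
#' line, fields are set name, description, then one gene symbol per field.
#' Module memberships for a transcriptional module repertoire are exchanged
#' in this format so they remain reusable by other gene-set tools.
#'
#' Gene symbols are treated as opaque, case-sensitive strings; no identifier
#' mapping is attempted. Duplicate genes within one line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return Named list mapping module id to a character vector of unique gene
#'   symbols. The GMT description field is attached as the `"descriptions"`
#'   attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stop("GMT file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("GMT file is empty: ", path)
    out <- list()
    attr(out, "descriptions") <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields < 3L)
  if (length(bad) > 0L) {
    stop("Malformed GMT line (fewer than 3 tab-separated fields) at line ",
         paste(bad, collapse = ", "), " of ", path)
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("Duplicate module name(s) in GMT: ", paste(dup, collapse = ", "))
  }
  descriptions <- vapply(fields, `[[`, character(1), 2L)
  genes <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(genes) <- ids
  names(descriptions) <- ids
  attr(genes, "descriptions") <- descriptions
  genes
}

#' Write gene-set memberships to a GMT file
#'
#' @param genes Named list of character vectors (module id -> gene symbols).
#' @param path Output path.
#' @param descriptions Optional named character vector of per-set
#'   descriptions; sets without one get `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(genes, path, descriptions = NULL) {
  stopifnot(is.list(genes), !is.null(names(genes)))
  if (is.null(descriptions)) {
    descriptions <- attr(genes, "descriptions")
  }
  lines <- vapply(names(genes), function(id) {
    desc <- if (!is.null(descriptions) && id %in% names(descriptions)) {
      descriptions[[id]]
    } else {
      "na"
    }
    paste(c(id, desc, genes[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Parse "A35-3"-style grid positions into (aggregate, column). Strict: the
# fixed-grid interchange depends on bit-exact position strings.
parse_grid_position <- function(pos) {
  m <- regmatches(pos, regexec("^(A[0-9]+)-([0-9]+)$", pos))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("Unparseable grid position string(s): ",
         paste(unique(pos[bad]), collapse = ", "),
         " (expected e.g. \"A35-3\")")
  }
  data.frame(
    aggregate = vapply(m, `[[`, character(1), 2L),
    column = as.integer(vapply(m, `[[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
}

#' Read a module grid-layout/annotation table
#'
#' The layout table carries the fixed-grid semantics of a module repertoire:
#' each module's position string (aggregate row plus integer column, e.g.
#' `"A35-3"`), an optional declared transcript count, and an optional
#' free-text functional annotation. Expected as TSV with a header containing
#' at least `module_id` and `grid_position`; `n_transcripts` and
#' `annotation` are optional.
#'
#' @param path Path to the layout TSV.
#' @return A data.frame with columns `module_id`, `aggregate`, `column`,
#'   `n_transcripts` (integer, NA when absent), `annotation` (character, NA
#'   when absent).
#' @export
read_grid_layout <- function(path) {
  if (!file.exists(path)) {
    stop("Layout file not found: ", path)
  }
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  required <- c("module_id", "grid_position")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("Layout table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dup_id <- unique(tab$module_id[duplicated(tab$module_id)])
  if (length(dup_id) > 0L) {
    stop("Duplicate module id(s) in layout: ", paste(dup_id, collapse = ", "))
  }
  pos <- parse_grid_position(tab$grid_position)
  key <- paste(pos$aggregate, pos$column, sep = "-")
  dup_pos <- unique(key[duplicated(key)])
  if (length(dup_pos) > 0L) {
    stop("Duplicate grid position(s) in layout: ",
         paste(dup_pos, collapse = ", "))
  }
  layout <- data.frame(
    module_id = tab$module_id,
    aggregate = pos$aggregate,
    column = pos$column,
    n_transcripts = if ("n_transcripts" %in% names(tab)) {
      suppressWarnings(as.integer(tab$n_transcripts))
    } else {
      NA_integer_
    },
    annotation = if ("annotation" %in% names(tab)) {
      ifelse(nzchar(trimws(tab$annotation)), tab$annotation, NA_character_)
    } else {
      NA_character_
    },
    stringsAsFactors = FALSE
  )
  layout
}

#' Write a module grid-layout table
#'
#' Inverse of [read_grid_layout()]: serialises the layout columns of a
#' repertoire (or a bare layout data.frame) back to the
#' `module_id / grid_position / n_transcripts / annotation` TSV dialect.
#'
#' @param layout A `module_repertoire` or a layout data.frame with columns
#'   `module_id`, `aggregate`, `column` (plus optional `n_transcripts`,
#'   `annotation`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_layout <- function(layout, path) {
  if (inherits(layout, "module_repertoire")) {
    layout <- layout$layout
  }
  out <- data.frame(
    module_id = layout$module_id,
    grid_position = paste0(layout$aggregate, "-", layout$column),
    n_transcripts = if ("n_transcripts" %in% names(layout)) {
      layout$n_transcripts
    } else {
      NA_integer_
    },
    annotation = if ("annotation" %in% names(layout)) {
      layout$annotation
    } else {
      NA_character_
    },
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Assemble and validate a module repertoire
#'
#' Combines gene memberships (from [read_gmt()]) with a fixed grid layout
#' (from [read_grid_layout()]) into a validated `module_repertoire`. A
#' repertoire may be membership-free (layout only, `genes = NULL`): such
#' fixture repertoires describe the grid but cannot be used to fingerprint a
#' cohort. When both a declared transcript count and loaded memberships are
#' present and memberships are exhaustive, the two must agree.
#'
#' Validation enforces: unique module ids, unique (aggregate, column)
#' positions, columns contiguous from 1 within each aggregate, non-empty
#' gene sets for every module with memberships, and declared-size
#' consistency.
#'
#' @param genes Named list of gene vectors (module id -> genes), or `NULL`
#'   for a membership-free repertoire.
#' @param layout Layout data.frame as returned by [read_grid_layout()].
#' @param exhaustive Logical; `TRUE` (default) when memberships are the full
#'   module contents, `FALSE` when they are a representative subset (then
#'   declared sizes are not cross-checked against membership sizes).
#' @return An object of class `module_repertoire`: a list with elements
#'   `layout` (data.frame), `genes` (named list or `NULL`), `aggregates`
#'   (character vector, sorted), and `exhaustive` (logical).
#' @export
assemble_repertoire <- function(genes = NULL, layout, exhaustive = TRUE) {
  stopifnot(is.data.frame(layout))
  required <- c("module_id", "aggregate", "column")
  missing_cols <- setdiff(required, names(layout))
  if (length(missing_cols) > 0L) {
    stop("Layout is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  dup_id <- unique(layout$module_id[duplicated(layout$module_id)])
  if (length(dup_id) > 0L) {
    stop("Duplicate module id(s): ", paste(dup_id, collapse = ", "))
  }
  if (any(!nzchar(layout$module_id))) {
    stop("Empty module id in layout")
  }
  key <- paste(layout$aggregate, layout$column, sep = "-")
  dup_pos <- unique(key[duplicated(key)])
  if (length(dup_pos) > 0L) {
    stop("Two modules share a grid position: ",
         paste(dup_pos, collapse = ", "))
  }
  for (agg in unique(layout$aggregate)) {
    cols <- sort(layout$column[layout$aggregate == agg])
    if (!identical(cols, seq_along(cols))) {
      stop("Columns within aggregate ", agg,
           " are not contiguous from 1: ", paste(cols, collapse = ", "))
    }
  }
  if (!is.null(genes)) {
    unknown <- setdiff(names(genes), layout$module_id)
    if (length(unknown) > 0L) {
      stop("Gene sets supplied for module(s) absent from the layout: ",
           paste(unknown, collapse = ", "))
    }
    no_members <- setdiff(layout$module_id, names(genes))
    if (length(no_members) > 0L) {
      stop("Layout module(s) have no gene set: ",
           paste(no_members, collapse = ", "),
           " (pass genes = NULL for a membership-free repertoire)")
    }
    sizes <- vapply(genes, function(g) length(unique(g)), integer(1))
    if (any(sizes == 0L)) {
      stop("Empty gene set for module(s): ",
           paste(names(genes)[sizes == 0L], collapse = ", "))
    }
    genes <- lapply(genes, unique)
    if (exhaustive && "n_transcripts" %in% names(layout)) {
      declared <- layout$n_transcripts[match(names(genes), layout$module_id)]
      mismatch <- !is.na(declared) & declared != sizes
      if (any(mismatch)) {
        offenders <- paste0(names(genes)[mismatch], " (declared ",
                            declared[mismatch], ", loaded ",
                            sizes[mismatch], ")")
        stop("Declared transcript count does not match loaded membership for: ",
             paste(offenders, collapse = "; "))
      }
    }
    genes <- genes[layout$module_id]
  }
  structure(
    list(
      layout = layout,
      genes = genes,
      aggregates = sort(unique(layout$aggregate)),
      exhaustive = exhaustive
    ),
    class = "module_repertoire"
  )
}

#' @export
print.module_repertoire <- function(x, ...) {
  cat("Module repertoire:", nrow(x$layout), "modules in",
      length(x$aggregates), "aggregate(s)\n")
  if (is.null(x$genes)) {
    cat("  memberships: none (layout-only repertoire)\n")
  } else {
    n_genes <- length(unique(unlist(x$genes)))
    cat("  memberships:", n_genes, "unique genes",
        if (x$exhaustive) "(exhaustive)" else "(representative subset)", "\n")
  }
  cat("  aggregates:", paste(x$aggregates, collapse = ", "), "\n")
  invisible(x)
}

#' Load the packaged A35 repertoire fixture
#'
#' Ships the 21 inflammation-associated modules of aggregate A35 as a small
#' built-in repertoire: grid positions A35-1 through A35-21, declared
#' transcript counts (summing to 784), functional annotations, and the
#' published representative genes as partial memberships. The gene sets are
#' flagged non-exhaustive (`exhaustive = FALSE`): they are the handful of
#' representative symbols per module, not the full module contents, so
#' declared sizes are deliberately larger than the loaded sets. Full
#' repertoire memberships are user-supplied via [read_gmt()].
#'
#' @return A `module_repertoire` of 21 modules in aggregate A35.
#' @export
load_packaged_a35 <- function() {
  path <- system.file("extdata", "a35_modules.tsv", package = "txfingerprint",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  pos <- parse_grid_position(tab$grid_position)
  layout <- data.frame(
    module_id = tab$module_id,
    aggregate = pos$aggregate,
    column = pos$column,
    n_transcripts = as.integer(tab$n_transcripts),
    annotation = tab$annotation,
    stringsAsFactors = FALSE
  )
  genes <- lapply(strsplit(tab$representative_genes, ",", fixed = TRUE),
                  function(g) unique(trimws(g)))
  names(genes) <- tab$module_id
  assemble_repertoire(genes = genes, layout = layout, exhaustive = FALSE)
}
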