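#' Percent-response of one module, with dominant-trend retention
#'
#' Summarises a module's per-transcript direction calls as a signed percent
#' response. With `n_detected` members present in the direction table,
#' `percent_up` is 100 times the fraction of detected members called +1 and
#' `percent_down` the fraction called -1. The module's signed response
#' retains the dominant trend: `+percent_up` when increases dominate,
#' `-percent_down` when decreases dominate. When both percentages are equal
#' and non-zero, the direction whose significant members carry the larger
#' summed |log2 fold change| wins; an exact tie yields 0. Modules with
#' fewer than `min_coverage_genes` detected members are flagged
#' low-coverage and their response left undefined (NA) rather than reported
#' as a percentage of too few genes.
#'
#' @param dirs A `direction_table` from [call_directions()].
#' @param members Character vector of the module's gene symbols.
#' @param module_id Module identifier used in the output row.
#' @param min_coverage_genes Minimum detected members needed for a defined
#'   response; default 5.
#' @return One-row data.frame with columns `module_id`, `n_members`,
#'   `n_detected`, `coverage`, `percent_up`, `percent_down`, `response`,
#'   `low_coverage`.
#' @export
module_response <- function(dirs, members, module_id = "module",
                            min_coverage_genes = 5L) {
  stopifnot(is.character(members))
  members <- unique(members)
  if (length(members) == 0L) {
    stop("Module ", module_id, " has no gene memberships loaded")
  }
  hit <- dirs[dirs$gene %in% members, , drop = FALSE]
  n_members <- length(members)
  n_detected <- nrow(hit)
  base <- data.frame(
    module_id = module_id,
    n_members = n_members,
    n_detected = n_detected,
    coverage = n_detected / n_members,
    stringsAsFactors = FALSE
  )
  if (n_detected < min_coverage_genes) {
    return(cbind(base, data.frame(percent_up = NA_real_,
                                  percent_down = NA_real_,
                                  response = NA_real_,
                                  low_coverage = TRUE)))
  }
  percent_up <- 100 * sum(hit$direction == 1L) / n_detected
  percent_down <- 100 * sum(hit$direction == -1L) / n_detected
  if (percent_up > percent_down) {
    response <- percent_up
  } else if (percent_down > percent_up) {
    response <- -percent_down
  } else if (percent_up == 0) {
    response <- 0
  } else {
    # tie with both trends present: effect-size evidence decides
    up_mass <- sum(abs(hit$log2fc[hit$direction == 1L]))
    down_mass <- sum(abs(hit$log2fc[hit$direction == -1L]))
    response <- if (up_mass > down_mass) {
      percent_up
    } else if (down_mass > up_mass) {
      -percent_down
    } else {
      0
    }
  }
  cbind(base, data.frame(percent_up = percent_up,
                         percent_down = percent_down,
                         response = response,
                         low_coverage = FALSE))
}

#' Fingerprint one case/control cohort against a module repertoire
#'
#' Runs the full group-level pipeline for one cohort: abundance transform,
#' per-transcript direction calls, then the percent-response of every
#' module in the repertoire. Every module of the repertoire appears in the
#' output; modules with too few detected members are flagged low-coverage,
#' not dropped, so fingerprints built on different platforms stay
#' comparable position by position.
#'
#' @param expr Numeric genes-by-samples matrix.
#' @param groups Sample-to-group assignment (see [call_directions()]).
#' @param repertoire A `module_repertoire` with loaded gene memberships.
#' @param cfg A [diff_config()].
#' @param cohort Cohort label attached to the fingerprint.
#' @param min_coverage_genes Low-coverage floor passed to
#'   [module_response()].
#' @return A `fingerprint`: data.frame with one row per module (columns
#'   `module_id`, `aggregate`, `column`, `n_members`, `n_detected`,
#'   `coverage`, `percent_up`, `percent_down`, `response`,
#'   `low_coverage`), with attributes `cohort`, `config`, and
#'   `min_coverage_genes`.
#' @export
fingerprint_cohort <- function(expr, groups, repertoire,
                               cfg = diff_config(), cohort = "cohort",
                               min_coverage_genes = 5L) {
  stopifnot(inherits(repertoire, "module_repertoire"))
  if (is.null(repertoire$genes)) {
    stop("fingerprint_cohort: repertoire has no gene memberships loaded")
  }
  dirs <- tryCatch(
    call_directions(expr, groups, cfg),
    error = function(e) stop("call_directions: ", conditionMessage(e),
                             call. = FALSE)
  )
  rows <- lapply(seq_len(nrow(repertoire$layout)), function(i) {
    id <- repertoire$layout$module_id[i]
    tryCatch(
      module_response(dirs, repertoire$genes[[id]], module_id = id,
                      min_coverage_genes = min_coverage_genes),
      error = function(e) stop("module_response: ", conditionMessage(e),
                               call. = FALSE)
    )
  })
  fp <- do.call(rbind, rows)
  fp <- cbind(
    fp[, "module_id", drop = FALSE],
    repertoire$layout[, c("aggregate", "column")],
    fp[, setdiff(names(fp), "module_id")]
  )
  rownames(fp) <- NULL
  attr(fp, "cohort") <- cohort
  attr(fp, "config") <- cfg
  attr(fp, "min_coverage_genes") <- as.integer(min_coverage_genes)
  class(fp) <- c("fingerprint", "data.frame")
  fp
}

#' Stack cohort fingerprints into a cohorts x modules matrix
#'
#' Builds the cross-cohort comparison object: one row per cohort, one
#' column per module, entries the signed percent responses. All
#' fingerprints must cover the same module set (checked by id-set
#' equality); low-coverage responses are carried as NA, never zero-filled,
#' because "no information" and "no change" are different statements.
#'
#' @param fps List of `fingerprint` objects. Cohort row labels come from
#'   each fingerprint's `cohort` attribute (list names win when present).
#' @return A `fingerprint_matrix`: numeric matrix, rows cohorts in input
#'   order, columns modules in the first fingerprint's order.
#' @export
stack_fingerprints <- function(fps) {
  stopifnot(is.list(fps), length(fps) >= 1L)
  ref_ids <- fps[[1]]$module_id
  for (i in seq_along(fps)) {
    ids <- fps[[i]]$module_id
    if (!setequal(ids, ref_ids)) {
      extra <- setdiff(ids, ref_ids)
      missing <- setdiff(ref_ids, ids)
      stop("Fingerprint ", i, " covers a different module set; ",
           "only in it: {", paste(extra, collapse = ", "),
           "}; missing from it: {", paste(missing, collapse = ", "), "}")
    }
  }
  labels <- vapply(seq_along(fps), function(i) {
    nm <- names(fps)[i]
    if (!is.null(nm) && nzchar(nm)) nm
    else as.character(attr(fps[[i]], "cohort") %||% paste0("cohort", i))
  }, character(1))
  mat <- do.call(rbind, lapply(fps, function(fp) {
    fp$response[match(ref_ids, fp$module_id)]
  }))
  dimnames(mat) <- list(labels, ref_ids)
  class(mat) <- c("fingerprint_matrix", class(mat))
  mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a fingerprint as TSV with a JSON provenance sidecar
#'
#' The TSV carries one row per module; the sidecar (`<path>.json`) records
#' the cohort label, the full direction-calling config, the low-coverage
#' floor, and MD5 checksums of any input files supplied.
#'
#' @param fp A `fingerprint`.
#' @param path Output TSV path; the sidecar goes to `paste0(path, ".json")`.
#' @param input_files Optional character vector of input paths to checksum
#'   into the sidecar.
#' @return `path`, invisibly.
#' @export
write_fingerprint <- function(fp, path, input_files = character(0)) {
  utils::write.table(as.data.frame(fp), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  sidecar <- list(
    cohort = attr(fp, "cohort"),
    config = unclass(attr(fp, "config")),
    min_coverage_genes = attr(fp, "min_coverage_genes"),
    package_version = as.character(utils::packageVersion("txfingerprint")),
    input_checksums = as.list(tools::md5sum(input_files))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a fingerprint TSV written by [write_fingerprint()]
#'
#' @param path Path to the fingerprint TSV.
#' @return A `fingerprint` data.frame. If the JSON sidecar is present the
#'   cohort label is restored from it.
#' @export
read_fingerprint <- function(path) {
  fp <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    attr(fp, "cohort") <- meta$cohort
  }
  class(fp) <- c("fingerprint", "data.frame")
  fp
}

#' Write a fingerprint matrix as TSV (missing entries as "NA")
#'
#' @param fm A `fingerprint_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fingerprint_matrix <- function(fm, path) {
  out <- data.frame(cohort = rownames(fm), unclass(fm), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a fingerprint matrix TSV
#'
#' @param path Path written by [write_fingerprint_matrix()].
#' @return A `fingerprint_matrix`.
#' @export
read_fingerprint_matrix <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- as.character(tab[[1]])
  storage.mode(mat) <- "double"
  class(mat) <- c("fingerprint_matrix", class(mat))
  mat
}
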