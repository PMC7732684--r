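#' Configuration for per-transcript direction calling
#'
#' Bundles the statistical choices behind the "significantly increased /
#' decreased" gate applied per transcript: the two-sample test, the
#' significance level, the multiplicity correction, an optional absolute
#' log2 fold-change floor, and an optional log transform for linear-scale
#' RNA-seq abundances (RPKM-like). All defaults are deliberate but
#' configurable, and the config travels with every downstream result for
#' provenance.
#'
#' @param test Two-sample test: `"welch_t"` (default), `"student_t"`, or
#'   `"wilcoxon"` (rank-sum). Two-sided in all cases.
#' @param alpha Significance level applied to the (adjusted) p-value, in
#'   (0, 1]. Default 0.05.
#' @param multiplicity `"bh"` (Benjamini-Hochberg step-up FDR, default) or
#'   `"none"` (q = p).
#' @param min_abs_log2fc Non-negative absolute log2 fold-change floor a
#'   transcript must additionally clear to be called; default 0.5.
#' @param rnaseq_transform `"none"` (input already log2-like, default) or
#'   `"log2_plus1"` (apply log2(x + 1) to non-negative linear-scale input).
#' @param group_labels Length-2 named character vector mapping the labels
#'   used in the metadata to the roles `case` and `control`; matching is
#'   case-insensitive. Default `c(case = "case", control = "control")`.
#' @return An object of class `diff_config`.
#' @export
diff_config <- function(test = c("welch_t", "student_t", "wilcoxon"),
                        alpha = 0.05,
                        multiplicity = c("bh", "none"),
                        min_abs_log2fc = 0.5,
                        rnaseq_transform = c("none", "log2_plus1"),
                        group_labels = c(case = "case", control = "control")) {
  test <- match.arg(test)
  multiplicity <- match.arg(multiplicity)
  rnaseq_transform <- match.arg(rnaseq_transform)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1)
  stopifnot(is.numeric(min_abs_log2fc), length(min_abs_log2fc) == 1L,
            min_abs_log2fc >= 0)
  if (!all(c("case", "control") %in% names(group_labels))) {
    stop("group_labels must name both 'case' and 'control'")
  }
  structure(
    list(test = test, alpha = alpha, multiplicity = multiplicity,
         min_abs_log2fc = min_abs_log2fc,
         rnaseq_transform = rnaseq_transform,
         group_labels = group_labels),
    class = "diff_config"
  )
}

#' @export
print.diff_config <- function(x, ...) {
  cat("Direction-calling config:\n")
  cat("  test:", x$test, " alpha:", x$alpha,
      " multiplicity:", x$multiplicity, "\n")
  cat("  min |log2FC|:", x$min_abs_log2fc,
      " transform:", x$rnaseq_transform, "\n")
  invisible(x)
}

check_expression_matrix <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("Expression input must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("Expression matrix must carry gene row names and sample column names")
  }
  if (anyDuplicated(rownames(expr))) {
    stop("Duplicate gene ids in expression matrix")
  }
  if (anyDuplicated(colnames(expr))) {
    stop("Duplicate sample ids in expression matrix")
  }
  if (any(!is.finite(expr))) {
    stop("Expression matrix contains non-finite values; ",
         "impute or filter upstream")
  }
  invisible(expr)
}

#' Transform an expression matrix ahead of testing
#'
#' Applies the configured abundance transform: `log2_plus1` maps linear
#' RNA-seq abundances x to log2(x + 1) so t-statistics are computed on the
#' same log2-like scale as microarray intensities; `none` passes the matrix
#' through unchanged. Labels are preserved.
#'
#' @param expr Numeric genes-by-samples matrix with dimnames.
#' @param cfg A [diff_config()].
#' @return The transformed matrix.
#' @export
preprocess_expression <- function(expr, cfg = diff_config()) {
  check_expression_matrix(expr)
  if (cfg$rnaseq_transform == "log2_plus1") {
    if (any(expr < 0)) {
      stop("log2_plus1 transform requires non-negative values")
    }
    expr[] <- log2(expr + 1)
  }
  expr
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' In-house implementation of the BH step-up procedure: with p-values sorted
#' ascending and m = length(p), q for the i-th sorted value is
#' min over j >= i of m * p_(j) / j, clipped to 1, reported back in input
#' order. Guarantees the monotone step-up property.
#'
#' @param p Numeric vector of p-values, all in \[0, 1\].
#' @return Numeric vector of q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must all lie in [0, 1]")
  }
  m <- length(p)
  ord <- order(p)
  ranked <- m * p[ord] / seq_len(m)
  q_sorted <- rev(cummin(rev(ranked)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Vectorised row-wise two-sample tests. Rows are genes; x and y are the
# case and control sub-matrices. Degenerate rows (zero variance in both
# groups) get the limit p-value: 1 if the means agree, 0 otherwise.
row_t_test <- function(x, y, pooled = FALSE) {
  n1 <- ncol(x)
  n2 <- ncol(y)
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2, length(m1))
  } else {
    a1 <- v1 / n1
    a2 <- v2 / n2
    se <- sqrt(a1 + a2)
    df <- (a1 + a2)^2 / (a1^2 / (n1 - 1) + a2^2 / (n2 - 1))
  }
  p <- ifelse(se > 0,
              2 * stats::pt(-abs((m1 - m2) / se), df),
              ifelse(m1 == m2, 1, 0))
  list(mean_case = m1, mean_control = m2, p = unname(p))
}

row_wilcoxon <- function(x, y) {
  p <- vapply(seq_len(nrow(x)), function(i) {
    if (all(x[i, ] == x[i, 1]) && all(y[i, ] == y[i, 1])) {
      # degenerate constant rows: same limit rule as the t tests
      return(if (x[i, 1] == y[i, 1]) 1 else 0)
    }
    suppressWarnings(
      stats::wilcox.test(x[i, ], y[i, ], alternative = "two.sided")$p.value
    )
  }, numeric(1))
  list(mean_case = rowMeans(x), mean_control = rowMeans(y), p = p)
}

resolve_groups <- function(expr, groups, cfg) {
  if (is.data.frame(groups)) {
    if (!all(c("sample_id", "group") %in% names(groups))) {
      stop("Group metadata needs columns 'sample_id' and 'group'")
    }
    labels <- stats::setNames(as.character(groups$group),
                              as.character(groups$sample_id))
  } else if (!is.null(names(groups))) {
    labels <- stats::setNames(as.character(groups), names(groups))
  } else {
    stop("groups must be a data.frame(sample_id, group) or a named vector")
  }
  missing_samples <- setdiff(names(labels), colnames(expr))
  if (length(missing_samples) > 0L) {
    stop("Labeled sample(s) absent from the expression matrix: ",
         paste(missing_samples, collapse = ", "))
  }
  lab_lower <- tolower(labels)
  case_ids <- names(labels)[lab_lower == tolower(cfg$group_labels[["case"]])]
  control_ids <-
    names(labels)[lab_lower == tolower(cfg$group_labels[["control"]])]
  unmatched <- setdiff(names(labels), c(case_ids, control_ids))
  if (length(unmatched) > 0L) {
    stop("Sample(s) with group label matching neither case nor control: ",
         paste(unmatched, collapse = ", "))
  }
  if (length(case_ids) < 2L || length(control_ids) < 2L) {
    stop("Each group needs at least 2 samples (found ",
         length(case_ids), " case, ", length(control_ids), " control)")
  }
  list(case = case_ids, control = control_ids)
}

#' Call per-transcript direction of change between cases and controls
#'
#' For every gene, compares cases against controls with the configured
#' two-sample test and emits a three-valued direction call: +1
#' (significantly increased), -1 (significantly decreased), or 0. A gene is
#' called only when its adjusted p-value is at most `alpha` and its
#' |log2 fold change| clears `min_abs_log2fc`; the sign of the call is the
#' sign of the fold change. The fold change is mean(case) - mean(control)
#' on the (post-transform) log2-like scale.
#'
#' @param expr Numeric genes-by-samples matrix (already on a log2-like
#'   scale, or transformed here per `cfg$rnaseq_transform`).
#' @param groups Sample-to-group assignment: a data.frame with columns
#'   `sample_id` and `group`, or a named character vector. Labels are
#'   matched case-insensitively to `cfg$group_labels`.
#' @param cfg A [diff_config()].
#' @return A `direction_table`: data.frame with columns `gene`,
#'   `mean_case`, `mean_control`, `log2fc`, `p`, `q`, `direction`, one row
#'   per gene in the input row order, with the config attached as the
#'   `"config"` attribute.
#' @export
call_directions <- function(expr, groups, cfg = diff_config()) {
  expr <- preprocess_expression(expr, cfg)
  grp <- resolve_groups(expr, groups, cfg)
  x <- expr[, grp$case, drop = FALSE]
  y <- expr[, grp$control, drop = FALSE]
  res <- switch(cfg$test,
    welch_t = row_t_test(x, y, pooled = FALSE),
    student_t = row_t_test(x, y, pooled = TRUE),
    wilcoxon = row_wilcoxon(x, y)
  )
  log2fc <- unname(res$mean_case - res$mean_control)
  q <- if (cfg$multiplicity == "bh") bh_adjust(res$p) else res$p
  direction <- integer(length(log2fc))
  hit <- q <= cfg$alpha & abs(log2fc) >= cfg$min_abs_log2fc
  direction[hit] <- sign(log2fc[hit])
  out <- data.frame(
    gene = rownames(expr),
    mean_case = unname(res$mean_case),
    mean_control = unname(res$mean_control),
    log2fc = log2fc,
    p = res$p,
    q = q,
    direction = as.integer(direction),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(out, "config") <- cfg
  class(out) <- c("direction_table", "data.frame")
  out
}

#' Read an expression matrix from delimited text
#'
#' Genes as rows, first column gene symbols, remaining columns one per
#' sample with sample ids in the header. Tab- or comma-separated, inferred
#' from the file extension (`.csv` means comma).
#'
#' @param path Path to the matrix file.
#' @return Numeric genes-by-samples matrix with dimnames.
#' @export
read_expression_matrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    stop("Non-numeric expression values in ", path)
  }
  rownames(mat) <- as.character(tab[[1]])
  check_expression_matrix(mat)
}

#' Write an expression matrix as TSV
#'
#' @param expr Numeric genes-by-samples matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  out <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-group assignment table
#'
#' TSV with columns `sample_id` and `group`.
#'
#' @param path Path to the metadata TSV.
#' @return data.frame with columns `sample_id`, `group`.
#' @export
read_group_assignment <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(tab))) {
    stop("Group metadata needs columns 'sample_id' and 'group': ", path)
  }
  tab[, c("sample_id", "group")]
}

#' Write a direction table as TSV
#'
#' @param dirs A `direction_table` from [call_directions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_direction_table <- function(dirs, path) {
  utils::write.table(dirs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
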