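test_that("bh_adjust matches the step-up definition and stats::p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(11)
  for (i in 1:50) {
    p <- stats::runif(sample(1:200, 1))
    expect_identical(bh_adjust(p), bh_oracle(p))
    expect_equal(bh_adjust(p), stats::p.adjust(p, method = "BH"))
  }
})

test_that("preprocess applies log2(x+1) only on request and guards sign", {
  mat <- matrix(c(0, 7, 3, 1), nrow = 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  out <- preprocess_expression(mat, diff_config(rnaseq_transform = "log2_plus1"))
  expect_equal(out["g1", "s1"], 0)   # log2(0 + 1)
  expect_equal(out["g2", "s1"], 3)   # log2(7 + 1)
  expect_identical(preprocess_expression(mat, diff_config()), mat)
  mat[1, 1] <- -1
  expect_error(
    preprocess_expression(mat, diff_config(rnaseq_transform = "log2_plus1")),
    "non-negative"
  )
})

test_that("call_directions agrees with per-gene t.test and calls planted shifts", {
  sim <- two_group_matrix(delta = c(2, 0, -1.5, 0.05, 0), n_case = 20L,
                          n_control = 20L, sd = 0.5, seed = 7)
  cfg <- diff_config(alpha = 0.05, min_abs_log2fc = 0.5)
  dirs <- call_directions(sim$expr, sim$groups, cfg)
  expect_identical(dirs$gene, rownames(sim$expr))

  # independent oracle: stats::t.test per gene on the same draws
  for (i in seq_len(nrow(sim$expr))) {
    tt <- stats::t.test(sim$expr[i, 1:20], sim$expr[i, 21:40],
                        var.equal = FALSE)
    expect_equal(dirs$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(dirs$log2fc[i],
                 unname(tt$estimate[1] - tt$estimate[2]),
                 tolerance = 1e-12)
  }
  expect_identical(dirs$direction[1], 1L)   # +2 sd shift
  expect_identical(dirs$direction[3], -1L)  # -1.5 shift
  expect_identical(dirs$direction[2], 0L)   # null gene
  expect_identical(dirs$direction[4], 0L)   # below the fold-change floor

  # student_t path against the pooled-variance oracle
  dirs_s <- call_directions(sim$expr, sim$groups,
                            diff_config(test = "student_t"))
  tt <- stats::t.test(sim$expr[1, 1:20], sim$expr[1, 21:40], var.equal = TRUE)
  expect_equal(dirs_s$p[1], tt$p.value, tolerance = 1e-12)

  # wilcoxon path against the rank-sum oracle
  dirs_w <- call_directions(sim$expr, sim$groups,
                            diff_config(test = "wilcoxon"))
  ww <- stats::wilcox.test(sim$expr[1, 1:20], sim$expr[1, 21:40])
  expect_equal(dirs_w$p[1], ww$p.value, tolerance = 1e-12)
})

test_that("identical groups give log2fc 0 and direction 0", {
  mat <- matrix(rep(c(5, 8, 2), each = 8), nrow = 3, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:8)))
  groups <- data.frame(sample_id = sprintf("s%d", 1:8),
                       group = rep(c("case", "control"), each = 4))
  dirs <- call_directions(mat, groups)
  expect_equal(dirs$log2fc, c(0, 0, 0))
  expect_identical(dirs$direction, c(0L, 0L, 0L))
  expect_equal(dirs$p, c(1, 1, 1))  # degenerate rule: equal constant rows
})

test_that("degenerate zero-variance genes never produce NaN", {
  mat <- rbind(g1 = c(1, 1, 1, 2, 2, 2),
               g2 = c(3, 3, 3, 3, 3, 3))
  colnames(mat) <- sprintf("s%d", 1:6)
  groups <- data.frame(sample_id = colnames(mat),
                       group = rep(c("case", "control"), each = 3))
  for (test in c("welch_t", "student_t", "wilcoxon")) {
    dirs <- call_directions(mat, groups, diff_config(test = test,
                                                     multiplicity = "none"))
    expect_false(any(is.na(dirs$p)), info = test)
    expect_equal(dirs$p[1], 0, info = test)  # means differ, no variance
    expect_equal(dirs$p[2], 1, info = test)  # identical constants
  }
})

test_that("an alpha no gene can meet zeroes every direction", {
  sim <- two_group_matrix(delta = c(3, -3, 2), seed = 3)
  dirs <- call_directions(sim$expr, sim$groups,
                          diff_config(alpha = 1e-300))
  expect_identical(unique(dirs$direction), 0L)
})

test_that("label swap negates log2fc and direction, keeps p", {
  sim <- two_group_matrix(delta = c(2, 0, -1, 0.4, 0.7), seed = 5)
  swapped <- sim$groups
  swapped$group <- ifelse(swapped$group == "case", "control", "case")
  cfg <- diff_config()
  d1 <- call_directions(sim$expr, sim$groups, cfg)
  d2 <- call_directions(sim$expr, swapped, cfg)
  expect_equal(d2$log2fc, -d1$log2fc)
  expect_identical(d2$direction, -d1$direction)
  expect_equal(d2$p, d1$p, tolerance = 1e-12)
})

test_that("row and column order do not affect the calls", {
  sim <- two_group_matrix(delta = c(2, 0, -1, 0.4), seed = 9)
  cfg <- diff_config()
  d1 <- call_directions(sim$expr, sim$groups, cfg)
  set.seed(1)
  rperm <- sample(nrow(sim$expr))
  cperm <- sample(ncol(sim$expr))
  d2 <- call_directions(sim$expr[rperm, cperm], sim$groups, cfg)
  d2 <- d2[match(d1$gene, d2$gene), ]
  expect_equal(d2$p, d1$p, tolerance = 1e-12)
  expect_identical(d2$direction, d1$direction)
})

test_that("group validation rejects tiny or mislabeled designs", {
  sim <- two_group_matrix(delta = c(1, 0), seed = 2)
  one_case <- sim$groups[c(1, 11:20), ]
  expect_error(call_directions(sim$expr, one_case, diff_config()),
               "at least 2 samples")
  bad_label <- sim$groups
  bad_label$group[1] <- "patient"
  expect_error(call_directions(sim$expr, bad_label, diff_config()),
               "neither case nor control")
  ghost <- rbind(sim$groups,
                 data.frame(sample_id = "nope", group = "case"))
  expect_error(call_directions(sim$expr, ghost, diff_config()),
               "absent from the expression matrix")
})

test_that("null simulation stays within the binomial false-positive band", {
  set.seed(21)
  n_genes <- 2000L
  mat <- matrix(stats::rnorm(n_genes * 30, 8, 0.5), nrow = n_genes,
                dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                sprintf("s%02d", 1:30)))
  groups <- data.frame(sample_id = colnames(mat),
                       group = rep(c("case", "control"), each = 15))
  alpha <- 0.05
  raw <- call_directions(mat, groups,
                         diff_config(alpha = alpha, multiplicity = "none",
                                     min_abs_log2fc = 0))
  frac <- mean(raw$direction != 0L)
  tol <- 3 * sqrt(alpha * (1 - alpha) / n_genes)
  expect_lt(abs(frac - alpha), tol)

  gated <- call_directions(mat, groups,
                           diff_config(alpha = alpha, multiplicity = "bh",
                                       min_abs_log2fc = 0.5))
  expect_lt(mean(gated$direction != 0L), 0.002)
})

test_that("expression and group tables round-trip through their TSV dialects", {
  sim <- two_group_matrix(delta = c(1, 0, 2), seed = 4)
  ep <- withr::local_tempfile(fileext = ".tsv")
  gp <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(sim$expr, ep)
  utils::write.table(sim$groups, gp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_equal(read_expression_matrix(ep), sim$expr, tolerance = 1e-9)
  expect_identical(read_group_assignment(gp), sim$groups)
})
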