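test_that("module_response follows the percent/dominant-trend definition", {
  dirs <- data.frame(
    gene = sprintf("G%02d", 1:10),
    mean_case = 0, mean_control = 0,
    log2fc = c(rep(1, 6), -1, rep(0, 3)),
    p = 0.01, q = 0.01,
    direction = c(rep(1L, 6), -1L, rep(0L, 3)),
    stringsAsFactors = FALSE
  )
  r <- module_response(dirs, dirs$gene, "Mx")
  expect_equal(r$percent_up, 60)
  expect_equal(r$percent_down, 10)
  expect_equal(r$response, 60)
  expect_false(r$low_coverage)

  none <- dirs
  none$direction <- 0L
  expect_equal(module_response(none, none$gene, "Mx")$response, 0)
})

test_that("the tie rule uses summed |log2fc| and breaks exact ties to zero", {
  # 5 up vs 5 down of 10; up carries more fold-change mass
  dirs <- data.frame(
    gene = sprintf("G%02d", 1:10),
    mean_case = 0, mean_control = 0,
    log2fc = c(2, 2, 2, 2, 2, -1, -1, -1, -1, -1),
    p = 0.01, q = 0.01,
    direction = rep(c(1L, -1L), each = 5),
    stringsAsFactors = FALSE
  )
  expect_equal(module_response(dirs, dirs$gene, "Mx")$response, 50)
  # enumerate both masses: up 10, down 5 -> up dominates
  expect_equal(sum(abs(dirs$log2fc[dirs$direction == 1])), 10)
  expect_equal(sum(abs(dirs$log2fc[dirs$direction == -1])), 5)

  dirs$log2fc <- rep(c(1.5, -1.5), each = 5)  # exact tie in mass
  expect_equal(module_response(dirs, dirs$gene, "Mx")$response, 0)

  dirs$log2fc <- rep(c(1, -2), each = 5)      # down mass dominates
  expect_equal(module_response(dirs, dirs$gene, "Mx")$response, -50)
})

test_that("low-coverage modules are flagged, never divided by zero", {
  dirs <- random_direction_table(50)
  r0 <- module_response(dirs, c("ZZZ1", "ZZZ2"), "Mmissing")
  expect_true(r0$low_coverage)
  expect_identical(r0$n_detected, 0L)
  expect_true(is.na(r0$response))

  r4 <- module_response(dirs, dirs$gene[1:4], "Msmall",
                        min_coverage_genes = 5L)
  expect_true(r4$low_coverage)
  r4b <- module_response(dirs, dirs$gene[1:4], "Msmall",
                         min_coverage_genes = 3L)
  expect_false(r4b$low_coverage)
})

test_that("module_response agrees with a brute-force recount and is antisymmetric", {
  set.seed(31)
  for (i in 1:100) {
    dirs <- random_direction_table(sample(6:40, 1))
    members <- sample(dirs$gene, sample(5:nrow(dirs), 1))
    got <- module_response(dirs, members, "Mx")
    want <- recount_oracle(dirs, members)
    expect_identical(got$percent_up, want$percent_up)
    expect_identical(got$percent_down, want$percent_down)
    expect_identical(got$response, want$response)
    swapped <- module_response(swap_direction_table(dirs), members, "Mx")
    expect_identical(swapped$response, -got$response)
  }
})

test_that("fingerprint_cohort recovers a fully planted module and stays null elsewhere", {
  toy <- toy_repertoire(n_modules = 4L, module_size = 20L)
  spec <- synthetic_cohort_spec(toy, n_cases = 30L, n_controls = 30L,
                                effects = list(planted_effect("M2", 1, 4)),
                                background_genes = 300L, seed = 17L)
  sim <- generate_cohort(spec)
  fp <- fingerprint_cohort(sim$expr, sim$groups, toy, cohort = "sim")
  expect_s3_class(fp, "fingerprint")
  expect_identical(fp$module_id, toy$layout$module_id)
  planted <- fp$response[fp$module_id == "M2"]
  expect_gte(planted, 90)  # per-gene power ~ 1 at +4 sd, n = 30/30
  expect_true(all(abs(fp$response[fp$module_id != "M2"]) <= 10))

  # null cohort: permuting labels within one pooled group
  null_groups <- sim$groups
  null_groups$group <- rep(c("case", "control"),
                           length.out = nrow(null_groups))
  fp_null <- fingerprint_cohort(sim$expr, null_groups, toy)
  expect_true(all(abs(fp_null$response) <= 10))

  # determinism: bit-identical rerun
  fp2 <- fingerprint_cohort(sim$expr, sim$groups, toy, cohort = "sim")
  expect_identical(as.data.frame(fp), as.data.frame(fp2))
})

test_that("fingerprints refuse membership-free repertoires", {
  layout <- data.frame(module_id = "M1", aggregate = "A1", column = 1L)
  bare <- assemble_repertoire(NULL, layout)
  sim <- two_group_matrix(delta = 1, seed = 1)
  expect_error(fingerprint_cohort(sim$expr, sim$groups, bare),
               "no gene memberships")
})

test_that("stack_fingerprints aligns module sets and keeps NA for low coverage", {
  toy <- toy_repertoire(n_modules = 3L, module_size = 8L)
  spec <- synthetic_cohort_spec(toy, n_cases = 10L, n_controls = 10L,
                                effects = list(planted_effect("M1", 1, 5)),
                                background_genes = 50L, seed = 5L)
  sim <- generate_cohort(spec)
  fp <- fingerprint_cohort(sim$expr, sim$groups, toy, cohort = "c1")
  # drop one module's genes from the matrix to force low coverage
  keep <- !rownames(sim$expr) %in% toy$genes$M3
  fp_partial <- fingerprint_cohort(sim$expr[keep, ], sim$groups, toy,
                                   cohort = "c2")
  expect_true(fp_partial$low_coverage[fp_partial$module_id == "M3"])

  fm <- stack_fingerprints(list(fp, fp_partial))
  expect_identical(dim(fm), c(2L, 3L))
  expect_identical(rownames(fm), c("c1", "c2"))
  expect_true(is.na(fm["c2", "M3"]))
  expect_false(anyNA(fm["c1", ]))

  two_same <- stack_fingerprints(list(a = fp, b = fp))
  expect_identical(unname(two_same["a", ]), unname(two_same["b", ]))

  other <- toy_repertoire(n_modules = 2L, module_size = 8L)
  sim2 <- synthetic_cohort_spec(other, n_cases = 10L, n_controls = 10L,
                                background_genes = 10L, seed = 6L)
  fp_other <- with(generate_cohort(sim2),
                   fingerprint_cohort(expr, groups, other))
  expect_error(stack_fingerprints(list(fp, fp_other)),
               "different module set")
})

test_that("fingerprint TSV + sidecar and matrix TSV round-trip", {
  toy <- toy_repertoire(n_modules = 2L, module_size = 6L)
  spec <- synthetic_cohort_spec(toy, n_cases = 8L, n_controls = 8L,
                                background_genes = 20L, seed = 3L)
  sim <- generate_cohort(spec)
  fp <- fingerprint_cohort(sim$expr, sim$groups, toy, cohort = "rt")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fingerprint(fp, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_fingerprint(path)
  expect_equal(back$response, fp$response)
  expect_identical(attr(back, "cohort"), "rt")
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(meta$config$test, "welch_t")

  fm <- stack_fingerprints(list(x = fp, y = fp))
  mp <- withr::local_tempfile(fileext = ".tsv")
  write_fingerprint_matrix(fm, mp)
  expect_equal(unclass(read_fingerprint_matrix(mp)), unclass(fm),
               tolerance = 1e-9)
})
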