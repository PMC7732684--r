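# Deterministic per-component sub-seed: one master seed drives independent
# named substreams (baselines, planted-subset choice, noise) so perturbing
# one component never shifts the draws of another. Kept within 32-bit
# integer range.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Describe one planted module effect
#'
#' A planted effect shifts the case-group means of a random subset of a
#' module's genes: `fraction_affected` of the members (rounded, at least
#' one gene) move by `shift` per-gene baseline standard deviations; the
#' sign of `shift` sets the direction.
#'
#' @param module Module id present in the repertoire being simulated.
#' @param fraction_affected Fraction of members shifted, in (0, 1].
#' @param shift Signed shift in units of each gene's baseline SD.
#' @return An object of class `planted_effect`.
#' @export
planted_effect <- function(module, fraction_affected, shift) {
  stopifnot(is.character(module), length(module) == 1L)
  stopifnot(fraction_affected > 0, fraction_affected <= 1)
  stopifnot(is.finite(shift))
  structure(list(module = module, fraction_affected = fraction_affected,
                 shift = shift),
            class = "planted_effect")
}

#' Specify a synthetic case/control cohort
#'
#' Defines the generative model realised by [generate_cohort()]: every gene
#' draws a baseline mean and SD uniformly from the configured ranges, all
#' samples draw independent Gaussians on the log2-like scale, and the
#' planted effects shift case means for known gene subsets. Defaults mimic
#' a modest whole-blood case/control cohort: 30 cases vs 30 controls,
#' baseline log2 intensities in \[6, 12\] with per-gene SD in \[0.25, 1\],
#' and 1000 unaffected background genes outside all modules.
#'
#' @param repertoire A `module_repertoire` with gene memberships.
#' @param n_cases,n_controls Group sizes, each at least 2; defaults 30/30.
#' @param baseline_mean_range,baseline_sd_range Uniform ranges for per-gene
#'   baseline mean and SD.
#' @param effects List of [planted_effect()] objects (possibly empty).
#' @param background_genes Number of genes outside all modules; default 1000.
#' @param seed Integer master seed.
#' @return An object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(repertoire, n_cases = 30L,
                                  n_controls = 30L,
                                  baseline_mean_range = c(6, 12),
                                  baseline_sd_range = c(0.25, 1),
                                  effects = list(),
                                  background_genes = 1000L,
                                  seed = 1L) {
  stopifnot(inherits(repertoire, "module_repertoire"))
  if (is.null(repertoire$genes)) {
    stop("Simulation needs a repertoire with gene memberships")
  }
  stopifnot(n_cases >= 2L, n_controls >= 2L, background_genes >= 0L)
  stopifnot(length(baseline_mean_range) == 2L,
            diff(baseline_mean_range) >= 0)
  stopifnot(length(baseline_sd_range) == 2L, baseline_sd_range[1] > 0)
  if (length(effects) > 0L) {
    if (inherits(effects, "planted_effect")) effects <- list(effects)
    ok <- vapply(effects, inherits, logical(1), "planted_effect")
    if (!all(ok)) stop("effects must be a list of planted_effect objects")
    absent <- setdiff(vapply(effects, `[[`, character(1), "module"),
                      repertoire$layout$module_id)
    if (length(absent) > 0L) {
      stop("Planted effect names module(s) absent from the repertoire: ",
           paste(absent, collapse = ", "))
    }
  }
  structure(
    list(repertoire = repertoire, n_cases = as.integer(n_cases),
         n_controls = as.integer(n_controls),
         baseline_mean_range = baseline_mean_range,
         baseline_sd_range = baseline_sd_range,
         effects = effects, background_genes = as.integer(background_genes),
         seed = as.integer(seed)),
    class = "synthetic_cohort_spec"
  )
}

#' Generate a synthetic case/control cohort with planted module effects
#'
#' Realises a [synthetic_cohort_spec()]: Gaussian per-gene baselines on the
#' log2 scale, independent samples, and case-mean shifts for the planted
#' gene subsets. The returned truth table records exactly which genes were
#' shifted and by how much, so recovery can be scored against ground
#' truth. Fully reproducible: the same spec (same seed) yields
#' bit-identical output.
#'
#' @param spec A `synthetic_cohort_spec`.
#' @return List with elements `expr` (genes x samples matrix), `groups`
#'   (data.frame `sample_id`, `group`), `truth` (data.frame `gene`,
#'   `module`, `shift_sd`, `delta` — the realised mean shift on the log2
#'   scale), and `baselines` (data.frame `gene`, `mean`, `sd`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  module_genes <- unique(unlist(spec$repertoire$genes, use.names = FALSE))
  bg <- if (spec$background_genes > 0L) {
    sprintf("BG%05d", seq_len(spec$background_genes))
  } else {
    character(0)
  }
  clash <- intersect(bg, module_genes)
  if (length(clash) > 0L) {
    stop("Background gene names collide with module genes: ",
         paste(utils::head(clash, 5), collapse = ", "))
  }
  genes <- c(module_genes, bg)
  n_genes <- length(genes)
  n_samples <- spec$n_cases + spec$n_controls
  sample_ids <- c(sprintf("case_%03d", seq_len(spec$n_cases)),
                  sprintf("control_%03d", seq_len(spec$n_controls)))
  groups <- data.frame(
    sample_id = sample_ids,
    group = rep(c("case", "control"), c(spec$n_cases, spec$n_controls)),
    stringsAsFactors = FALSE
  )

  set.seed(substream_seed(spec$seed, "baselines"))
  mu <- stats::runif(n_genes, spec$baseline_mean_range[1],
                     spec$baseline_mean_range[2])
  sigma <- stats::runif(n_genes, spec$baseline_sd_range[1],
                        spec$baseline_sd_range[2])
  names(mu) <- names(sigma) <- genes

  set.seed(substream_seed(spec$seed, "subset"))
  truth_rows <- lapply(spec$effects, function(eff) {
    members <- spec$repertoire$genes[[eff$module]]
    n_affected <- max(1L, round(eff$fraction_affected * length(members)))
    chosen <- sort(sample(members, n_affected))
    data.frame(gene = chosen, module = eff$module,
               shift_sd = eff$shift,
               delta = eff$shift * unname(sigma[chosen]),
               stringsAsFactors = FALSE)
  })
  truth <- if (length(truth_rows) > 0L) {
    do.call(rbind, truth_rows)
  } else {
    data.frame(gene = character(0), module = character(0),
               shift_sd = numeric(0), delta = numeric(0),
               stringsAsFactors = FALSE)
  }

  set.seed(substream_seed(spec$seed, "noise"))
  expr <- matrix(stats::rnorm(n_genes * n_samples, mean = mu, sd = sigma),
                 nrow = n_genes, ncol = n_samples,
                 dimnames = list(genes, sample_ids))
  if (nrow(truth) > 0L) {
    # shifts are additive per effect; a gene planted in several modules
    # accumulates each of its shifts
    case_cols <- seq_len(spec$n_cases)
    for (i in seq_len(nrow(truth))) {
      expr[truth$gene[i], case_cols] <-
        expr[truth$gene[i], case_cols] + truth$delta[i]
    }
  }
  list(expr = expr, groups = groups, truth = truth,
       baselines = data.frame(gene = genes, mean = unname(mu),
                              sd = unname(sigma),
                              stringsAsFactors = FALSE))
}

#' Monte-Carlo expected response of a planted module
#'
#' Brute-force oracle for parameter-recovery tests: simulates `n_sim`
#' independent single-module cohorts under the full pipeline (baseline
#' draws, Gaussian samples, planted shift, direction calling,
#' percent-response) and returns the mean signed response with its
#' Monte-Carlo standard error. With per-gene power near 1 the expectation
#' approaches `100 * fraction_affected * sign(shift)`.
#'
#' @param effect A [planted_effect()]; its `module` id is used only for
#'   labelling.
#' @param module_size Number of genes in the simulated module.
#' @param n_cases,n_controls Group sizes.
#' @param cfg A [diff_config()] applied inside each simulation.
#' @param n_sim Number of Monte-Carlo replicates, at least 100.
#' @param seed Integer seed.
#' @param baseline_mean_range,baseline_sd_range Baseline ranges, as in
#'   [synthetic_cohort_spec()].
#' @param min_coverage_genes Low-coverage floor for the response.
#' @return List with `mean`, `se`, and `n_sim`.
#' @export
expected_response <- function(effect, module_size, n_cases = 30L,
                              n_controls = 30L, cfg = diff_config(),
                              n_sim = 200L, seed = 1L,
                              baseline_mean_range = c(6, 12),
                              baseline_sd_range = c(0.25, 1),
                              min_coverage_genes = 5L) {
  stopifnot(inherits(effect, "planted_effect"))
  stopifnot(n_sim >= 100L)
  members <- sprintf("G%03d", seq_len(module_size))
  layout <- data.frame(module_id = effect$module, aggregate = "A1",
                       column = 1L, stringsAsFactors = FALSE)
  rep1 <- assemble_repertoire(
    genes = stats::setNames(list(members), effect$module), layout = layout
  )
  responses <- vapply(seq_len(n_sim), function(i) {
    spec <- synthetic_cohort_spec(
      rep1, n_cases = n_cases, n_controls = n_controls,
      baseline_mean_range = baseline_mean_range,
      baseline_sd_range = baseline_sd_range,
      effects = list(effect), background_genes = 0L,
      seed = substream_seed(seed, paste0("sim", i))
    )
    cohort <- generate_cohort(spec)
    dirs <- call_directions(cohort$expr, cohort$groups, cfg)
    module_response(dirs, members, effect$module,
                    min_coverage_genes = min_coverage_genes)$response
  }, numeric(1))
  list(mean = mean(responses),
       se = stats::sd(responses) / sqrt(n_sim),
       n_sim = as.integer(n_sim))
}

#' Generate a synthetic reference fingerprint panel with planted blocks
#'
#' Builds a cohorts x modules fingerprint matrix whose module columns fall
#' into known blocks: modules in one block share a cohort-response profile
#' plus independent Gaussian noise. The block profiles are mutually
#' decorrelated by construction (centred and orthogonalised before use) so
#' the planted partition is recoverable by correlation-based clustering;
#' the truth partition is returned for adjusted-Rand scoring.
#'
#' @param n_cohorts Number of reference cohorts (rows), at least 2.
#' @param block_structure Named list of character vectors: block label ->
#'   module ids. No block may be empty.
#' @param seed Integer seed.
#' @param profile_sd SD of the shared block profiles (response-percentage
#'   units); default 30.
#' @param noise_sd SD of the per-module independent noise; default 5.
#' @return List with `fm` (a `fingerprint_matrix`, entries clipped to
#'   \[-100, 100\]) and `truth` (data.frame `module_id`, `block`).
#' @export
generate_reference_panel <- function(n_cohorts, block_structure, seed = 1L,
                                     profile_sd = 30, noise_sd = 5) {
  stopifnot(n_cohorts >= 2L)
  stopifnot(is.list(block_structure), length(block_structure) >= 1L)
  if (any(lengths(block_structure) == 0L)) {
    stop("Empty block in block_structure")
  }
  if (is.null(names(block_structure))) {
    names(block_structure) <- paste0("B", seq_along(block_structure))
  }
  modules <- unlist(block_structure, use.names = FALSE)
  if (anyDuplicated(modules)) {
    stop("A module appears in more than one block")
  }
  n_blocks <- length(block_structure)
  if (n_blocks > n_cohorts - 1L) {
    stop("Cannot decorrelate ", n_blocks, " block profiles over only ",
         n_cohorts, " cohorts; need n_cohorts > number of blocks")
  }
  set.seed(substream_seed(seed, "profiles"))
  raw <- matrix(stats::rnorm(n_cohorts * n_blocks), nrow = n_cohorts)
  # centre, then Gram-Schmidt: pairwise Pearson correlation exactly 0
  raw <- sweep(raw, 2, colMeans(raw))
  for (j in seq_len(n_blocks)) {
    if (j > 1L) {
      prev <- raw[, seq_len(j - 1L), drop = FALSE]
      raw[, j] <- raw[, j] - prev %*% crossprod(prev, raw[, j])
    }
    nrm <- sqrt(sum(raw[, j]^2))
    if (nrm < 1e-10) stop("Degenerate profile draw; change the seed")
    raw[, j] <- raw[, j] / nrm
  }
  profiles <- raw * profile_sd * sqrt(n_cohorts - 1)

  set.seed(substream_seed(seed, "panel_noise"))
  fm <- matrix(NA_real_, nrow = n_cohorts, ncol = length(modules),
               dimnames = list(sprintf("cohort_%02d", seq_len(n_cohorts)),
                               modules))
  truth <- data.frame(module_id = character(0), block = character(0),
                      stringsAsFactors = FALSE)
  for (b in seq_len(n_blocks)) {
    ids <- block_structure[[b]]
    for (id in ids) {
      fm[, id] <- profiles[, b] + stats::rnorm(n_cohorts, sd = noise_sd)
    }
    truth <- rbind(truth, data.frame(module_id = ids,
                                     block = names(block_structure)[b],
                                     stringsAsFactors = FALSE))
  }
  fm <- pmin(pmax(fm, -100), 100)
  class(fm) <- c("fingerprint_matrix", class(fm))
  list(fm = fm, truth = truth)
}

#' Read a synthetic-cohort spec from YAML or JSON
#'
#' The file names the repertoire inputs (`gmt`, `layout`) plus the
#' simulation fields of [synthetic_cohort_spec()]; `effects` is a list of
#' maps with keys `module`, `fraction_affected`, `shift`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` spec file.
#' @return A `synthetic_cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  for (f in c("gmt", "layout")) {
    if (is.null(raw[[f]])) stop("Spec file must name a '", f, "' path")
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base, p)
  }
  repertoire <- assemble_repertoire(
    genes = read_gmt(resolve(raw$gmt)),
    layout = read_grid_layout(resolve(raw$layout))
  )
  effects <- lapply(raw$effects %||% list(), function(e) {
    planted_effect(e$module, e$fraction_affected, e$shift)
  })
  synthetic_cohort_spec(
    repertoire,
    n_cases = raw$n_cases %||% 30L,
    n_controls = raw$n_controls %||% 30L,
    baseline_mean_range = unlist(raw$baseline_mean_range %||% c(6, 12)),
    baseline_sd_range = unlist(raw$baseline_sd_range %||% c(0.25, 1)),
    effects = effects,
    background_genes = raw$background_genes %||% 1000L,
    seed = raw$seed %||% 1L
  )
}
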