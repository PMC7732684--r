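# Independent brute-force oracles and fixture builders shared across tests.
# Oracles follow the definitions literally and share no code with the
# implementation paths they check.

# BH step-up from the definition: for the i-th smallest p, q is the minimum
# of m * p_(j) / j over all j with p_(j) >= p_(i), clipped to 1.
bh_oracle <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

# Literal recount of a module's percent responses from a direction table.
recount_oracle <- function(dirs, members) {
  rows <- dirs[dirs$gene %in% unique(members), , drop = FALSE]
  n <- nrow(rows)
  pu <- 100 * sum(rows$direction == 1) / n
  pd <- 100 * sum(rows$direction == -1) / n
  if (pu > pd) {
    resp <- pu
  } else if (pd > pu) {
    resp <- -pd
  } else if (pu == 0) {
    resp <- 0
  } else {
    um <- sum(abs(rows$log2fc[rows$direction == 1]))
    dm <- sum(abs(rows$log2fc[rows$direction == -1]))
    resp <- if (um > dm) pu else if (dm > um) -pd else 0
  }
  list(percent_up = pu, percent_down = pd, response = resp)
}

# A direction table with random calls; small sizes keep up/down ties common
# enough to exercise the tie rule.
random_direction_table <- function(n_genes) {
  data.frame(
    gene = sprintf("G%04d", seq_len(n_genes)),
    mean_case = 0, mean_control = 0,
    log2fc = round(stats::rnorm(n_genes), 2),
    p = stats::runif(n_genes), q = stats::runif(n_genes),
    direction = sample(c(-1L, 0L, 1L), n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Negate a direction table as a case/control label swap would.
swap_direction_table <- function(dirs) {
  sw <- dirs
  mc <- sw$mean_case
  sw$mean_case <- sw$mean_control
  sw$mean_control <- mc
  sw$log2fc <- -sw$log2fc
  sw$direction <- -sw$direction
  sw
}

# Small full-membership repertoire for simulation-backed tests.
toy_repertoire <- function(n_modules = 3L, module_size = 20L,
                           aggregate = "A1") {
  genes <- lapply(seq_len(n_modules), function(i) {
    sprintf("M%d_G%03d", i, seq_len(module_size))
  })
  names(genes) <- paste0("M", seq_len(n_modules))
  layout <- data.frame(
    module_id = names(genes),
    aggregate = aggregate,
    column = seq_len(n_modules),
    n_transcripts = module_size,
    annotation = NA_character_,
    stringsAsFactors = FALSE
  )
  assemble_repertoire(genes, layout)
}

# Deterministic two-group matrix: each row i drawn N(mean_control, sd) for
# controls and N(mean_control + delta[i], sd) for cases.
two_group_matrix <- function(delta, n_case = 10L, n_control = 10L,
                             base = 8, sd = 0.5, seed = 1L) {
  set.seed(seed)
  n_genes <- length(delta)
  samples <- c(sprintf("c%02d", seq_len(n_case)),
               sprintf("h%02d", seq_len(n_control)))
  mat <- matrix(stats::rnorm(n_genes * (n_case + n_control), base, sd),
                nrow = n_genes,
                dimnames = list(sprintf("G%03d", seq_len(n_genes)), samples))
  mat[, seq_len(n_case)] <- mat[, seq_len(n_case)] + delta
  groups <- data.frame(
    sample_id = samples,
    group = rep(c("case", "control"), c(n_case, n_control)),
    stringsAsFactors = FALSE
  )
  list(expr = mat, groups = groups)
}
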