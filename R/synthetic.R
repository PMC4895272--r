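#' Define a planted-module scenario for synthetic expression data
#'
#' Describes matched miRNA/mRNA matrices in which a few known modules are
#' planted on a noise background. Each module is driven by a single latent
#' factor (one value per sample): member miRNAs load positively on the
#' factor and member mRNAs negatively (`sign = "anti"`, reflecting miRNA
#' repression), or with random per-mRNA signs (`sign = "mixed"`, exercising
#' the absolute-correlation weighting that handles both up- and
#' down-regulation). All features, members or not, receive i.i.d. Gaussian
#' noise; non-members are pure noise.
#'
#' The defaults define the standard study scenario: 60 samples, 30 miRNAs,
#' 200 mRNAs, two disjoint modules of (4 miRNAs, 20 mRNAs) and (5 miRNAs,
#' 30 mRNAs), loading 1.0 and noise sd 0.5 — a within-module correlation
#' around 0.8 against a near-zero background.
#'
#' @param n_samples Number of matched samples (default 60).
#' @param n_mirnas,n_mrnas Feature totals (default 30 and 200).
#' @param modules List of module descriptors; each is either a length-2
#'   numeric vector `c(n_mirnas, n_mrnas)` or a list with fields
#'   `n_mirnas`, `n_mrnas` and optional `loading`, `sign` overriding the
#'   scenario-level values. Default `list(c(4, 20), c(5, 30))`.
#' @param loading Latent-factor loading magnitude (>= 0; 0 gives a
#'   pure-noise null scenario in which no module signal exists).
#' @param noise_sd Standard deviation of the additive Gaussian noise (> 0;
#'   default 0.5).
#' @param sign_pattern `"anti"` (default) or `"mixed"`.
#' @param overlap Fraction in \[0, 1) of each module's members shared with
#'   the previous module (default 0, disjoint modules).
#' @param seed Integer RNG seed; generation is bit-reproducible given the
#'   scenario.
#' @return A `planted_scenario` list.
#' @export
planted_scenario <- function(n_samples = 60, n_mirnas = 30, n_mrnas = 200,
                             modules = list(c(4, 20), c(5, 30)),
                             loading = 1.0, noise_sd = 0.5,
                             sign_pattern = c("anti", "mixed"),
                             overlap = 0, seed = 1L) {
  sign_pattern <- match.arg(sign_pattern)
  assert_scalar_number(loading, "loading", lower = 0)
  assert_scalar_number(noise_sd, "noise_sd", lower = 1e-12)
  assert_scalar_number(overlap, "overlap", lower = 0, upper = 1 - 1e-9)
  if (n_samples < 3) abort_mircore("need at least 3 samples", "mircore_parameter_error")
  mods <- lapply(modules, function(m) {
    if (is.numeric(m) && length(m) == 2L) m <- list(n_mirnas = m[1L], n_mrnas = m[2L])
    m$loading <- m$loading %||% loading
    m$sign <- m$sign %||% sign_pattern
    if (m$n_mirnas < 1 || m$n_mrnas < 1) {
      abort_mircore("module member counts must be positive", "mircore_scenario_error")
    }
    m
  })
  need_mirnas <- sum(vapply(mods, `[[`, numeric(1), "n_mirnas"))
  need_mrnas <- sum(vapply(mods, `[[`, numeric(1), "n_mrnas"))
  # overlapping members are re-used, so the disjoint total is an upper bound
  if (need_mirnas > n_mirnas || need_mrnas > n_mrnas) {
    abort_mircore("module member counts exceed feature totals", "mircore_scenario_error")
  }
  structure(list(n_samples = n_samples, n_mirnas = n_mirnas, n_mrnas = n_mrnas,
                 modules = mods, loading = loading, noise_sd = noise_sd,
                 sign_pattern = sign_pattern, overlap = overlap,
                 seed = as.integer(seed)),
            class = "planted_scenario")
}

#' Generate matched expression matrices with planted modules
#'
#' Draws the data a scenario describes. Module k's latent factor is a
#' standard-normal vector over samples; each member feature's profile is
#' `sign * loading * factor + noise`; non-members are noise only. Feature
#' IDs are `mir001...` and `gene0001...`, samples `s01...`. Given the same
#' scenario (seed included) the output is bit-identical; the global RNG
#' state is left untouched.
#'
#' @param scenario A [planted_scenario()].
#' @return List with `pair` (an aligned `matched_pair`) and `truth`, a list
#'   of planted modules each holding sorted `mirnas` and `mrnas` ID vectors.
#' @export
generate_planted <- function(scenario) {
  stopifnot(inherits(scenario, "planted_scenario"))
  withr::with_seed(scenario$seed, generate_planted_impl(scenario))
}

generate_planted_impl <- function(sc) {
  n <- sc$n_samples
  mirna_ids <- sprintf("mir%03d", seq_len(sc$n_mirnas))
  mrna_ids <- sprintf("gene%04d", seq_len(sc$n_mrnas))
  sample_ids <- sprintf("s%02d", seq_len(n))

  X <- matrix(stats::rnorm(sc$n_mirnas * n, sd = sc$noise_sd), sc$n_mirnas, n,
              dimnames = list(mirna_ids, sample_ids))
  Y <- matrix(stats::rnorm(sc$n_mrnas * n, sd = sc$noise_sd), sc$n_mrnas, n,
              dimnames = list(mrna_ids, sample_ids))

  truth <- list()
  next_mirna <- 1L
  next_mrna <- 1L
  prev <- NULL
  for (k in seq_along(sc$modules)) {
    m <- sc$modules[[k]]
    n_share_x <- if (is.null(prev)) 0L else min(floor(sc$overlap * m$n_mirnas),
                                                length(prev$mirnas))
    n_share_y <- if (is.null(prev)) 0L else min(floor(sc$overlap * m$n_mrnas),
                                                length(prev$mrnas))
    mx <- c(utils::head(prev$mirnas, n_share_x),
            mirna_ids[seq.int(next_mirna, length.out = m$n_mirnas - n_share_x)])
    my <- c(utils::head(prev$mrnas, n_share_y),
            mrna_ids[seq.int(next_mrna, length.out = m$n_mrnas - n_share_y)])
    next_mirna <- next_mirna + m$n_mirnas - n_share_x
    next_mrna <- next_mrna + m$n_mrnas - n_share_y

    z <- stats::rnorm(n)
    X[mx, ] <- X[mx, , drop = FALSE] + m$loading * matrix(z, length(mx), n, byrow = TRUE)
    sgn <- if (m$sign == "anti") rep(-1, length(my)) else sample(c(-1, 1), length(my), TRUE)
    Y[my, ] <- Y[my, , drop = FALSE] +
      m$loading * sgn * matrix(z, length(my), n, byrow = TRUE)

    mod <- list(mirnas = sort(mx, method = "radix"), mrnas = sort(my, method = "radix"))
    truth[[k]] <- mod
    prev <- mod
  }

  pair <- structure(list(mirna = X, mrna = Y,
                         dropped_mirna = character(0), dropped_mrna = character(0)),
                    class = "matched_pair")
  validate_expression_matrix(X)
  validate_expression_matrix(Y)
  list(pair = pair, truth = truth)
}

#' Build a perfect interaction reference from planted truth
#'
#' Emits every within-module miRNA x mRNA cross pair as a confirmed
#' interaction, giving [count_confirmed()] an exact oracle on synthetic
#' data.
#'
#' @param truth The `truth` element of [generate_planted()]'s result.
#' @return An `interaction_reference` data frame (deduplicated).
#' @export
reference_from_truth <- function(truth) {
  if (!length(truth)) return(new_interaction_reference(character(0), character(0)))
  mirna <- unlist(lapply(truth, function(m) rep(m$mirnas, each = length(m$mrnas))))
  mrna <- unlist(lapply(truth, function(m) rep(m$mrnas, times = length(m$mirnas))))
  new_interaction_reference(mirna, mrna)
}

#' Write a generated scenario to disk
#'
#' Writes `mirna.tsv`, `mrna.tsv`, `truth.json` and `reference.tsv` under
#' `dir` — the file set the command-line `synth` subcommand produces.
#'
#' @param generated Result of [generate_planted()].
#' @param dir Output directory (created if needed).
#' @export
write_scenario_files <- function(generated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(generated$pair$mirna, file.path(dir, "mirna.tsv"))
  write_expression(generated$pair$mrna, file.path(dir, "mrna.tsv"))
  jsonlite::write_json(generated$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  ref <- reference_from_truth(generated$truth)
  writeLines(c("mirna\tmrna", paste(ref$mirna, ref$mrna, sep = "\t")),
             file.path(dir, "reference.tsv"))
  invisible(dir)
}

#' Membership Jaccard between a CORE and a planted module
#'
#' Jaccard index between the union of the CORE's member sets (both sides)
#' and the union of the module's planted members.
#'
#' @param core One row of a `core_set` (or list with `mirna_members`,
#'   `mrna_members`).
#' @param module One element of the planted `truth` (fields `mirnas`,
#'   `mrnas`).
#' @return Jaccard index in \[0, 1\].
#' @export
module_jaccard <- function(core, module) {
  a <- c(core_members(core, "mirna_members"), core_members(core, "mrna_members"))
  b <- c(module$mirnas, module$mrnas)
  length(intersect(a, b)) / length(union(a, b))
}
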