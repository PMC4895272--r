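#' Run the full module-discovery pipeline over one or more eta values
#'
#' For each cutoff `eta`: interaction weights (Pearson, abs or negative-only)
#' -> cutoff -> collaboration matrices for both sides -> greedy grouping of
#' miRNAs and of mRNAs -> canonical-correlation scoring of every group pair
#' -> CORE ranking and a summary row. Pearson correlations are computed once
#' and re-thresholded per eta. The run is fully deterministic.
#'
#' @param pair Aligned `matched_pair` from [align_samples()].
#' @param eta Numeric vector of cutoff values in \[0, 1\] (default the
#'   standard sweep 0 to 1 in steps of 0.05).
#' @param weights_mode `"abs"` or `"neg_abs"` (see [pearson_weights()]).
#' @param mirna_params,mrna_params [grouping_params()] per side. Defaults:
#'   miRNA min size 3; mRNA min size 5, max size 500; penalty `alpha = 2`
#'   and merge overlap 0.8 on both sides.
#' @param rho Minimum canonical correlation for a CORE (default 0.5).
#' @param cca_method CCA solver (default `"sparse_pmd"`).
#' @param reference Optional `interaction_reference` for confirmed-pair
#'   counting in the written outputs.
#' @param out_dir Optional output directory: one subdirectory per eta
#'   (`eta_0.60/groups.json`, `cores.json`, `cores.tsv`, and
#'   `confirmed.tsv` when a reference is given) plus a top-level
#'   `summary.tsv`.
#' @param raw_weights Optional precomputed raw weight matrix in \[0, 1\]
#'   (miRNA rows, mRNA columns) used instead of Pearson correlations.
#' @param ... Extra arguments (penalties) passed to the CCA solver.
#' @return A list with `per_eta` (named list of per-eta results, each
#'   holding `eta`, `groups_mirna`, `groups_mrna`, `cores`, `summary`) and
#'   `summary`, a data frame of the non-empty summary rows.
#' @export
run_core_discovery <- function(pair,
                               eta = seq(0, 1, by = 0.05),
                               weights_mode = c("abs", "neg_abs"),
                               mirna_params = grouping_params(min_size = 3),
                               mrna_params = grouping_params(min_size = 5, max_size = 500),
                               rho = 0.5,
                               cca_method = c("sparse_pmd", "ridge", "classical"),
                               reference = NULL,
                               out_dir = NULL,
                               raw_weights = NULL,
                               ...) {
  weights_mode <- match.arg(weights_mode)
  cca_method <- match.arg(cca_method)
  if (!length(eta)) abort_mircore("`eta` must be a nonempty vector", "mircore_parameter_error")
  for (e in eta) assert_scalar_number(e, "eta", lower = 0, upper = 1)

  raw <- if (is.null(raw_weights)) pearson_weights(pair, weights_mode) else raw_weights

  per_eta <- list()
  summary_rows <- list()
  for (e in eta) {
    res <- tryCatch(
      run_single_eta(pair, raw, e, mirna_params, mrna_params, rho, cca_method, ...),
      mircore_error = function(err) {
        abort_mircore(sprintf("eta = %s: %s", format(e), conditionMessage(err)),
                      class = class(err)[1L])
      }
    )
    key <- format_eta(e)
    per_eta[[key]] <- res
    if (!is.null(res$summary)) summary_rows[[key]] <- res$summary
    if (!is.null(out_dir)) write_eta_outputs(res, out_dir, key, reference)
  }

  summary <- if (length(summary_rows)) {
    do.call(rbind, c(summary_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(eta = numeric(0), n_cores = integer(0), mean_mrnas = numeric(0),
               mean_mirnas = numeric(0), mean_strength = numeric(0))
  }
  if (!is.null(out_dir)) write_summary_tsv(summary, file.path(out_dir, "summary.tsv"))
  list(per_eta = per_eta, summary = summary)
}

run_single_eta <- function(pair, raw, eta, mirna_params, mrna_params, rho,
                           cca_method, ...) {
  W <- apply_cutoff(raw, eta)
  S <- collaboration_scores(W, "mirna")
  T_ <- collaboration_scores(W, "mrna")
  groups_mirna <- discover_groups(S, mirna_params, side = "mirna")
  groups_mrna <- discover_groups(T_, mrna_params, side = "mrna")
  cores <- score_group_pairs(groups_mirna, groups_mrna, pair, rho = rho,
                             method = cca_method, ...)
  list(eta = eta,
       groups_mirna = groups_mirna,
       groups_mrna = groups_mrna,
       cores = cores,
       summary = summarize_cores(cores, eta))
}

format_eta <- function(e) sprintf("eta_%.2f", e)

#' Summary row for a set of COREs at one eta
#'
#' Arithmetic means of the mRNA count, miRNA count and strength over the
#' COREs found at one cutoff. An empty CORE set yields `NULL` (the row is
#' omitted from the summary table).
#'
#' @param cores A `core_set` from [score_group_pairs()].
#' @param eta The cutoff the COREs were obtained at.
#' @return A one-row data frame with columns `eta`, `n_cores`, `mean_mrnas`,
#'   `mean_mirnas`, `mean_strength`, or `NULL` when `cores` is empty.
#' @export
summarize_cores <- function(cores, eta) {
  if (!nrow(cores)) return(NULL)
  data.frame(eta = eta,
             n_cores = nrow(cores),
             mean_mrnas = mean(cores$n_mrnas),
             mean_mirnas = mean(cores$n_mirnas),
             mean_strength = mean(cores$strength))
}

#' Count experimentally confirmed interactions inside a CORE
#'
#' Intersects the CORE's full miRNA x mRNA cross product with a reference
#' pair list and reports the hits grouped by miRNA. The count is bounded by
#' `|C_x| * |C_y|`.
#'
#' @param core A single CORE: either one row of a `core_set` or any list
#'   with `mirna_members` and `mrna_members` character vectors.
#' @param ref An `interaction_reference` from [read_reference()] or
#'   [reference_from_truth()].
#' @return List with `n_confirmed` (integer) and `by_mirna` (named list of
#'   sorted confirmed target vectors, miRNAs with no hits omitted).
#' @export
count_confirmed <- function(core, ref) {
  stopifnot(inherits(ref, "interaction_reference"))
  mirnas <- core_members(core, "mirna_members")
  mrnas <- core_members(core, "mrna_members")
  hits <- ref[ref$mirna %in% mirnas & ref$mrna %in% mrnas, , drop = FALSE]
  by_mirna <- lapply(split(hits$mrna, hits$mirna), function(v) sort(unique(v)))
  by_mirna <- by_mirna[order(names(by_mirna), method = "radix")]
  list(n_confirmed = nrow(hits), by_mirna = by_mirna)
}

core_members <- function(core, field) {
  v <- core[[field]]
  if (is.list(v)) v <- v[[1L]]
  as.character(v)
}

# --- serialization ----------------------------------------------------------

groups_to_list <- function(groups) {
  lapply(groups, function(g) {
    list(side = g$side, members = g$members, cohesiveness = g$cohesiveness)
  })
}

#' Serialize groups as JSON
#' @param groups List of `feature_group`s.
#' @param path Output path.
#' @export
write_groups_json <- function(groups, path) {
  jsonlite::write_json(groups_to_list(groups), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Serialize groups as GMT-style lines
#'
#' One line per group: group id, cohesiveness, then the tab-separated
#' members — the conventional gene-set exchange layout.
#'
#' @param groups List of `feature_group`s.
#' @param path Output path.
#' @param prefix Group id prefix (default the side of the first group).
#' @export
write_groups_gmt <- function(groups, path, prefix = NULL) {
  if (is.null(prefix)) {
    prefix <- if (length(groups)) substr(groups[[1L]]$side, 1L, 1L) else "g"
  }
  lines <- vapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    paste(c(sprintf("%s%d", prefix, i), sprintf("%.6f", g$cohesiveness), g$members),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

cores_to_list <- function(cores) {
  lapply(seq_len(nrow(cores)), function(i) {
    list(rank = cores$rank[i],
         r = cores$strength[i],
         method = cores$method[i],
         mirna_members = cores$mirna_members[[i]],
         mrna_members = cores$mrna_members[[i]])
  })
}

#' Serialize a CORE set as JSON
#' @param cores A `core_set`.
#' @param path Output path.
#' @export
write_cores_json <- function(cores, path) {
  jsonlite::write_json(cores_to_list(cores), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Serialize a CORE set as flat TSV
#' @param cores A `core_set`.
#' @param path Output path.
#' @export
write_cores_tsv <- function(cores, path) {
  lines <- c(paste(c("core_id", "r", "n_mirnas", "n_mrnas", "mirna_members",
                     "mrna_members"), collapse = "\t"),
             vapply(seq_len(nrow(cores)), function(i) {
               paste(c(sprintf("C%d", cores$rank[i]),
                       sprintf("%.6f", cores$strength[i]),
                       cores$n_mirnas[i], cores$n_mrnas[i],
                       paste(cores$mirna_members[[i]], collapse = ","),
                       paste(cores$mrna_members[[i]], collapse = ",")),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

write_summary_tsv <- function(summary, path) {
  lines <- c(paste(c("eta", "n_cores", "mean_mrnas", "mean_mirnas", "mean_strength"),
                   collapse = "\t"),
             vapply(seq_len(nrow(summary)), function(i) {
               paste(c(sprintf("%.2f", summary$eta[i]),
                       summary$n_cores[i],
                       sprintf("%.2f", summary$mean_mrnas[i]),
                       sprintf("%.2f", summary$mean_mirnas[i]),
                       sprintf("%.2f", summary$mean_strength[i])),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

write_eta_outputs <- function(res, out_dir, key, reference) {
  dir <- file.path(out_dir, key)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_groups_json(c(res$groups_mirna, res$groups_mrna),
                    file.path(dir, "groups.json"))
  write_cores_json(res$cores, file.path(dir, "cores.json"))
  write_cores_tsv(res$cores, file.path(dir, "cores.tsv"))
  if (!is.null(reference) && nrow(res$cores)) {
    lines <- c("core_id\tn_confirmed\tconfirmed_pairs")
    for (i in seq_len(nrow(res$cores))) {
      cc <- count_confirmed(res$cores[i, ], reference)
      flat <- unlist(lapply(names(cc$by_mirna), function(m) {
        paste0(m, ":", paste(cc$by_mirna[[m]], collapse = "|"))
      }))
      lines <- c(lines, paste(c(sprintf("C%d", res$cores$rank[i]), cc$n_confirmed,
                                paste(flat, collapse = ";")), collapse = "\t"))
    }
    writeLines(lines, file.path(dir, "confirmed.tsv"))
  }
  invisible(dir)
}
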