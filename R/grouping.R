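#' Parameters for greedy group discovery
#'
#' @param alpha Cohesiveness penalty (>= 0). Each member is assumed to carry
#'   `alpha` undetected external interactions, which discourages absorbing
#'   weakly attached vertices. Default 2 for every run.
#' @param min_size Minimum group size kept after clustering (3 for miRNA
#'   groups, 5 for mRNA groups in the standard configuration).
#' @param max_size Maximum group size kept (default `Inf`; the standard
#'   configuration caps mRNA groups at 500).
#' @param merge_overlap Overlap score threshold omega in (0, 1\] at or above
#'   which two groups are merged (union, cohesiveness recomputed). The
#'   overlap score is \eqn{|A \cap B|^2 / (|A| |B|)}. Default 0.8.
#' @param min_density Optional density floor: groups whose mean internal
#'   pair score `2 w_int / (|C| (|C|-1))` falls below it are discarded.
#'   `NULL` (default) disables the filter.
#' @return A `grouping_params` list.
#' @export
grouping_params <- function(alpha = 2, min_size = 3, max_size = Inf,
                            merge_overlap = 0.8, min_density = NULL) {
  assert_scalar_number(alpha, "alpha", lower = 0)
  if (!is.numeric(min_size) || min_size < 1 || min_size != floor(min_size)) {
    abort_mircore("`min_size` must be a positive integer", "mircore_parameter_error")
  }
  if (!(identical(max_size, Inf) ||
        (is.numeric(max_size) && max_size >= min_size && max_size == floor(max_size)))) {
    abort_mircore("`max_size` must be an integer >= min_size, or Inf",
                  "mircore_parameter_error")
  }
  assert_scalar_number(merge_overlap, "merge_overlap", lower = 1e-12, upper = 1)
  if (!is.null(min_density)) assert_scalar_number(min_density, "min_density", lower = 0)
  structure(list(alpha = alpha, min_size = min_size, max_size = max_size,
                 merge_overlap = merge_overlap, min_density = min_density),
            class = "grouping_params")
}

#' Cohesiveness of a member set
#'
#' \deqn{cs(C) = \frac{w_{int}(C)}{w_{int}(C) + w_{ext}(C) + \alpha |C|}}
#'
#' where `w_int` sums the collaboration scores over unordered pairs inside
#' `C` and `w_ext` over pairs with exactly one endpoint in `C`. Returns 0
#' when the denominator is 0 (an isolated singleton with `alpha = 0`).
#'
#' @param members Character vector of member IDs (nonempty, all present in
#'   `M`).
#' @param M Collaboration matrix.
#' @param alpha Penalty >= 0.
#' @return The cohesiveness score in \[0, 1\].
#' @export
cohesiveness <- function(members, M, alpha = 2) {
  assert_scalar_number(alpha, "alpha", lower = 0)
  idx <- match(members, rownames(M))
  if (!length(idx) || anyNA(idx)) {
    abort_mircore(sprintf("member(s) not in collaboration matrix: %s",
                          paste(members[is.na(idx)], collapse = ", ")),
                  class = "mircore_membership_error")
  }
  w_int <- sum(M[idx, idx]) / 2
  w_ext <- sum(M[idx, , drop = FALSE]) - 2 * w_int
  denom <- w_int + w_ext + alpha * length(idx)
  if (denom <= 0) return(0)
  w_int / denom
}

# Ratio form used by the incremental grower: sum(deg over C) = 2 w_int + w_ext.
cs_from_sums <- function(w_int, sum_deg, size, alpha) {
  denom <- sum_deg - w_int + alpha * size
  if (denom <= 0) return(0)
  w_int / denom
}

#' Grow a cohesive group from a seed vertex
#'
#' Greedy neighbourhood expansion: starting from the singleton seed,
#' repeatedly evaluates every admissible single move — adding an external
#' vertex connected to the group, or removing a current member (the seed is
#' never removable) — and applies the move with the largest strict increase
#' in cohesiveness, stopping at a local maximum. Cohesiveness never
#' decreases along the accepted sequence. Ties between equally improving
#' moves are resolved deterministically: additions are preferred over
#' removals, then the lexicographically smallest ID wins.
#'
#' @param seed Seed feature ID (must be a row of `M`).
#' @param M Collaboration matrix.
#' @param params A [grouping_params()] object (only `alpha` is used here;
#'   size and merge settings apply in [discover_groups()]).
#' @return A `feature_group`: list with `members` (sorted character vector),
#'   `cohesiveness`, `seed` and `side`.
#' @export
grow_group <- function(seed, M, params = grouping_params()) {
  ids <- rownames(M)
  seed_idx <- match(seed, ids)
  if (is.na(seed_idx)) {
    abort_mircore(sprintf("seed '%s' not in collaboration matrix", seed),
                  class = "mircore_membership_error")
  }
  alpha <- params$alpha
  n <- nrow(M)
  deg <- rowSums(M)
  in_group <- logical(n)
  in_group[seed_idx] <- TRUE
  conn <- M[, seed_idx]            # conn[v] = sum of scores from v into the group
  w_int <- 0
  sum_deg <- deg[seed_idx]
  cs_cur <- cs_from_sums(w_int, sum_deg, 1L, alpha)

  repeat {
    size <- sum(in_group)
    add_cand <- which(!in_group & conn > 0)
    rem_cand <- if (size > 1L) setdiff(which(in_group), seed_idx) else integer(0)
    if (!length(add_cand) && !length(rem_cand)) break

    cs_add <- if (length(add_cand)) {
      vapply(add_cand, function(v) {
        cs_from_sums(w_int + conn[v], sum_deg + deg[v], size + 1L, alpha)
      }, numeric(1))
    } else numeric(0)
    cs_rem <- if (length(rem_cand)) {
      vapply(rem_cand, function(u) {
        cs_from_sums(w_int - conn[u], sum_deg - deg[u], size - 1L, alpha)
      }, numeric(1))
    } else numeric(0)

    best <- max(c(cs_add, cs_rem))
    if (!(best > cs_cur + 1e-12)) break

    # deterministic tie-break: additions first, then smallest ID
    tol <- 1e-15
    add_hits <- add_cand[cs_add >= best - tol]
    if (length(add_hits)) {
      v <- add_hits[order(ids[add_hits], method = "radix")][1L]
      w_int <- w_int + conn[v]
      sum_deg <- sum_deg + deg[v]
      in_group[v] <- TRUE
      conn <- conn + M[, v]
      cs_cur <- cs_from_sums(w_int, sum_deg, sum(in_group), alpha)
    } else {
      rem_hits <- rem_cand[cs_rem >= best - tol]
      u <- rem_hits[order(ids[rem_hits], method = "radix")][1L]
      w_int <- w_int - conn[u]
      sum_deg <- sum_deg - deg[u]
      in_group[u] <- FALSE
      conn <- conn - M[, u]
      cs_cur <- cs_from_sums(w_int, sum_deg, sum(in_group), alpha)
    }
  }

  members <- sort(ids[in_group], method = "radix")
  new_feature_group(members, cohesiveness(members, M, alpha),
                    side = attr(M, "side", exact = TRUE) %||% "unknown",
                    seed = seed)
}

new_feature_group <- function(members, cs, side, seed = NULL) {
  structure(list(members = members, cohesiveness = cs, side = side, seed = seed),
            class = "feature_group")
}

#' @export
print.feature_group <- function(x, ...) {
  cat(sprintf("%s group, %d members, cohesiveness %.4f\n  %s\n",
              x$side, length(x$members), x$cohesiveness,
              paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Overlap score between two member sets
#'
#' \eqn{\omega(A, B) = |A \cap B|^2 / (|A| |B|)}; 1 iff the sets are equal.
#'
#' @param a,b Character vectors of member IDs.
#' @return Overlap score in \[0, 1\].
#' @export
overlap_score <- function(a, b) {
  length(intersect(a, b))^2 / (length(a) * length(b))
}

#' Discover cohesive groups on one side of the bipartite graph
#'
#' Runs the full per-side clustering: vertices are taken as seeds in
#' descending total-collaboration order (ties lexicographic), skipping any
#' vertex already covered by a previously grown group; each remaining seed
#' is grown with [grow_group()]; groups outside
#' `[min_size, max_size]` (and, if set, below `min_density`) are discarded;
#' remaining groups with pairwise overlap score >= `merge_overlap` are merged
#' (union, cohesiveness recomputed) until no such pair remains, always
#' merging the currently most-overlapping pair first. Merging can push a
#' group past `max_size`; such groups are discarded with a message. The
#' result is sorted by descending cohesiveness, ties by smallest member ID.
#'
#' The whole procedure is deterministic: identical inputs and parameters
#' give identical output, ordering included.
#'
#' @param M Collaboration matrix for one side.
#' @param params A [grouping_params()] object.
#' @param side `"mirna"` or `"mrna"` label stamped on the groups (defaults
#'   to the matrix's own `side` attribute).
#' @return List of `feature_group` objects (possibly empty).
#' @export
discover_groups <- function(M, params = grouping_params(),
                            side = attr(M, "side", exact = TRUE) %||% "unknown") {
  stopifnot(inherits(params, "grouping_params"))
  ranking <- total_collaboration_ranking(M)
  covered <- character(0)
  grown <- list()
  for (seed in ranking$id) {
    if (seed %in% covered) next
    g <- grow_group(seed, M, params)
    g$side <- side
    grown[[length(grown) + 1L]] <- g
    covered <- union(covered, g$members)
  }

  keep <- vapply(grown, function(g) {
    n <- length(g$members)
    ok <- n >= params$min_size && n <= params$max_size
    if (ok && !is.null(params$min_density) && n >= 2L) {
      idx <- match(g$members, rownames(M))
      dens <- sum(M[idx, idx]) / (n * (n - 1))
      ok <- dens >= params$min_density
    }
    ok
  }, logical(1))
  groups <- grown[keep]

  groups <- merge_overlapping(groups, M, params, side)

  over <- vapply(groups, function(g) length(g$members) > params$max_size, logical(1))
  if (any(over)) {
    message(sprintf("discarding %d merged group(s) exceeding max_size = %s",
                    sum(over), format(params$max_size)))
    groups <- groups[!over]
  }

  first_member <- vapply(groups, function(g) g$members[1L], character(1))
  cs <- vapply(groups, function(g) g$cohesiveness, numeric(1))
  groups[order(-cs, first_member, method = "radix")]
}

# Merge groups whose overlap score reaches the threshold, highest first,
# until fixpoint. Duplicate member sets count as overlap 1.
merge_overlapping <- function(groups, M, params, side) {
  repeat {
    k <- length(groups)
    if (k < 2L) return(groups)
    best <- c(0, 0L, 0L)
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        om <- overlap_score(groups[[i]]$members, groups[[j]]$members)
        if (om > best[1L]) best <- c(om, i, j)
      }
    }
    if (best[1L] < params$merge_overlap) return(groups)
    i <- best[2L]; j <- best[3L]
    members <- sort(union(groups[[i]]$members, groups[[j]]$members), method = "radix")
    merged <- new_feature_group(members, cohesiveness(members, M, params$alpha), side)
    groups <- c(groups[-c(i, j)], list(merged))
  }
}
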