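# Shared fixtures and independent oracles. Every oracle here recomputes the
# quantity it checks by a different route than the implementation (explicit
# loops over sets and pairs rather than matrix algebra).

# Build an aligned pair straight from two feature-by-sample matrices that
# already share sample IDs.
make_pair <- function(X, Y) {
  align_samples(X, Y)
}

rand_matrix <- function(p, n, ids, samples = sprintf("s%02d", seq_len(n)), sd = 1) {
  matrix(rnorm(p * n, sd = sd), p, n, dimnames = list(ids, samples))
}

write_expr_tsv <- function(lines, path = withr::local_tempfile(fileext = ".tsv",
                                                               .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

# Strip the interaction_weights attributes down to a plain matrix.
unclass_w <- function(w) {
  matrix(as.numeric(w), nrow(w), ncol(w), dimnames = dimnames(w))
}

# Random binary weight matrix with dimnames.
rand_binary_W <- function(p, q, prob = 0.4) {
  W <- matrix(rbinom(p * q, 1L, prob), p, q,
              dimnames = list(sprintf("m%02d", seq_len(p)),
                              sprintf("g%02d", seq_len(q))))
  storage.mode(W) <- "double"
  W
}

# Set-based collaboration oracle for binary W: |N(i) n N(j)|^2 / (|N(i)||N(j)|).
collab_oracle_binary <- function(W) {
  p <- nrow(W)
  V <- matrix(0, p, p, dimnames = list(rownames(W), rownames(W)))
  nb <- lapply(seq_len(p), function(i) which(W[i, ] != 0))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    di <- length(nb[[i]]); dj <- length(nb[[j]])
    if (di == 0 || dj == 0) next
    V[i, j] <- length(intersect(nb[[i]], nb[[j]]))^2 / (di * dj)
  }
  V
}

# Direct pair-summation cohesiveness oracle (explicit double loops).
cohesiveness_oracle <- function(members, M, alpha) {
  ids <- rownames(M)
  inside <- ids %in% members
  w_int <- 0
  for (i in which(inside)) for (j in which(inside)) if (i < j) w_int <- w_int + M[i, j]
  w_ext <- 0
  for (i in which(inside)) for (j in which(!inside)) w_ext <- w_ext + M[i, j]
  denom <- w_int + w_ext + alpha * length(members)
  if (denom <= 0) 0 else w_int / denom
}

# Independent greedy grower used as a move-by-move oracle: same move rule
# (best strict improvement; additions preferred; smallest ID), implemented
# naively on ID sets with full recomputation at every step.
grow_oracle <- function(seed, M, alpha) {
  ids <- rownames(M)
  members <- seed
  cs_cur <- cohesiveness_oracle(members, M, alpha)
  repeat {
    outside <- setdiff(ids, members)
    adds <- outside[vapply(outside, function(v) sum(M[v, members]) > 0, logical(1))]
    rems <- setdiff(members, seed)
    cand <- c(lapply(adds, function(v) list(kind = "add", id = v,
                                            set = c(members, v))),
              lapply(rems, function(u) list(kind = "rem", id = u,
                                            set = setdiff(members, u))))
    if (!length(cand)) break
    cs <- vapply(cand, function(cc) cohesiveness_oracle(cc$set, M, alpha), numeric(1))
    best <- max(cs)
    if (!(best > cs_cur + 1e-12)) break
    hit <- which(cs >= best - 1e-15)
    kinds <- vapply(cand[hit], `[[`, character(1), "kind")
    hit <- if (any(kinds == "add")) hit[kinds == "add"] else hit
    pick <- hit[order(vapply(cand[hit], `[[`, character(1), "id"))][1L]
    members <- cand[[pick]]$set
    cs_cur <- cohesiveness_oracle(members, M, alpha)
  }
  sort(members)
}

# Collaboration matrix with planted diagonal blocks (within-block score
# `inside`, elsewhere `outside`).
block_collab <- function(sizes, inside = 1, outside = 0,
                         ids = sprintf("v%02d", seq_len(sum(sizes)))) {
  n <- sum(sizes)
  M <- matrix(outside, n, n, dimnames = list(ids, ids))
  stop_at <- cumsum(sizes)
  start_at <- c(1L, utils::head(stop_at, -1L) + 1L)
  for (b in seq_along(sizes)) {
    idx <- start_at[b]:stop_at[b]
    M[idx, idx] <- inside
  }
  diag(M) <- 0
  attr(M, "side") <- "mirna"
  M
}

# Classical first canonical correlation via the eigendecomposition of
# solve(Sxx) Sxy solve(Syy) Syx -- independent of the SVD route used by the
# implementation.
cca_eigen_oracle <- function(X, Y) {
  n <- ncol(X)
  Xc <- t(scale(t(X)))
  Yc <- t(scale(t(Y)))
  Sxx <- tcrossprod(Xc) / (n - 1)
  Syy <- tcrossprod(Yc) / (n - 1)
  Sxy <- tcrossprod(Xc, Yc) / (n - 1)
  Mx <- solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy)
  sqrt(max(Re(eigen(Mx)$values)))
}
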