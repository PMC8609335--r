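# shared oracles and fixtures, independent of the package implementation
# wherever they stand in for one

# cache expensive fixtures across test files (test_dir runs in one session)
.fixtureCache <- new.env(parent = emptyenv())
cachedFixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, force(expr), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# 1-D path mesh with unit edge lengths, encoded with degenerate triangles
pathMesh <- function(n, spacing = 1) {
  coords <- cbind(seq_len(n) * spacing, 0, 0)
  tri <- cbind(seq_len(n - 1), seq_len(n - 1) + 1, seq_len(n - 1) + 1)
  surfaceMesh(coords, tri)
}

# Floyd-Warshall all-pairs shortest paths from an edge list (oracle for the
# igraph-backed geodesic distances)
floydOracle <- function(coords, edges) {
  n <- nrow(coords)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    w <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    D[i, j] <- min(D[i, j], w)
    D[j, i] <- min(D[j, i], w)
  }
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

meshEdges <- function(mesh) {
  tri <- mesh@triangles
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(1, 3)])
  unique(t(apply(e, 1, sort)))
}

# brute-force T1I1 validator (independent of isT1I1)
t1i1Oracle <- function(labels, nLabels) {
  if (length(labels) != nLabels^2 + 1) return(FALSE)
  if (labels[1] != labels[length(labels)]) return(FALSE)
  cnt <- matrix(0L, nLabels, nLabels)
  for (t in 2:length(labels))
    cnt[labels[t - 1], labels[t]] <- cnt[labels[t - 1], labels[t]] + 1L
  all(cnt == 1L)
}

# naive normal-equations GLM oracle: betas, t-values
glmOracle <- function(y, X) {
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  res <- y - X %*% beta
  dof <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / dof
  tval <- beta / sqrt(s2 * diag(XtXi))
  list(beta = as.numeric(beta), t = as.numeric(tval))
}

# hand step-up BH oracle
bhOracle <- function(p, alpha = 0.05) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- prev
  }
  list(q = q, significant = q <= alpha)
}

# grid-search Procrustes oracle over 2x2 rotations and reflections,
# iteratively refined around the best angle
procrustesGridOracle <- function(source, target) {
  obj <- function(R) sum((source %*% R - target)^2)
  rot <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  refl <- function(a) matrix(c(cos(a), sin(a), sin(a), -cos(a)), 2)
  best <- NULL; bestVal <- Inf
  for (maker in list(rot, refl)) {
    lo <- 0; hi <- 2 * pi; step <- 2 * pi / 720
    for (it in 1:8) {
      angles <- seq(lo, hi, by = step)
      vals <- vapply(angles, function(a) obj(maker(a)), numeric(1))
      k <- which.min(vals)
      if (vals[k] < bestVal) { bestVal <- vals[k]; best <- maker(angles[k]) }
      lo <- angles[k] - step; hi <- angles[k] + step; step <- step / 40
    }
  }
  best
}

# independent random orthogonal matrix (QR with sign fix)
randomOrthogonalOracle <- function(d) {
  qr_ <- qr(matrix(rnorm(d * d), d, d))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))), d, d)
}

# small worlds shared by several test files
tinyWorld <- function() cachedFixture("tinyWorld", makeFixture("tiny", seed = 42))
tinyNullWorld <- function()
  cachedFixture("tinyNullWorld",
                makeFixture("tiny", seed = 43, snrCore = 0, snrExtended = 0))
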