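# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG state seeded with `seed`; restore the
# caller's RNG afterwards.  With seed = NULL the expression runs under the
# current RNG stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic fan-out of one parent seed into per-stage child seeds.
# Keeps every child strictly below 2^31.
childSeed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  stages <- c(sequence = 1L, world = 2L, glm = 3L, hyperalign = 4L,
              decode = 5L, infer = 6L, fixture = 7L, permute = 8L,
              bootstrap = 9L)
  k <- stages[[stage]]
  (as.integer(seed) %% 1000003L) * 1009L + k * 101L + as.integer(index) %% 100000L
}

# z-score the rows (vertices) of a vertex x time matrix; constant rows become 0
zscoreRows <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  (x - mu) / s
}

# random orthogonal matrix (Haar via QR with sign fix)
randomOrthogonal <- function(d) {
  qr_ <- qr(matrix(stats::rnorm(d * d), d, d))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))), d, d)
}

#' Write a numeric matrix as a plain tab-separated table
#'
#' @param x numeric matrix.
#' @param path output file.
#' @export
writeMatrixTSV <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
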