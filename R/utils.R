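#' @importFrom stats cor fft sd var rnorm runif rbinom rlnorm rgeom qt pt
#'   p.adjust lm.fit hclust dist cutree quantile predict coef median
#'   model.matrix t.test setNames complete.cases
#' @importFrom utils head modifyList write.csv
#' @importFrom rlang abort warn hash .data
NULL

# Derive a reproducible 32-bit child seed from a parent seed and an index.
# Kept strictly below 2^31 - 1 so set.seed() accepts it on all platforms.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807 + 11) %%
               2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Row-major upper-triangle pair index for an N-node undirected graph:
# (1,2), (1,3), ..., (1,N), (2,3), ..., (N-1,N).
pair_index <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

upper_tri_values <- function(m) {
  idx <- pair_index(nrow(m))
  m[cbind(idx[, 1], idx[, 2])]
}

# Pearson correlation with an explicit zero-variance policy: degenerate
# pairs get 0 and are flagged via the "degenerate" attribute rather than
# propagating NaN into feature matrices.
safe_cor <- function(x, y) {
  sx <- sd(x)
  sy <- sd(y)
  if (sx == 0 || sy == 0) {
    structure(0, degenerate = TRUE)
  } else {
    structure(cor(x, y), degenerate = FALSE)
  }
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
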