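# Seeding, smoothing and small array helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded internals do not
#' perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  code
}

#' Derive a per-component seed from a master seed
#'
#' One master seed fans out into deterministic sub-seeds, keeping every
#' component independently reproducible. Results stay below 2^31.
#'
#' @param master integer master seed.
#' @param k component index (any non-negative integer).
#' @return integer seed.
#' @export
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 48271 + as.numeric(k) * 16807 + 1) %%
               2147483647)
}

# separable Gaussian smoothing along every axis of a 2D/3D array
gaussian_smooth <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  d <- dim(a)
  nd <- length(d)
  for (ax in seq_len(nd)) {
    out <- array(0, d)
    for (k in -r:r) {
      idx_src <- pmin(pmax(seq_len(d[ax]) + k, 1L), d[ax])  # replicate edges
      if (nd == 2) {
        out <- out + w[k + r + 1] * (if (ax == 1) a[idx_src, , drop = FALSE]
                                     else a[, idx_src, drop = FALSE])
      } else {
        out <- out + w[k + r + 1] * (if (ax == 1) a[idx_src, , , drop = FALSE]
                                     else if (ax == 2) a[, idx_src, , drop = FALSE]
                                     else a[, , idx_src, drop = FALSE])
      }
    }
    a <- out
  }
  a
}

# Soerensen-Dice between two binary arrays
dice_binary <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
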