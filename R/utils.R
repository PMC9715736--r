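# Internal helpers shared across modules.

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed derived from a master seed (kept < 2^31;
# arithmetic in double to avoid integer overflow for large seeds).
child_seed <- function(seed, offset) {
  as.integer(((as.numeric(seed) %% 2147483647) * 1009 +
                as.numeric(offset)) %% 2147483647)
}

# Center rows of a maps matrix (maps x channels) to zero mean across channels.
center_rows <- function(m) {
  m - rowMeans(m)
}

# Scale rows to unit L2 norm; zero rows are left as zero.
unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

#' Spatial correlation between two topographic maps
#'
#' Pearson correlation of two scalp maps across channels, i.e. the cosine
#' similarity of the channel-mean-removed maps. This is the similarity used
#' throughout microstate analysis; its absolute value is polarity-invariant.
#'
#' @param x,y Numeric vectors of per-channel potentials (same length).
#' @return Correlation in `[-1, 1]`, or `NA` if either map is spatially flat.
#' @export
spatial_corr <- function(x, y) {
  x <- x - mean(x); y <- y - mean(y)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(NA_real_)
  sum(x * y) / (nx * ny)
}

# Correlation matrix between rows of X (n x C) and rows of P (k x C).
# Rows with zero spatial variance yield NA.
spatial_corr_matrix <- function(X, P) {
  Xc <- center_rows(X); Pc <- center_rows(P)
  nx <- sqrt(rowSums(Xc^2)); np <- sqrt(rowSums(Pc^2))
  out <- (Xc %*% t(Pc)) / outer(nx, np)
  out[!is.finite(out)] <- NA_real_
  out
}

# All permutations of 1..n as a list (n <= 8 in practice).
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", 0L)
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
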