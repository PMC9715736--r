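#' Polarity-invariant modified k-means over GFP-peak maps
#'
#' The k-means variant standard for EEG microstates: similarity between a
#' map and a prototype is the squared spatial correlation (so a map and its
#' polarity reversal are identical), and each prototype is updated as the
#' dominant eigenvector of the covariance of its assigned (channel-mean
#' removed) maps rather than the arithmetic mean. Convergence is monitored
#' on the global explained variance (GEV); the best of `n_restarts` random
#' restarts by GEV is returned.
#'
#' If a cluster empties during iteration, its prototype is re-seeded from
#' the currently worst-explained peak map.
#'
#' @param peaks A `peak_maps` object (n_peaks >= k).
#' @param k Number of prototypes.
#' @param n_restarts Random restarts (default 20).
#' @param max_iter Iteration cap per restart (default 100).
#' @param tol Convergence threshold on the relative GEV change
#'   (default 1e-6).
#' @param seed Integer seed (mandatory; each restart derives a child seed).
#' @param verbose Emit a message when a cluster is re-seeded.
#' @return A `prototype_set`: list with `maps` (k x channels, zero-mean
#'   unit-norm rows), `k`, `labels` (placeholder `M1..Mk` until
#'   [label_prototypes()]), `gev_per_class`, `diagnostics` (list with
#'   `gev_total`), `assignment` (per-peak class index) and `channel_labels`.
#' @export
modified_kmeans <- function(peaks, k, n_restarts = 20, max_iter = 100,
                            tol = 1e-6, seed, verbose = FALSE) {
  stopifnot(inherits(peaks, "peak_maps"))
  if (missing(seed)) stop("modified_kmeans requires an explicit seed")
  n <- nrow(peaks$maps)
  if (n < k) stop("cannot fit ", k, " prototypes to ", n, " peak maps")

  X <- center_rows(peaks$maps)
  g2 <- rowSums(X^2)                    # proportional to squared peak GFP
  if (sum(g2) == 0) stop("all peak maps are spatially flat")
  U <- unit_rows(X)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(child_seed(seed, r), {
      kmeans_once(X, U, g2, k, max_iter, tol, verbose)
    })
    if (is.null(best) || fit$gev > best$gev) best <- fit
  }

  maps <- best$P
  gev_class <- gev_terms(U, g2, maps, best$assignment)
  structure(list(
    maps = maps,
    k = k,
    labels = paste0("M", seq_len(k)),
    gev_per_class = gev_class,
    diagnostics = list(gev_total = best$gev),
    assignment = best$assignment,
    channel_labels = peaks$channel_labels
  ), class = "prototype_set")
}

# One restart of the modified k-means loop. X: centered maps, U: unit rows,
# g2: squared norms (GFP weights).
kmeans_once <- function(X, U, g2, k, max_iter, tol, verbose = FALSE) {
  n <- nrow(X)
  P <- U[sample.int(n, k), , drop = FALSE]
  gev_prev <- -Inf
  assignment <- rep(1L, n)
  for (it in seq_len(max_iter)) {
    corr <- U %*% t(P)                       # unit & zero-mean rows: cosine
    assignment <- max.col(corr^2, ties.method = "first")
    # Re-seed empty clusters from the worst-explained peak.
    for (c in seq_len(k)) {
      if (!any(assignment == c)) {
        worst <- which.min(corr[cbind(seq_len(n), assignment)]^2 * g2)
        if (verbose) message("re-seeding empty cluster ", c,
                             " from peak ", worst)
        P[c, ] <- U[worst, ]
        assignment[worst] <- c
      }
    }
    # Prototype update: dominant eigenvector of each cluster's scatter.
    for (c in seq_len(k)) {
      members <- X[assignment == c, , drop = FALSE]
      S <- crossprod(members)
      v <- eigen(S, symmetric = TRUE)$vectors[, 1]
      P[c, ] <- v / sqrt(sum(v^2))
    }
    P <- unit_rows(center_rows(P))           # numeric guard; rows already ~0-mean
    corr <- U %*% t(P)
    assignment <- max.col(corr^2, ties.method = "first")
    gev <- sum(g2 * corr[cbind(seq_len(n), assignment)]^2) / sum(g2)
    if (is.finite(gev_prev) &&
        abs(gev - gev_prev) < tol * max(gev_prev, .Machine$double.eps)) {
      break
    }
    gev_prev <- gev
  }
  list(P = P, assignment = assignment, gev = gev)
}

gev_terms <- function(U, g2, P, assignment) {
  corr <- U %*% t(P)
  num <- g2 * corr[cbind(seq_along(assignment), assignment)]^2
  vapply(seq_len(nrow(P)),
         function(c) sum(num[assignment == c]) / sum(g2), numeric(1))
}

#' @export
print.prototype_set <- function(x, ...) {
  cat(sprintf("<prototype_set> k = %d (%s), GEV = %.4f\n", x$k,
              paste(x$labels, collapse = ", "),
              x$diagnostics$gev_total %||% NA))
  invisible(x)
}

#' Global explained variance of an assignment
#'
#' `GEV = sum_peaks GFP_p^2 * corr^2(map_p, prototype_{a(p)}) /
#' sum_peaks GFP_p^2`; the per-class entries partition the numerator by
#' assigned class.
#'
#' @param peaks A `peak_maps` object.
#' @param prototypes A `prototype_set` (or bare k x channels matrix).
#' @param assignment Integer per-peak class in `1..k` (defaults to the
#'   polarity-invariant winner-take-all assignment).
#' @return List with `gev_total` and `gev_per_class`.
#' @export
compute_gev <- function(peaks, prototypes, assignment = NULL) {
  stopifnot(inherits(peaks, "peak_maps"))
  P <- if (inherits(prototypes, "prototype_set")) prototypes$maps
       else as.matrix(prototypes)
  X <- center_rows(peaks$maps)
  g2 <- rowSums(X^2)
  if (sum(g2) == 0) stop("GEV undefined: total peak GFP is zero")
  U <- unit_rows(X)
  Pc <- unit_rows(center_rows(P))
  corr <- U %*% t(Pc)
  if (is.null(assignment)) {
    assignment <- max.col(corr^2, ties.method = "first")
  }
  stopifnot(length(assignment) == nrow(X),
            all(assignment >= 1), all(assignment <= nrow(P)))
  num <- g2 * corr[cbind(seq_along(assignment), assignment)]^2
  list(
    gev_total = sum(num) / sum(g2),
    gev_per_class = vapply(seq_len(nrow(P)), function(c) {
      sum(num[assignment == c]) / sum(g2)
    }, numeric(1))
  )
}

# Within-cluster dispersion on unit-norm maps with polarity-aligned
# distances d^2 = 2 * (1 - |corr|), summed over members vs their prototype.
dispersion_w <- function(U, P, assignment) {
  corr <- U %*% t(P)
  a <- abs(corr[cbind(seq_along(assignment), assignment)])
  sum(2 * (1 - a))
}

#' Fit prototype sets over a range of k with selection diagnostics
#'
#' Runs [modified_kmeans()] for each k and reports the diagnostics used to
#' discuss the choice of cluster number: GEV, the cross-validation
#' criterion `CV = sigma_hat^2 * ((C-1)/(C-1-k))^2` (residual noise
#' variance penalized by degrees of freedom, C = channel count), the
#' within-cluster dispersion `W` (polarity-aligned squared distances to the
#' prototypes on unit-norm maps), and the Krzanowski-Lai index
#' `KL(k) = |DIFF(k)| / |DIFF(k+1)|` with
#' `DIFF(k) = (k-1)^(2/C) W(k-1) - k^(2/C) W(k)`. All are reported, none is
#' auto-applied: resting-state analyses conventionally fix k = 4 for
#' cross-study comparability.
#'
#' To evaluate KL at the range edges, k-1 and k+1 fits beyond `k_range` are
#' computed internally when feasible.
#'
#' @param peaks A `peak_maps` object.
#' @param k_range Integer vector of k values (default `3:8`).
#' @param ... Passed to [modified_kmeans()] (`n_restarts`, `max_iter`,
#'   `tol`, `seed`).
#' @param seed Integer seed; each k derives a child seed.
#' @return List with `table` (data.frame: k, gev, cv, w, kl) and `fits`
#'   (one `prototype_set` per k in `k_range`).
#' @export
scan_k <- function(peaks, k_range = 3:8, seed, ...) {
  stopifnot(inherits(peaks, "peak_maps"))
  if (missing(seed)) stop("scan_k requires an explicit seed")
  k_range <- sort(unique(as.integer(k_range)))
  n <- nrow(peaks$maps); C <- ncol(peaks$maps)
  if (max(k_range) > n) stop("k_range exceeds the number of peak maps")

  k_all <- (min(k_range) - 1L):(max(k_range) + 1L)
  k_all <- k_all[k_all >= 1 & k_all <= n]
  X <- center_rows(peaks$maps)
  U <- unit_rows(X)

  fits <- list(); w <- cv <- gev <- stats::setNames(
    rep(NA_real_, length(k_all)), k_all)
  for (k in k_all) {
    fit <- modified_kmeans(peaks, k, seed = child_seed(seed, 100L + k), ...)
    fits[[as.character(k)]] <- fit
    a <- fit$assignment
    corr <- U %*% t(fit$maps)
    ca <- corr[cbind(seq_len(n), a)]
    gev[as.character(k)] <- fit$diagnostics$gev_total
    sigma2 <- sum(rowSums(X^2) - (rowSums(X^2)) * ca^2) / (n * (C - 1))
    cv[as.character(k)] <- sigma2 * ((C - 1) / (C - 1 - k))^2
    w[as.character(k)] <- dispersion_w(U, fit$maps, a)
  }

  diff_k <- function(k) {
    if (!((k - 1) %in% k_all) || !(k %in% k_all)) return(NA_real_)
    (k - 1)^(2 / C) * w[as.character(k - 1)] - k^(2 / C) * w[as.character(k)]
  }
  kl <- vapply(k_range, function(k) {
    d1 <- diff_k(k); d2 <- diff_k(k + 1L)
    if (is.na(d1) || is.na(d2) || d2 == 0) return(NA_real_)
    abs(d1) / abs(d2)
  }, numeric(1))

  out_fits <- fits[as.character(k_range)]
  for (i in seq_along(out_fits)) {
    kk <- k_range[i]
    out_fits[[i]]$diagnostics <- list(
      gev_total = gev[as.character(kk)], cv = cv[as.character(kk)],
      w = w[as.character(kk)], kl = kl[i])
  }
  list(
    table = data.frame(k = k_range,
                       gev = unname(gev[as.character(k_range)]),
                       cv = unname(cv[as.character(k_range)]),
                       w = unname(w[as.character(k_range)]),
                       kl = kl),
    fits = out_fits
  )
}

#' Label prototypes against a template set
#'
#' Finds the one-to-one matching between fitted prototypes and template
#' maps that maximizes the total absolute spatial correlation (polarity
#' ignored), solved exactly over all permutations (k <= 8). The returned
#' set has its rows reordered into template order and carries the template
#' labels.
#'
#' @param prototypes A `prototype_set` with k maps.
#' @param templates A `prototype_set` or k x channels matrix of template
#'   maps; its `labels` (default `A, B, C, D, ...`) are transferred.
#' @return The relabeled, reordered `prototype_set`; attribute `"matching"`
#'   gives, per template, the index of the matched input prototype, and
#'   `"match_corr"` the absolute correlations.
#' @export
label_prototypes <- function(prototypes, templates) {
  stopifnot(inherits(prototypes, "prototype_set"))
  if (inherits(templates, "prototype_set")) {
    Tm <- templates$maps
    tlabels <- templates$labels
  } else {
    Tm <- as.matrix(templates)
    tlabels <- LETTERS[seq_len(nrow(Tm))]
  }
  k <- prototypes$k
  if (nrow(Tm) != k) {
    stop("template count (", nrow(Tm), ") must equal k (", k, ")")
  }
  if (k > 8) stop("exact permutation matching supported for k <= 8")
  A <- abs(spatial_corr_matrix(Tm, prototypes$maps))  # templates x protos
  A[is.na(A)] <- 0
  perms <- all_permutations(k)
  scores <- vapply(perms, function(p) sum(A[cbind(seq_len(k), p)]),
                   numeric(1))
  best <- perms[[which.max(scores)]]

  out <- prototypes
  out$maps <- prototypes$maps[best, , drop = FALSE]
  out$labels <- tlabels
  out$gev_per_class <- prototypes$gev_per_class[best]
  if (!is.null(prototypes$assignment)) {
    remap <- match(seq_len(k), best)
    out$assignment <- remap[prototypes$assignment]
  }
  attr(out, "matching") <- best
  attr(out, "match_corr") <- A[cbind(seq_len(k), best)]
  out
}
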