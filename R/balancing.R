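# Minority-class oversampling on encoded feature matrices. Both methods
# create synthetic minority points by linear interpolation
#   s = x_i + lambda * (x_k - x_i),   lambda ~ Uniform(0, 1)
# between a minority point x_i and one of its k nearest minority neighbours
# x_k. They differ only in how many synthetics each minority point is
# allotted: ADASYN weights points by the majority share of their
# k-neighbourhood in the full data (adaptively concentrating synthesis near
# the class boundary), SMOTE allocates uniformly.

euclidean_dist <- function(m) as.matrix(stats::dist(m, method = "euclidean"))

# Largest-remainder apportionment of `total` among weights w (sums exactly).
apportion <- function(w, total) {
  if (total <= 0) return(integer(length(w)))
  if (sum(w) == 0) w <- rep(1, length(w))
  quota <- total * w / sum(w)
  g <- floor(quota)
  rem <- total - sum(g)
  if (rem > 0) {
    extra <- order(quota - g, decreasing = TRUE)[seq_len(rem)]
    g[extra] <- g[extra] + 1L
  }
  as.integer(g)
}

resample_core <- function(m, labels, k, target_ratio, seed, method) {
  stopifnot(is.matrix(m), nrow(m) == length(labels), all(labels %in% c(0, 1)))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  minority <- if (n1 <= n0) 1L else 0L
  min_idx <- which(labels == minority)
  n_min <- length(min_idx); n_maj <- nrow(m) - n_min
  if (n_min < k + 1L) {
    stop("minority class has ", n_min, " members; needs at least k + 1 = ", k + 1L)
  }
  G <- max(0L, as.integer(ceiling(n_maj * target_ratio)) - n_min)

  base <- list(matrix = m, labels = labels,
               provenance = rep("original", nrow(m)),
               method = method, seed = seed,
               pairs = data.frame(i = integer(), k = integer(),
                                  lambda = numeric()))
  if (G == 0L) return(structure(base, class = "resampled_dataset"))

  D <- euclidean_dist(m)
  # per-point allotment
  if (method == "ADASYN") {
    r <- vapply(min_idx, function(i) {
      nb <- order(D[i, -i])                      # neighbours among all points
      nb_idx <- seq_len(nrow(m))[-i][nb[seq_len(k)]]
      sum(labels[nb_idx] != minority) / k
    }, numeric(1))
    g <- apportion(r, G)
  } else {
    g <- apportion(rep(1, n_min), G)
  }

  # k nearest minority neighbours of each minority point (interpolation pool)
  pool <- lapply(seq_len(n_min), function(j) {
    others <- min_idx[-j]
    others[order(D[min_idx[j], others])][seq_len(k)]
  })

  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed))
  set.seed(seed)
  syn <- vector("list", G); prov_i <- integer(G); prov_k <- integer(G)
  lam <- numeric(G); s <- 0L
  for (j in seq_len(n_min)) {
    for (rep_ in seq_len(g[j])) {
      s <- s + 1L
      xi <- m[min_idx[j], ]
      kk <- pool[[j]][sample.int(k, 1L)]
      l <- stats::runif(1)
      syn[[s]] <- xi + l * (m[kk, ] - xi)
      prov_i[s] <- min_idx[j]; prov_k[s] <- kk; lam[s] <- l
    }
  }
  syn_m <- do.call(rbind, syn)
  colnames(syn_m) <- colnames(m)
  rownames(syn_m) <- paste0("syn", seq_len(G))
  out <- list(matrix = rbind(m, syn_m),
              labels = c(labels, rep(minority, G)),
              provenance = c(rep("original", nrow(m)), rep("synthetic", G)),
              method = method, seed = seed,
              pairs = data.frame(i = prov_i, k = prov_k, lambda = lam))
  structure(out, class = "resampled_dataset")
}

# Save/restore the global RNG state so oversampling is seed-local.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' ADASYN adaptive synthetic oversampling
#'
#' Oversamples the minority class of a labelled feature matrix up to
#' `target_ratio` times the majority count. The total synthetic budget
#' G = N_maj * target_ratio - N_min is apportioned across minority points in
#' proportion to the majority share of each point's k nearest neighbours in
#' the full data (largest-remainder rounding, so the allotments sum to G
#' exactly); points near the class boundary thus receive more synthetics.
#' Each synthetic is an interpolation s = x_i + lambda (x_k - x_i) with x_k
#' drawn uniformly from the k nearest *minority* neighbours of x_i and
#' lambda ~ Uniform(0, 1).
#'
#' Original rows are preserved verbatim and come first in the output; the
#' generating pair and lambda of every synthetic row are logged in the
#' `pairs` element for auditability.
#'
#' @param m Numeric feature matrix.
#' @param labels 0/1 vector, one per row.
#' @param k Neighbourhood size (default 5).
#' @param target_ratio Desired minority/majority ratio after resampling
#'   (default 1, i.e. full balance).
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @return A `resampled_dataset`: list with `matrix`, `labels`, `provenance`
#'   (`"original"`/`"synthetic"` per row), `method`, `seed`, and `pairs`
#'   (data.frame of generating indices `i`, `k` and `lambda` per synthetic).
#' @references He, H., Bai, Y., Garcia, E. A., Li, S. (2008) ADASYN:
#'   adaptive synthetic sampling approach for imbalanced learning.
#' @export
adasyn_oversample <- function(m, labels, k = 5L, target_ratio = 1.0, seed = 1L) {
  resample_core(m, labels, k, target_ratio, seed, "ADASYN")
}

#' SMOTE synthetic minority oversampling
#'
#' Identical interpolation rule to [adasyn_oversample()] but with a uniform
#' (non-density-weighted) allocation of synthetics across minority points.
#'
#' @inheritParams adasyn_oversample
#' @return A `resampled_dataset`; see [adasyn_oversample()].
#' @references Chawla, N. V. et al. (2002) SMOTE: synthetic minority
#'   over-sampling technique. JAIR 16, 321-357.
#' @export
smote_oversample <- function(m, labels, k = 5L, target_ratio = 1.0, seed = 1L) {
  resample_core(m, labels, k, target_ratio, seed, "SMOTE")
}

#' Apply a named balancing method
#'
#' Dispatch helper used by the evaluation protocol: `method = "none"` returns
#' the input unchanged (wrapped with all-original provenance).
#'
#' @inheritParams adasyn_oversample
#' @param method One of `"ADASYN"`, `"SMOTE"`, `"none"`.
#' @return A `resampled_dataset`.
#' @export
balance_dataset <- function(m, labels, method = c("none", "ADASYN", "SMOTE"),
                            k = 5L, target_ratio = 1.0, seed = 1L) {
  method <- match.arg(method)
  if (method == "none") {
    return(structure(list(matrix = m, labels = as.integer(labels),
                          provenance = rep("original", nrow(m)),
                          method = "none", seed = seed,
                          pairs = data.frame(i = integer(), k = integer(),
                                             lambda = numeric())),
                     class = "resampled_dataset"))
  }
  if (method == "ADASYN") adasyn_oversample(m, labels, k, target_ratio, seed)
  else smote_oversample(m, labels, k, target_ratio, seed)
}

#' @export
print.resampled_dataset <- function(x, ...) {
  cat(sprintf("resampled_dataset (%s): %d rows (%d original + %d synthetic)\n",
              x$method, nrow(x$matrix), sum(x$provenance == "original"),
              sum(x$provenance == "synthetic")))
  invisible(x)
}
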