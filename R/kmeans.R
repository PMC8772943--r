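# Run code under a temporary RNG state so package functions do not disturb
# the caller's random stream.
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

l1_dist_to <- function(x, centroid) {
  # rowwise L1 distance of matrix x to one centroid vector
  colSums(abs(t(x) - centroid))
}

kmedians_objective <- function(x, centroids, assign) {
  total <- 0
  for (j in seq_len(nrow(centroids))) {
    i <- which(assign == j)
    if (length(i)) total <- total + sum(l1_dist_to(x[i, , drop = FALSE],
                                                   centroids[j, ]))
  }
  total
}

kmedians_seed_pp <- function(x, k) {
  # k-means++-style seeding under L1: next centre drawn with probability
  # proportional to the distance to the nearest chosen centre
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d <- l1_dist_to(x, x[idx[1L], ])
    for (j in 2:k) {
      if (all(d == 0)) {
        idx[j] <- sample.int(n, 1L)
      } else {
        idx[j] <- sample.int(n, 1L, prob = d)
      }
      d <- pmin(d, l1_dist_to(x, x[idx[j], ]))
    }
  }
  x[idx, , drop = FALSE]
}

kmedians_once <- function(x, k, max_iter, centroid_update) {
  centroids <- kmedians_seed_pp(x, k)
  assign <- rep(NA_integer_, nrow(x))
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    dmat <- vapply(seq_len(k), function(j) l1_dist_to(x, centroids[j, ]),
                   numeric(nrow(x)))
    new_assign <- max.col(-dmat, ties.method = "first")
    for (j in seq_len(k)) {
      i <- which(new_assign == j)
      if (!length(i)) {
        # re-seed an empty cluster at the point farthest from its centre
        far <- which.max(dmat[cbind(seq_len(nrow(x)), new_assign)])
        new_assign[far] <- j
        i <- far
      }
      centroids[j, ] <- if (centroid_update == "median") {
        apply(x[i, , drop = FALSE], 2L, stats::median)
      } else {
        colMeans(x[i, , drop = FALSE])
      }
    }
    trace <- c(trace, kmedians_objective(x, centroids, new_assign))
    if (!anyNA(assign) && all(new_assign == assign)) break
    assign <- new_assign
  }
  list(assignments = assign, centroids = centroids,
       objective = kmedians_objective(x, centroids, assign), trace = trace)
}

#' Manhattan-distance k-means (k-medians) of an expression matrix
#'
#' Clusters features of a TPM matrix after subtracting each feature's mean
#' expression level, so clusters capture expression *profiles* rather than
#' absolute abundance. Uses Lloyd-style iterations under the L1 (Manhattan)
#' metric with component-wise **median** centroid updates — the true L1
#' minimizer, so the objective is non-increasing at every step — repeated
#' over `restarts` independent k-means++-style seeded initializations
#' ("rounds"); the run with the lowest total Manhattan distance is kept.
#' `centroid = "mean"` reproduces conventional mean-update behaviour for
#' compatibility.
#'
#' @param m An [expression_matrix()] (features x samples).
#' @param k Number of clusters (1 <= k <= number of features).
#' @param restarts Number of independent seeded rounds (default 6).
#' @param seed Integer seed; the whole procedure is deterministic given it.
#' @param max_iter Maximum Lloyd iterations per round.
#' @param centroid `"median"` (default) or `"mean"` update.
#' @return A `kmedians_fit` list: `assignments` (named integer vector,
#'   feature -> cluster in 1..k), `centroids` (k x samples matrix on the
#'   mean-centered scale), `objective`, `objective_trace` of the winning
#'   round, `seed`, `restarts`.
#' @export
kmeans_manhattan <- function(m, k, restarts = 6, seed = 1, max_iter = 100,
                             centroid = c("median", "mean")) {
  centroid <- match.arg(centroid)
  x <- unclass(m)
  if (k < 1 || k > nrow(x)) {
    stop("k must be between 1 and the number of features (", nrow(x), ")",
         call. = FALSE)
  }
  x <- x - rowMeans(x)  # "mean expression level ... subtracted"
  best <- NULL
  with_local_seed(seed, {
    for (r in seq_len(restarts)) {
      fit <- kmedians_once(x, k, max_iter, centroid)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
  })
  structure(
    list(assignments = stats::setNames(best$assignments, rownames(x)),
         centroids = best$centroids, objective = best$objective,
         objective_trace = best$trace, seed = seed, restarts = restarts,
         centroid = centroid),
    class = "kmedians_fit"
  )
}

#' @export
print.kmedians_fit <- function(x, ...) {
  cat("<kmedians_fit> k =", nrow(x$centroids), "clusters,",
      length(x$assignments), "features, objective =",
      format(x$objective), "\n")
  invisible(x)
}
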