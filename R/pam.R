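#' One-dimensional partitioning around medoids
#'
#' k-medoids clustering of a numeric vector under absolute-difference
#' distance. For the k = 2 case used to dichotomize ERG expression or
#' signature scores, inputs up to `exhaustive_limit` points are solved
#' exactly by scanning every medoid pair; larger inputs (or k > 2) use
#' the classic BUILD + SWAP iteration. Ties are broken toward the lowest
#' index, so results are order-stable and reproducible.
#'
#' @param values finite numeric vector, length >= k.
#' @param k number of clusters (default 2).
#' @param exhaustive_limit maximum n for the exact k = 2 pair scan.
#' @return object of class `pam_result`: list with `medoids` (values),
#'   `medoid_index`, `assignment` (cluster id per input), `total_cost`
#'   (sum of distances to assigned medoids) and `method`.
#' @export
pam_1d <- function(values, k = 2L, exhaustive_limit = 500L) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop_parameter("`values` must be finite numeric.")
  }
  k <- check_count(k, "k", min = 1L)
  n <- length(values)
  if (n < k) {
    stop_parameter(sprintf("Need at least k = %d values, got %d.", k, n))
  }
  if (k == 2L && n <= exhaustive_limit) {
    res <- pam_exhaustive_k2(values)
    method <- "exhaustive"
  } else {
    res <- pam_build_swap(values, k)
    method <- "build+swap"
  }
  assignment <- assign_to_medoids(values, res)
  structure(
    list(
      medoids = values[res],
      medoid_index = res,
      assignment = assignment,
      total_cost = sum(abs(values - values[res][assignment])),
      method = method
    ),
    class = "pam_result"
  )
}

# Exact scan over all C(n, 2) medoid pairs. Cost ties are genuine in
# 1-D (any point between the middle order statistics of an even-sized
# cluster has the same absolute-deviation sum), so ties are broken by
# the lexicographically smallest sorted medoid-value pair, which makes
# the result invariant to input order; among equal-value duplicates the
# lowest index wins.
pam_exhaustive_k2 <- function(values) {
  n <- length(values)
  d <- abs(outer(values, values, "-"))
  tol <- 1e-9
  best_cost <- Inf
  best <- c(1L, 2L)
  best_vals <- c(Inf, Inf)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    costs <- colSums(pmin(d[, js, drop = FALSE], d[, i]))
    hit <- which(costs <= min(costs[which.min(costs)], best_cost) + tol)
    for (h in hit) {
      cand_cost <- costs[h]
      if (cand_cost > best_cost + tol) next
      cand <- c(i, js[h])
      cand_vals <- sort(values[cand])
      better <- cand_cost < best_cost - tol ||
        (cand_vals[1] < best_vals[1] - tol) ||
        (abs(cand_vals[1] - best_vals[1]) <= tol &&
           cand_vals[2] < best_vals[2] - tol)
      if (better) {
        best_cost <- min(best_cost, cand_cost)
        best <- cand
        best_vals <- cand_vals
      }
    }
  }
  best
}

# Classic PAM: greedy BUILD seeding then steepest-descent SWAP.
pam_build_swap <- function(values, k) {
  n <- length(values)
  d <- abs(outer(values, values, "-"))
  medoids <- which.min(colSums(d))[1L]
  while (length(medoids) < k) {
    cur <- apply(d[, medoids, drop = FALSE], 1L, min)
    gains <- vapply(seq_len(n), function(j) {
      if (j %in% medoids) return(-Inf)
      sum(pmax(cur - d[, j], 0))
    }, numeric(1))
    medoids <- c(medoids, which.max(gains)[1L])
  }
  cost_of <- function(meds) sum(apply(d[, meds, drop = FALSE], 1L, min))
  repeat {
    cur_cost <- cost_of(medoids)
    best_cost <- cur_cost
    best_meds <- medoids
    for (mi in seq_along(medoids)) {
      for (j in setdiff(seq_len(n), medoids)) {
        cand <- medoids
        cand[mi] <- j
        cc <- cost_of(cand)
        if (cc < best_cost - 1e-12) {
          best_cost <- cc
          best_meds <- cand
        }
      }
    }
    if (best_cost >= cur_cost - 1e-12) break
    medoids <- best_meds
  }
  sort(medoids)
}

# Nearest-medoid assignment; distance ties go to the lower-index medoid.
assign_to_medoids <- function(values, medoid_index) {
  d <- abs(outer(values, values[medoid_index], "-"))
  apply(d, 1L, which.min)
}

#' @export
print.pam_result <- function(x, ...) {
  cat(sprintf(
    "PAM (%s): %d medoids at %s; total cost %.4g\n",
    x$method, length(x$medoids),
    paste(format(x$medoids), collapse = ", "), x$total_cost
  ))
  invisible(x)
}

#' @method tidy pam_result
#' @export
tidy.pam_result <- function(x, ...) {
  tibble(
    cluster = x$assignment,
    medoid = x$medoids[x$assignment]
  )
}

#' @method glance pam_result
#' @export
glance.pam_result <- function(x, ...) {
  tibble(
    k = length(x$medoids),
    total_cost = x$total_cost,
    method = x$method
  )
}

#' Label a two-cluster PAM result as high/low
#'
#' @param result a k = 2 [pam_1d()] result.
#' @param positive_means_high when `TRUE` (default) the cluster with the
#'   larger medoid receives `high_label`.
#' @param high_label,low_label labels to assign (e.g. "positive" /
#'   "negative" for ERG status).
#' @return character vector of labels, one per input value.
#' @export
label_clusters <- function(result, positive_means_high = TRUE,
                           high_label = "high", low_label = "low") {
  if (!inherits(result, "pam_result") || length(result$medoids) != 2L) {
    stop_parameter("`result` must be a k = 2 pam_result.")
  }
  if (result$medoids[1] == result$medoids[2]) {
    stop_parameter("Cluster medoids are equal; high/low labelling is undefined.")
  }
  high_cluster <- which.max(result$medoids)
  lab <- ifelse(result$assignment == high_cluster, high_label, low_label)
  if (!positive_means_high) {
    lab <- ifelse(result$assignment == high_cluster, low_label, high_label)
  }
  lab
}
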