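new_cluster_model <- function(method, means, labels, settings = list(),
                              weights = NULL, variances = NULL,
                              loglik = NULL, seed = NULL) {
  ord <- order(means)
  relab <- match(seq_along(means), ord)
  structure(list(method = method, k = length(means),
                 means = as.numeric(means[ord]),
                 labels = relab[labels], sizes = tabulate(relab[labels],
                                                          length(means)),
                 weights = if (!is.null(weights)) weights[ord],
                 variances = if (!is.null(variances)) variances[ord],
                 loglik = loglik, settings = settings, seed = seed),
            class = "baccam_cluster")
}

#' @export
print.baccam_cluster <- function(x, ...) {
  cat(sprintf("baccam_cluster: %s, k = %d\n", x$method, x$k))
  cat("  means:", paste0("M", seq_len(x$k) - 1L, "=",
                         formatC(x$means, digits = 3, format = "f"),
                         collapse = " "), "\n")
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  if (!is.null(x$loglik))
    cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}

# reduce k when the data cannot support it (fewer distinct values than
# requested clusters/components)
effective_k <- function(values, k, what) {
  nd <- length(unique(values))
  if (nd < k) {
    warning("only ", nd, " distinct values; reducing ", what, " from ",
            k, " to ", nd)
    k <- nd
  }
  k
}

#' Fit a one-dimensional Gaussian mixture by EM
#'
#' Expectation--maximisation for a univariate Gaussian mixture on the
#' per-well ratio values, the clustering engine behind the automated
#' deconvolution. Initialisation is k-means++-style (seeded), the
#' log-likelihood is non-decreasing across iterations, convergence is
#' declared when it improves by less than `tol`, and component variances
#' are floored at `var_floor` to survive degenerate (point-mass) clusters.
#' Components are reported sorted by ascending mean; each point is labelled
#' by maximum responsibility.
#'
#' @param values numeric vector (no NAs).
#' @param n_components number of Gaussian components (2 or 3 in the
#'   deconvolution menu). Reduced with a warning if the data has fewer
#'   distinct values.
#' @param seed integer seed (initialisation).
#' @param tol convergence tolerance on the log-likelihood. Default 1e-6.
#' @param max_iter iteration cap. Default 500.
#' @param var_floor variance floor. Default 1e-6.
#' @return a `baccam_cluster` with means, labels, weights, variances and
#'   the final log-likelihood.
#' @export
fit_gmm_1d <- function(values, n_components = 2, seed = 1, tol = 1e-6,
                       max_iter = 500, var_floor = 1e-6) {
  stopifnot(!anyNA(values), length(values) >= 1)
  k <- effective_k(values, n_components, "n_components")
  n <- length(values)
  if (k == 1L) {
    v <- max(stats::var(values) * (n - 1) / n, var_floor)
    if (is.na(v)) v <- var_floor
    ll <- sum(stats::dnorm(values, mean(values), sqrt(v), log = TRUE))
    return(new_cluster_model("gmm", mean(values), rep(1L, n),
                             settings = list(n_components = 1L, tol = tol),
                             weights = 1, variances = v, loglik = ll,
                             seed = seed))
  }
  local_rng(seed)
  # k-means++-style spread-out initial means
  mu <- numeric(k)
  mu[1] <- values[sample.int(n, 1L)]
  for (j in 2:k) {
    d2 <- vapply(values, function(v) min((v - mu[1:(j - 1)])^2), numeric(1))
    mu[j] <- if (sum(d2) > 0) values[sample.int(n, 1L, prob = d2)]
             else values[sample.int(n, 1L)]
  }
  v0 <- max(stats::var(values), var_floor)
  sigma2 <- rep(v0, k)
  w <- rep(1 / k, k)

  loglik <- -Inf
  for (iter in seq_len(max_iter)) {
    logdens <- vapply(seq_len(k), function(j) {
      log(w[j]) + stats::dnorm(values, mu[j], sqrt(sigma2[j]), log = TRUE)
    }, numeric(n))
    if (n == 1L) logdens <- matrix(logdens, nrow = 1L)
    m <- apply(logdens, 1L, max)
    lse <- m + log(rowSums(exp(logdens - m)))
    new_loglik <- sum(lse)
    resp <- exp(logdens - lse)
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-12)
    w <- nk / n
    mu <- colSums(resp * values) / nk
    sigma2 <- pmax(colSums(resp * (outer(values, mu, "-")^2)) / nk,
                   var_floor)
    if (is.finite(loglik) && new_loglik - loglik < tol) {
      loglik <- new_loglik
      break
    }
    loglik <- new_loglik
  }
  labels <- max.col(vapply(seq_len(k), function(j) {
    log(w[j]) + stats::dnorm(values, mu[j], sqrt(sigma2[j]), log = TRUE)
  }, numeric(n)), ties.method = "first")
  new_cluster_model("gmm", mu, labels,
                    settings = list(n_components = k, tol = tol,
                                    max_iter = max_iter,
                                    var_floor = var_floor),
                    weights = w, variances = sigma2, loglik = loglik,
                    seed = seed)
}

# ---- DBSCAN (1-D) ----------------------------------------------------------

dbscan_1d <- function(values, eps, min_samples = 5) {
  n <- length(values)
  d <- abs(outer(values, values, "-"))
  adj <- d <= eps
  core <- rowSums(adj) >= min_samples  # the point itself counts
  labels <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(labels[i])) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      if (!core[p]) next
      nb <- which(adj[p, ] & is.na(labels))
      labels[nb] <- cl
      queue <- c(queue, nb)
    }
  }
  labels  # NA = noise
}

# ---- OPTICS with xi extraction --------------------------------------------

# OPTICS ordering pass: returns the processing order and the reachability
# value each point had when it was chosen (the reachability plot)
optics_run <- function(values, min_samples) {
  n <- length(values)
  d <- abs(outer(values, values, "-"))
  core <- if (n >= min_samples)
    apply(d, 1L, function(r) sort(r, partial = min_samples)[min_samples])
  else rep(Inf, n)  # nothing is dense enough to be a core point
  reach <- rep(Inf, n)
  processed <- rep(FALSE, n)
  ordering <- integer(n)
  plot_reach <- numeric(n)
  for (step in seq_len(n)) {
    cand <- which(!processed)
    p <- cand[which.min(reach[cand])]
    ordering[step] <- p
    plot_reach[step] <- reach[p]
    processed[p] <- TRUE
    un <- which(!processed)
    if (length(un))
      reach[un] <- pmin(reach[un], pmax(core[p], d[p, un]))
  }
  list(ordering = ordering, reachability = plot_reach)
}

# steep-area cluster extraction from a reachability plot (the xi method)
xi_extract <- function(reach, xi = 0.05, min_samples = 5,
                       min_cluster_size = min_samples) {
  n <- length(reach)
  r <- c(reach, Inf)
  xic <- 1 - xi
  ratio <- r[1:n] / r[2:(n + 1)]
  ratio[is.nan(ratio)] <- 1  # inf/inf and 0/0: level, not steep
  steep_up <- ratio <= xic
  steep_down <- ratio >= 1 / xic
  upward <- ratio < 1
  downward <- ratio > 1

  extend <- function(steep, xward, start) {
    non_xward <- 0L; index <- start; end <- start
    while (index <= n) {
      if (steep[index]) { non_xward <- 0L; end <- index }
      else if (!xward[index]) {
        non_xward <- non_xward + 1L
        if (non_xward > min_samples) break
      } else break
      index <- index + 1L
    }
    end
  }

  sdas <- list()
  clusters <- list()
  index <- 1L
  mib <- 0
  filter_sdas <- function(sdas, mib) {
    if (is.infinite(mib)) return(list())
    keep <- Filter(function(D) mib <= r[D$start] * xic, sdas)
    lapply(keep, function(D) { D$mib <- max(D$mib, mib); D })
  }
  steep_idx <- which(steep_up | steep_down)
  for (si in steep_idx) {
    if (si < index) next
    mib <- max(mib, max(r[index:si]))
    if (steep_down[si]) {
      sdas <- filter_sdas(sdas, mib)
      D_end <- extend(steep_down, upward, si)
      sdas <- c(sdas, list(list(start = si, end = D_end, mib = 0)))
      index <- D_end + 1L
      mib <- if (index <= n + 1L) r[index] else Inf
    } else {
      sdas <- filter_sdas(sdas, mib)
      U_start <- si
      U_end <- extend(steep_up, downward, si)
      index <- U_end + 1L
      mib <- if (index <= n + 1L) r[index] else Inf
      r_end <- r[min(U_end + 1L, n + 1L)]
      for (D in sdas) {
        if (r_end * xic < D$mib) next
        c_start <- D$start; c_end <- U_end
        D_max <- r[D$start]
        if (D_max * xic >= r_end) {
          while (c_start < D$end && r[c_start + 1L] > r_end)
            c_start <- c_start + 1L
        } else if (r_end * xic >= D_max) {
          while (c_end > U_start && r[c_end - 1L] > D_max)
            c_end <- c_end - 1L
        }
        if (c_end - c_start + 1L < min_cluster_size) next
        if (c_start > D$end) next
        if (c_end < U_start) next
        clusters <- c(clusters, list(c(c_start, c_end)))
      }
    }
  }
  clusters
}

optics_1d <- function(values, min_samples = 5, xi = 0.05,
                      min_cluster_size = min_samples) {
  run <- optics_run(values, min_samples)
  clusters <- xi_extract(run$reachability, xi = xi,
                         min_samples = min_samples,
                         min_cluster_size = min_cluster_size)
  n <- length(values)
  lab_order <- rep(NA_integer_, n)
  if (length(clusters)) {
    sizes <- vapply(clusters, function(cc) cc[2] - cc[1] + 1L, numeric(1))
    cl <- 0L
    for (ci in order(sizes)) {  # leaves (smallest spans) claim points first
      span <- clusters[[ci]][1]:clusters[[ci]][2]
      if (all(is.na(lab_order[span]))) {
        cl <- cl + 1L
        lab_order[span] <- cl
      }
    }
  }
  labels <- rep(NA_integer_, n)
  labels[run$ordering] <- lab_order
  labels
}

# assign noise points (NA labels) to the nearest cluster by value
absorb_noise <- function(values, labels) {
  if (!anyNA(labels)) return(labels)
  ok <- which(!is.na(labels))
  for (i in which(is.na(labels))) {
    labels[i] <- labels[ok[which.min(abs(values[ok] - values[i]))]]
  }
  labels
}

#' One-dimensional clustering of ratio values
#'
#' Unified front end for the deconvolution's clustering menu: k-means
#' (seeded restarts of [stats::kmeans()]), density-based DBSCAN, OPTICS
#' with steep-area (xi) cluster extraction, and the Gaussian mixture of
#' [fit_gmm_1d()]. DBSCAN/OPTICS noise points are assigned to the nearest
#' cluster by value before any downstream grouping; if a density method
#' finds no cluster at all, the plate collapses to a single cluster with a
#' warning.
#'
#' @param values numeric vector (no NAs).
#' @param method `"kmeans"`, `"dbscan"`, `"optics"` or `"gmm"`.
#' @param k clusters for k-means (2 or 3 in the menu). Default 2.
#' @param eps DBSCAN neighbourhood radius (0.4 or 0.2 in the menu).
#' @param min_samples density threshold for DBSCAN/OPTICS. Default 5.
#' @param xi OPTICS steepness. Default 0.05.
#' @param n_components GMM components. Default 2.
#' @param nstart k-means restarts. Default 25.
#' @param seed integer seed.
#' @return a `baccam_cluster` (clusters sorted by ascending mean; labels
#'   1..k accordingly).
#' @export
cluster_1d <- function(values, method = c("gmm", "kmeans", "dbscan", "optics"),
                       k = 2, eps = 0.4, min_samples = 5, xi = 0.05,
                       n_components = 2, nstart = 25, seed = 1) {
  method <- match.arg(method)
  stopifnot(!anyNA(values), length(values) >= 1)
  if (method == "gmm")
    return(fit_gmm_1d(values, n_components = n_components, seed = seed))
  if (method == "kmeans") {
    kk <- effective_k(values, k, "k")
    if (kk == 1L)
      return(new_cluster_model("kmeans", mean(values),
                               rep(1L, length(values)),
                               settings = list(k = 1L), seed = seed))
    if (kk >= length(values)) {
      # one point per cluster: the partition is forced (stats::kmeans
      # requires k < n)
      return(new_cluster_model("kmeans", values, seq_along(values),
                               settings = list(k = kk), seed = seed))
    }
    local_rng(seed)
    fit <- stats::kmeans(values, centers = kk, nstart = nstart,
                         iter.max = 100)
    return(new_cluster_model("kmeans", as.numeric(fit$centers), fit$cluster,
                             settings = list(k = kk, nstart = nstart),
                             seed = seed))
  }
  labels <- if (method == "dbscan") dbscan_1d(values, eps, min_samples)
            else optics_1d(values, min_samples = min_samples, xi = xi)
  if (all(is.na(labels))) {
    warning(method, " found no cluster; falling back to a single cluster")
    labels <- rep(1L, length(values))
  }
  labels <- absorb_noise(values, labels)
  means <- tapply(values, labels, mean)
  relab <- match(labels, as.integer(names(means)))
  settings <- if (method == "dbscan") list(eps = eps, min_samples = min_samples)
              else list(min_samples = min_samples, xi = xi)
  new_cluster_model(method, as.numeric(means), relab, settings = settings,
                    seed = seed)
}
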