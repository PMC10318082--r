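#' Local Outlier Factor scores for 1-D data
#'
#' Density-based outlier scores computed from first principles on the
#' per-well ratio values. For each point, with `k = n_neighbors`:
#' the k-distance is the distance to its k-th nearest neighbour; the
#' neighbourhood `N_k` contains every other point within the k-distance
#' (ties included, so it can exceed k); the reachability distance from p to
#' o is `max(k-distance(o), d(p, o))`; the local reachability density
#' `lrd(p)` is the reciprocal of the mean reachability distance from p to
#' its neighbours; and `LOF(p)` is the mean ratio of its neighbours' lrd to
#' its own. Scores near 1 indicate points embedded in their local density;
#' scores well above 1 indicate points in sparser regions than their
#' neighbours.
#'
#' @param values numeric vector (NAs not allowed here).
#' @param n_neighbors neighbourhood size `k`.
#' @return numeric vector of LOF scores.
#' @export
lof_scores <- function(values, n_neighbors) {
  n <- length(values)
  stopifnot(n >= n_neighbors + 1L, n_neighbors >= 1L, !anyNA(values))
  d <- abs(outer(values, values, "-"))
  diag(d) <- Inf
  kdist <- apply(d, 1L, function(r) sort(r, partial = n_neighbors)[n_neighbors])
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= kdist[i]))
  # a tiny additive constant keeps lrd finite on duplicated values
  lrd <- vapply(seq_len(n), function(i) {
    1 / (mean(pmax(kdist[nbrs[[i]]], d[i, nbrs[[i]]])) + 1e-10)
  }, numeric(1))
  vapply(seq_len(n), function(i) mean(lrd[nbrs[[i]]]) / lrd[i], numeric(1))
}

#' Detect outlier wells by Local Outlier Factor
#'
#' Flags wells whose ratio value sits in a low-density region of the
#' plate's value distribution, the curation step that precedes clustering.
#' The neighbourhood size is the channel-tuned knob (blue-light data uses
#' 20, red-light data 10). A point is an outlier iff its LOF score exceeds
#' both the `1 - contamination` score quantile and the absolute floor
#' `lof_min`: the quantile caps how many wells can be flagged, while the
#' floor guarantees that clean, evenly dense data yields no outliers.
#'
#' @param values numeric vector of ratio values (NAs allowed; NA entries
#'   are returned as inliers with NA score and never enter the
#'   computation).
#' @param n_neighbors neighbourhood size. Default 20 (blue-channel
#'   setting); use 10 for red-channel data.
#' @param contamination upper bound on the flagged fraction. Default 0.05.
#' @param lof_min absolute LOF floor below which nothing is flagged.
#'   Default 1.5.
#' @return a data.frame with columns `value`, `score`, `label`
#'   (+1 inlier / -1 outlier), and attribute `cutoff`.
#' @examples
#' v <- c(runif(95, 0, 0.1), 0.9)
#' table(lof_detect(v, n_neighbors = 20)$label)
#' @export
lof_detect <- function(values, n_neighbors = 20, contamination = 0.05,
                       lof_min = 1.5) {
  ok <- which(!is.na(values))
  score <- rep(NA_real_, length(values))
  label <- rep(1L, length(values))
  if (length(ok) < n_neighbors + 1L) {
    warning("fewer than n_neighbors + 1 non-missing values; ",
            "treating all wells as inliers")
    out <- data.frame(value = values, score = score, label = label)
    attr(out, "cutoff") <- NA_real_
    return(out)
  }
  s <- lof_scores(values[ok], n_neighbors)
  cutoff <- max(stats::quantile(s, 1 - contamination, names = FALSE),
                lof_min)
  score[ok] <- s
  label[ok] <- ifelse(s > cutoff, -1L, 1L)
  out <- data.frame(value = values, score = score, label = label)
  attr(out, "cutoff") <- cutoff
  out
}

#' Reassign outlier wells to the nearest inlier value
#'
#' Each flagged well's value is replaced by the raw value of the nearest
#' inlier (smallest absolute difference; ties resolved to the lower
#' value); inliers are untouched. Applying the operation twice equals
#' applying it once. This curation removes small low-density clumps so the
#' subsequent 1-D clustering sees sharper cluster edges.
#'
#' @param values numeric vector (NAs pass through).
#' @param labels +1/-1 labels from [lof_detect()] (its `label` column, or
#'   the data.frame itself).
#' @return curated numeric vector.
#' @export
reassign_outliers <- function(values, labels) {
  if (is.data.frame(labels)) labels <- labels$label
  stopifnot(length(labels) == length(values))
  inl <- which(labels == 1L & !is.na(values))
  out <- which(labels == -1L & !is.na(values))
  if (!length(out)) return(values)
  if (!length(inl)) {
    warning("no inliers available; returning values unchanged")
    return(values)
  }
  pool <- sort(unique(values[inl]))  # ascending: ties pick the lower value
  curated <- values
  for (i in out) {
    curated[i] <- pool[which.min(abs(pool - values[i]))]
  }
  curated
}
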