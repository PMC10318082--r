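# Independent brute-force oracles, written straight from the definitions.
# They deliberately share no code with the package internals they check.

# LOF from the textbook definition, plain loops
brute_lof <- function(values, k) {
  n <- length(values)
  d <- abs(outer(values, values, "-"))
  diag(d) <- Inf
  kdist <- numeric(n)
  nbrs <- vector("list", n)
  for (i in 1:n) {
    kdist[i] <- sort(d[i, ])[k]
    nbrs[[i]] <- which(d[i, ] <= kdist[i])
  }
  lrd <- numeric(n)
  for (i in 1:n) {
    reach <- numeric(0)
    for (j in nbrs[[i]]) reach <- c(reach, max(kdist[j], d[i, j]))
    lrd[i] <- 1 / (mean(reach) + 1e-10)
  }
  lof <- numeric(n)
  for (i in 1:n) {
    lof[i] <- mean(lrd[nbrs[[i]]]) / lrd[i]
  }
  lof
}

# exhaustive optimal 1-D k-means: in one dimension the optimal partition is
# contiguous in sorted order, so enumerate all contiguous splits
brute_kmeans_1d <- function(values, k) {
  sv <- sort(values)
  n <- length(sv)
  cuts <- utils::combn(n - 1, k - 1, simplify = FALSE)
  best <- NULL
  best_ss <- Inf
  for (cut in cuts) {
    bounds <- c(0, cut, n)
    ss <- 0
    means <- numeric(k)
    for (j in 1:k) {
      seg <- sv[(bounds[j] + 1):bounds[j + 1]]
      means[j] <- mean(seg)
      ss <- ss + sum((seg - means[j])^2)
    }
    if (ss < best_ss - 1e-12) {
      best_ss <- ss
      best <- means
    }
  }
  list(means = best, withinss = best_ss)
}

# exhaustive threshold scan: try every observed value as a cut, both sides
brute_threshold <- function(values, truth) {
  cand <- sort(unique(c(values[!is.na(values)] - 1e-9,
                        values[!is.na(values)] + 1e-9)))
  best_acc <- -1
  best_t <- NA
  for (t in cand) {
    pred <- ifelse(is.na(values), 0L, as.integer(values > t))
    acc <- mean(pred == truth)
    if (acc > best_acc + 1e-12) {
      best_acc <- acc
      best_t <- t
    }
  }
  list(threshold = best_t, accuracy = best_acc)
}

# per-character popcount of a text payload
brute_popcount <- function(text) {
  if (!nchar(text)) return(0L)
  sum(vapply(utf8ToInt(text), function(code) {
    sum(as.integer(intToBits(code)[1:8]))
  }, integer(1)))
}
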