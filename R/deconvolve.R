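#' Full ON/OFF criteria assessment
#'
#' Edge-case test run after clustering: a plate is declared fully ON when
#' even its lowest cluster mean lies above the calibrated cutoff, fully
#' OFF when even its highest cluster mean lies below it, and MIXED
#' otherwise (in which case cluster grouping decides the per-well states).
#'
#' @param model a `baccam_cluster` fit.
#' @param cutoff calibrated ratio threshold. Default 0.5 on the bounded
#'   excision fraction; see [calibrate_cutoff()].
#' @return `"ALL_ON"`, `"ALL_OFF"` or `"MIXED"`.
#' @export
full_on_off_check <- function(model, cutoff = 0.5) {
  stopifnot(inherits(model, "baccam_cluster"))
  if (min(model$means) > cutoff) "ALL_ON"
  else if (max(model$means) < cutoff) "ALL_OFF"
  else "MIXED"
}

#' Group clusters into binary well states
#'
#' Collapses a MIXED-mode clustering into ON/OFF bits. Blue-channel rule:
#' the cluster with the lowest mean is OFF, every other cluster is ON.
#' Red-channel rule: the two lowest-mean clusters are OFF and the rest ON
#' (the red channel's raw ratios are distributed differently); with only
#' two clusters the lowest is OFF.
#'
#' @param model a `baccam_cluster` with at least 2 clusters.
#' @param channel `"blue"` or `"red"`.
#' @return integer vector of 0/1 states, one per clustered value.
#' @export
group_clusters <- function(model, channel = c("blue", "red")) {
  channel <- match.arg(channel)
  stopifnot(inherits(model, "baccam_cluster"))
  if (model$k < 2L)
    stop("cluster grouping needs at least 2 clusters in MIXED mode, got ",
         model$k)
  n_off <- if (channel == "red" && model$k > 2L) 2L else 1L
  as.integer(model$labels > n_off)
}

#' Calibrate the full ON/OFF cutoff from existing fits
#'
#' The midpoint between the grand mean of the lowest cluster means and the
#' grand mean of the highest cluster means across a collection of fitted
#' plates: a data-driven stand-in for the default 0.5 cutoff on the
#' bounded excision fraction.
#'
#' @param models list of `baccam_cluster` fits (from MIXED plates).
#' @return a cutoff value.
#' @export
calibrate_cutoff <- function(models) {
  stopifnot(length(models) >= 1,
            all(vapply(models, inherits, logical(1), "baccam_cluster")))
  lo <- mean(vapply(models, function(m) min(m$means), numeric(1)))
  hi <- mean(vapply(models, function(m) max(m$means), numeric(1)))
  (lo + hi) / 2
}

#' Oracle threshold from ground truth
#'
#' The manual-thresholding benchmark: with the encoded image known, scan
#' every midpoint between adjacent sorted ratio values (plus the extremes)
#' and return the threshold maximising decode accuracy (ties resolved to
#' the lowest threshold). Used only to benchmark the automated workflow.
#'
#' @param values numeric ratio values (NAs count as state 0 at any
#'   threshold).
#' @param truth 0/1 vector (or [bitgrid]) of true bits, same length/shape.
#' @return list with `threshold` and `accuracy`.
#' @export
oracle_threshold <- function(values, truth) {
  if (is_bitgrid(truth)) truth <- grid_bits(truth)
  stopifnot(length(values) == length(truth), all(truth %in% c(0L, 1L)))
  sv <- sort(unique(values[!is.na(values)]))
  cand <- if (length(sv) >= 2L)
    c(sv[1] - 1, (sv[-length(sv)] + sv[-1]) / 2, sv[length(sv)] + 1)
  else c((if (length(sv)) sv[1] else 0.5) + c(-1, 1))
  acc <- vapply(cand, function(t) {
    pred <- ifelse(is.na(values), 0L, as.integer(values > t))
    mean(pred == truth)
  }, numeric(1))
  best <- which.max(acc)  # first maximum = lowest threshold
  list(threshold = cand[best], accuracy = acc[best])
}

#' Automated deconvolution of a ratio table into a binary image
#'
#' The automated image-deconvolution workflow: local-outlier-factor
#' detection on the per-well excision ratios, reassignment of outliers to
#' the nearest inlier value, one-dimensional clustering (GMM by default;
#' k-means, DBSCAN or OPTICS on request), full ON/OFF criteria assessment
#' against a calibrated cutoff, and cluster grouping into binary states.
#' Wells with no informative reads (MISSING) never enter the clustering
#' and are assigned state 0 ("no reads, no evidence of exposure") with a
#' warning. When the true pattern is supplied, the error mask and decode
#' accuracy (matching wells / 96) are filled in.
#'
#' @param ratios a `baccam_ratios` table (from [count_and_ratio()] or
#'   [read_ratios()]), or a bare numeric vector of 96 ratio values in
#'   plate order.
#' @param channel `"blue"` or `"red"`: selects the ratio rows, the
#'   grouping rule, and the default `n_neighbors` (blue 20, red 10).
#' @param method clustering method, see [cluster_1d()].
#' @param cutoff full ON/OFF cutoff. Default 0.5.
#' @param n_neighbors LOF neighbourhood; `NULL` = channel default.
#' @param contamination,lof_min LOF flagging rule, see [lof_detect()].
#' @param truth optional true [bitgrid] for scoring.
#' @param seed integer seed for the clustering stage.
#' @param ... clustering settings passed to [cluster_1d()]
#'   (`k`, `eps`, `min_samples`, `xi`, `n_components`, `nstart`).
#' @return a `baccam_decode` object: the decoded [bitgrid] (`$grid`),
#'   per-well states and values, `$mode` (`MIXED`/`ALL_ON`/`ALL_OFF`),
#'   the cluster `$model`, the LOF table, and `$accuracy`/`$errors` when
#'   truth was given. Methods: `print`, `summary`, `plot`, `coef`.
#' @examples
#' codes <- generate_well_codes(96, seed = 1)
#' truth <- pattern_grid("SMILEY")
#' reads <- simulate_plate(truth, channel_params(), codes,
#'                         default_index_table()[1, ], seed = 7)
#' ratios <- count_and_ratio(reads, codes)
#' dec <- deconvolute(ratios, truth = truth, seed = 7)
#' dec$accuracy
#' @export
deconvolute <- function(ratios, channel = "blue",
                        method = c("gmm", "kmeans", "dbscan", "optics"),
                        cutoff = 0.5, n_neighbors = NULL,
                        contamination = 0.05, lof_min = 1.5,
                        truth = NULL, seed = 1, ...) {
  method <- match.arg(method)
  stopifnot(channel %in% c("blue", "red"))
  if (inherits(ratios, "baccam_ratios") || is.data.frame(ratios)) {
    sub <- ratios[ratios$channel == channel, , drop = FALSE]
    if (!nrow(sub)) stop("no '", channel, "' rows in the ratio table")
    values <- sub$value[match(plate_wells(), sub$well)]
  } else {
    stopifnot(is.numeric(ratios), length(ratios) == 96L)
    values <- as.numeric(ratios)
  }
  if (is.null(n_neighbors)) n_neighbors <- if (channel == "blue") 20L else 10L

  wells <- plate_wells()
  missing <- is.na(values)
  if (any(missing))
    warning(sum(missing), " well(s) have no informative reads (MISSING); ",
            "excluded from clustering and set to state 0")

  lof <- lof_detect(values, n_neighbors = n_neighbors,
                    contamination = contamination, lof_min = lof_min)
  curated <- reassign_outliers(values, lof$label)

  obs <- which(!missing)
  states <- rep(0L, 96L)
  if (length(obs) >= 2L) {
    model <- cluster_1d(curated[obs], method = method, seed = seed, ...)
    mode <- full_on_off_check(model, cutoff)
    states[obs] <- switch(mode,
      ALL_ON = 1L,
      ALL_OFF = 0L,
      MIXED = group_clusters(model, channel))
  } else if (length(obs) == 1L) {
    model <- cluster_1d(curated[obs], method = method, seed = seed, ...)
    mode <- full_on_off_check(model, cutoff)
    states[obs] <- if (mode == "ALL_ON") 1L else 0L
  } else {
    warning("no informative wells at all; decoding an all-OFF plate")
    model <- NULL
    mode <- "ALL_OFF"
  }

  grid <- bitgrid(states)
  res <- list(grid = grid, states = states, wells = wells,
              values = values, curated = curated, missing = missing,
              lof = lof, model = model, mode = mode, channel = channel,
              method = method, cutoff = cutoff,
              n_neighbors = n_neighbors, seed = seed)
  if (!is.null(truth)) {
    stopifnot(is_bitgrid(truth))
    tb <- grid_bits(truth)
    res$truth <- truth
    res$accuracy <- grid_accuracy(grid, truth)
    res$errors <- wells[states != tb]
  }
  structure(res, class = "baccam_decode")
}

#' @export
print.baccam_decode <- function(x, ...) {
  cat(sprintf("baccam_decode: %s channel, method %s, mode %s\n",
              x$channel, x$method, x$mode))
  if (!is.null(x$model))
    cat("  cluster means:",
        paste0("M", seq_len(x$model$k) - 1L, "=",
               formatC(x$model$means, digits = 3, format = "f"),
               collapse = " "), "\n")
  cat(sprintf("  outliers reassigned: %d; missing wells: %d\n",
              sum(x$lof$label == -1L, na.rm = TRUE), sum(x$missing)))
  if (!is.null(x$accuracy))
    cat(sprintf("  accuracy vs truth: %.3f (%d error wells%s)\n",
                x$accuracy, length(x$errors),
                if (length(x$errors))
                  paste0(": ", paste(x$errors, collapse = " ")) else ""))
  print(x$grid)
  invisible(x)
}

#' @export
summary.baccam_decode <- function(object, ...) {
  tab <- data.frame(well = object$wells, value = object$values,
                    curated = object$curated,
                    lof_score = object$lof$score,
                    outlier = object$lof$label == -1L,
                    missing = object$missing,
                    cluster = NA_integer_, state = object$states,
                    stringsAsFactors = FALSE)
  if (!is.null(object$model))
    tab$cluster[!object$missing] <- object$model$labels
  if (!is.null(object$truth)) {
    tab$truth <- grid_bits(object$truth)
    tab$error <- tab$state != tab$truth
  }
  structure(list(table = tab, mode = object$mode, model = object$model,
                 accuracy = object$accuracy), class = "summary.baccam_decode")
}

#' @export
print.summary.baccam_decode <- function(x, ...) {
  cat("mode:", x$mode, "\n")
  if (!is.null(x$accuracy)) cat(sprintf("accuracy: %.3f\n", x$accuracy))
  print(utils::head(x$table, 12L), row.names = FALSE)
  if (nrow(x$table) > 12L) cat("  ... (", nrow(x$table), "wells )\n")
  invisible(x)
}

#' @export
coef.baccam_decode <- function(object, ...) {
  if (is.null(object$model)) return(numeric(0))
  stats::setNames(object$model$means,
                  paste0("M", seq_len(object$model$k) - 1L))
}

#' Plot the deconvolution stages for one plate
#'
#' A base-graphics scatter of raw and curated per-well ratio values
#' against plate position, coloured by final bit state, with LOF outliers
#' ringed, cluster means as horizontal lines and the ON/OFF cutoff dashed.
#'
#' @param x a `baccam_decode` object.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.baccam_decode <- function(x, ...) {
  idx <- seq_len(96L)
  col <- ifelse(x$states == 1L, "#1f4e9c", "#9ecbff")
  plot(idx, x$values, pch = 16, col = col, xlab = "well (A1..H12)",
       ylab = "excision ratio", ylim = c(0, 1),
       main = sprintf("%s / %s: mode %s", x$channel, x$method, x$mode), ...)
  out <- which(!is.na(x$lof$label) & x$lof$label == -1L)
  if (length(out)) points(idx[out], x$values[out], pch = 1, cex = 2,
                          col = "#d95f02")
  moved <- which(x$curated != x$values & !is.na(x$values))
  if (length(moved)) points(idx[moved], x$curated[moved], pch = 4,
                            col = "#d95f02")
  if (!is.null(x$model)) abline(h = x$model$means, col = "grey50", lty = 3)
  abline(h = x$cutoff, lty = 2)
  if (!is.null(x$truth)) {
    err <- which(x$states != grid_bits(x$truth))
    if (length(err)) points(idx[err], rep(-0.02, length(err)), pch = 17,
                            col = "#d95f02", xpd = NA)
  }
  invisible(x)
}

#' Decode report as JSON
#'
#' Serialises a `baccam_decode` to a JSON report (mode, method, settings,
#' cluster means, per-well value/label/state, accuracy and error wells
#' when truth was supplied).
#'
#' @param decode a `baccam_decode`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_decode_report <- function(decode, path) {
  stopifnot(inherits(decode, "baccam_decode"))
  per_well <- summary(decode)$table
  rep <- list(
    channel = decode$channel, method = decode$method, mode = decode$mode,
    cutoff = decode$cutoff, n_neighbors = decode$n_neighbors,
    seed = decode$seed,
    cluster_means = if (!is.null(decode$model)) decode$model$means,
    settings = if (!is.null(decode$model)) decode$model$settings,
    accuracy = decode$accuracy,
    error_wells = decode$errors,
    wells = per_well)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
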