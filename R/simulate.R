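#' Amplicon template structure
#'
#' Describes the ordered segments of the sequenced recording amplicon:
#'
#' `i7 index | upstream pad | well-code | (color spacer, red only) |
#'  left flank | LoxP | intervening region | LoxP | right flank | i5 index`
#'
#' The recorder excises the region between the two directly repeated 34-bp
#' LoxP sites, so an excised read retains exactly one LoxP site and lacks
#' the intervening (double-terminator) region; that junction is the
#' signature the decoder looks for. The red-light recording construct
#' carries an extra spacer barcode between the well-code and the locus,
#' which is how red-channel edits are told apart from blue-channel edits.
#' Flank/pad/spacer sequences are fixed arbitrary constants of this
#' package's default configuration.
#'
#' @param i7_len,i5_len index lengths (bases).
#' @param pad upstream pad sequence between i7 and well-code.
#' @param spacer red-channel spacer barcode.
#' @param left_flank,right_flank sequences flanking the LoxP locus.
#' @param loxp the 34-bp LoxP site (canonical sequence by default).
#' @param intervening region between the two LoxP sites on the intact
#'   template (terminator region).
#' @param sig_len length of the signature window used to classify reads as
#'   intact/excised. Default 16.
#' @return a `library_structure` list of segment constants and lengths.
#' @export
library_structure <- function(i7_len = 8L, i5_len = 8L,
                              pad = "ACACTCTTTCCCTACACGAC",
                              spacer = "GCTAGCTTGCAT",
                              left_flank = "GGTACCGAGCTCGAAT",
                              loxp = "ATAACTTCGTATAATGTATGCTATACGAAGTTAT",
                              intervening = "CCAGGCATCAAATAAAACGAAAGGCTCAGTCGAAAGACTG",
                              right_flank = "GCGGCCGCTCTAGAAG",
                              sig_len = 16L) {
  stopifnot(nchar(loxp) == 34L,
            sig_len <= nchar(intervening), sig_len <= nchar(right_flank),
            sig_len <= nchar(left_flank),
            nchar(spacer) <= nchar(left_flank))
  structure(list(i7_len = as.integer(i7_len), i5_len = as.integer(i5_len),
                 pad = pad, spacer = spacer, left_flank = left_flank,
                 loxp = loxp, intervening = intervening,
                 right_flank = right_flank, sig_len = as.integer(sig_len)),
            class = "library_structure")
}

# assemble the full single-end template for one well
build_template <- function(structure, i7, code, i5, color, excised) {
  s <- structure
  locus <- if (excised) paste0(s$loxp, s$right_flank)
           else paste0(s$loxp, s$intervening, s$loxp, s$right_flank)
  paste0(i7, s$pad, code,
         if (color == "red") s$spacer else "",
         s$left_flank, locus, i5)
}

#' Recording-channel parameters
#'
#' The latent per-well excision fraction `f_w` is Beta-distributed:
#' light-exposed ('1') wells draw from `Beta(f_on)`, unexposed ('0') wells
#' from `Beta(f_off)`, with `E[f_on] > E[f_off]` (the channel's
#' separability assumption). Per-well read counts follow a negative
#' binomial with mean `depth_mean` and size `depth_dispersion`
#' (`Inf` = fixed depth). Each sequenced base is substituted independently
#' with probability `sub_error_rate`. A scalar `f_on`/`f_off` denotes a
#' point mass (a noiseless channel uses `f_on = 1, f_off = 0`).
#'
#' @param f_on,f_off Beta shape pairs `c(a, b)`, or a scalar in `[0, 1]`
#'   for a degenerate (point-mass) fraction.
#' @param depth_mean mean reads per well. Default 500.
#' @param depth_dispersion negative-binomial size; `Inf` for fixed depth.
#'   Default 5.
#' @param sub_error_rate per-base substitution probability. Default 0.001.
#' @return a `channel_params` list.
#' @examples
#' channel_params()                      # study defaults
#' channel_params(f_on = 1, f_off = 0,   # noiseless channel
#'                depth_mean = 50, depth_dispersion = Inf,
#'                sub_error_rate = 0)
#' @export
channel_params <- function(f_on = c(9, 1), f_off = c(1, 9),
                           depth_mean = 500, depth_dispersion = 5,
                           sub_error_rate = 0.001) {
  chk_f <- function(f, nm) {
    if (length(f) == 1L) {
      if (f < 0 || f > 1) stop(nm, " point mass must lie in [0, 1]")
    } else if (length(f) == 2L) {
      if (any(f <= 0)) stop(nm, " Beta parameters must be positive")
    } else stop(nm, " must be a scalar or a Beta shape pair")
    f
  }
  f_on <- chk_f(f_on, "f_on"); f_off <- chk_f(f_off, "f_off")
  e_mean <- function(f) if (length(f) == 1L) f else f[1] / (f[1] + f[2])
  if (e_mean(f_on) <= e_mean(f_off))
    stop("channel not separable: E[f_on] must exceed E[f_off]")
  stopifnot(depth_mean >= 0, depth_dispersion > 0,
            sub_error_rate >= 0, sub_error_rate < 1)
  structure(list(f_on = f_on, f_off = f_off, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 sub_error_rate = sub_error_rate),
            class = "channel_params")
}

draw_fraction <- function(f, n) {
  if (length(f) == 1L) rep(f, n) else stats::rbeta(n, f[1], f[2])
}

draw_depth <- function(params, n) {
  if (is.infinite(params$depth_dispersion)) rep(round(params$depth_mean), n)
  else stats::rnbinom(n, size = params$depth_dispersion,
                      mu = params$depth_mean)
}

# i.i.d. per-base substitutions, vectorized: one pass per error multiplicity
add_substitutions <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, rate)
  for (pass in seq_len(max(n_err, 0L))) {
    sel <- which(n_err >= pass)
    if (!length(sel)) break
    pos <- floor(stats::runif(length(sel)) * lens[sel]) + 1L
    cur <- substr(seqs[sel], pos, pos)
    shift <- sample.int(3L, length(sel), replace = TRUE)
    new <- DNA_BASES[(match(cur, DNA_BASES) - 1L + shift) %% 4L + 1L]
    substr(seqs[sel], pos, pos) <- new
    seqs[sel] <- seqs[sel]
  }
  seqs
}

revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' Simulate sequencing reads from one recorded plate
#'
#' The synthetic-data generator for the recording channel. For each well
#' `w`: a latent excision fraction `f_w` is drawn from the ON or OFF Beta
#' distribution according to the true bit; a read count `n_w` is drawn from
#' the depth model; each read is excised with probability `f_w` and its
#' sequence assembled per the [library_structure()] (excised reads carry
#' the single-LoxP junction), with i.i.d. substitution errors applied.
#' Read provenance is retained only implicitly via the barcodes, as in a
#' real pooled library. Qualities are constant Q30 placeholders.
#'
#' @param truth the true [bitgrid] (the projected light pattern).
#' @param params [channel_params()].
#' @param codes a 96-entry well-code set from [generate_well_codes()].
#' @param index one row of an index table (fields `i7`, `i5`, `image`).
#' @param color `"blue"` or `"red"` (red templates carry the spacer
#'   barcode).
#' @param structure [library_structure()].
#' @param seed integer seed.
#' @param paired emit paired-end reads (`r1` from the 5' end, `r2` the
#'   reverse complement of the 3' end, each `read_length` bases) instead of
#'   full-template single-end reads.
#' @param read_length mate length in paired mode. Default 150.
#' @return a [read_set()] (or `list(r1, r2)` of class `paired_reads` when
#'   `paired = TRUE`), with attribute `sidecar`: a data.frame
#'   `(well, true_bit, f_w, depth, n_excised)` of the latent ground truth,
#'   for testing and calibration only.
#' @export
simulate_plate <- function(truth, params, codes, index, color = "blue",
                           structure = library_structure(), seed = 1,
                           paired = FALSE, read_length = 150L) {
  stopifnot(is_bitgrid(truth), inherits(params, "channel_params"),
            nrow(codes) == 96L, color %in% c("blue", "red"))
  index <- as.list(index)[c("i7", "i5", "image")]
  stopifnot(nchar(index$i7) == structure$i7_len,
            nchar(index$i5) == structure$i5_len)
  local_rng(seed)
  bits <- grid_bits(truth)
  wells <- plate_wells()
  code_of <- codes$sequence[match(wells, codes$well)]
  if (anyNA(code_of)) stop("well-code set must cover all 96 wells")

  f_w <- numeric(96L)
  on <- bits == 1L
  f_w[on] <- draw_fraction(params$f_on, sum(on))
  f_w[!on] <- draw_fraction(params$f_off, sum(!on))
  n_w <- draw_depth(params, 96L)
  n_exc <- stats::rbinom(96L, n_w, f_w)
  n_int <- n_w - n_exc

  chunks <- vector("list", 192L)
  for (w in seq_len(96L)) {
    t_exc <- build_template(structure, index$i7, code_of[w], index$i5,
                            color, excised = TRUE)
    t_int <- build_template(structure, index$i7, code_of[w], index$i5,
                            color, excised = FALSE)
    chunks[[2L * w - 1L]] <- rep.int(t_exc, n_exc[w])
    chunks[[2L * w]] <- rep.int(t_int, n_int[w])
  }
  seqs <- unlist(chunks, use.names = FALSE)
  ord <- sample.int(length(seqs))
  seqs <- add_substitutions(seqs[ord], params$sub_error_rate)
  ids <- sprintf("%s:%s:%06d", index$image, color, seq_along(seqs))

  sidecar <- data.frame(well = wells, true_bit = bits, f_w = f_w,
                        depth = n_w, n_excised = n_exc,
                        stringsAsFactors = FALSE)
  out <- if (paired) {
    r1 <- substr(seqs, 1L, read_length)
    lens <- nchar(seqs)
    r2 <- revcomp(substr(seqs, pmax(1L, lens - read_length + 1L), lens))
    structure(list(r1 = read_set(paste0(ids, "/1"), r1),
                   r2 = read_set(paste0(ids, "/2"), r2)),
              class = "paired_reads")
  } else {
    read_set(ids, seqs)
  }
  attr(out, "sidecar") <- sidecar
  out
}

subset_reads <- function(x, idx) {
  if (inherits(x, "paired_reads"))
    structure(list(r1 = read_set(x$r1$id[idx], x$r1$seq[idx], x$r1$qual[idx]),
                   r2 = read_set(x$r2$id[idx], x$r2$seq[idx], x$r2$qual[idx])),
              class = "paired_reads")
  else read_set(x$id[idx], x$seq[idx], x$qual[idx])
}

n_reads <- function(x) {
  if (inherits(x, "paired_reads")) nrow(x$r1) else nrow(x)
}

#' Pool, dilute and selectively re-amplify read sets
#'
#' `pool_images()` concatenates the indexed read sets of several plates
#' into one pool (order shuffled under `seed`), the in-silico counterpart
#' of pooling all libraries in one tube. `dilute()` retains each read
#' independently with probability `1/factor`, emulating a serial dilution
#' of the stored pool. `random_access()` emulates index-selective
#' re-amplification: reads carrying the target (i7, i5) pair are resampled
#' with replacement to `amplification` times their count, while off-target
#' reads survive only with probability `off_target_rate`.
#'
#' @param read_sets list of [read_set()]s (or `paired_reads`).
#' @param pool a [read_set()] (or `paired_reads`).
#' @param factor dilution factor (>= 1); 1 is the identity.
#' @param index target row of the index table (`i7`, `i5`, `image`).
#' @param amplification fold amplification of target reads (>= 1).
#' @param off_target_rate survival probability of non-target reads.
#' @param structure [library_structure()] (locates the index bases).
#' @param max_mismatch index mismatches tolerated by the primers. Default 1.
#' @param seed integer seed.
#' @return a read set of the same kind as the input.
#' @export
pool_images <- function(read_sets, seed = 1) {
  stopifnot(length(read_sets) >= 1L)
  paired <- inherits(read_sets[[1]], "paired_reads")
  local_rng(seed)
  if (paired) {
    r1 <- do.call(rbind, lapply(read_sets, function(x) x$r1))
    r2 <- do.call(rbind, lapply(read_sets, function(x) x$r2))
    ord <- sample.int(nrow(r1))
    structure(list(r1 = read_set(r1$id[ord], r1$seq[ord], r1$qual[ord]),
                   r2 = read_set(r2$id[ord], r2$seq[ord], r2$qual[ord])),
              class = "paired_reads")
  } else {
    pool <- do.call(rbind, lapply(read_sets, as_read_set))
    ord <- sample.int(nrow(pool))
    read_set(pool$id[ord], pool$seq[ord], pool$qual[ord])
  }
}

#' @rdname pool_images
#' @export
dilute <- function(pool, factor, seed = 1) {
  stopifnot(factor >= 1)
  if (factor == 1) return(pool)
  local_rng(seed)
  keep <- which(stats::runif(n_reads(pool)) < 1 / factor)
  subset_reads(pool, keep)
}

#' @rdname pool_images
#' @export
random_access <- function(pool, index, amplification = 1000,
                          off_target_rate = 0,
                          structure = library_structure(),
                          max_mismatch = 1, seed = 1) {
  stopifnot(amplification >= 1, off_target_rate >= 0, off_target_rate <= 1)
  index <- as.list(index)
  local_rng(seed)
  paired <- inherits(pool, "paired_reads")
  idx <- extract_indices(pool, structure)
  hit <- str_mismatch(idx$i7, index$i7) <= max_mismatch &
         str_mismatch(idx$i5, index$i5) <= max_mismatch
  hit[is.na(hit)] <- FALSE
  if (!any(hit)) {
    warning("target index (", index$i7, ", ", index$i5,
            ") absent from pool; returning empty read set")
    return(subset_reads(pool, integer(0)))
  }
  n_target <- sum(hit)
  amp <- sample(which(hit), round(amplification * n_target), replace = TRUE)
  off <- which(!hit)
  off <- off[stats::runif(length(off)) < off_target_rate]
  keep <- c(amp, off)
  out <- subset_reads(pool, keep[sample.int(length(keep))])
  if (paired) {
    out$r1$id <- make.unique(out$r1$id, sep = "_dup")
    out$r2$id <- make.unique(out$r2$id, sep = "_dup")
  } else {
    out$id <- make.unique(out$id, sep = "_dup")
  }
  out
}

#' Write the simulator's latent ground truth sidecar as TSV
#'
#' @param reads a read set produced by [simulate_plate()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(reads, path) {
  sc <- attr(reads, "sidecar")
  if (is.null(sc)) stop("read set carries no sidecar ground truth")
  write_tsv(sc, path)
}
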