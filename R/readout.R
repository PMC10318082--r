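# number of mismatches between each string in x (fixed width nchar(ref))
# and a constant reference; NA where x has the wrong width
str_mismatch <- function(x, ref) {
  k <- nchar(ref)
  out <- integer(length(x))
  out[nchar(x) != k] <- NA_integer_
  for (i in seq_len(k)) {
    out <- out + (substr(x, i, i) != substr(ref, i, i))
  }
  out
}

# pull (i7, i5) off every read; for paired input i7 sits at the start of R1
# and i5 is the reverse complement of the start of R2
extract_indices <- function(reads, structure) {
  if (inherits(reads, "paired_reads")) {
    i7 <- substr(reads$r1$seq, 1L, structure$i7_len)
    i5 <- revcomp(substr(reads$r2$seq, 1L, structure$i5_len))
    lens <- nchar(reads$r1$seq)
    short <- lens < structure$i7_len |
      nchar(reads$r2$seq) < structure$i5_len
  } else {
    lens <- nchar(reads$seq)
    i7 <- substr(reads$seq, 1L, structure$i7_len)
    i5 <- substr(reads$seq, lens - structure$i5_len + 1L, lens)
    short <- lens < min_read_length(structure)
  }
  i7[short] <- NA_character_
  i5[short] <- NA_character_
  list(i7 = i7, i5 = i5, short = short)
}

# shortest well-formed single-end read: excised blue template with the
# supplied well-code length unknown; use segments independent of the code
min_read_length <- function(structure) {
  structure$i7_len + nchar(structure$pad) + 1L + nchar(structure$left_flank) +
    nchar(structure$loxp) + nchar(structure$right_flank) + structure$i5_len
}

#' Demultiplex pooled reads by dual index
#'
#' Assigns each read to at most one stored image by matching both the i7
#' and i5 index against the index table, each within `max_mismatch`
#' substitutions. A read matching no entry, tying between two entries, or
#' too short to carry both indexes is left unassigned (with a reason), so
#' assigned + unassigned always equals the input count.
#'
#' @param reads a [read_set()] or `paired_reads`.
#' @param index_table an index table (columns `i7`, `i5`, `image`).
#' @param structure [library_structure()].
#' @param max_mismatch per-index mismatch tolerance. Default 1.
#' @return a list with elements `images` (named list of read sets),
#'   `unassigned` (read set), and `summary` (data.frame of per-image
#'   counts, plus `unassigned` reasons).
#' @export
demultiplex <- function(reads, index_table, structure = library_structure(),
                        max_mismatch = 1) {
  index_table <- as_index_table(index_table)
  idx <- extract_indices(reads, structure)
  key <- paste(idx$i7, idx$i5)
  tab_key <- paste(index_table$i7, index_table$i5)
  assign <- index_table$image[match(key, tab_key)]

  todo <- which(is.na(assign) & !idx$short)
  if (length(todo) && max_mismatch > 0) {
    uk <- unique(key[todo])
    u7 <- idx$i7[todo][match(uk, key[todo])]
    u5 <- idx$i5[todo][match(uk, key[todo])]
    res <- character(length(uk))
    for (u in seq_along(uk)) {
      d7 <- vapply(index_table$i7, function(r) str_mismatch(u7[u], r),
                   integer(1))
      d5 <- vapply(index_table$i5, function(r) str_mismatch(u5[u], r),
                   integer(1))
      ok <- which(d7 <= max_mismatch & d5 <= max_mismatch)
      if (length(ok) == 0L) { res[u] <- NA_character_; next }
      tot <- d7[ok] + d5[ok]
      best <- ok[tot == min(tot)]
      res[u] <- if (length(best) == 1L) index_table$image[best]
                else NA_character_  # tie -> unassigned
    }
    assign[todo] <- res[match(key[todo], uk)]
  }

  images <- lapply(stats::setNames(index_table$image, index_table$image),
                   function(img) subset_reads(reads, which(!is.na(assign) & assign == img)))
  images <- images[vapply(images, n_reads, integer(1)) > 0L]
  unassigned <- subset_reads(reads, which(is.na(assign)))
  summary <- data.frame(
    image = c(names(images), "unassigned", "malformed"),
    reads = c(vapply(images, n_reads, integer(1)),
              sum(is.na(assign)) - sum(idx$short), sum(idx$short)),
    stringsAsFactors = FALSE)
  list(images = images, unassigned = unassigned, summary = summary)
}

#' Classify reads as excised or intact
#'
#' Looks for the locus signature at its fixed template offset: after the
#' left flank and first LoxP site, an intact read continues with the
#' intervening (terminator) region while an excised read continues
#' straight into the right flank (the single-LoxP excision junction). A
#' read showing the intervening signature (within `sig_mismatch`
#' substitutions) is `INTACT`, one showing the junction signature is
#' `EXCISED`, and a read showing neither or both is `AMBIGUOUS`. The
#' channel (`blue`/`red`) is read off the presence of the color spacer
#' after the well-code. Reads are structured amplicons, so positional
#' anchoring replaces alignment.
#'
#' @param reads a [read_set()] or `paired_reads`.
#' @param codes the well-code set (fixes the well-code length and maps
#'   codes to wells).
#' @param structure [library_structure()].
#' @param sig_mismatch mismatch budget per signature window. Default 2.
#' @param code_mismatch well-code mismatch tolerance. Default 1.
#' @return a data.frame with one row per read: `well` (NA if the
#'   well-code is unmatched), `channel` (`"blue"`/`"red"`/NA), and `class`
#'   (`"EXCISED"`, `"INTACT"`, `"AMBIGUOUS"`).
#' @export
classify_reads <- function(reads, codes, structure = library_structure(),
                           sig_mismatch = 2, code_mismatch = 1) {
  paired <- inherits(reads, "paired_reads")
  seqs <- if (paired) reads$r1$seq else reads$seq
  n <- length(seqs)
  code_len <- attr(codes, "length")
  if (is.null(code_len)) code_len <- nchar(codes$sequence[1])
  code_off <- structure$i7_len + nchar(structure$pad)
  spacer_len <- nchar(structure$spacer)

  obs_code <- substr(seqs, code_off + 1L, code_off + code_len)
  well <- rep(NA_character_, n)
  full_len <- !is.na(obs_code) & nchar(obs_code) == code_len
  if (any(full_len))
    well[full_len] <- match_barcode(obs_code[full_len], codes,
                                    max_mismatch = code_mismatch)

  after <- code_off + code_len
  win_sp <- substr(seqs, after + 1L, after + spacer_len)
  d_spacer <- str_mismatch(win_sp, structure$spacer)
  d_blue <- str_mismatch(win_sp, substr(structure$left_flank, 1L, spacer_len))
  is_red <- !is.na(d_spacer) & d_spacer <= sig_mismatch &
    (is.na(d_blue) | d_blue > sig_mismatch)
  is_blue <- !is.na(d_blue) & d_blue <= sig_mismatch &
    (is.na(d_spacer) | d_spacer > sig_mismatch)
  channel <- rep(NA_character_, n)
  channel[is_red] <- "red"
  channel[is_blue] <- "blue"

  # locus classification window sits right after left flank + first LoxP
  sig <- structure$sig_len
  ref_int <- substr(structure$intervening, 1L, sig)
  ref_exc <- substr(structure$right_flank, 1L, sig)
  cls <- rep("AMBIGUOUS", n)
  if (paired) {
    # classify from the 3' mate. Both template variants end with
    # [... | LoxP | right flank | i5]; what distinguishes them is the
    # region before that final LoxP: the intervening tail on an intact
    # template versus the left-flank tail at the excision junction.
    rc2 <- revcomp(reads$r2$seq)
    lens <- nchar(rc2)
    tail_off <- structure$i5_len + nchar(structure$right_flank) +
      nchar(structure$loxp)
    win <- substr(rc2, lens - tail_off - sig + 1L, lens - tail_off)
    ref_int3 <- substring(structure$intervening,
                          nchar(structure$intervening) - sig + 1L)
    ref_exc3 <- substring(structure$left_flank,
                          nchar(structure$left_flank) - sig + 1L)
    d_int <- str_mismatch(win, ref_int3)
    d_exc <- str_mismatch(win, ref_exc3)
  } else {
    locus_off <- after + ifelse(is_red, spacer_len, 0L) +
      nchar(structure$left_flank) + nchar(structure$loxp)
    win <- substr(seqs, locus_off + 1L, locus_off + sig)
    d_int <- str_mismatch(win, ref_int)
    d_exc <- str_mismatch(win, ref_exc)
  }
  hit_int <- !is.na(d_int) & d_int <= sig_mismatch
  hit_exc <- !is.na(d_exc) & d_exc <= sig_mismatch
  cls[hit_int & !hit_exc] <- "INTACT"
  cls[hit_exc & !hit_int] <- "EXCISED"
  data.frame(well = well, channel = channel, class = cls,
             stringsAsFactors = FALSE)
}

#' Per-well excision counts and ratio table
#'
#' Routes each demultiplexed read to a well by well-code, splits reads into
#' color channels by the spacer barcode, classifies each as excised or
#' intact, and reports per well and channel the counts and the bounded
#' excision fraction `value = n_excised / (n_excised + n_intact)`. A high
#' value means most of that well's recorder population excised its locus,
#' i.e. the well saw light (bit 1). Wells with zero informative coverage
#' are reported `MISSING` (`value = NA`), not 0; downstream deconvolution
#' decides how to impute them.
#'
#' @inheritParams classify_reads
#' @param channels channels to tabulate; default both `"blue"` and
#'   `"red"`, restricted to those observed.
#' @return a `baccam_ratios` data.frame with columns `well`, `channel`,
#'   `n_excised`, `n_intact`, `n_ambiguous`, `coverage`, `value`,
#'   `missing`; 96 rows per reported channel, in plate order.
#' @export
count_and_ratio <- function(reads, codes, structure = library_structure(),
                            sig_mismatch = 2, code_mismatch = 1,
                            channels = NULL) {
  cl <- classify_reads(reads, codes, structure,
                       sig_mismatch = sig_mismatch,
                       code_mismatch = code_mismatch)
  if (is.null(channels)) {
    channels <- intersect(c("blue", "red"), unique(cl$channel))
    if (!length(channels)) channels <- "blue"
  }
  wells <- plate_wells()
  out <- do.call(rbind, lapply(channels, function(ch) {
    sub <- cl[!is.na(cl$channel) & cl$channel == ch & !is.na(cl$well), ,
              drop = FALSE]
    cnt <- function(klass) {
      t <- table(factor(sub$well[sub$class == klass], levels = wells))
      as.integer(t)
    }
    n_exc <- cnt("EXCISED"); n_int <- cnt("INTACT"); n_amb <- cnt("AMBIGUOUS")
    cov <- n_exc + n_int
    data.frame(well = wells, channel = ch, n_excised = n_exc,
               n_intact = n_int, n_ambiguous = n_amb, coverage = cov,
               value = ifelse(cov > 0L, n_exc / pmax(cov, 1L), NA_real_),
               missing = cov == 0L, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("baccam_ratios", "data.frame"))
}

#' @export
print.baccam_ratios <- function(x, ...) {
  for (ch in unique(x$channel)) {
    sub <- x[x$channel == ch, ]
    cat(sprintf("ratio table [%s]: %d wells, %d missing, median coverage %.0f\n",
                ch, nrow(sub), sum(sub$missing),
                stats::median(sub$coverage)))
  }
  invisible(x)
}

#' Write/read a per-well ratio table as TSV
#' @param ratios a `baccam_ratios` table.
#' @param path TSV path.
#' @return the table (reader) or `path` invisibly (writer).
#' @export
write_ratios <- function(ratios, path) write_tsv(ratios, path)

#' @rdname write_ratios
#' @export
read_ratios <- function(path) {
  tab <- read_tsv_checked(path, c("well", "channel", "n_excised", "n_intact",
                                  "n_ambiguous", "coverage", "value"),
                          "ratio")
  if (!"missing" %in% names(tab)) tab$missing <- tab$coverage == 0L
  tab$value[tab$missing] <- NA_real_
  structure(tab, class = c("baccam_ratios", "data.frame"))
}
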