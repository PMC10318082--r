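DNA_BASES <- c("A", "C", "G", "T")

# pairwise Hamming distance between equal-length sequences held as a
# character matrix (rows = sequences); returns integer matrix
hamming_matrix <- function(chars) {
  n <- nrow(chars)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    di <- rowSums(chars != matrix(chars[i, ], n, ncol(chars), byrow = TRUE))
    d[i, ] <- as.integer(di)
  }
  d
}

# Hamming distances from one observed sequence (split into chars) to each
# row of a code character matrix
hamming_to_set <- function(obs_chars, code_chars) {
  rowSums(code_chars != matrix(obs_chars, nrow(code_chars),
                               ncol(code_chars), byrow = TRUE))
}

split_chars <- function(seqs) {
  do.call(rbind, strsplit(seqs, ""))
}

#' Generate a well-code set
#'
#' Well-codes are the per-well DNA barcodes that tie each sequencing read to
#' one well (pixel) of the plate. Codes are drawn by greedy closure over a
#' seeded random candidate stream: a random sequence is accepted iff its
#' Hamming distance to every already-accepted code is at least `d_min`.
#' With `d_min >= 2k + 1`, decoding tolerates up to `k` substitutions per
#' barcode (sphere packing).
#'
#' @param n number of codes (96 for a full plate).
#' @param length code length in bases. Default 10.
#' @param d_min minimum pairwise Hamming distance. Default 3.
#' @param seed integer seed; the set is a pure function of
#'   `(n, length, d_min, seed)`.
#' @param max_tries candidate draws before giving up (capacity error).
#' @return a `well_code_set`: data.frame with columns `sequence` and `well`
#'   (well id for codes 1..96, `code<i>` beyond that), plus attributes
#'   `length` and `d_min`.
#' @examples
#' codes <- generate_well_codes(8, length = 6, d_min = 3, seed = 1)
#' codes$sequence
#' @export
generate_well_codes <- function(n, length = 10, d_min = 3, seed = 1,
                                max_tries = 10000 * n) {
  stopifnot(n >= 1, length >= 1, d_min >= 1)
  if (d_min > length)
    stop("d_min cannot exceed the code length")
  rng <- local_rng(seed)
  accepted <- matrix(character(), nrow = 0, ncol = length)
  tries <- 0L
  while (nrow(accepted) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("barcode capacity error: could not place ", n, " codes of length ",
           length, " at pairwise distance >= ", d_min)
    cand <- sample(DNA_BASES, length, replace = TRUE)
    if (nrow(accepted) == 0L ||
        all(hamming_to_set(cand, accepted) >= d_min)) {
      accepted <- rbind(accepted, cand)
    }
  }
  seqs <- apply(accepted, 1L, paste, collapse = "")
  wells <- if (n <= 96L) plate_wells()[seq_len(n)] else
    c(plate_wells(), paste0("code", 97:n))[seq_len(n)]
  structure(
    data.frame(sequence = seqs, well = wells, stringsAsFactors = FALSE),
    length = as.integer(length), d_min = as.integer(d_min),
    class = c("well_code_set", "data.frame"))
}

#' @export
print.well_code_set <- function(x, ...) {
  cat("well_code_set:", nrow(x), "codes, length", attr(x, "length"),
      "bp, pairwise Hamming >=", attr(x, "d_min"), "\n")
  print.data.frame(utils::head(as.data.frame(x), 4L), row.names = FALSE)
  if (nrow(x) > 4L) cat("  ...\n")
  invisible(x)
}

#' Match an observed barcode against a code set
#'
#' Returns the well of the unique code within `max_mismatch` substitutions
#' of the observed sequence. If no code is close enough, or two codes tie at
#' the minimal distance, the read is left unassigned (`NA`): a silently
#' mis-assigned barcode corrupts a pixel, so ties are discarded rather than
#' broken.
#'
#' @param observed character vector of observed barcode sequences, each the
#'   code length.
#' @param codes a `well_code_set` from [generate_well_codes()] or
#'   [read_well_codes()].
#' @param max_mismatch maximum Hamming distance accepted. Default 1.
#' @return character vector of well ids, `NA` where unassigned.
#' @export
match_barcode <- function(observed, codes, max_mismatch = 1) {
  L <- attr(codes, "length")
  if (is.null(L)) L <- nchar(codes$sequence[1])
  if (any(nchar(observed) != L))
    stop("observed barcode length differs from code length ", L)
  out <- codes$well[match(observed, codes$sequence)]
  todo <- which(is.na(out))
  if (length(todo) && max_mismatch > 0) {
    code_chars <- split_chars(codes$sequence)
    uniq <- unique(observed[todo])
    uniq_chars <- strsplit(uniq, "")
    assigned <- vapply(uniq_chars, function(oc) {
      d <- hamming_to_set(oc, code_chars)
      dmin <- min(d)
      if (dmin > max_mismatch || sum(d == dmin) > 1L) NA_character_
      else codes$well[which.min(d)]
    }, character(1))
    out[todo] <- assigned[match(observed[todo], uniq)]
  }
  out
}

#' Image index table
#'
#' The second barcode layer: each stored image carries a dual (i7, i5) index
#' pair appended during library preparation, so multiple plate images can be
#' pooled in one tube and demultiplexed from one sequencing run. The default
#' table pairs the 12 public Nextera N7xx i7 indexes with 2 S5xx i5 indexes
#' (24 combinatorial pairs), labelled `img01`..`img24`.
#'
#' @return an `index_table`: data.frame with columns `i7`, `i5`, `image`.
#' @export
default_index_table <- function() {
  i7 <- c("TAAGGCGA", "CGTACTAG", "AGGCAGAA", "TCCTGAGC", "GGACTCCT",
          "TAGGCATG", "CTCTCTAC", "CAGAGAGG", "GCTACGCT", "CGAGGCTG",
          "AAGAGGCA", "GTAGAGGA")
  i5 <- c("TAGATCGC", "CTCTCTAT")
  tab <- expand.grid(i7 = i7, i5 = i5, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  tab$image <- sprintf("img%02d", seq_len(nrow(tab)))
  structure(tab, class = c("index_table", "data.frame"))
}

as_index_table <- function(x) {
  stopifnot(is.data.frame(x), all(c("i7", "i5", "image") %in% names(x)))
  if (anyDuplicated(paste(x$i7, x$i5))) stop("duplicate (i7, i5) index pairs")
  if (anyDuplicated(x$image)) stop("duplicate image labels in index table")
  structure(as.data.frame(x), class = c("index_table", "data.frame"))
}

#' Read/write barcode tables
#'
#' Well-code maps and index tables are exchanged as TSV. Codes can also be
#' exported as FASTA (via Biostrings) for use with external tools.
#'
#' @param codes,table objects from [generate_well_codes()] /
#'   [default_index_table()].
#' @param path file path.
#' @param d_min recorded minimum distance when reading a code table.
#' @return readers return the parsed table; writers return `path`
#'   invisibly.
#' @export
write_well_codes <- function(codes, path) write_tsv(codes, path)

#' @rdname write_well_codes
#' @export
read_well_codes <- function(path, d_min = NA_integer_) {
  tab <- read_tsv_checked(path, c("sequence", "well"), "well-code")
  if (length(unique(nchar(tab$sequence))) != 1L)
    stop("well-codes must share one length: ", path)
  if (anyDuplicated(tab$sequence)) stop("duplicate well-code sequences: ", path)
  structure(tab, length = nchar(tab$sequence[1]),
            d_min = as.integer(d_min),
            class = c("well_code_set", "data.frame"))
}

#' @rdname write_well_codes
#' @export
write_index_table <- function(table, path) write_tsv(table, path)

#' @rdname write_well_codes
#' @export
read_index_table <- function(path) {
  as_index_table(read_tsv_checked(path, c("i7", "i5", "image"), "index"))
}

#' @rdname write_well_codes
#' @export
write_codes_fasta <- function(codes, path) {
  dna <- Biostrings::DNAStringSet(codes$sequence)
  names(dna) <- codes$well
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}
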