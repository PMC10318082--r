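#' Read and write bit grids as text
#'
#' The grid text format is 8 lines of 12 characters from `{0,1}` (row A
#' first). `write_pgm()`/`read_pgm()` use the plain PBM/PGM "P1" bitmap
#' format for interoperability with image tools; note P1 uses 1 = black,
#' which is mapped to bit 1.
#'
#' @param grid a [bitgrid].
#' @param path file path.
#' @return `read_grid`/`read_pgm` return a [bitgrid]; the writers return
#'   `path` invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(is_bitgrid(grid))
  lines <- apply(unclass(grid), 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 8L || any(nchar(lines) != 12L))
    stop("grid text must be 8 lines x 12 chars, got ",
         length(lines), " lines in ", path)
  chars <- do.call(rbind, strsplit(lines, ""))
  if (!all(chars %in% c("0", "1")))
    stop("grid text may only contain 0 and 1: ", path)
  bitgrid(matrix(as.integer(chars == "1"), 8L, 12L))
}

#' @rdname write_grid
#' @export
write_pgm <- function(grid, path) {
  stopifnot(is_bitgrid(grid))
  body <- apply(unclass(grid), 1L, paste, collapse = " ")
  writeLines(c("P1", "12 8", body), path)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_pgm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines) || lines[1] != "P1")
    stop("not a plain P1 bitmap: ", path)
  toks <- scan(text = paste(lines[-1], collapse = " "), what = integer(),
               quiet = TRUE)
  if (length(toks) < 2L || toks[1] != 12L || toks[2] != 8L)
    stop("bitmap must be 12x8 for a 96-well plate: ", path)
  bits <- toks[-(1:2)]
  if (length(bits) != 96L) stop("bitmap body must hold 96 bits: ", path)
  bitgrid(matrix(bits, 8L, 12L, byrow = TRUE))
}

# ---- sequencing reads ------------------------------------------------------

#' Construct a table of sequencing reads
#'
#' Reads are carried through the pipeline as a plain data.frame with columns
#' `id`, `seq` and `qual` (Phred+33). This is the in-memory counterpart of a
#' FASTQ file.
#'
#' @param id,seq,qual character vectors of equal length.
#' @return a `data.frame` with class `read_set` prepended.
#' @export
read_set <- function(id = character(), seq = character(),
                     qual = strrep("?", nchar(seq))) {
  stopifnot(length(id) == length(seq), length(qual) == length(seq))
  structure(
    data.frame(id = as.character(id), seq = as.character(seq),
               qual = as.character(qual), stringsAsFactors = FALSE),
    class = c("read_set", "data.frame"))
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set with", nrow(x), "reads\n")
  if (nrow(x)) {
    show <- utils::head(x, 3L)
    show$seq <- paste0(substr(show$seq, 1L, 40L),
                       ifelse(nchar(show$seq) > 40L, "...", ""))
    print.data.frame(show[, c("id", "seq")], row.names = FALSE)
    if (nrow(x) > 3L) cat("  ...\n")
  }
  invisible(x)
}

#' Read and write FASTQ
#'
#' Thin wrappers around Biostrings' FASTQ support operating on [read_set()]
#' tables. Gzipped files are handled automatically by extension.
#'
#' @param reads a [read_set()] data.frame.
#' @param path FASTQ file path (`.gz` allowed).
#' @return `read_fastq` returns a [read_set()]; `write_fastq` returns
#'   `path` invisibly.
#' @export
write_fastq <- function(reads, path) {
  reads <- as_read_set(reads)
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$id
  Biostrings::writeXStringSet(
    dna, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  quals <- as.character(S4Vectors::mcols(dna)$qualities)
  if (is.null(quals)) quals <- strrep("?", Biostrings::width(dna))
  read_set(id = names(dna), seq = as.character(dna), qual = quals)
}

as_read_set <- function(x) {
  if (inherits(x, "read_set")) return(x)
  if (is.data.frame(x) && all(c("id", "seq", "qual") %in% names(x)))
    return(read_set(x$id, x$seq, x$qual))
  stop("expected a read_set (data.frame with id/seq/qual columns)")
}

# ---- TSV tables ------------------------------------------------------------

read_tsv_checked <- function(path, required, what) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("malformed ", what, " table ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  tab
}

write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
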