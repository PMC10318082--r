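GRID_NROW <- 8L
GRID_NCOL <- 12L
GRID_ROWS <- LETTERS[1:8]

#' Binary plate image (bit grid)
#'
#' A `bitgrid` is an 8-row by 12-column binary matrix, one bit per well of a
#' 96-well plate. Rows are labelled A--H and columns 1--12, so the top-left
#' well is A1. It is the unit of information the recording workflow captures:
#' each well holds one pixel of a 96-pixel, 1-bit-depth image.
#'
#' @param values a numeric/integer/logical vector of length 96 (filled
#'   row-major, A1..A12, B1..B12, ...) or an 8x12 matrix; every entry must be
#'   0 or 1.
#' @return an object of class `bitgrid`: an integer 8x12 matrix with
#'   dimnames `LETTERS[1:8]` x `1:12`.
#' @examples
#' g <- bitgrid(rep(c(0, 1), 48))
#' g["A", "2"]
#' @export
bitgrid <- function(values) {
  if (is.matrix(values)) {
    if (!identical(dim(values), c(GRID_NROW, GRID_NCOL)))
      stop("bitgrid matrix must be 8x12, got ", nrow(values), "x", ncol(values))
    m <- values
  } else {
    if (length(values) != 96L)
      stop("bitgrid needs 96 values, got ", length(values))
    m <- matrix(values, nrow = GRID_NROW, ncol = GRID_NCOL, byrow = TRUE)
  }
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m %in% c(0L, 1L)))
    stop("bitgrid entries must all be 0 or 1")
  dimnames(m) <- list(GRID_ROWS, as.character(1:GRID_NCOL))
  class(m) <- c("bitgrid", class(m))
  m
}

#' @export
print.bitgrid <- function(x, on = "#", off = ".", ...) {
  cat("bitgrid (8 x 12 wells,", sum(x), "ON)\n")
  body <- apply(unclass(x), 1L, function(r) paste(ifelse(r == 1L, on, off), collapse = ""))
  cat(paste0("  ", GRID_ROWS, " ", body, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
as.matrix.bitgrid <- function(x, ...) {
  m <- unclass(x)
  attr(m, "class") <- NULL
  m
}

is_bitgrid <- function(x) inherits(x, "bitgrid")

#' Well addresses
#'
#' Convert between plate well identifiers ("A1".."H12"), (row, column)
#' pairs, and the row-major linear index 0..95 used internally
#' (index = 12 * row + (col - 1), with row A = 0). The mapping is bijective.
#'
#' @param well character vector of well ids such as "A1" or "H12".
#' @param index integer vector of linear indices in 0..95.
#' @return `well_to_index` returns integer indices; `index_to_well` returns
#'   well id strings.
#' @examples
#' well_to_index("A1")  # 0
#' index_to_well(95)    # "H12"
#' @export
well_to_index <- function(well) {
  well <- toupper(as.character(well))
  ok <- grepl("^[A-H](1[0-2]|[1-9])$", well)
  if (!all(ok)) stop("malformed well id(s): ", paste(well[!ok], collapse = ", "))
  row <- match(substr(well, 1L, 1L), GRID_ROWS) - 1L
  col <- as.integer(substring(well, 2L))
  12L * row + (col - 1L)
}

#' @rdname well_to_index
#' @export
index_to_well <- function(index) {
  index <- as.integer(index)
  if (anyNA(index) || any(index < 0L | index > 95L))
    stop("linear well index must be in 0..95")
  paste0(GRID_ROWS[index %/% 12L + 1L], index %% 12L + 1L)
}

#' All 96 well ids in row-major plate order (A1..A12, B1..B12, ...).
#' @return character vector of length 96.
#' @export
plate_wells <- function() index_to_well(0:95)

# row-major vector of grid bits, aligned with plate_wells()
grid_bits <- function(grid) as.integer(t(unclass(grid)))

#' Encode a text payload on a plate
#'
#' Each plate column of 8 wells stores one 8-bit character: column j holds
#' the binary expansion of the code point of character j, most-significant
#' bit in row A. A plate therefore stores up to 12 characters (96 bits).
#' Code points 0..255 are accepted so that non-letter symbols round-trip.
#' Columns beyond the payload are all-zero (NUL).
#'
#' @param text a single string of at most 12 characters with code points in
#'   0..255.
#' @return a [bitgrid].
#' @seealso [grid_to_text()] for the inverse.
#' @examples
#' g <- text_to_grid("Hi")
#' grid_to_text(g)
#' @export
text_to_grid <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  codes <- utf8ToInt(text)
  if (length(codes) > GRID_NCOL)
    stop("payload capacity exceeded: ", length(codes), " characters > 12")
  if (length(codes) && any(codes > 255L))
    stop("characters with code points above 255 cannot be encoded")
  m <- matrix(0L, GRID_NROW, GRID_NCOL)
  for (j in seq_along(codes)) {
    # MSB in row A: bit 7 first
    m[, j] <- as.integer(bitwAnd(bitwShiftR(codes[j], 7:0), 1L))
  }
  bitgrid(m)
}

#' Decode a plate back into text
#'
#' Inverse of [text_to_grid()]: reads each column of 8 wells as one 8-bit
#' code point, row A the most-significant bit.
#'
#' @param grid a [bitgrid].
#' @param strip_nul drop trailing NUL (code point 0) columns, so short
#'   payloads round-trip readably. Default `TRUE`. R strings cannot carry
#'   NUL characters, so with `strip_nul = FALSE` a grid containing NUL
#'   columns is an error rather than a silently truncated string.
#' @return a single string.
#' @export
grid_to_text <- function(grid, strip_nul = TRUE) {
  stopifnot(is_bitgrid(grid))
  m <- unclass(grid)
  codes <- as.integer(crossprod(m, 2^(7:0)))
  if (strip_nul) {
    last <- max(c(0L, which(codes != 0L)))
    codes <- codes[seq_len(last)]
  }
  if (!length(codes)) return("")
  if (any(codes == 0L))
    stop("grid decodes to interior NUL characters, which R strings ",
         "cannot represent; re-run with strip_nul = TRUE or inspect ",
         "the grid directly")
  intToUtf8(codes)
}

#' Decoding accuracy of a reconstructed plate image
#'
#' The fraction of the 96 wells whose bit state matches the ground truth:
#' `(# matching wells) / 96`. Equivalently one minus the normalised Hamming
#' distance between the two grids; it is symmetric in its arguments.
#'
#' @param predicted,truth [bitgrid]s of identical shape.
#' @return a fraction in `[0, 1]`.
#' @examples
#' g <- text_to_grid("A")
#' grid_accuracy(g, g)  # 1
#' @export
grid_accuracy <- function(predicted, truth) {
  stopifnot(is_bitgrid(predicted), is_bitgrid(truth))
  if (!identical(dim(predicted), dim(truth))) stop("grid shapes differ")
  mean(unclass(predicted) == unclass(truth))
}

#' Built-in demonstration patterns
#'
#' 8x12 binary patterns used throughout examples and tests: block-letter
#' renderings of "NUS", "SYNCTI" and "BACCAM", a smiley face, and the
#' "Heloo wo{|d!" ASCII payload (the only pattern whose bits are fully
#' determined, via [text_to_grid()]). The letter/smiley bitmaps are this
#' package's own synthetic renderings at 8x12.
#'
#' @param name one of `"NUS"`, `"SYNCTI"`, `"BACCAM"`, `"SMILEY"`,
#'   `"HELOO"`, `"ON"`, `"OFF"`.
#' @return a [bitgrid].
#' @examples
#' print(pattern_grid("SMILEY"))
#' @export
pattern_grid <- function(name = c("NUS", "SYNCTI", "BACCAM", "SMILEY",
                                  "HELOO", "ON", "OFF")) {
  name <- match.arg(toupper(name), c("NUS", "SYNCTI", "BACCAM", "SMILEY",
                                     "HELOO", "ON", "OFF"))
  if (name == "HELOO") return(text_to_grid("Heloo wo{|d!"))
  if (name == "ON") return(bitgrid(rep(1L, 96)))
  if (name == "OFF") return(bitgrid(rep(0L, 96)))
  rows <- switch(name,
    NUS = c("............",
            "#..#.#..#.##",
            "##.#.#..#.#.",
            "#.##.#..#.##",
            "#..#.#..#..#",
            "#..#.#..#..#",
            "#..#..##..##",
            "............"),
    SYNCTI = c("............",
               ".##.#.#.#.#.",
               "#...#.#.##..",
               ".#...#..#.#.",
               "..#..#..#.#.",
               "##...#..#.#.",
               "............",
               "..###..##..#"),
    BACCAM = c("............",
               "##...#..##..",
               "#.#.#.#.#...",
               "##..###.#...",
               "#.#.#.#.#...",
               "##..#.#..##.",
               "............",
               ".#..##..#..#"),
    SMILEY = c("............",
               "...#....#...",
               "...#....#...",
               "............",
               ".#........#.",
               "..#......#..",
               "...######...",
               "............"))
  bitgrid(t(vapply(rows, function(r) as.integer(strsplit(r, "")[[1]] == "#"),
                   integer(GRID_NCOL))))
}
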