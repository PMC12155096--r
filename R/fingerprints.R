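#' Pack binary fingerprints into hex strings
#'
#' @param bits a 0/1 matrix, one fingerprint per row; the number of columns
#'   must be a multiple of 4.
#' @return Character vector of lower-case hex strings (4 bits per character,
#'   most significant bit first).
#' @export
fp_pack <- function(bits) {
  bits <- as.matrix(bits)
  if (ncol(bits) %% 4L != 0L)
    stop("fingerprint length must be a multiple of 4", call. = FALSE)
  hexd <- c(0:9, letters[1:6])
  apply(bits, 1L, function(b) {
    nib <- matrix(as.integer(b), nrow = 4L)
    paste(hexd[crossprod(nib, c(8L, 4L, 2L, 1L))[, 1L] + 1L], collapse = "")
  })
}

#' Unpack hex fingerprints into a 0/1 matrix
#'
#' @param hex character vector of hex strings of equal length.
#' @return Integer 0/1 matrix with one fingerprint per row.
#' @export
fp_unpack <- function(hex) {
  nibble <- matrix(c(0L,0L,0L,0L, 0L,0L,0L,1L, 0L,0L,1L,0L, 0L,0L,1L,1L,
                     0L,1L,0L,0L, 0L,1L,0L,1L, 0L,1L,1L,0L, 0L,1L,1L,1L,
                     1L,0L,0L,0L, 1L,0L,0L,1L, 1L,0L,1L,0L, 1L,0L,1L,1L,
                     1L,1L,0L,0L, 1L,1L,0L,1L, 1L,1L,1L,0L, 1L,1L,1L,1L),
                   nrow = 16L, byrow = TRUE,
                   dimnames = list(c(0:9, letters[1:6]), NULL))
  if (length(unique(nchar(hex))) != 1L)
    stop("hex fingerprints must all have the same length", call. = FALSE)
  t(vapply(strsplit(tolower(hex), ""), function(ch) {
    as.integer(t(nibble[ch, , drop = FALSE]))
  }, integer(4L * nchar(hex[1L]))))
}

#' Pairwise Tanimoto similarity of binary fingerprints
#'
#' Tanimoto (Jaccard) similarity `|A & B| / |A | B|`; two all-zero
#' fingerprints are assigned similarity 1.
#'
#' @param x 0/1 matrix, fingerprints in rows.
#' @param y optional second matrix; defaults to `x`.
#' @return Matrix of similarities, `nrow(x)` x `nrow(y)`.
#' @export
tanimoto <- function(x, y = x) {
  x <- as.matrix(x); y <- as.matrix(y)
  inter <- tcrossprod(x, y)
  nx <- rowSums(x); ny <- rowSums(y)
  uni <- outer(nx, ny, "+") - inter
  s <- inter / uni
  s[uni == 0] <- 1
  s
}
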