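#' Reverse complement of a DNA character string
#'
#' @param x character scalar over the IUPAC DNA alphabet.
#' @return character scalar, the reverse complement.
#' @keywords internal
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Wrap a padded circular coordinate back onto the mitogenome
#'
#' Positions on a circularly padded mitochondrial sequence run from 1 to
#' `mt_length + pad`; positions beyond `mt_length` are images of the first
#' `pad` positions. This is the single place where padded 1-based coordinates
#' are folded back to 1-based mitogenome coordinates.
#'
#' @param pos integer vector of 1-based positions on the padded sequence.
#' @param mt_length mitogenome length in bases.
#' @return integer vector of 1-based circular positions in `[1, mt_length]`.
#' @export
mt_wrap <- function(pos, mt_length) {
  stopifnot(all(pos >= 1L))
  ((as.integer(pos) - 1L) %% as.integer(mt_length)) + 1L
}

# length of a circular 1-based inclusive interval (start may exceed end when
# the interval wraps the origin)
circular_span <- function(start, end, mt_length) {
  ifelse(end >= start, end - start + 1L, mt_length - start + 1L + end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
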