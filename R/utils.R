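# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Report tables round GI to 2 decimals with halves rounded away from zero
#' (the convention of the printed tables this package emulates), unlike
#' [base::round()] which rounds halves to even. A tiny tolerance absorbs
#' binary floating-point dust so that values like 0.345 round up.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' roundHalfUp(0.345, 2) # 0.35, where round() gives 0.34
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
}

# first/second allele character of a diploid call ("GT" -> "G","T")
.allele1 <- function(calls) substr(calls, 1L, 1L)
.allele2 <- function(calls) substr(calls, 2L, 2L)

.isHet <- function(calls) !is.na(calls) & .allele1(calls) != .allele2(calls)
.isHom <- function(calls) !is.na(calls) & .allele1(calls) == .allele2(calls)

# nucleotide complement, errors on anything else
.complementAllele <- function(a) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  out <- map[a]
  if (anyNA(out[!is.na(a)])) {
    bad <- unique(a[!is.na(a) & !(a %in% names(map))])
    stop("cannot strand-complement non-nucleotide allele(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(out)
}

.complementCalls <- function(calls) {
  out <- calls
  ok <- !is.na(calls)
  out[ok] <- paste0(.complementAllele(.allele1(calls[ok])),
                    .complementAllele(.allele2(calls[ok])))
  out
}

# read a delimited table, separator chosen from the file extension
.readDelim <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
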