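#' Round half away from zero
#'
#' Reports in this package round halves upwards (5/12 -> 0.42, 104.5 -> 105)
#' rather than using R's round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Dog autosomes: 1..38. Chromosome labels are normalised to bare integers;
# X/Y/Un/MT and anything non-autosomal is rejected or dropped by callers.
.AUTOSOMES <- as.character(1:38)

#' Normalise chromosome labels
#'
#' Strips a leading "chr" prefix and returns the bare label ("1".."38", "X",
#' "MT", "Un", ...). No filtering is done here.
#'
#' @param chrom character or integer vector of chromosome labels.
#' @return character vector.
#' @keywords internal
normalize_chrom <- function(chrom) {
  sub("^[Cc][Hh][Rr]", "", as.character(chrom))
}

#' Is a chromosome label an autosome?
#' @param chrom character vector (already normalised).
#' @return logical vector.
#' @keywords internal
is_autosome <- function(chrom) {
  normalize_chrom(chrom) %in% .AUTOSOMES
}

.log_filter <- function(rule, removed, kept, verbose = TRUE) {
  if (isTRUE(verbose)) {
    message(sprintf("[filter] %s: removed=%d kept=%d", rule, removed, kept))
  }
  invisible(NULL)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# sample() helpers immune to the scalar-x convenience of base::sample
.sample1 <- function(x) x[sample.int(length(x), 1L)]
.sample_n <- function(x, n) x[sample.int(length(x), n)]
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
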