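# shared internal helpers

#' Round half away from zero at a fixed number of decimals
#'
#' Base \code{round()} rounds half to even; printed summary tables in this
#' package use conventional half-up rounding (99.625 -> 99.6 at one decimal).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half-up.
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage at printed precision
#'
#' \code{100 * count / total}, rounded half-up to \code{digits} decimals —
#' the arithmetic used for every percentage column in the summary tables.
#'
#' @param count,total numeric.
#' @param digits decimal places, default 1.
#' @return numeric percentage.
#' @export
percentOf <- function(count, total, digits = 1) {
  roundHalfUp(100 * count / total, digits)
}

# canonical internal alphabet: uppercase DNA (U -> T); N allowed
canonDNA <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(canonDNA(x))))
}

# complementarity classes on the canonical DNA alphabet
.isWC <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}
.isGU <- function(a, b) {
  (a == "G" & b == "T") | (a == "T" & b == "G")
}

# pair table from a dot-bracket string: integer vector, 0 = unpaired,
# otherwise 1-based partner index
pairTable <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  pt <- integer(length(chars))
  stk <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stk <- c(stk, i)
    } else if (chars[i] == ")") {
      if (length(stk) == 0L) stop("unbalanced brackets in structure")
      j <- stk[length(stk)]
      stk <- stk[-length(stk)]
      pt[i] <- j
      pt[j] <- i
    } else if (chars[i] != ".") {
      stop("unexpected character in dot-bracket string: ", chars[i])
    }
  }
  if (length(stk) > 0L) stop("unbalanced brackets in structure")
  pt
}

.msg <- function(...) {
  if (isTRUE(getOption("plantSmallRNA.verbose", FALSE))) message(...)
}

# stage log in the style "stage: n_in -> n_out (params)"
logStage <- function(stage, n_in, n_out, params = NULL) {
  p <- if (is.null(params)) "" else
    paste0(" [", paste(names(params), unlist(params), sep = "=", collapse = ", "), "]")
  .msg(sprintf("%s: %d -> %d%s", stage, n_in, n_out, p))
  invisible(NULL)
}
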