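# Regulatory signs and feed-forward-loop type classification.
#
# Signs are stored internally as +1L (activation) / -1L (inhibition) so the
# sign of a two-arm path is a plain product.

#' Feed-forward loop sign table
#'
#' The eight three-node feed-forward loops (FFLs), one per assignment of
#' signs to the X->Y, Y->Z and X->Z edges.  A loop is *coherent* when the
#' sign of the indirect arm (product of X->Y and Y->Z) equals the sign of
#' the direct X->Z arm, *incoherent* otherwise.  The numbering follows the
#' standard Mangan-Alon convention: c1 is the all-activating coherent loop,
#' c4 the coherent loop whose indirect arm holds two inhibitions, i4 the
#' incoherent loop with inhibitory X->Y and activating Y->Z, X->Z.
#'
#' @return A data frame with columns `type`, `sXY`, `sYZ`, `sXZ` (signs as
#'   `+1`/`-1`) and `coherent` (logical), one row per FFL type.
#' @examples
#' ffl_sign_table()
#' @export
ffl_sign_table <- function() {
  tab <- data.frame(
    type = c("c1", "c2", "c3", "c4", "i1", "i2", "i3", "i4"),
    sXY  = c(+1L,  -1L,  +1L,  -1L,  +1L,  -1L,  +1L,  -1L),
    sYZ  = c(+1L,  +1L,  -1L,  -1L,  -1L,  -1L,  +1L,  +1L),
    sXZ  = c(+1L,  -1L,  -1L,  +1L,  +1L,  -1L,  -1L,  +1L),
    stringsAsFactors = FALSE
  )
  tab$coherent <- tab$sXY * tab$sYZ == tab$sXZ
  tab
}

#' Convert between sign representations
#'
#' @param s a vector of signs given as `+1`/`-1`, `"+"`/`"-"`, or
#'   `"activation"`/`"inhibition"`.
#' @return `as_sign()` returns an integer vector of `+1L`/`-1L`;
#'   `sign_chr()` the `"+"`/`"-"` form.
#' @export
as_sign <- function(s) {
  if (is.numeric(s)) {
    if (!all(s %in% c(-1, 1))) stop("numeric signs must be +1 or -1")
    return(as.integer(s))
  }
  map <- c("+" = 1L, "-" = -1L, "−" = -1L,
           "activation" = 1L, "inhibition" = -1L)
  out <- map[as.character(s)]
  if (anyNA(out)) stop("unrecognised sign value: ", paste(s[is.na(out)], collapse = ", "))
  unname(out)
}

#' @rdname as_sign
#' @export
sign_chr <- function(s) c("-", "+")[(as_sign(s) > 0) + 1L]

#' Classify a feed-forward loop from its edge signs
#'
#' @param sXY,sYZ,sXZ signs of the X->Y, Y->Z and X->Z edges (any form
#'   accepted by [as_sign()]).
#' @return A list with elements `type` (e.g. `"c1"`) and `coherent`.
#' @examples
#' classify_ffl("+", "+", "+")  # c1, coherent
#' classify_ffl("-", "-", "+")  # c4, coherent
#' classify_ffl("-", "+", "+")  # i4, incoherent
#' @export
classify_ffl <- function(sXY, sYZ, sXZ) {
  sXY <- as_sign(sXY); sYZ <- as_sign(sYZ); sXZ <- as_sign(sXZ)
  tab <- ffl_sign_table()
  hit <- tab$sXY == sXY & tab$sYZ == sYZ & tab$sXZ == sXZ
  stopifnot(sum(hit) == 1L)
  list(type = tab$type[hit], coherent = tab$coherent[hit])
}

#' Admissible logic gates for a multiply-regulated node
#'
#' Regulators of equal sign may be integrated either independently (OR) or
#' jointly (AND).  When the incoming signs differ only the independent,
#' OR-like integration is defined, so a single gate remains.
#'
#' @param input_signs signs of all incoming regulatory edges (length >= 2).
#' @return Character vector of admissible gates: `c("AND", "OR")` when all
#'   signs agree, `"OR"` otherwise.
#' @examples
#' gate_options(c("+", "+"))       # AND, OR
#' gate_options(c("+", "-"))       # OR only
#' gate_options(c("+", "+", "+"))  # AND, OR (three-input node)
#' @export
gate_options <- function(input_signs) {
  s <- as_sign(input_signs)
  if (length(s) < 2L)
    stop("a logic gate requires at least two regulators")
  if (length(unique(s)) == 1L) c("AND", "OR") else "OR"
}
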