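## Double-quadrant encoding of signed interaxial angles and the pairwise
## code scoring function used by the matching objective.

.normalizeAngle <- function(omega) {
  ## map into (-180, 180]
  w <- (omega + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

#' Encode a signed interaxial angle as a two-character tableau code
#'
#' The angle is classified into quadrants in two ways that differ by 45
#' degrees, so that a perturbation smaller than 45 degrees changes at most
#' one of the two characters. First character: P on [-45, 45), R on
#' [45, 135), O on [135, 180] and (-180, -135), L on [-135, -45). Second
#' character: E on [0, 90), T on [90, 180], D on [-90, 0), S on
#' (-180, -90). Intervals are half-open toward increasing angle. Two
#' anti-parallel SSEs therefore encode as OS or OT; 143 degrees gives OT.
#'
#' @param omega numeric vector of signed angles in degrees; values are
#'   normalized into (-180, 180].
#' @return Character vector of two-character tableau codes.
#' @export
#' @examples
#' encodeAngle(143)   # "OT"
#' encodeAngle(c(10, -10, 45))
encodeAngle <- function(omega) {
  if (!is.numeric(omega) || any(!is.finite(omega)))
    stop("omega must be finite numeric angle(s) in degrees")
  w <- .normalizeAngle(omega)
  first <- ifelse(w >= -45 & w < 45, "P",
           ifelse(w >= 45 & w < 135, "R",
           ifelse(w >= -135 & w < -45, "L", "O")))
  second <- ifelse(w >= 0 & w < 90, "E",
            ifelse(w >= 90, "T",
            ifelse(w >= -90, "D", "S")))
  paste0(first, second)
}

#' Pairwise tableau-code score
#'
#' Scores a pair of orientation codes: 2 if identical, 1 if they agree in
#' exactly one of the two quadrant characters, -2 otherwise. Because of the
#' 45-degree offset between the two quadrant schemes, codes of similar
#' angles always score at least 1.
#'
#' @param a,b character vectors of valid tableau codes (recycled).
#' @return Integer vector with values in \{2, 1, -2\}.
#' @export
#' @examples
#' zetaScore("OT", "OT")  # 2
#' zetaScore("OT", "OS")  # 1
#' zetaScore("PE", "OT")  # -2
zetaScore <- function(a, b) {
  if (!all(.validTableauCode(a)) || !all(.validTableauCode(b)))
    stop("invalid tableau code")
  m <- (substr(a, 1L, 1L) == substr(b, 1L, 1L)) +
       (substr(a, 2L, 2L) == substr(b, 2L, 2L))
  c(-2L, 1L, 2L)[m + 1L]
}

#' SSE type class (helix or strand)
#'
#' @param type character vector of SSE type codes (\code{e}, \code{xa},
#'   \code{xi}, \code{xg}).
#' @return Character vector, \code{"strand"} or \code{"helix"}.
#' @export
#' @examples
#' sseTypeClass(c("e", "xa", "xg"))
sseTypeClass <- function(type) {
  if (!all(.validSSEType(type)))
    stop("invalid SSE type code")
  unname(.TYPE_CLASS[type])
}

#' Are two SSE types in the same class?
#'
#' SSEs of different classes (a helix and a strand) are never matched; all
#' helix subtypes (alpha, pi, 3-10) share one class.
#'
#' @param a,b character vectors of SSE type codes (recycled).
#' @return Logical vector.
#' @export
#' @examples
#' sameTypeClass("xa", "xg")  # TRUE
#' sameTypeClass("e", "xa")   # FALSE
sameTypeClass <- function(a, b) {
  sseTypeClass(a) == sseTypeClass(b)
}
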