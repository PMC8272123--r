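#' Integral projection profiles
#'
#' The horizontal projection of a binary image sums pixel values along
#' each row, \eqn{H(i) = \sum_j f(i, j)}; the vertical projection sums
#' along each column, \eqn{V(j) = \sum_i f(i, j)}. On a binarized
#' bitewing the row of minimum horizontal projection marks the gap
#' between the upper and lower rows of teeth, and column minima of the
#' vertical projection mark interdental gaps.
#'
#' @param bin Binary image matrix over `{0, 255}` (any numeric matrix is
#'   accepted; values are summed as-is).
#' @return A numeric vector of length `nrow(bin)` (horizontal) or
#'   `ncol(bin)` (vertical).
#' @export
horizontal_projection <- function(bin) rowSums(bin)

#' @rdname horizontal_projection
#' @export
vertical_projection <- function(bin) colSums(bin)
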