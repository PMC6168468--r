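#' @useDynLib spatialnet3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor lm quantile rnorm runif sd setNames coef fft nextn
#'   var weighted.mean complete.cases
#' @importFrom utils modifyList read.csv write.csv
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## wrap degrees into (-180, 180]
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## cross product of 3-vectors
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) v / sqrt(sum(v^2))

## angle between two plane normals, sign-invariant, in degrees [0, 90]
plane_angle <- function(n1, n2) {
  d <- abs(sum(unit3(n1) * unit3(n2)))
  rad2deg(acos(pmin(1, d)))
}
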