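#' @useDynLib synspace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif approx cor pf qf ptukey qtukey var sd
#' @importFrom utils read.csv write.csv head tail combn
NULL

# Canonical channel order: three shoulder orientation angles, two forearm
# orientation angles. FA_x = pronation-supination, FA_y = elbow
# flexion-extension.
SYN_CHANNELS <- c("SH_x", "SH_y", "SH_z", "FA_x", "FA_y")
SH_CHANNELS <- c("SH_x", "SH_y", "SH_z")
FA_CHANNELS <- c("FA_x", "FA_y")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

#' Deterministically derive a stage seed from a master seed and labels
#'
#' Stage seeds are a stable 31-bit hash of the master seed and an arbitrary
#' set of string/numeric labels (subject id, scenario fields, stage name), so
#' that a single master seed reproducibly drives every stochastic stage of an
#' experiment without seed collisions between stages.
#'
#' @param master integer master seed.
#' @param ... labels (coerced to character) identifying the stage.
#' @return a single integer in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(master, ...) {
  labels <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = "|"),
                         character(1)), collapse = "::")
  bytes <- utf8ToInt(paste0(master, "#", labels))
  # multiply-add hash reduced mod the Mersenne prime 2^31 - 1; the product
  # stays below 2^48 so double arithmetic is exact
  h <- 17
  for (b in bytes) h <- (h * 69069 + b + 1) %% 2147483647
  as.integer(h)
}

# Orthonormalize columns in order (classical Gram-Schmidt via QR) and fix the
# sign of each column so its largest-magnitude entry is positive.
orthonormalize <- function(M) {
  Q <- qr.Q(qr(M))
  fix_column_signs(Q)
}

fix_column_signs <- function(Q) {
  for (k in seq_len(ncol(Q))) {
    j <- which.max(abs(Q[, k]))
    if (Q[j, k] < 0) Q[, k] <- -Q[, k]
  }
  Q
}

#' Principal angles between two column subspaces
#'
#' Computed from the singular values of `Q_a' Q_b` after orthonormalizing the
#' columns of each basis. Used to quantify how well an estimated synergy
#' subspace matches a reference basis.
#'
#' @param a,b matrices with the same number of rows; columns span the
#'   subspaces.
#' @param degrees return angles in degrees (default) or radians.
#' @return numeric vector of principal angles, ascending.
#' @export
principal_angles <- function(a, b, degrees = TRUE) {
  qa <- qr.Q(qr(as.matrix(a)))
  qb <- qr.Q(qr(as.matrix(b)))
  s <- svd(crossprod(qa, qb))$d
  ang <- acos(pmin(pmax(s, -1), 1))
  if (degrees) ang * 180 / pi else ang
}
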