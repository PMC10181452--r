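#' Extract spatial kinematic synergies by principal component analysis
#'
#' Decomposes the row-mean-centered source matrix `X` as `W %*% C`, where the
#' columns of `W` (the spatial synergy loadings) are the leading eigenvectors
#' of the channel covariance and `C = t(W) %*% (X - means)` are the
#' activation signals. Among all rank-`N` factorizations this truncation
#' minimizes the Frobenius reconstruction error (Eckart-Young). Computed via
#' thin SVD of the centered matrix; column signs are fixed so each loading's
#' largest-magnitude entry is positive, making the result reproducible
#' across backends.
#'
#' @param source a `source_matrix` from [assemble_source_matrix()], or a
#'   plain numeric matrix with channels in rows (at least 2 columns).
#' @param n_components number of components to retain as `n_retained`;
#'   `NULL` (default) applies [select_components()] at the 0.85 cumulative
#'   explained-variance threshold. All `j` loadings are always stored; the
#'   retained count only sets the default rank for projection and
#'   reconstruction.
#' @param threshold cumulative explained-variance threshold used when
#'   `n_components` is `NULL`.
#' @return an object of class `synergy_decomp` with fields `loadings`
#'   (`j x j`, orthonormal columns), `activations` (`j x n_samples`),
#'   `channel_means`, `variance_fraction` (descending, sums to 1),
#'   `n_retained`, `channels`, and the source's `segment_boundaries` when
#'   available.
#' @export
extract_synergies <- function(source, n_components = NULL, threshold = 0.85) {
  if (inherits(source, "source_matrix")) {
    X <- source$values
    boundaries <- source$segment_boundaries
  } else {
    X <- as.matrix(source)
    boundaries <- NULL
  }
  j <- nrow(X)
  if (ncol(X) < 2L) stop("rank error: source needs at least 2 columns")
  if (!is.null(n_components) && n_components > j)
    stop("rank error: cannot retain more components than channels")
  if (is.null(rownames(X))) rownames(X) <- paste0("ch", seq_len(j))
  means <- rowMeans(X)
  Xc <- X - means
  sv <- svd(Xc, nu = j, nv = 0L)
  W <- fix_column_signs(sv$u)
  C <- crossprod(W, Xc)
  ev <- sv$d^2
  ev <- c(ev, numeric(j - length(ev)))[seq_len(j)]
  vf <- ev / sum(ev)
  rownames(W) <- rownames(X)
  colnames(W) <- paste0("synergy", seq_len(j))
  rownames(C) <- colnames(W)
  out <- structure(list(
    loadings = W,
    activations = C,
    channel_means = means,
    variance_fraction = vf,
    n_retained = NA_integer_,
    channels = rownames(X),
    segment_boundaries = boundaries
  ), class = "synergy_decomp")
  out$n_retained <- if (is.null(n_components)) select_components(out, threshold)
                    else as.integer(n_components)
  out
}

#' Minimum number of components exceeding a variance threshold
#'
#' Returns the smallest `N` whose cumulative explained-variance fraction is
#' strictly greater than `threshold` (the "at least more than 85% of total
#' variance" retention rule).
#'
#' @param decomp a `synergy_decomp`, or a numeric vector of per-component
#'   variance fractions (descending).
#' @param threshold cumulative variance threshold in `(0, 1]`
#'   (default 0.85).
#' @return integer count of retained components.
#' @export
select_components <- function(decomp, threshold = 0.85) {
  vf <- if (inherits(decomp, "synergy_decomp")) decomp$variance_fraction else decomp
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  cum <- cumsum(vf)
  n <- which(cum > threshold)[1L]
  if (is.na(n)) length(vf) else as.integer(n)
}

#' Reconstruct signals from synergy loadings and activations
#'
#' Computes `means + W[, 1:n] %*% C` for the requested channel rows: the
#' synergy model's signal reconstruction, used both for variance-truncated
#' reproduction of the source matrix and for turning predicted activation
#' signals into forearm angle estimates.
#'
#' @param decomp a `synergy_decomp`.
#' @param activations activation matrix (`n x T`); defaults to the stored
#'   activations.
#' @param n number of components to use (defaults to `nrow(activations)`).
#' @param channels channel names (rows) to return; default all.
#' @return reconstructed signal matrix, channels in rows.
#' @export
reconstruct <- function(decomp, activations = NULL, n = NULL, channels = NULL) {
  stopifnot(inherits(decomp, "synergy_decomp"))
  C <- activations %||% decomp$activations
  C <- as.matrix(C)
  n <- n %||% nrow(C)
  if (nrow(C) < n || n > ncol(decomp$loadings))
    stop("dimension mismatch between activations and loadings")
  channels <- channels %||% decomp$channels
  W <- decomp$loadings[channels, seq_len(n), drop = FALSE]
  decomp$channel_means[channels] + W %*% C[seq_len(n), , drop = FALSE]
}

#' Frobenius reconstruction error
#'
#' The Frobenius norm of `X - Xhat`, the quantity the synergy decomposition
#' minimizes at fixed rank.
#'
#' @param X,Xhat matrices of identical shape.
#' @return nonnegative scalar.
#' @export
reconstruction_error <- function(X, Xhat) {
  X <- as.matrix(X); Xhat <- as.matrix(Xhat)
  if (!identical(dim(X), dim(Xhat)))
    stop("shape mismatch: ", paste(dim(X), collapse = "x"), " vs ",
         paste(dim(Xhat), collapse = "x"))
  sqrt(sum((X - Xhat)^2))
}

#' Project new signals onto the synergy space
#'
#' Least-squares activation signals for given loadings:
#' `C = t(W[, 1:n]) %*% (X - means)`. Projecting the training source matrix
#' reproduces its stored activations exactly; this is how per-trial
#' activation targets for decoder training are obtained.
#'
#' @param decomp a `synergy_decomp`.
#' @param x new signal matrix with the decomposition's channels in rows.
#' @param n number of components (default: the decomposition's
#'   `n_retained`).
#' @return `n x T` activation matrix.
#' @export
project <- function(decomp, x, n = NULL) {
  stopifnot(inherits(decomp, "synergy_decomp"))
  x <- as.matrix(x)
  n <- n %||% decomp$n_retained
  ch <- decomp$channels
  if (!all(ch %in% (rownames(x) %||% ch)) || nrow(x) != length(ch))
    stop("dimension mismatch: signals must carry the decomposition's channels")
  if (!is.null(rownames(x))) x <- x[ch, , drop = FALSE]
  W <- decomp$loadings[, seq_len(n), drop = FALSE]
  crossprod(W, x - decomp$channel_means)
}

#' Synergy loadings mapped back to degrees
#'
#' The decomposition operates on normalized signals, so its loading columns
#' live in normalized units; row-wise multiplication by each channel's
#' half-range `(max - min) / 2` maps them back to degrees per unit
#' activation, the space in which a generating basis is expressed. Use this
#' when comparing an extracted synergy subspace against a known
#' ground-truth basis (e.g. with [principal_angles()]).
#'
#' @param decomp a `synergy_decomp` fitted on normalized data.
#' @param record the `normalization_record` that produced that data.
#' @param n number of columns to return (default `n_retained`).
#' @return a `j x n` loading matrix in degrees (columns not re-normalized).
#' @export
loadings_in_degrees <- function(decomp, record, n = decomp$n_retained) {
  stopifnot(inherits(decomp, "synergy_decomp"),
            inherits(record, "normalization_record"))
  scale <- (record$max[decomp$channels] - record$min[decomp$channels]) / 2
  decomp$loadings[, seq_len(n), drop = FALSE] * scale
}

#' @export
print.synergy_decomp <- function(x, ...) {
  cat(sprintf("<synergy_decomp> %d channels, %d samples; %d component(s) retained\n",
              length(x$channels), ncol(x$activations), x$n_retained))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.synergy_decomp <- function(object, ...) {
  df <- data.frame(
    component = seq_along(object$variance_fraction),
    variance_fraction = object$variance_fraction,
    cumulative = cumsum(object$variance_fraction),
    retained = seq_along(object$variance_fraction) <= object$n_retained)
  structure(list(table = df, loadings = object$loadings,
                 n_retained = object$n_retained),
            class = "summary.synergy_decomp")
}

#' @export
print.summary.synergy_decomp <- function(x, ...) {
  cat("Synergy decomposition\n\nExplained variance:\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("\nLoadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' @export
#' @importFrom graphics barplot abline legend matplot
plot.synergy_decomp <- function(x, type = c("variance", "loadings"), ...) {
  type <- match.arg(type)
  if (type == "variance") {
    bp <- barplot(cumsum(x$variance_fraction), names.arg = seq_along(x$variance_fraction),
                  ylab = "cumulative variance fraction", xlab = "components",
                  ylim = c(0, 1), ...)
    abline(h = 0.85, lty = 2)
  } else {
    barplot(t(x$loadings[, seq_len(x$n_retained), drop = FALSE]), beside = TRUE,
            names.arg = x$channels, ylab = "loading",
            legend.text = paste("synergy", seq_len(x$n_retained)), ...)
  }
  invisible(x)
}
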