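#' Principal coordinates analysis of a distance matrix
#'
#' Classical (Gower) scaling: the squared distances are double-centered into
#' -0.5 * J D^2 J, whose eigendecomposition gives axes ordered by descending
#' eigenvalue. Negative eigenvalues are retained and reported but their axes
#' are excluded from the coordinates.
#'
#' @param d A symmetric distance matrix (or `dist`) with zero diagonal.
#' @param tol Asymmetry tolerance (default 1e-8); larger asymmetry errors.
#' @return Object of class `pcoa_ordination`: `coordinates` (tibble with
#'   `library_id` and `Axis1..k`), `eigenvalues` (all, including negative),
#'   and `relative_inertia` (eigenvalue / sum of positive eigenvalues).
#' @export
#' @examples
#' pts <- cbind(x = c(0, 1, 0), y = c(0, 0, 2))
#' ord <- pcoa_ordination(as.matrix(dist(pts)))
#' ord$eigenvalues
pcoa_ordination <- function(d, tol = 1e-8) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square",
                               call. = FALSE)
  if (max(abs(d - t(d))) > tol) {
    stop("distance matrix is asymmetric beyond tolerance", call. = FALSE)
  }
  if (max(abs(diag(d))) > tol) {
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (d^2) %*% J
  G <- (G + t(G)) / 2
  eig <- eigen(G, symmetric = TRUE)
  values <- eig$values
  pos <- which(values > max(values) * 1e-12 & values > 0)
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(values[pos]), length(pos))
  colnames(coords) <- paste0("Axis", seq_along(pos))
  ids <- rownames(d) %||% paste0("sample", seq_len(n))
  structure(
    list(coordinates = dplyr::bind_cols(tibble::tibble(library_id = ids),
                                        tibble::as_tibble(coords)),
         eigenvalues = values,
         relative_inertia = values / sum(values[values > 0]),
         gower_trace = sum(diag(G))),
    class = "pcoa_ordination"
  )
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  k <- ncol(x$coordinates) - 1L
  cat(sprintf("<pcoa_ordination> %d samples, %d positive axes\n",
              nrow(x$coordinates), k))
  if (k > 0) {
    cat(sprintf("  Axis1 %.1f%%, Axis2 %.1f%% of positive inertia\n",
                100 * x$relative_inertia[1],
                if (k > 1) 100 * x$relative_inertia[2] else 0))
  }
  invisible(x)
}

#' @export
tidy.pcoa_ordination <- function(x, ...) {
  tibble::tibble(axis = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 relative_inertia = x$relative_inertia)
}
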