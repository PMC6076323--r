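#' Build the genomic relationship matrix G = XX'/p
#'
#' Each marker column is centered by its mean and divided by its population
#' standard deviation (divisor n, not n - 1), and G is the cross-product of
#' the standardized matrix divided by the number of markers. Under this
#' standardization `trace(G)/n = 1` holds exactly, so the mean diagonal is 1
#' and the matrix is on the usual relatedness scale.
#'
#' @param m A [marker_matrix()] with no missing entries (run
#'   [filter_and_impute()] first).
#' @return An object of class `genomic_relationship`: a list with elements
#'   `G` (symmetric n-by-n matrix with line IDs as dimnames), `lines`
#'   (character) and `p` (number of markers used).
#' @export
build_grm <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  x <- m$dosages
  if (anyNA(x)) {
    abort("Marker matrix contains missing entries; run filter_and_impute() first.")
  }
  mu <- colMeans(x)
  # population SD: divisor n
  sd_pop <- sqrt(colMeans(sweep(x, 2, mu, "-")^2))
  poly <- sd_pop > 0
  if (!any(poly)) abort("No polymorphic markers; cannot build G.")
  if (!all(poly)) {
    warn(sprintf("Dropping %d monomorphic marker(s).", sum(!poly)))
    x <- x[, poly, drop = FALSE]
    mu <- mu[poly]
    sd_pop <- sd_pop[poly]
  }
  X <- sweep(sweep(x, 2, mu, "-"), 2, sd_pop, "/")
  p <- ncol(X)
  G <- tcrossprod(X) / p
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(x), rownames(x))
  structure(
    list(G = G, lines = rownames(x), p = p),
    class = "genomic_relationship"
  )
}

#' @export
print.genomic_relationship <- function(x, ...) {
  cat(sprintf(
    "<genomic_relationship> %d lines, %d markers; mean diagonal %.4f\n",
    length(x$lines), x$p, mean(diag(x$G))
  ))
  invisible(x)
}

#' @export
dim.genomic_relationship <- function(x) dim(x$G)

#' Tidy a genomic relationship matrix into long format
#'
#' @param x A `genomic_relationship`.
#' @param ... Unused.
#' @return A tibble with columns `line1`, `line2`, `relationship`.
#' @export
tidy.genomic_relationship <- function(x, ...) {
  g <- x$G
  tibble(
    line1 = rep(rownames(g), times = ncol(g)),
    line2 = rep(colnames(g), each = nrow(g)),
    relationship = as.vector(g)
  )
}

#' Write / read a GRM as a tab-delimited square matrix
#'
#' @param grm A `genomic_relationship`.
#' @param path File path.
#' @return `path` (write) or a `genomic_relationship` (read).
#' @export
write_grm <- function(grm, path) {
  stopifnot(inherits(grm, "genomic_relationship"))
  df <- as.data.frame(grm$G)
  df <- cbind(line = grm$lines, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @param p Marker count to record on the re-read object (optional).
#' @export
read_grm <- function(path, p = NA_integer_) {
  df <- utils::read.delim(path, check.names = FALSE)
  g <- as.matrix(df[, -1, drop = FALSE])
  rownames(g) <- as.character(df[[1]])
  structure(
    list(G = g, lines = rownames(g), p = p),
    class = "genomic_relationship"
  )
}
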