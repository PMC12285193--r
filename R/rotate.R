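#' Rotate and align the 2D top space with annotated axes
#'
#' The likelihood of the model is invariant to orthogonal transforms of the
#' top space, so after fitting the two components can be aligned with
#' interpretable axes (e.g. maturation stage along component 1, condition
#' along component 2). Searches a grid of 100 rotation angles in [0, 2*pi)
#' crossed with the 4 axis flips and keeps the transform maximizing the sum,
#' over the requested targets, of the Pearson correlation between the
#' integer-encoded labels and the targeted rotated axis.
#'
#' @param embedding a \code{decipher_embedding} with 2D v.
#' @param axis_targets a list of targets, each a list with \code{column}
#'   (annotation column name), \code{order} (character vector giving the
#'   category order; ties allowed by repeating a rank via \code{ranks}), and
#'   \code{axis} (1 or 2). Alternatively \code{ranks}, a named numeric
#'   vector mapping category to rank, may replace \code{order}.
#' @param n_angles number of rotation angles tried (default 100).
#' @return The embedding with \code{v} transformed and \code{transform} set
#'   to the chosen orthogonal matrix (applied on the right: v_new = v M').
#' @export
rotate_space <- function(embedding, axis_targets, n_angles = 100L) {
  stopifnot(inherits(embedding, "decipher_embedding"), ncol(embedding$v) == 2)
  if (!is.null(axis_targets$column)) axis_targets <- list(axis_targets)
  scores <- lapply(axis_targets, function(tg) {
    if (is.null(embedding$annotations) ||
        is.null(embedding$annotations[[tg$column]])) {
      stop("annotation column not found: ", tg$column)
    }
    labels <- as.character(embedding$annotations[[tg$column]])
    ranks <- if (!is.null(tg$ranks)) tg$ranks
             else stats::setNames(seq_along(tg$order), tg$order)
    if (any(!labels %in% names(ranks))) {
      stop("unordered categories in ", tg$column, ": ",
           paste(utils::head(setdiff(labels, names(ranks)), 5), collapse = ", "))
    }
    list(y = as.numeric(ranks[labels]), axis = as.integer(tg$axis))
  })
  v <- embedding$v
  angles <- seq(0, 2 * pi, length.out = n_angles + 1L)[seq_len(n_angles)]
  flips <- list(c(1, 1), c(-1, 1), c(1, -1), c(-1, -1))
  best <- -Inf; best_M <- diag(2)
  for (ang in angles) {
    R <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2, byrow = TRUE)
    for (fl in flips) {
      M <- diag(fl) %*% R
      vt <- v %*% t(M)
      s <- sum(vapply(scores, function(sc) {
        stats::cor(sc$y, vt[, sc$axis])
      }, numeric(1)))
      if (s > best) { best <- s; best_M <- M }
    }
  }
  embedding$v <- v %*% t(best_M)
  embedding$transform <- best_M %*% embedding$transform
  embedding$alignment_score <- best
  embedding
}
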