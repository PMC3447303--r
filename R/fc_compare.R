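#' Model functional connectivity at the edge of bifurcation
#'
#' Sweeps the coupling grid, locates the edge of bifurcation W* (the
#' steepest entropy rise; see [find_edge_of_bifurcation()]), and returns the
#' exact pairwise spin correlation matrix at W* — the model's functional
#' connectivity. An optional grid-point offset lets the FC be evaluated
#' slightly before or after the located point.
#'
#' @param c a `connectome` (structural connectivity).
#' @param p_base an [ising_params()].
#' @param W_grid strictly increasing coupling grid.
#' @param offset integer grid-point shift applied to W* (default 0).
#' @param chunk_size passed to the enumeration.
#' @return list: `fc` (N x N correlation matrix, diagonal 1), `w_star`,
#'   `sweep` (the entropy sweep), `labels`.
#' @export
model_fc <- function(c, p_base, W_grid, offset = 0L, chunk_size = 65536L) {
  sweep <- entropy_sweep(c, p_base, W_grid, chunk_size = chunk_size)
  w_star <- find_edge_of_bifurcation(sweep)
  idx <- match(w_star, W_grid) + as.integer(offset)
  idx <- min(max(idx, 1L), length(W_grid))
  w_use <- W_grid[idx]
  p_at <- ising_params(W = w_use, theta = p_base$theta,
                       epsilon = p_base$epsilon,
                       energy_convention = p_base$energy_convention)
  ps <- pair_stats(c, p_at, chunk_size = chunk_size)
  fc <- ps$corr
  diag(fc) <- 1
  list(fc = fc, w_star = w_use, sweep = sweep, labels = c$labels)
}

#' Pattern correlation between two functional-connectivity matrices
#'
#' Pearson (or Spearman) correlation over the strictly-upper-triangle
#' entries only; the diagonal and lower triangle never influence the
#' statistic. This is the scalar used to compare model FC against empirical
#' (or synthetic) FC.
#'
#' @param model,empirical square symmetric matrices of equal dimension (or
#'   lists with an `fc` element, as returned by [model_fc()]).
#' @param method "pearson" (default) or "spearman".
#' @return correlation in [-1, 1].
#' @export
fc_pattern_correlation <- function(model, empirical,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- if (is.list(model) && !is.null(model$fc)) model$fc else model
  e <- if (is.list(empirical) && !is.null(empirical$fc)) empirical$fc
       else empirical
  if (!all(dim(m) == dim(e)))
    stop("FC matrices have different dimensions")
  ut <- upper.tri(m)
  a <- m[ut]
  b <- e[ut]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in an upper triangle; pattern correlation undefined")
  stats::cor(a, b, method = method)
}
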