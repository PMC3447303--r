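#' Construct a connectome object
#'
#' A connectome is a symmetric, non-negative, zero-diagonal weighted
#' adjacency matrix with node labels and optional hemisphere tags. Weights
#' are dimensionless fiber densities or binary 0/1 indicators; symmetry is
#' required because tractography cannot resolve fiber directionality and the
#' Boltzmann analytics assume symmetric couplings.
#'
#' Matrices asymmetric within `tol` are symmetrized as (A + t(A))/2; larger
#' asymmetries are an error.
#'
#' @param weights square numeric matrix of non-negative weights.
#' @param labels character vector of node identifiers; defaults to 0-based
#'   indices as strings.
#' @param hemisphere optional character vector with entries "left"/"right",
#'   one per node.
#' @param tol symmetry tolerance (default 1e-9).
#' @return an object of class `connectome` with elements `weights`, `labels`,
#'   `hemisphere`.
#' @export
connectome <- function(weights, labels = NULL, hemisphere = NULL, tol = 1e-9) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("weights must be a numeric matrix")
  n <- nrow(weights)
  if (ncol(weights) != n)
    stop(sprintf("weights must be square, got %d x %d", n, ncol(weights)))
  if (anyNA(weights) || any(!is.finite(weights)))
    stop("weights contains non-finite values")
  asym <- abs(weights - t(weights))
  if (any(asym > tol)) {
    idx <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("asymmetry %.3g beyond tolerance at row %d, column %d",
                 max(asym), idx[1], idx[2]))
  }
  weights <- (weights + t(weights)) / 2
  if (any(weights < 0)) {
    idx <- which(weights < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative weight at row %d, column %d", idx[1], idx[2]))
  }
  if (any(diag(weights) != 0)) {
    bad <- which(diag(weights) != 0)[1]
    stop(sprintf("nonzero diagonal at node %d; self-coupling is not allowed", bad))
  }
  if (is.null(labels)) labels <- as.character(seq_len(n) - 1L)
  if (length(labels) != n)
    stop(sprintf("labels has length %d, need %d", length(labels), n))
  if (!is.null(hemisphere)) {
    if (length(hemisphere) != n)
      stop("hemisphere tags must cover all nodes")
    if (!all(hemisphere %in% c("left", "right")))
      stop("hemisphere tags must be 'left' or 'right'")
  }
  dimnames(weights) <- NULL
  structure(list(weights = weights, labels = as.character(labels),
                 hemisphere = hemisphere),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  n <- n_nodes(x)
  m <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("connectome: %d nodes, %d edges, %s\n", n, m,
              if (all(x$weights %in% c(0, 1))) "binary" else "weighted"))
  if (!is.null(x$hemisphere))
    cat(sprintf("  hemispheres: %d left, %d right\n",
                sum(x$hemisphere == "left"), sum(x$hemisphere == "right")))
  invisible(x)
}

#' Number of nodes of a connectome
#' @param c a `connectome`.
#' @return integer node count.
#' @export
n_nodes <- function(c) nrow(c$weights)

#' Number of (undirected) edges of a connectome
#' @param c a `connectome`.
#' @return integer count of node pairs with nonzero weight.
#' @export
n_edges <- function(c) sum(c$weights[upper.tri(c$weights)] != 0)

#' Read a connectivity matrix from disk
#'
#' Supported formats: `matrix-csv` / `matrix-tsv` (plain numeric square
#' matrix, optional single header row of labels) and `edge-list`
#' (whitespace- or comma-separated `i j weight` lines, undirected; each
#' entry is mirrored). Integer node identifiers in an edge list are taken as
#' 0-based indices; other identifiers become labels in order of first
#' appearance.
#'
#' @param path file path.
#' @param format one of "matrix-csv", "matrix-tsv", "edge-list"; guessed
#'   from the extension when missing (.csv, .tsv; anything else = edge list).
#' @return a validated [connectome()].
#' @export
read_connectome <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "matrix-csv", tsv = "matrix-tsv", "edge-list")
  }
  format <- match.arg(format, c("matrix-csv", "matrix-tsv", "edge-list"))
  if (format == "edge-list") return(read_edge_list(path))
  sep <- if (format == "matrix-csv") "," else "\t"
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  tab <- utils::read.table(path, sep = sep, header = has_header,
                           check.names = FALSE, comment.char = "")
  labels <- if (has_header) colnames(tab) else NULL
  m <- as.matrix(tab)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))),
                 arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row %d, column %d", bad[1], bad[2]))
  }
  dimnames(m) <- NULL
  connectome(m, labels = labels)
}

read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty edge list")
  parts <- strsplit(lines, "[,[:space:]]+")
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0)
    stop(sprintf("edge list row %d does not have 3 fields", bad[1]))
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(w)) stop(sprintf("non-numeric weight at edge list row %d",
                             which(is.na(w))[1]))
  ids <- c(from, to)
  int_ids <- suppressWarnings(as.integer(ids))
  if (!anyNA(int_ids) && all(int_ids >= 0) &&
      all(int_ids == as.numeric(ids))) {
    n <- max(int_ids) + 1L
    labels <- as.character(seq_len(n) - 1L)
    i <- as.integer(from) + 1L
    j <- as.integer(to) + 1L
  } else {
    labels <- unique(ids)
    n <- length(labels)
    i <- match(from, labels)
    j <- match(to, labels)
  }
  m <- matrix(0, n, n)
  for (k in seq_along(i)) {
    m[i[k], j[k]] <- w[k]
    m[j[k], i[k]] <- w[k]
  }
  connectome(m, labels = labels)
}

#' Binarize a connectome
#'
#' Weights strictly above `threshold` become 1, everything else 0. Symmetry
#' and the zero diagonal are preserved; binarize is idempotent.
#'
#' @param c a `connectome`.
#' @param threshold non-negative real cut (default 0: any positive weight is
#'   an edge).
#' @return a binary `connectome`.
#' @export
binarize <- function(c, threshold = 0) {
  if (threshold < 0) stop("threshold must be non-negative")
  w <- (c$weights > threshold) * 1
  diag(w) <- 0
  connectome(w, labels = c$labels, hemisphere = c$hemisphere)
}

#' Split a connectome into its two hemispheres
#'
#' Uses the `hemisphere` tags when present; otherwise, for even N, the first
#' half is taken as the left hemisphere and the second as the right (the
#' center-symmetric ordering convention for homotopic areas). Only
#' intra-hemisphere weights are retained.
#'
#' @param c a `connectome`.
#' @return list with `left` and `right` connectomes.
#' @export
split_hemispheres <- function(c) {
  n <- n_nodes(c)
  if (!is.null(c$hemisphere)) {
    left <- which(c$hemisphere == "left")
    right <- which(c$hemisphere == "right")
    if (length(left) + length(right) != n)
      stop("hemisphere tags do not bipartition the nodes")
  } else {
    if (n %% 2 != 0)
      stop("odd node count and no hemisphere tags; cannot split")
    left <- seq_len(n / 2)
    right <- seq(n / 2 + 1, n)
  }
  sub <- function(idx, tag) {
    connectome(c$weights[idx, idx, drop = FALSE], labels = c$labels[idx],
               hemisphere = rep(tag, length(idx)))
  }
  list(left = sub(left, "left"), right = sub(right, "right"))
}

#' Write a numeric matrix to disk
#'
#' Full-precision plain-text output that round-trips through
#' [read_connectome()] (or [utils::read.table()]) within 1e-12.
#'
#' @param m numeric matrix with finite entries.
#' @param path output path.
#' @param format "matrix-csv", "matrix-tsv", or "edge-list" (upper triangle
#'   of nonzero entries as 0-based `i j weight` lines).
#' @param labels optional header labels (matrix formats only).
#' @return invisibly, `path`.
#' @export
write_matrix <- function(m, path, format = c("matrix-csv", "matrix-tsv",
                                             "edge-list"), labels = NULL) {
  format <- match.arg(format)
  if (!all(is.finite(m))) stop("matrix has non-finite entries")
  if (format == "edge-list") {
    idx <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
    lines <- sprintf("%d %d %s", idx[, 1] - 1L, idx[, 2] - 1L,
                     format(m[idx], digits = 17, scientific = FALSE,
                            trim = TRUE))
    writeLines(lines, path)
    return(invisible(path))
  }
  sep <- if (format == "matrix-csv") "," else "\t"
  txt <- apply(m, 1, function(r)
    paste(format(r, digits = 17, scientific = TRUE, trim = TRUE),
          collapse = sep))
  if (!is.null(labels)) txt <- c(paste(labels, collapse = sep), txt)
  writeLines(txt, path)
  invisible(path)
}
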