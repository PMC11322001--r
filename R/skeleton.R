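# Morphological skeletonization (Zhang-Suen thinning) and geodesic paths on
# the skeleton pixel graph. Written here because no installed imaging package
# exposes a thinning primitive; the graph work is delegated to igraph.

shift_mat <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  ri <- seq_len(nr) + di; cj <- seq_len(nc) + dj
  ok_i <- ri >= 1 & ri <= nr; ok_j <- cj >= 1 & cj <= nc
  out[ok_i, ok_j] <- m[ri[ok_i], cj[ok_j]]
  out
}

#' Skeletonize a binary mask by Zhang-Suen thinning
#'
#' Iteratively peels boundary pixels while preserving 8-connectivity until a
#' one-pixel-wide skeleton remains.
#'
#' @param mask logical or 0/1 matrix.
#' @param max_iter safety cap on thinning iterations.
#' @return logical matrix of the same shape.
#' @export
thin_mask <- function(mask, max_iter = 1000) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours clockwise from north
      p2 <- shift_mat(m, -1,  0); p3 <- shift_mat(m, -1,  1)
      p4 <- shift_mat(m,  0,  1); p5 <- shift_mat(m,  1,  1)
      p6 <- shift_mat(m,  1,  0); p7 <- shift_mat(m,  1, -1)
      p8 <- shift_mat(m,  0, -1); p9 <- shift_mat(m, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
           (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
           (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- m == 1 & B >= 2 & B <= 6 & A == 1
      if (step == 1)
        cond <- cond & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      else
        cond <- cond & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

# Build the 8-neighbour pixel graph of a skeleton. Edge weights are the
# Euclidean pixel step lengths (1 or sqrt(2)).
skeleton_graph <- function(skeleton) {
  idx <- which(skeleton, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty skeleton", call. = FALSE)
  key <- paste(idx[, 1], idx[, 2])
  id <- seq_len(nrow(idx)); names(id) <- key
  edges <- NULL; weights <- NULL
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1))  # half-neighbourhood
  for (r in seq_len(nrow(offs))) {
    nb <- cbind(idx[, 1] + offs[r, 1], idx[, 2] + offs[r, 2])
    nbkey <- paste(nb[, 1], nb[, 2])
    hit <- nbkey %in% key
    if (any(hit)) {
      edges <- rbind(edges, cbind(id[key[hit]], id[nbkey[hit]]))
      weights <- c(weights, rep(sqrt(sum(offs[r, ]^2)), sum(hit)))
    }
  }
  g <- igraph::make_empty_graph(n = nrow(idx), directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges), weight = weights)
  list(graph = g, pixels = idx)
}

# Vertex sequence of the longest geodesic (weighted diameter path).
skeleton_longest_path <- function(g) {
  if (igraph::vcount(g$graph) == 1) return(1L)
  as.integer(igraph::get_diameter(g$graph,
                                  weights = igraph::E(g$graph)$weight))
}

# Geodesic length (in pixels) of the longest skeleton path, plus the pixel
# index path itself.
skeleton_path_info <- function(mask) {
  sk <- thin_mask(mask)
  g <- skeleton_graph(sk)
  path <- skeleton_longest_path(g)
  pix <- g$pixels[path, , drop = FALSE]
  len <- if (nrow(pix) > 1)
    sum(sqrt(diff(pix[, 1])^2 + diff(pix[, 2])^2)) else 0
  list(pixels = pix, length_px = len, skeleton = sk)
}
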