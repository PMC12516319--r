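# Topological skeletonization and skeleton-graph pruning. No installed
# R package offers binary thinning, so the Zhang-Suen algorithm is
# implemented here, vectorised over whole-image shifts (each
# sub-iteration peels one boundary layer; cost is O(iterations x pixels)
# with iterations ~ half the maximal shape width).

#' @noRd
shiftMat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  okr <- rs >= 1L & rs <= nr; okc <- cs >= 1L & cs <= nc
  out[okr, okc] <- m[rs[okr], cs[okc]]
  out
}

#' Topological skeleton of a binary mask (Zhang-Suen thinning)
#'
#' Iteratively removes boundary pixels while preserving connectivity
#' until a one-pixel-wide, 8-connected skeleton remains.
#'
#' @param mask logical or 0/1 matrix.
#' @return logical matrix of the same size.
#' @export
thinMask <- function(mask) {
  img <- (mask != 0) * 1L
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours in Zhang-Suen order: P2 = north ... P9 = north-west
      P2 <- shiftMat(img, -1L, 0L);  P3 <- shiftMat(img, -1L, 1L)
      P4 <- shiftMat(img, 0L, 1L);   P5 <- shiftMat(img, 1L, 1L)
      P6 <- shiftMat(img, 1L, 0L);   P7 <- shiftMat(img, 1L, -1L)
      P8 <- shiftMat(img, 0L, -1L);  P9 <- shiftMat(img, -1L, -1L)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0L & P3 == 1L) + (P3 == 0L & P4 == 1L) +
           (P4 == 0L & P5 == 1L) + (P5 == 0L & P6 == 1L) +
           (P6 == 0L & P7 == 1L) + (P7 == 0L & P8 == 1L) +
           (P8 == 0L & P9 == 1L) + (P9 == 0L & P2 == 1L)
      cond <- img == 1L & B >= 2L & B <= 6L & A == 1L
      if (step == 1L) {
        cond <- cond & (P2 * P4 * P6 == 0L) & (P4 * P6 * P8 == 0L)
      } else {
        cond <- cond & (P2 * P4 * P8 == 0L) & (P2 * P6 * P8 == 0L)
      }
      if (any(cond)) {
        img[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img > 0L
}

#' @noRd
#' Longest geodesic path through the skeleton of a mask, as an ordered
#' matrix of pixel (row, col) indices. Endpoint pair with the largest
#' Euclidean-weighted geodesic distance wins; ties break on the
#' lexicographically smallest endpoint pixel. Skeletons without leaves
#' (cycles) fall back to a double-sweep farthest pair.
skeletonPath <- function(mask) {
  sk <- thinMask(mask)
  px <- which(sk, arr.ind = TRUE)
  if (nrow(px) == 0L) stop("skeleton is empty")
  if (nrow(px) == 1L) return(px)
  nr <- nrow(sk)
  id <- matrix(NA_integer_, nr, ncol(sk))
  id[px] <- seq_len(nrow(px))
  # 8-neighbour edges (4 directions suffice; graph is undirected)
  edges <- NULL; weights <- NULL
  for (d in list(c(0L, 1L, 1), c(1L, 0L, 1), c(1L, 1L, sqrt(2)),
                 c(1L, -1L, sqrt(2)))) {
    r2 <- px[, 1] + d[1]; c2 <- px[, 2] + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(sk)
    tgt <- rep(NA_integer_, nrow(px))
    tgt[ok] <- id[cbind(r2[ok], c2[ok])]
    has <- !is.na(tgt)
    if (any(has)) {
      edges <- rbind(edges, cbind(which(has), tgt[has]))
      weights <- c(weights, rep(d[3], sum(has)))
    }
  }
  if (is.null(edges)) return(px[1, , drop = FALSE])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- weights
  if (igraph::vcount(g) < nrow(px))
    g <- igraph::add_vertices(g, nrow(px) - igraph::vcount(g))
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  inMain <- comp$membership == main
  deg <- igraph::degree(g)
  leaves <- which(deg == 1L & inMain)
  # row-major pixel order defines the lexicographic tie-break
  ord <- order(px[, 1], px[, 2])
  rank <- integer(nrow(px)); rank[ord] <- seq_len(nrow(px))
  if (length(leaves) >= 2L) {
    cand <- leaves[order(rank[leaves])]
    dm <- igraph::distances(g, v = cand, to = cand)
    best <- which(dm == max(dm), arr.ind = TRUE)
    # smallest endpoint rank first, then smallest partner
    best <- best[order(pmin(best[, 1], best[, 2]),
                       pmax(best[, 1], best[, 2])), , drop = FALSE]
    from <- cand[min(best[1, ])]; to <- cand[max(best[1, ])]
  } else {
    v0 <- which(inMain)[which.min(rank[inMain])]
    d0 <- igraph::distances(g, v = v0)[1, ]
    d0[!inMain] <- -Inf
    from <- which.max(d0)
    d1 <- igraph::distances(g, v = from)[1, ]
    d1[!inMain] <- -Inf
    to <- which.max(d1)
  }
  vp <- igraph::shortest_paths(g, from = from, to = to)$vpath[[1]]
  path <- px[as.integer(vp), , drop = FALSE]
  # canonical orientation: lexicographically smaller endpoint first
  if (rank[as.integer(vp[1])] > rank[as.integer(vp[length(vp)])])
    path <- path[rev(seq_len(nrow(path))), , drop = FALSE]
  path
}
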