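## Morphological thinning (Zhang & Suen 1984) and skeleton-graph utilities.
## No installed package in this stack provides 2D skeletonization, so the
## classic two-subiteration thinning is implemented here, vectorized over
## the image.

shiftMat <- function(M, dr, dc) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- M[rs - dr, cs - dc]
  out
}

#' Skeletonize a binary mask by Zhang-Suen thinning
#'
#' @param mask logical (or 0/1) matrix.
#' @return Logical matrix of the same size containing the 1-px skeleton.
#' @export
skeletonize <- function(mask) {
  M <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      ## neighbours P2..P9 clockwise from north (row-1)
      P2 <- shiftMat(M, 1, 0);  P3 <- shiftMat(M, 1, -1)
      P4 <- shiftMat(M, 0, -1); P5 <- shiftMat(M, -1, -1)
      P6 <- shiftMat(M, -1, 0); P7 <- shiftMat(M, -1, 1)
      P8 <- shiftMat(M, 0, 1);  P9 <- shiftMat(M, 1, 1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
        (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
        (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (sub == 1) {
        cond <- M == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
      } else {
        cond <- M == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
      }
      if (any(cond)) { M[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  M == 1
}

## Build an igraph over skeleton pixels (8-connectivity, Euclidean weights).
## Vertices are named by linear pixel index.
skeletonGraph <- function(skel) {
  idx <- which(skel)
  if (!length(idx)) return(NULL)
  nr <- nrow(skel)
  pos <- arrayInd(idx, dim(skel))
  key <- setNames(seq_along(idx), idx)
  edges <- list(); weights <- numeric(0)
  offs <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (k in seq_len(nrow(offs))) {
    nb <- cbind(pos[, 1] + offs[k, 1], pos[, 2] + offs[k, 2])
    ok <- nb[, 1] >= 1 & nb[, 1] <= nr & nb[, 2] >= 1 & nb[, 2] <= ncol(skel)
    nb_idx <- (nb[, 2] - 1) * nr + nb[, 1]
    ok[ok] <- skel[nb_idx[ok]]
    if (any(ok)) {
      edges[[length(edges) + 1]] <- rbind(key[as.character(idx[ok])],
                                          key[as.character(nb_idx[ok])])
      weights <- c(weights, rep(sqrt(sum(offs[k, ]^2)), sum(ok)))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) {
    em <- do.call(cbind, edges)
    g <- igraph::add_edges(g, as.vector(em))
    igraph::E(g)$weight <- weights
  }
  igraph::V(g)$row <- pos[, 1]
  igraph::V(g)$col <- pos[, 2]
  g
}

## Fast 3x3 median filter via a 19-exchange sorting network, vectorized
## over the whole image (edge pixels use replicated borders).
median3x3 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- img[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  p <- vector("list", 9)
  k <- 1
  for (dc in 0:2) for (dr in 0:2) {
    p[[k]] <- pad[dr + seq_len(nr), dc + seq_len(nc)]
    k <- k + 1
  }
  sw <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  ## median-of-9 network (Smith); p[[5]] holds the median afterwards
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 2); sw(4, 5); sw(7, 8); sw(2, 3)
  sw(5, 6); sw(8, 9); sw(1, 4); sw(6, 9); sw(5, 8); sw(4, 7); sw(2, 5)
  sw(3, 6); sw(5, 8); sw(5, 3); sw(7, 5); sw(5, 3)
  p[[5]]
}
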