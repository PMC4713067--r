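# Small image-processing primitives shared by the generators and analyzers.
# Images are plain numeric matrices, rows = y, cols = x, 1-based indexing
# internally; user-facing pixel coordinates are 0-based (x = column, y = row).

#' @noRd
gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma))
  x <- -half:half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Dense 1-D blur operator with replicated (nearest) boundary handling.
#' @noRd
blur_operator <- function(n, sigma) {
  k <- gaussian_kernel_1d(sigma)
  half <- (length(k) - 1L) %/% 2L
  B <- matrix(0, n, n)
  for (j in seq_along(k)) {
    off <- j - half - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    B[cbind(seq_len(n), idx)] <- B[cbind(seq_len(n), idx)] + k[j]
  }
  B
}

#' Separable Gaussian blur of a matrix
#'
#' Replicate-padding at the borders; `sigma = 0` returns the input unchanged.
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return blurred matrix of the same shape.
#' @keywords internal
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  Br <- blur_operator(nrow(img), sigma)
  Bc <- blur_operator(ncol(img), sigma)
  Br %*% img %*% t(Bc)
}

# Binary dilation with a square structuring element of radius `margin` px.
#' @noRd
dilate_mask <- function(mask, margin) {
  if (margin <= 0) return(mask)
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (dr in -margin:margin) {
    rs <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    shifted_r <- mask[rs, , drop = FALSE]
    for (dc in -margin:margin) {
      cs <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
      out <- out | shifted_r[, cs, drop = FALSE]
    }
  }
  out
}

# Morphological closing (dilate then erode) with a square element; fills
# holes up to ~2*radius wide inside a mask.
#' @noRd
close_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  !dilate_mask(!dilate_mask(mask, radius), radius)
}

# Bilinear sample of `img` at fractional (row, col) positions (1-based).
# Positions outside the image are clamped to the border.
#' @noRd
bilinear_sample <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  row <- pmin(pmax(row, 1), nr)
  col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(row), nr - 1L); c0 <- pmin(floor(col), nc - 1L)
  fr <- row - r0; fc <- col - c0
  i00 <- img[cbind(r0, c0)]
  i10 <- img[cbind(r0 + 1, c0)]
  i01 <- img[cbind(r0, c0 + 1)]
  i11 <- img[cbind(r0 + 1, c0 + 1)]
  (1 - fr) * (1 - fc) * i00 + fr * (1 - fc) * i10 +
    (1 - fr) * fc * i01 + fr * fc * i11
}

# 8-connected component labelling by flood fill (images here are small).
#' @noRd
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((p - 1L) %% nr) + 1L
      c <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        q <- (cc - 1L) * nr + rr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# Zhang-Suen thinning: reduces a binary mask to a 1-px-wide skeleton.
# No skeletonizer exists in the installed R stack, so it is implemented here.
#' @noRd
thin_mask <- function(mask) {
  img <- mask * 1L
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- img
  neighbours <- function(P) {
    nr2 <- nrow(P); nc2 <- ncol(P)
    core <- function(dr, dc) P[(2:(nr2 - 1L)) + dr, (2:(nc2 - 1L)) + dc]
    list(p2 = core(-1, 0), p3 = core(-1, 1), p4 = core(0, 1), p5 = core(1, 1),
         p6 = core(1, 0), p7 = core(1, -1), p8 = core(0, -1), p9 = core(-1, -1))
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- neighbours(pad)
      B <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      seqn <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
      A <- 0
      for (i in 1:8) A <- A + (seqn[[i]] == 0L & seqn[[i + 1L]] == 1L)
      core <- pad[2:(nr + 1L), 2:(nc + 1L)]
      if (step == 1) {
        cond <- core == 1L & B >= 2 & B <= 6 & A == 1 &
          (nb$p2 * nb$p4 * nb$p6 == 0L) & (nb$p4 * nb$p6 * nb$p8 == 0L)
      } else {
        cond <- core == 1L & B >= 2 & B <= 6 & A == 1 &
          (nb$p2 * nb$p4 * nb$p8 == 0L) & (nb$p2 * nb$p6 * nb$p8 == 0L)
      }
      if (any(cond)) {
        core[cond] <- 0L
        pad[2:(nr + 1L), 2:(nc + 1L)] <- core
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[2:(nr + 1L), 2:(nc + 1L)] == 1L
}

# Endpoints of a skeleton: pixels with exactly one 8-connected neighbour.
#' @noRd
skeleton_endpoints <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- skel
  count <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    count <- count + pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  which(skel & count == 1L, arr.ind = TRUE)
}
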