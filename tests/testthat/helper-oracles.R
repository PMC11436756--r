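# Independent brute-force oracles used to validate the pipeline
# primitives. These deliberately share no code with the package: plain
# loops and first-principles definitions only.

random_mask <- function(nr, nc, p = 0.2) {
  matrix(runif(nr * nc) < p, nr, nc)
}

# flood-fill connected-component labeling (stack-based), connectivity 4/8
oracle_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbrs <- if (connectivity == 4L)
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else as.matrix(expand.grid(dy = -1:1, dx = -1:1))[-5, ]
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j)); lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nbrs))) {
        y <- p[1] + nbrs[k, 1]; x <- p[2] + nbrs[k, 2]
        if (y >= 1 && y <= nr && x >= 1 && x <= nc &&
            mask[y, x] && lab[y, x] == 0L) {
          lab[y, x] <- cur
          stack[[length(stack) + 1L]] <- c(y, x)
        }
      }
    }
  }
  lab
}

# multiset of component areas from an oracle labeling
oracle_area_multiset <- function(lab) sort(tabulate(lab[lab > 0L]))

# all-pairs nearest-foreground Euclidean distance, um
oracle_distance_map <- function(mask, pixel_size) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, nr, nc)
  if (nrow(fg) == 0L) return(out)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    out[i, j] <- sqrt(min((fg[, 1] - i)^2 + (fg[, 2] - j)^2)) * pixel_size
  }
  out
}

# explicit dilate-then-erode with a given 0/1 structuring element,
# background-padded (outside image treated as background)
oracle_close <- function(mask, elem) {
  r <- (nrow(elem) - 1L) %/% 2L
  nr <- nrow(mask); nc <- ncol(mask)
  big <- matrix(FALSE, nr + 4L * r, nc + 4L * r)
  big[(2L * r + 1L):(2L * r + nr), (2L * r + 1L):(2L * r + nc)] <- mask
  dil <- matrix(FALSE, nrow(big), ncol(big))
  for (j in (r + 1L):(ncol(big) - r)) for (i in (r + 1L):(nrow(big) - r)) {
    nb <- big[(i - r):(i + r), (j - r):(j + r)]
    dil[i, j] <- any(nb & elem)
  }
  ero <- matrix(FALSE, nrow(big), ncol(big))
  for (j in (r + 1L):(ncol(big) - r)) for (i in (r + 1L):(nrow(big) - r)) {
    nb <- dil[(i - r):(i + r), (j - r):(j + r)]
    ero[i, j] <- all(nb[elem == 1] )
  }
  ero[(2L * r + 1L):(2L * r + nr), (2L * r + 1L):(2L * r + nc)]
}

# point-in-polygon by angle-summing-free even-odd ray cast, per pixel centre
oracle_polygon_mask <- function(verts, shape) {
  out <- matrix(FALSE, shape[1], shape[2])
  n <- nrow(verts)
  for (r in seq_len(shape[1])) for (c in seq_len(shape[2])) {
    py <- r - 0.5; px <- c - 0.5
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      y1 <- verts[i, 1]; x1 <- verts[i, 2]
      y2 <- verts[j, 1]; x2 <- verts[j, 2]
      if ((y1 > py) != (y2 > py)) {
        xint <- (x2 - x1) * (py - y1) / (y2 - y1) + x1
        if (px < xint) inside <- !inside
      }
      j <- i
    }
    out[r, c] <- inside
  }
  out
}

# pooled-variance Student's t from the textbook formulas, two-tailed p
# via the incomplete-beta relation of the t distribution
oracle_t_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  x <- df / (df + t^2)
  p <- pbeta(x, df / 2, 0.5)  # = 2 * P(T > |t|)
  list(t = t, df = df, p = p)
}

# noiseless two-compartment test image: a 100-px cell of which 20 px are
# the compartment, on a background level
paint_cell_image <- function(nr = 40, nc = 40, cell_val = 10, comp_val = 30,
                             background = 0) {
  img <- matrix(background, nr, nc)
  cell <- matrix(FALSE, nr, nc); cell[11:20, 11:20] <- TRUE   # 100 px
  comp <- matrix(FALSE, nr, nc); comp[13:14, 11:20] <- TRUE   # 20 px
  img[cell] <- cell_val
  img[comp] <- comp_val
  list(img = img, cell = cell, comp = comp)
}

noiseless_scene <- function(...) {
  scene_config(poisson_on = FALSE, gaussian_sd = 0, ...)
}
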