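# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths: flood fill instead of union-find,
# explicit pair counting instead of ranks, explicit subset enumeration
# instead of the vectorised permutation machinery.

# Brute-force 8-connected labeling by breadth-first flood fill.
flood_fill_labels <- function(img) {
  nr <- nrow(img)
  nc <- ncol(img)
  labels <- matrix(0L, nr, nc)
  lab <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (img[i, j] > 0 && labels[i, j] == 0L) {
      lab <- lab + 1L
      queue <- list(c(i, j))
      labels[i, j] <- lab
      while (length(queue)) {
        p <- queue[[1]]
        queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di
          jj <- p[2] + dj
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              img[ii, jj] > 0 && labels[ii, jj] == 0L) {
            labels[ii, jj] <- lab
            queue[[length(queue) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  labels
}

# Same partition up to label renaming?
same_partition <- function(a, b) {
  if (!identical(dim(a), dim(b))) return(FALSE)
  nz <- a > 0
  if (!identical(nz, b > 0)) return(FALSE)
  if (!any(nz)) return(TRUE)
  key <- paste(a[nz], b[nz])
  length(unique(key)) == length(unique(a[nz])) &&
    length(unique(key)) == length(unique(b[nz]))
}

# Brute-force AUC by enumerating all case/control pairs.
pairwise_auc <- function(scores, labels, case) {
  d <- scores[labels == case]
  c <- scores[labels != case]
  tot <- 0
  for (x in d) for (y in c) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(d) * length(c))
}

# Brute-force exact two-sided permutation p by explicit subset loops.
brute_perm_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  obs <- abs(mean(x) - mean(y))
  idx <- utils::combn(length(pooled), n1)
  hits <- 0L
  for (k in seq_len(ncol(idx))) {
    g1 <- pooled[idx[, k]]
    g2 <- pooled[-idx[, k]]
    if (abs(mean(g1) - mean(g2)) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / ncol(idx)
}

# Single-disk ground truth centred in the FOV, densely labelled so the
# rendered support reflects the true geometry.
disk_truth <- function(d_nm, settings, spacing_nm = 11) {
  nf <- max(30L, as.integer(ceiling(pi * (d_nm / 2)^2 / spacing_nm^2)))
  tibble::tibble(
    truth_id = 1L,
    x_nm = fov_nm(settings)[1] / 2, y_nm = fov_nm(settings)[2] / 2,
    a_nm = d_nm / 2, b_nm = d_nm / 2, theta = 0,
    n_fluorophores = nf, class = "disk",
    d_true_nm = d_nm, circ_true = 1,
    mean_localizations = 3 * nf
  )
}

# Render + segment one simulated disk and return the measured
# equivalent diameter (nm) of its main component.
measure_disk <- function(d_nm, seed, sigma_nm = 5, render_pixel_nm = 15) {
  s <- acquisition_settings(fov_px = 24)
  locs <- simulate_localizations(disk_truth(d_nm, s), s,
                                 sigma_mean_nm = sigma_nm, sigma_sd_nm = 0,
                                 seed = seed)
  img <- render_localizations(locs, render_pixel_nm, settings = s)
  agg <- segment_aggregates(img, 5)
  agg$d_area_um[which.max(agg$n_locs)] * 1000
}
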