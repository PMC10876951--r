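# Independent brute-force oracles. These deliberately avoid the package's
# own algorithms: distances by exhaustive all-pairs minima, components by
# label propagation to a fixed point, perimeters by explicit neighbour
# counting.

# all-pairs minimum Euclidean distance (meters) to the target set
brute_min_dist <- function(values, target, res_m) {
  idx <- which(values == target, arr.ind = TRUE)
  nr <- nrow(values); nc <- ncol(values)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (co in seq_len(nc)) {
      out[r, co] <- sqrt(min((idx[, 1] - r)^2 + (idx[, 2] - co)^2)) * res_m
    }
  }
  out
}

# connected components by iterative minimum-label propagation
brute_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (co in seq_len(nc)) {
      if (!mask[r, co]) next
      for (o in offs) {
        r2 <- r + o[1]; c2 <- co + o[2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && mask[r2, c2] &&
            lab[r2, c2] < lab[r, co]) {
          lab[r, co] <- lab[r2, c2]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

# perimeter by counting exposed 4-edges of a pixel set
brute_perimeter <- function(pixels, res_m) {
  key <- paste(pixels[, 1], pixels[, 2])
  exposed <- 0L
  for (i in seq_len(nrow(pixels))) {
    for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      if (!(paste(pixels[i, 1] + o[1], pixels[i, 2] + o[2]) %in% key))
        exposed <- exposed + 1L
    }
  }
  exposed * res_m
}

# elevated-hazard flags by exhaustive pixel-pair enumeration
brute_hazard <- function(dmg_values, support_values, res_m,
                         min_sup_ha, adj_m) {
  sup_lab <- brute_components(!is.na(support_values) & support_values == 1, 8)
  keep <- matrix(FALSE, nrow(sup_lab), ncol(sup_lab))
  for (l in setdiff(unique(as.vector(sup_lab)), 0L)) {
    if (sum(sup_lab == l) * res_m^2 / 1e4 >= min_sup_ha)
      keep[sup_lab == l] <- TRUE
  }
  dmg_lab <- brute_components(!is.na(dmg_values) & dmg_values == 1, 8)
  sup_idx <- which(keep, arr.ind = TRUE)
  out <- list()
  for (l in setdiff(sort(unique(as.vector(dmg_lab))), 0L)) {
    px <- which(dmg_lab == l, arr.ind = TRUE)
    d <- Inf
    if (nrow(sup_idx)) {
      for (i in seq_len(nrow(px)))
        d <- min(d, sqrt((sup_idx[, 1] - px[i, 1])^2 +
                           (sup_idx[, 2] - px[i, 2])^2) * res_m)
    }
    out[[length(out) + 1L]] <- data.frame(
      area_ha = nrow(px) * res_m^2 / 1e4, dist = d, elevated = d <= adj_m)
  }
  do.call(rbind, out)
}

# random categorical grid helper
random_grid <- function(nr, nc, p_on = 0.3, res_m = 30) {
  fs_grid(matrix(rbinom(nr * nc, 1, p_on), nr, nc), res_m = res_m)
}
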