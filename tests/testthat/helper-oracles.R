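# Independent flood-fill oracle for patch labeling, written deliberately
# apart from the package's labeling kernel: breadth-first over explicit
# coordinate queues, labels in row-major first-encounter order.
flood_fill_oracle <- function(m, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    nb <- expand.grid(dr = -1:1, dc = -1:1)
    nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  } else {
    nb <- data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  cur <- 0L
  sizes <- integer(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!isTRUE(m[r, c] == 1) || lab[r, c] != 0L) next
    cur <- cur + 1L
    qr <- r; qc <- c
    lab[r, c] <- cur
    sz <- 0L
    while (length(qr)) {
      cr <- qr[1]; cc <- qc[1]
      qr <- qr[-1]; qc <- qc[-1]
      sz <- sz + 1L
      for (k in seq_len(nrow(nb))) {
        rr <- cr + nb$dr[k]; cc2 <- cc + nb$dc[k]
        if (rr >= 1 && rr <= nr && cc2 >= 1 && cc2 <= nc &&
            isTRUE(m[rr, cc2] == 1) && lab[rr, cc2] == 0L) {
          lab[rr, cc2] <- cur
          qr <- c(qr, rr); qc <- c(qc, cc2)
        }
      }
    }
    sizes[cur] <- sz
  }
  list(labels = lab, n_patches = cur, patch_sizes = sizes)
}

# canonical relabeling by row-major first encounter, so two labelings of the
# same partition compare equal regardless of label order
canonical_labels <- function(lab) {
  row_major <- as.vector(t(lab))
  first <- unique(row_major[row_major != 0])
  out <- lab
  for (i in seq_along(first)) out[lab == first[i]] <- i
  out
}

# random rectangular test landscape, optionally with an outside border
rand_landscape <- function(nr = 20, nc = nr, p = 0.4, cell_size = 30,
                           outside = FALSE) {
  m <- matrix(stats::rbinom(nr * nc, 1, p), nr, nc)
  if (outside) {
    m[1, ] <- NA
    m[, 1] <- NA
  }
  binary_landscape(m, cell_size = cell_size)
}
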