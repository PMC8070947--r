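# small constructors used throughout the suite

mk_grid <- function(nr = 4, nc = nr, cell = 100) iev_grid(nr, nc, cell)

mk_raster <- function(v, cell = 100) {
  m <- if (is.matrix(v)) v else matrix(v, nrow = 1)
  iev_raster(m, iev_grid(nrow(m), ncol(m), cell))
}

mk_cat <- function(m, n_states = max(m, na.rm = TRUE), id = NULL, cell = 100) {
  if (!is.matrix(m)) m <- matrix(m, nrow = 1)
  categorical_raster(m, max(2, n_states), iev_grid(nrow(m), ncol(m), cell), id = id)
}

mk_mask <- function(m, cell = 100) {
  if (!is.matrix(m)) m <- matrix(m, nrow = 1)
  region_mask(m, iev_grid(nrow(m), ncol(m), cell))
}

full_mask <- function(x) {
  g <- x$grid
  region_mask(matrix(TRUE, g$n_rows, g$n_cols), g)
}

# random m-state categorical layer on an nr x nc grid
rand_cat <- function(nr, nc, m, id = NULL) {
  mk_cat(matrix(sample.int(m, nr * nc, replace = TRUE), nr, nc),
         n_states = m, id = id)
}

# connected components of a mask under 4-neighbour adjacency (flood fill)
n_components <- function(mask) {
  m <- mask$member
  seen <- matrix(FALSE, nrow(m), ncol(m))
  comps <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (!m[i, j] || seen[i, j]) next
    comps <- comps + 1
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        p <- cur + d
        if (p[1] >= 1 && p[1] <= nrow(m) && p[2] >= 1 && p[2] <= ncol(m) &&
            m[p[1], p[2]] && !seen[p[1], p[2]]) {
          seen[p[1], p[2]] <- TRUE
          queue[[length(queue) + 1]] <- p
        }
      }
    }
  }
  comps
}
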