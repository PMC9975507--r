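# independent brute-force oracles and small fixtures used across tests

# stack-based 8-neighbour flood fill; deliberately a different algorithm
# from the package's union-find labeller
oracle_count_foci <- function(img, mask = NULL, band = c(20, 200),
                              min_size = 5) {
  if (is.null(mask)) mask <- matrix(1, nrow(img), ncol(img))
  fg <- mask == 1 & img >= band[1] & img <= band[2]
  visited <- matrix(FALSE, nrow(fg), ncol(fg))
  count <- 0L
  for (i in seq_len(nrow(fg))) {
    for (j in seq_len(ncol(fg))) {
      if (!fg[i, j] || visited[i, j]) next
      stack <- list(c(i, j))
      visited[i, j] <- TRUE
      size <- 0L
      while (length(stack) > 0L) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        size <- size + 1L
        for (di in -1L:1L) {
          for (dj in -1L:1L) {
            ii <- p[1] + di; jj <- p[2] + dj
            if (ii >= 1L && ii <= nrow(fg) && jj >= 1L && jj <= ncol(fg) &&
                fg[ii, jj] && !visited[ii, jj]) {
              visited[ii, jj] <- TRUE
              stack[[length(stack) + 1L]] <- c(ii, jj)
            }
          }
        }
      }
      if (size >= min_size) count <- count + 1L
    }
  }
  count
}

# noiseless standard curves for telomere tests
make_curve <- function(intercept, slope = -1 / log10(2)) {
  conc <- 100 / 3^(0:6)
  fit_standard_curve(conc, intercept + slope * log10(conc))
}

# tiny metadata: one condition, young controls + old test lines
small_meta <- function(n_test = 3L, n_ctrl = 4L) {
  data.frame(
    line_id = c(paste0("C", seq_len(n_ctrl)), paste0("T", seq_len(n_test))),
    condition = c(rep("young", n_ctrl), rep("old", n_test)),
    donor_age = c(rep(3, n_ctrl), 80 + seq_len(n_test)),
    stringsAsFactors = FALSE
  )
}

# measurement table with one component, given per-line replicate values
measurements_from <- function(values_by_line, meta,
                              component = "gH2AX_foci",
                              marker = "DNA_damage") {
  do.call(rbind, lapply(names(values_by_line), function(l) {
    v <- values_by_line[[l]]
    data.frame(line_id = l,
               condition = meta$condition[meta$line_id == l],
               marker = marker, component = component,
               replicate_id = seq_along(v), value = v, unit = "au",
               stringsAsFactors = FALSE)
  }))
}
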