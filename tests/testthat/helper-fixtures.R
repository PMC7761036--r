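# Builders for small in-memory fixtures used across test files.

make_peaks <- function(areas, linkages, rt = seq_along(areas)) {
  tibble::tibble(
    peak_id = paste0("p", seq_along(areas)),
    rt_min = rt,
    area = areas,
    spectrum = rep(list(NULL), length(areas)),
    linkage = linkages
  )
}

# A tiny PMAA reference library with distinctive fragment patterns.
make_library <- function() {
  list(
    list(linkage = "t-Araf",
         spectrum = cbind(mz = c(102, 118, 161), intensity = c(1, 0.8, 0.4)),
         rt_min = 10, rt_window = 0.5),
    list(linkage = "4-Glcp",
         spectrum = cbind(mz = c(102, 113, 118, 233), intensity = c(0.9, 1, 0.5, 0.3)),
         rt_min = 24, rt_window = 0.5),
    list(linkage = "4-GalAp",
         spectrum = cbind(mz = c(99, 135, 207), intensity = c(1, 0.7, 0.2)),
         rt_min = 26, rt_window = 0.5)
  )
}

# Write a peak CSV with given rows; returns the path.
write_peak_csv <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Random valid linkage profile over a vocabulary, for property tests.
random_profile <- function(vocab, n_linkages = NULL, fraction = "AIR") {
  if (is.null(n_linkages)) n_linkages <- sample(2:min(8, length(vocab)), 1)
  lks <- sample(vocab, n_linkages)
  v <- stats::runif(n_linkages)
  ord <- order(lks, method = "radix")
  linkage_profile(lks[ord], (100 * v / sum(v))[ord],
                  fraction = fraction, sum_tolerance = 1e-6)
}

table1_vocabulary <- function() {
  unique(unlist(default_assignment_table()$classes, use.names = FALSE))
}
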