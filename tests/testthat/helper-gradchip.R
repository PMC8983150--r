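# replicate vector with exactly the requested mean and SEM (sd = sem * sqrt(n))
make_replicates <- function(mean, sem, n) {
  z <- seq_len(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + z * sem * sqrt(n)
}

# printed seven-column gradient fractions (left-inlet drug, % of inlet)
published_fracs <- c(A = 99.9, B = 96.4, C = 82.0, D = 49.8,
                     E = 18.2, F = 3.3, G = 0.1)

# dose map built from the published fractions (600 uM TMZ left, 10 uM BAY right)
published_dose_map <- local({
  f <- published_fracs / 100
  dm <- data.frame(column = LETTERS[1:7],
                   frac_tmz = unname(f), dose_tmz_uM = unname(f) * 600,
                   frac_bay = unname(rev(f)), dose_bay_uM = unname(rev(f)) * 10,
                   stringsAsFactors = FALSE)
  class(dm) <- c("column_dose_map", "data.frame")
  dm
})

# one shared moderate-resolution gradient solve for the unit tests
grad100_cache <- new.env()
get_grad100 <- function() {
  if (is.null(grad100_cache$sol))
    grad100_cache$sol <- solve_gradient(chip_geometry(), cell_size_um = 100)
  grad100_cache$sol
}

# constant-viability replicate table covering columns A-G
flat_table <- function(viability, day = 7, n = 5, cell_line = "SYN") {
  do.call(rbind, lapply(LETTERS[1:7], function(cl)
    data.frame(cell_line = cell_line, column = cl, day = day,
               replicate = seq_len(n), viability = viability,
               stringsAsFactors = FALSE)))
}
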