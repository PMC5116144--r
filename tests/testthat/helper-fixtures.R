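# Reference scan conditions used across tests: standard C12, 10 um/s
# ablation, 0.270 s per point, 15 um between lines.
ref_params <- function() acq_params("C12", 10, 0.270, 15)

# Write a minimal line file from header + literal rows.
write_line_file <- function(path, header, rows) {
  writeLines(c(header, rows), path)
  path
}

# A raw_line built directly in code (bypassing files) for assembly tests.
raw_line_obj <- function(order_index, intensities, dt = 0.270) {
  n <- length(intensities[[1L]])
  structure(list(source_name = paste0("line ", order_index, ".xl"),
                 order_index = as.integer(order_index),
                 times = (seq_len(n) - 1L) * dt,
                 intensities = intensities),
            class = "raw_line")
}

# Positions data frame for n parallel lines.
positions_df <- function(n, orientation = "horizontal", spacing = 15,
                         scan_len = 100, reversed = rep(FALSE, n)) {
  cross <- (seq_len(n) - 1L) * spacing
  if (orientation == "horizontal") {
    data.frame(line_index = seq_len(n),
               x_start = ifelse(reversed, scan_len, 0),
               y_start = cross,
               x_end = ifelse(reversed, 0, scan_len),
               y_end = cross)
  } else {
    data.frame(line_index = seq_len(n),
               x_start = cross,
               y_start = ifelse(reversed, scan_len, 0),
               x_end = cross,
               y_end = ifelse(reversed, 0, scan_len))
  }
}
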