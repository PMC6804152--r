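# shared fixture builders (all fixtures are constructed in code)

make_peaks <- function(mz, intensity = 100) {
  tibble::tibble(mz = mz, intensity = rep_len(intensity, length(mz)))
}

make_spectrum <- function(mz, intensity = 100, precursor_mz = max(mz),
                          polarity = "negative", rt_min = NA_real_,
                          id = "test") {
  spectra_tbl(id, polarity, precursor_mz, rt_min,
              list(make_peaks(mz, intensity)))
}

lib_record <- function(lib, id) lib[lib$id == id, , drop = FALSE]

# independent brute-force enumeration of maximal loss chains: builds all
# sequences breadth-first, keeping a prefix only while every step lands on
# a peak; maximal = no single-loss extension matches
brute_force_paths <- function(peaks, start_mz, losses, config) {
  step_ok <- function(node, loss_mass) {
    target <- node - loss_mass
    if (target <= 0) return(NA_real_)
    ok <- peaks$intensity >= config$min_intensity &
      abs(1e6 * (peaks$mz - target) / target) <= config$ppm_fragment
    if (!any(ok)) return(NA_real_)
    target
  }
  frontier <- list(list(seq = character(0), node = start_mz))
  complete <- list()
  for (depth in seq_len(config$max_depth)) {
    nxt <- list()
    for (f in frontier) {
      extended <- FALSE
      for (i in seq_len(nrow(losses))) {
        target <- step_ok(f$node, losses$mass[i])
        if (!is.na(target)) {
          extended <- TRUE
          nxt[[length(nxt) + 1L]] <- list(seq = c(f$seq, losses$name[i]),
                                          node = target)
        }
      }
      if (!extended) complete[[length(complete) + 1L]] <- f
    }
    frontier <- nxt
    if (length(frontier) == 0L) break
  }
  # anything still extendable at the depth limit counts as (truncated) maximal
  complete <- c(complete, frontier)
  sort(vapply(complete, function(f) paste(f$seq, collapse = ";"), character(1)))
}
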