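# shared fixtures: built once per test run

canonical_track <- local({
  cache <- NULL
  function(n_units = 10) {
    key <- as.character(n_units)
    if (is.null(cache[[key]])) {
      pat <- make_drop_track(track_spec(n_units = n_units))
      cache[[key]] <<- list(pattern = pat, sources = pattern_sources(pat))
    }
    cache[[key]]
  }
})

disk_pattern <- function(radius = 10, n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  magnet_pattern(list(cbind(radius * cos(th), radius * sin(th))),
                 label = "disk",
                 meta = list(period = 2 * radius, direction = c(1, 0)))
}

sensing_field <- function(f_hz = 0.2) external_field(70, 70, f_hz)

# straight-track run helper: bead starts on the forward attractor
run_canonical <- function(d_um, f_hz = 0.2, n_periods = 5,
                          chi = bead_chi_default(d_um), n_units = 10) {
  ct <- canonical_track(n_units)
  lambda <- ct$pattern$meta$period
  bead <- magnetic_particle(d_um / 2, chi, pos = c(2 * lambda + 15, 0))
  simulate_transport(bead, ct$pattern, sensing_field(f_hz),
                     sim_config(duration = n_periods / f_hz),
                     sources = ct$sources)[[1]]
}
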