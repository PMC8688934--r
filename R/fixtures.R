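#' Named test fixtures
#'
#' Small, fast-converging parameterisations used by the test suite.
#'
#' * `"baseline"` - the full published baseline configuration (identical to
#'   `load_config` of an empty document).
#' * `"no-apical-GLUT2"` - baseline with the apical GLUT2 pool removed.
#' * `"dead-network"` - every transporter, channel and water pathway switched
#'   off, with identical lumen/blood compositions: all state derivatives are
#'   exactly zero.
#' * `"symmetric-membranes"` - identical channel sets and GLUT2 pools on both
#'   membranes, no SGLT1, no pump, symmetric baths: the two membrane
#'   potentials coincide.
#'
#' @param name fixture name.
#' @return A [model_config()].
#' @export
make_fixture <- function(name = c("baseline", "no-apical-GLUT2",
                                  "dead-network", "symmetric-membranes")) {
  name <- match.arg(name)
  base <- model_config()
  switch(name,
    "baseline" = base,
    "no-apical-GLUT2" = without_apical_glut2(base),
    "dead-network" = {
      cfg <- base
      cfg$sglt1$n_copies <- 0
      cfg$glut2_apical$n_copies <- 0
      cfg$glut2_basolateral$n_copies <- 0
      cfg$pump$n_copies <- 0
      cfg$channels <- lapply(cfg$channels, function(ch)
        channel_params(0, ch$valence, ch$membrane))
      cfg$water <- lapply(cfg$water, function(w)
        water_params(0, w$membrane, w$sigma))
      # identical baths so even a revived pathway would carry no gradient
      cfg$lumen <- list(na = 150, k = 5, cl = 150, hco3 = 0, glucose = 4,
                        ph = 7.4)
      cfg$blood_inflow <- cfg$lumen
      cfg
    },
    "symmetric-membranes" = {
      cfg <- base
      cfg$sglt1$n_copies <- 0
      cfg$pump$n_copies <- 0
      cfg$glut2_apical$n_copies <- 1e8
      cfg$glut2_basolateral$n_copies <- 1e8
      p <- 1e-18
      cfg$channels <- list(
        ap_na = channel_params(p, +1, "apical"),
        ap_k  = channel_params(p, +1, "apical"),
        ap_cl = channel_params(p, -1, "apical"),
        bl_na = channel_params(p, +1, "basolateral"),
        bl_k  = channel_params(p, +1, "basolateral"),
        bl_cl = channel_params(p, -1, "basolateral"),
        pc_na = channel_params(p / 10, +1, "paracellular"),
        pc_k  = channel_params(p / 10, +1, "paracellular"),
        pc_cl = channel_params(p / 10, -1, "paracellular"))
      cfg$lumen <- list(na = 150, k = 5, cl = 150, hco3 = 0, glucose = 4,
                        ph = 7.4)
      cfg$blood_inflow <- cfg$lumen
      cfg
    })
}
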