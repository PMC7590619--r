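#' Camphor-like toy adsorbate fixture
#'
#' A synthetic, desk-scale stand-in for a bulky ketone-on-metal system:
#' a seven-atom rigid molecule whose oxygen points along -z in the body
#' frame (so `beta = 0` poses are O-down and `beta = 180` poses H-down),
#' a one-layer fcc(111) slab, and eight energy minima records evaluated on
#' the bundled analytic adsorption surface — five deep O-down wells and
#' three shallow H-down wells, mirroring the two bonding classes the
#' workflow is designed to distinguish. Constructed entirely in code; all
#' energies come from [toy_adsorption_pes()].
#'
#' @param params A [toy_adsorption_params()].
#' @return List with `molecule` ([rigid_molecule()]), `slab`
#'   ([build_slab()]), `records` (tibble of 8 poses with `E_B`) and
#'   `backend`.
#' @export
camphor_fixture <- function(params = toy_adsorption_params()) {
  molecule <- toy_molecule()
  slab <- build_slab(slab_spec(3.632, n_layers = 1, repeats = c(1, 1),
                               vacuum = 20))
  zO <- params$z0_O; zH <- params$z0_H
  poses <- tibble(
    x     = c(0,   -0.5, 0.25, 0,    0.10, 0,    0,    0.30),
    y     = c(1/3,  1/6, 0.25, 0,    0.05, 1/3,  0,   -0.20),
    z     = c(zO, zO, zO, zO, zO,    zH, zH, zH),
    alpha = 0,
    beta  = c(0, 0, 0, 0, 0,        -180, -180, -180),
    gamma = c(0, 30, 0, 0, 45,       0, 0, 20)
  )
  poses$E_B <- toy_adsorption_pes(poses, params)
  list(molecule = molecule, slab = slab, records = poses,
       backend = toy_adsorption_backend(params))
}

#' @rdname camphor_fixture
#' @export
toy_molecule <- function() {
  rigid_molecule(
    elements = c("C", "C", "O", "H", "H", "H", "H"),
    coords = rbind(
      c(0.0,  0.0,  0.8),   # C1 (rotation-centre pair)
      c(0.0,  0.0, -0.8),   # C2
      c(0.0,  0.0, -2.0),   # O, points down in the body frame
      c(0.9,  0.0,  1.8),
      c(-0.9, 0.0,  1.8),
      c(0.0,  0.9,  1.8),
      c(0.0, -0.9,  1.8)
    ),
    center_atoms = c(1, 2)
  )
}
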