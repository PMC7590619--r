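# Shared toy surfaces and fixtures, all built in code.

double_well_backend <- function() {
  sp <- search_space("q", -1.5, 1.5)
  energy_backend(function(p) (p[[1]]^2 - 1)^2, sp, "double_well")
}

threefold_rotor_backend <- function(amplitude = 0.06) {
  sp <- search_space("gamma", -180, 180, periodic = TRUE)
  energy_backend(function(p) amplitude * (1 - cos(3 * p[[1]] * pi / 180)),
                 sp, "threefold_rotor")
}

# A methyl-like fragment: one carbon with three hydrogens of uneven lengths
# and angles, plus an anchor atom so center_atoms can be defined.
ragged_methyl <- function() {
  rigid_molecule(
    elements = c("C", "C", "H", "H", "H"),
    coords = rbind(
      c(0, 0, 1.5),                      # anchor carbon
      c(0, 0, 0),                        # methyl carbon
      1.05 * c(sin(1.9) * cos(0.1), sin(1.9) * sin(0.1), cos(1.9)),
      1.12 * c(sin(2.0) * cos(2.2), sin(2.0) * sin(2.2), cos(2.0)),
      1.09 * c(sin(1.85) * cos(4.1), sin(1.85) * sin(4.1), cos(1.85))
    ),
    center_atoms = c(1, 2)
  )
}

ch_lengths <- function(mol, cidx, hidx) {
  apply(mol$coords[hidx, , drop = FALSE], 1,
        function(h) sqrt(sum((h - mol$coords[cidx, ])^2)))
}

hch_angles <- function(mol, cidx, hidx) {
  u <- sweep(mol$coords[hidx, , drop = FALSE], 2, mol$coords[cidx, ])
  u <- u / sqrt(rowSums(u^2))
  combn(seq_along(hidx), 2, function(ij) {
    acos(sum(u[ij[1], ] * u[ij[2], ])) * 180 / pi
  })
}

random_pose <- function(n, seed = 1) {
  set.seed(seed)
  sp <- pose_space()
  m <- vapply(seq_len(nrow(sp)),
              function(j) runif(n, sp$lower[j], sp$upper[j]), numeric(n))
  m <- matrix(m, nrow = n, dimnames = list(NULL, sp$name))
  m
}
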