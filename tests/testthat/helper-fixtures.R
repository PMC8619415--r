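# Shared fixtures: reference device/oxide and meshes reused across tests.
# Meshes are deterministic, so building them once here is safe.

ref_device <- device()                              # design-parameter defaults
ref_oxide <- oxide_surface()                        # native SiO2 defaults
abrupt_device <- device(gauss_sigma_um = 0.005)     # abrupt-junction limit

mesh_default <- build_mesh(ref_device)
mesh_contact <- build_mesh(ref_device, n_nodes = 200, dx_surface = 1e-7)
mesh_abrupt <- build_mesh(abrupt_device, n_nodes = 400)

# paper-reported shift table for the DNA characterization: voltage
# sensitivity versus reference drain current
dna_shift_table <- data.frame(
  I_A = c(0.45, 0.50, 0.55, 0.60, 0.65) * 1e-3,
  shift_mV = c(29.38, 32.41, 35.40, 38.38, 41.40))

# CODATA constants for independent oracle arithmetic in tests
Q_E <- 1.602176634e-19
K_B <- 1.380649e-23
EPS0 <- 8.8541878128e-12
N_AV <- 6.02214076e23
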