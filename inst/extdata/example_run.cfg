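# Example pmfbind pipeline configuration (flat key = value dialect).
# Any key omitted here falls back to its documented default; unknown keys
# are rejected by name.

potential = open-like      # preset ground-truth potential for simulation
z_min = -49.5              # first window center, Angstrom
z_max = -7.5               # last window center, Angstrom
spacing = 0.5              # window spacing, Angstrom
force_constant = 10        # harmonic bias, kcal/(mol A^2)
bias_half = true           # U = (k/2)(z-z0)^2 convention
n_steps = 220000           # recorded samples per window
temperature = 310.15       # K
bin_width = 0.1            # histogram bin, Angstrom
burn_in_fraction = 0.090909090909  # discard first 2/22 of each window
tolerance = 1e-7           # WHAM convergence, kcal/mol
cylinder_radius = 10       # lateral restraint radius, Angstrom
bulk_width = 5             # bulk anchor width from the gate-side end, Angstrom
seed = 1                   # master seed (mandatory for pipeline runs)
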