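# motilitymap run configuration template
# Flat key = value pairs; '#' starts a comment. Units: s, um, uM, rad.
# Any key omitted keeps its documented default (see ?run_config).

seed = 1              # root RNG seed; all randomness derives from it
n_cells = 100         # cells in the simulated panel
duration = 120        # trajectory length (s)

# trajectory simulator (see ?swim_params, ?motor_params)
speed = 20            # run speed (um/s)
D_rot = 0.062         # rotational diffusion (rad^2/s)
depth = 10            # chamber z extent (um), reflecting boundaries
dt_sample = 0.1       # sampling interval (s), 10 Hz
dt_internal = 0.01    # heading-update integration step (s)
n_flagella = 1        # motors per cell (1 = validated default)
epsilon = 1.3         # motor base switching rate (1/s)
g = 40                # motor gain (dimensionless)
K_D = 3.06            # CheY-P dissociation constant at the motor (uM)

# classification and mapping
min_duration = 10     # discard tracks shorter than this (s)
tol = 0.01            # classifier outer-loop convergence tolerance
bandwidth = 0.2       # LOESS nearest-neighbor fraction
with_lna = TRUE       # include receptor-cluster signaling noise
verbosity = 1
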