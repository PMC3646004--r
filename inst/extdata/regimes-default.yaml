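# Default two-regime calibration for the synthetic trajectory generator.
# These are the package's reference values for a 'straight' (transiting)
# and an 'area_restricted' (slow, reversal-biased) movement regime; see the
# methods vignette for the reasoning behind each number. Units: turns in
# radians, step lengths in arbitrary planar length units per unit time.
straight:
  mu_turn: 0.0        # mean turn: directionally persistent travel
  kappa_turn: 10.0    # high von Mises concentration (circular SD ~ 18 deg)
  step_sd: 0.1        # SD of the step-length random-walk innovation
  step_init: 1.0      # first step of each straight segment
area_restricted:
  mu_turn: 3.141592653589793  # mean turn pi: reversal-biased foraging
  kappa_turn: 1.0             # broad turn distribution
  step_sd: 0.1
  step_init: 0.25             # slower movement during area-restricted bouts
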