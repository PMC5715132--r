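# Generator preset registry.
#
# Response probabilities are the published group-level PER response
# proportions (probability that a starved fly extends its proboscis within
# the 2 s scoring window after sucrose contact with the legs). Trace
# parameters describe the distance-trace generator: episode durations are
# the published group means with SDs back-computed from the published
# standard errors; tremor amplitude/frequency and sensor noise are
# calibrated quantities (see the package vignette) because the source
# assays quantify tremor only through the relative extra-path statistic.
#
# All times in seconds, distances in pixels, frequencies in Hz.

defaults:
  latency_s: 0.25
  duration_mean_s: 0.30
  duration_sd_s: 0.09
  amplitude_px: 30.0
  tremor_amplitude_px: 2.0
  tremor_freq_hz: 12.0
  noise_sd_px: 0.3
  frame_rate_hz: 200.0
  total_duration_s: 2.0
  ramp_frac: 0.25

traces:
  # no-transgene outcross control
  "TH/+": {}
  # wild-type human LRRK2: kinematics indistinguishable from control
  "TH>hLRRK2": {}
  # kinase-upregulated mutant: slower, more variable, doubled tremor
  "TH>G2019S":
    duration_mean_s: 0.57
    duration_sd_s: 0.40
    tremor_amplitude_px: 4.0
  # kinase-inhibitor feeding fully rescues speed and tremor
  "TH>G2019S+BMPPB-32": {}

assays:
  # young flies, dopaminergic driver, kinase-upregulated mutant vs control
  kinase_panel:
    "TH/+": 0.76
    "TH>G2019S": 0.35
  # second kinase-upregulated mutant vs its control
  i2020t_panel:
    "TH/+": 0.61
    "TH>I2020T": 0.35
  # independently generated transgene insertions
  independent_lines:
    "TH/+": 0.61
    "TH>hLRRK2": 0.52
    "TH>G2019S": 0.36
  # kinase-inhibitor feeding panel (2.5 uM in food from eclosion)
  kinase_inhibitors:
    "+/+": 0.73
    "TH>G2019S+vehicle": 0.32
    "TH>G2019S+LRRK2-IN-1": 0.47
    "TH>G2019S+BMPPB-32": 0.44
  # proportion of flies alive at 28 days (proportion arithmetic only)
  survival_28d:
    "TH/+": 0.80
    "TH>hLRRK2": 0.38
    "TH>G2019S": 0.53
    "TH>I2020T": 0.57
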