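# Genotype profile registry for the arbor/kymograph/FRAP simulator.
#
# lambda2: expected secondary count per region; p3: probability a secondary
# forms tertiary arms; mu4: expected quaternaries per tertiary arm.
# Expected whole-arbor totals are sum(lambda2) secondaries and
# 2 * sum(lambda2 * p3) * mu4 quaternaries.
#
# Wild-type and rab-10 totals are calibrated to the reported L4 genotype
# means (wild type 42 secondaries / 114 quaternaries; rab-10 mutants 28 /
# 17). Per-region splits and all other genotypes' parameters are estimates
# chosen to reproduce each genotype's described regional phenotype, not
# reported values.

wild_type:
  # dense menorahs in -1/+1/+2, sparse distal +3; sum(lambda2) = 42
  lambda2: {"-1": 10, "+1": 14, "+2": 14, "+3": 4}
  p3: {"-1": 0.9, "+1": 0.9, "+2": 0.9, "+3": 0.7}
  # 57/37: calibrated so 2 * 37 * mu4 = 114 expected quaternaries
  mu4: 1.5405405405405406
  defective_frac: 0.05
  polarity: {"-1": 0.9, "+1": 0.1, "+2": 0.1, "+3": 0.1, "axon": 0.95}
  frap: {f0: 0.2, f_inf: 0.8, tau: 30, noise_sd: 0.02}

rab_10:
  # anterior-shifted branching, reduced totals: sum(lambda2) = 28; most
  # posterior secondaries short/misoriented and failing the tertiary line
  lambda2: {"-1": 5, "+1": 6, "+2": 7, "+3": 10}
  p3: {"-1": 0.05, "+1": 0.05, "+2": 0.2, "+3": 0.55}
  # 17 / 14.9: calibrated so 2 * 7.45 * mu4 = 17 expected quaternaries
  mu4: 1.1409395973154362
  defective_frac: 0.6
  orient_sd_defective: 35
  polarity: {"-1": 0.9, "+1": 0.1, "+2": 0.1, "+3": 0.1, "axon": 0.95}
  frap: {f0: 0.2, f_inf: 0.45, tau: 80, noise_sd: 0.02}

dma_1:
  # near-total loss of menorahs; secondaries retained at a reduced rate
  lambda2: {"-1": 2, "+1": 3, "+2": 3, "+3": 2}
  p3: {"-1": 0, "+1": 0, "+2": 0, "+3": 0}
  mu4: 0
  defective_frac: 0.5
  frap: {f0: 0.2, f_inf: 0.7, tau: 40, noise_sd: 0.02}

exoc_8:
  # posterior loss of complexity, near-phenocopy of rab-10 with milder
  # secondary reduction in +2
  lambda2: {"-1": 5, "+1": 6, "+2": 11, "+3": 9}
  p3: {"-1": 0.1, "+1": 0.1, "+2": 0.35, "+3": 0.55}
  mu4: 1.2
  defective_frac: 0.45
  frap: {f0: 0.2, f_inf: 0.5, tau: 70, noise_sd: 0.02}

sec_5:
  # milder exocyst phenotype: secondaries spared, quaternaries reduced in
  # -1/+1/+2
  lambda2: {"-1": 9, "+1": 13, "+2": 13, "+3": 5}
  p3: {"-1": 0.5, "+1": 0.5, "+2": 0.6, "+3": 0.7}
  mu4: 0.9
  defective_frac: 0.2
  frap: {f0: 0.2, f_inf: 0.6, tau: 55, noise_sd: 0.02}

unc_116:
  # kinesin-1 hypomorph: severe loss of anterior branches, worst distally;
  # anterior microtubule polarity reversed to plus-end-out
  lambda2: {"-1": 10, "+1": 8, "+2": 4, "+3": 1}
  p3: {"-1": 0.85, "+1": 0.7, "+2": 0.5, "+3": 0.3}
  mu4: 1.3
  defective_frac: 0.2
  polarity: {"-1": 0.9, "+1": 0.85, "+2": 0.85, "+3": 0.85, "axon": 0.95}
  frap: {f0: 0.2, f_inf: 0.75, tau: 35, noise_sd: 0.02}

dhc_1:
  # dynein hypomorph: branches lost specifically in the distal anterior;
  # posterior complexity spared
  lambda2: {"-1": 10, "+1": 12, "+2": 7, "+3": 1}
  p3: {"-1": 0.9, "+1": 0.8, "+2": 0.5, "+3": 0.2}
  mu4: 1.4
  defective_frac: 0.1
  frap: {f0: 0.2, f_inf: 0.75, tau: 35, noise_sd: 0.02}

unc_116_rab_10:
  # double mutant: anterior shift suppressed; complexity highest in the
  # posterior regions (+1/-1) where microtubule minus-ends point
  lambda2: {"-1": 8, "+1": 9, "+2": 5, "+3": 2}
  p3: {"-1": 0.7, "+1": 0.7, "+2": 0.3, "+3": 0.15}
  mu4: 1.2
  defective_frac: 0.4
  polarity: {"-1": 0.9, "+1": 0.85, "+2": 0.85, "+3": 0.85, "axon": 0.95}
  frap: {f0: 0.2, f_inf: 0.5, tau: 70, noise_sd: 0.02}

dhc_1_rab_10:
  # conditional dynein knockdown in the rab-10 background: distal anterior
  # branches eliminated on top of the posterior rab-10 defect
  lambda2: {"-1": 5, "+1": 6, "+2": 7, "+3": 0.3}
  p3: {"-1": 0.1, "+1": 0.15, "+2": 0.3, "+3": 0.2}
  mu4: 1.1
  defective_frac: 0.5
  frap: {f0: 0.2, f_inf: 0.5, tau: 70, noise_sd: 0.02}

dma_1_rab_10:
  # double mutant: no menorahs and fewer secondaries than either single
  lambda2: {"-1": 1.5, "+1": 2, "+2": 2, "+3": 2}
  p3: {"-1": 0, "+1": 0, "+2": 0, "+3": 0}
  mu4: 0
  defective_frac: 0.6
  frap: {f0: 0.2, f_inf: 0.5, tau: 70, noise_sd: 0.02}
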