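# Monoisotopic mass constants. Residue masses are the standard amino-acid
# residue (dehydrated) monoisotopic masses; proton and water from CODATA-based
# elemental monoisotopic masses. Values fixed here so that mass arithmetic is
# self-contained and reproducible.

PROTON_MASS <- 1.00727646677
WATER_MASS  <- 18.0105646837

AA_MONO_MASS <- c(
  A = 71.037114, C = 103.009185, D = 115.026943, E = 129.042593,
  F = 147.068414, G = 57.021464, H = 137.058912, I = 113.084064,
  K = 128.094963, L = 113.084064, M = 131.040485, N = 114.042927,
  P = 97.052764, Q = 128.058578, R = 156.101111, S = 87.032028,
  T = 101.047678, V = 99.068414, W = 186.079313, Y = 163.063329
)

# Variable-modification mass deltas common in endogenous peptidomics:
# C-terminal amidation (-OH -> -NH2), methionine oxidation, and N-terminal
# pyro-glutamate formation from Gln (loss of NH3) or Glu (loss of H2O).
MOD_AMIDATION  <- -0.984016
MOD_OXIDATION  <- 15.994915
MOD_PYROGLU_Q  <- -17.026549
MOD_PYROGLU_E  <- -18.010565
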